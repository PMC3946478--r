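# External and relative validity indices against hand-derived values and
# brute-force direct-formula oracles.

table6 <- matrix(c(1118, 429, 1, 27,
                   100, 70, 3, 122,
                   76, 64, 16, 20), nrow = 4,
                 dimnames = list(class = 0:3, cluster = 0:2))

test_that("confusion matrix counts class-by-cluster memberships", {
  cm <- confusion_matrix(c(0, 0, 1, 1), c("A", "A", "B", "B"))
  expect_equal(unname(unclass(cm)), rbind(c(2L, 0L), c(0L, 2L)))

  cm1 <- confusion_matrix(c(0, 0, 0, 0), c("A", "A", "B", "B"))
  expect_equal(unname(unclass(cm1)), cbind(c(2L, 2L)))

  cm2 <- confusion_matrix(c(0, 0, 1, 1), c("A", "B", "A", "B"))
  expect_equal(unname(unclass(cm2)), rbind(c(1L, 1L), c(1L, 1L)))

  expect_error(confusion_matrix(c(0, 1), c("A")), "same length")
})

test_that("unassigned objects are excluded from external-index counts", {
  cm <- confusion_matrix(c(0, -1, 1, -1), c("A", "A", "B", "B"))
  expect_equal(sum(cm), 2)
  pc <- pair_counts(c(0, 0, 1, -1), c("A", "A", "B", "B"))
  expect_equal(pc$n, 3)
})

test_that("purity matches hand-derived values", {
  expect_equal(purity(confusion_matrix(c(0, 0, 1, 1), c("A", "A", "B", "B"))), 1)
  # one cluster holding 3 A and 3 B objects
  expect_equal(purity(matrix(c(3, 3), nrow = 2)), 0.5)
  # column maxima of the worked 4x3 matrix: 1118 + 122 + 76 = 1316
  expect_equal(purity(table6), 1316 / sum(table6))
})

test_that("entropy is 0 for pure clusterings and 1 for maximal confusion", {
  expect_equal(entropy(confusion_matrix(c(0, 0, 1, 1), c("A", "A", "B", "B"))), 0)
  expect_equal(entropy(matrix(c(3, 3), nrow = 2)), 1)
  expect_equal(entropy(matrix(c(5, 7), nrow = 1)), 0)  # single class
})

test_that("purity and entropy match the direct-formula oracle on random matrices", {
  set.seed(11)
  for (rep in 1:50) {
    cm <- matrix(rpois(12, 4), nrow = 3)
    if (sum(cm) == 0) next
    expect_equal(purity(cm), oracle_purity(cm))
    expect_equal(entropy(cm), oracle_entropy(cm))
  }
  expect_equal(entropy(table6), oracle_entropy(table6))
})

test_that("pair counts match hand enumeration and brute force", {
  pc <- pair_counts(c(0, 0, 1, 1), c("A", "A", "B", "B"))
  expect_equal(pc[c("a", "b", "c", "d")], list(a = 2, b = 0, c = 0, d = 4))

  pc2 <- pair_counts(c(0, 0, 1, 1), c("A", "B", "A", "B"))
  expect_equal(pc2[c("a", "b", "c", "d")], list(a = 0, b = 2, c = 2, d = 2))

  set.seed(7)
  for (rep in 1:30) {
    p <- random_partition(6, sample(2:3, 1))
    t <- random_partition(6, 2)
    got <- pair_counts(p, t)
    want <- oracle_pair_counts(p, t)
    expect_equal(got[c("a", "b", "c", "d")], want[c("a", "b", "c", "d")])
  }
})

test_that("pair-count conservation holds: a+b+c+d = N(N-1)/2", {
  set.seed(13)
  for (rep in 1:200) {
    n <- sample(2:20, 1)
    p <- random_partition(n, sample(2:4, 1))
    t <- random_partition(n, sample(2:4, 1))
    pc <- pair_counts(p, t)
    expect_equal(pc$a + pc$b + pc$c + pc$d, n * (n - 1) / 2)
  }
})

test_that("Rand/Jaccard/FM take their hand-derived values and stay in [0,1]", {
  pc <- pair_counts(c(0, 0, 1, 1), c("A", "A", "B", "B"))
  expect_equal(rand_index(pc), 1)
  expect_equal(jaccard_index(pc), 1)
  expect_equal(fowlkes_mallows(pc), 1)

  pc2 <- pair_counts(c(0, 0, 1, 1), c("A", "B", "A", "B"))
  expect_equal(rand_index(pc2), 1 / 3)
  expect_warning(expect_equal(jaccard_index(pc2), 0), NA)
  expect_equal(fowlkes_mallows(pc2), 0)

  set.seed(17)
  for (rep in 1:100) {
    n <- sample(4:15, 1)
    pc <- pair_counts(random_partition(n, 3), random_partition(n, 3))
    for (v in c(rand_index(pc), jaccard_index(pc), fowlkes_mallows(pc))) {
      expect_gte(v, 0)
      expect_lte(v, 1)
    }
  }
})

test_that("splitting a mixed cluster never decreases purity nor increases entropy", {
  truth <- c("A", "A", "A", "B", "B", "B", "C", "C")
  coarse <- c(1, 1, 1, 1, 1, 1, 2, 2)          # mixed cluster 1
  fine <- c(1, 1, 1, 3, 3, 3, 2, 2)            # split into pure sub-clusters
  expect_gte(purity(confusion_matrix(fine, truth)),
             purity(confusion_matrix(coarse, truth)))
  expect_lte(entropy(confusion_matrix(fine, truth)),
             entropy(confusion_matrix(coarse, truth)))
})

test_that("Dunn and diameter match hand geometry and scale invariance", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  part <- c(1, 1, 2, 2)
  expect_equal(dunn_index(pts, part), 10)
  expect_equal(max_diameter(pts, part), 1)
  expect_equal(dunn_index(pts * 3, part), 10)

  expect_true(is.na(dunn_index(pts, c(1, 1, 1, 1))))
  expect_equal(max_diameter(pts, c(1, 2, 3, 4)), 0)
  expect_equal(dunn_index(pts, c(1, 2, 3, 4)), Inf)
})

test_that("relative indices equal the brute-force oracles on random instances", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    data <- matrix(rnorm(n * 2), n, 2)
    part <- random_partition(n, sample(2:3, 1))
    expect_equal(dunn_index(data, part), oracle_dunn(data, part))
    expect_equal(max_diameter(data, part), oracle_max_diameter(data, part))
    expect_equal(davies_bouldin(data, part), oracle_davies_bouldin(data, part))
    expect_equal(rmsstd(data, part), oracle_rmsstd(data, part))
  }
})

test_that("merging two clusters never decreases the maximum diameter", {
  set.seed(29)
  for (rep in 1:20) {
    n <- 10
    data <- matrix(rnorm(n * 2), n, 2)
    part <- random_partition(n, 3)
    merged <- ifelse(part == 2, 1, part)
    expect_gte(max_diameter(data, merged), max_diameter(data, part))
  }
})

test_that("degenerate relative-index cases behave as documented", {
  pts <- rbind(c(0, 0), c(0, 0), c(0, 0))
  expect_equal(rmsstd(pts, c(1, 1, 1)), 0)
  expect_error(davies_bouldin(rbind(c(0, 0), c(0, 0)), c(1, 2)),
               "coincident centroids")
  # two tight, well-separated clusters: small Davies-Bouldin
  tight <- rbind(c(0, 0), c(0, 0.01), c(100, 0), c(100, 0.01))
  expect_lt(davies_bouldin(tight, c(1, 1, 2, 2)), 0.01)
})

test_that("data matrix reader handles label columns and rejects non-numeric data", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1.5,2,A", "3,4,B"), path)
  input <- read_data_matrix(path, labels = TRUE)
  expect_equal(dim(input$data), c(2, 2))
  expect_equal(input$truth, c("A", "B"))

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,x", "2,y"), path2)
  expect_error(read_data_matrix(path2), "non-numeric")
})
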