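# Instrumented clustering: K-Means (Lloyd) and DBSCAN runs that emit one
# iteration record per assign/update sweep (K-Means) or per core-object
# expansion round (DBSCAN), with the Dunn and diameter indices evaluated at
# every record.

#' Run K-Means and record an iteration trace
#'
#' Lloyd's algorithm with one record per assign-then-update sweep.  The
#' convergence flag is set when the within-cluster sum of squares (the
#' criterion) changes by at most `tol` between consecutive iterations, at
#' which point the run stops.  An empty cluster arising after assignment is
#' reseeded with the point farthest from its own cluster's centroid, keeping
#' the run deterministic under a fixed seed.
#'
#' @param data Numeric matrix or data frame, rows = objects.
#' @param k Number of clusters, `1 <= k <= nrow(data)`.
#' @param init Initialization: `"random"` (seeded sample of data points),
#'   `"farthest"` (farthest-point heuristic from the seeded first pick), or
#'   `"given"` with explicit `centers`.
#' @param centers Optional k x d matrix of initial centroids (implies
#'   `init = "given"`).
#' @param seed Integer seed for the initialization draw.
#' @param max_iter,tol Iteration cap and convergence tolerance on the
#'   criterion difference.
#' @return A `"cluster_trace"`; `deal = 1` throughout (K-Means allocates every
#'   object each sweep), `conv = 1` on the final record of a converged run.
#' @examples
#' pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
#' kmeans_trace(pts, k = 2, centers = rbind(c(0, 0), c(10, 0)))
#' @export
kmeans_trace <- function(data, k, init = c("random", "farthest", "given"),
                         centers = NULL, seed = NULL, max_iter = 100,
                         tol = 1e-6) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  n <- nrow(data)
  if (k < 1 || k > n) abort(sprintf("`k` must be in 1..%d (got %s).", n, k))
  if (max_iter < 1) abort("`max_iter` must be >= 1.")
  if (tol < 0) abort("`tol` must be >= 0.")
  if (!is.null(centers)) init <- "given"
  init <- match.arg(init)

  if (init == "given") {
    centers <- as.matrix(centers)
    if (nrow(centers) != k || ncol(centers) != ncol(data)) {
      abort("`centers` must be a k x d matrix.")
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    if (init == "random") {
      centers <- data[sample.int(n, k), , drop = FALSE]
    } else { # farthest-point heuristic
      picked <- sample.int(n, 1)
      while (length(picked) < k) {
        d2 <- apply(data, 1, function(x)
          min(colSums((t(data[picked, , drop = FALSE]) - x)^2)))
        picked <- c(picked, which.max(d2))
      }
      centers <- data[picked, , drop = FALSE]
    }
  }

  sq_dist_to <- function(cent) {
    # n x k matrix of squared distances
    vapply(seq_len(nrow(cent)), function(j)
      rowSums(sweep(data, 2, cent[j, ])^2), numeric(n))
  }

  records <- list()
  prev_assign <- NULL
  prev_crit <- NULL
  for (iter in seq_len(max_iter)) {
    d2 <- matrix(sq_dist_to(centers), nrow = n)
    assign <- max.col(-d2, ties.method = "first")
    # reseed empty clusters with the point farthest from its cluster centroid
    for (c in which(tabulate(assign, k) == 0)) {
      cand <- d2[cbind(seq_len(n), assign)]
      cand[tabulate(assign, k)[assign] <= 1] <- -Inf  # keep donors non-empty
      assign[which.max(cand)] <- c
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(data[assign == j, , drop = FALSE])
    }
    crit <- sum((data - centers[assign, , drop = FALSE])^2)
    conv <- as.integer(!is.null(prev_crit) && abs(crit - prev_crit) <= tol)
    records[[iter]] <- list(
      index = iter, assignment = as.integer(assign),
      rs = compute_rs(prev_assign, assign, k),
      conv = conv, deal = 1L,
      dunn = dunn_index(data, assign), diam = max_diameter(data, assign),
      criterion = crit
    )
    prev_assign <- assign
    prev_crit <- crit
    if (conv == 1L) break
  }

  new_trace(
    algorithm = "kmeans",
    parameters = list(k = k, init = init, seed = seed, max_iter = max_iter,
                      tol = tol),
    n_objects = n, k = k, records = records
  )
}

#' Run DBSCAN and record an iteration trace
#'
#' Density-based clustering with one record per core-object expansion round:
#' each round picks the lowest-id unvisited core object and absorbs its whole
#' density-reachable set into a new cluster.  Objects never reached stay
#' unassigned (`-1`, noise).  Every record carries `conv = 1` (a record is
#' taken once the current core object's density-reachable set is exhausted);
#' `deal` turns 1 once every object has been examined.  The criterion field
#' counts allocated objects.
#'
#' @param data Numeric matrix or data frame, rows = objects.
#' @param eps Neighbourhood radius (> 0).
#' @param min_pts Minimum neighbourhood size (self included) for a core
#'   object.
#' @return A `"cluster_trace"` with `k` = number of clusters found (0 if all
#'   noise, in which case a single all-unassigned record is emitted).
#' @export
dbscan_trace <- function(data, eps, min_pts) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (eps <= 0) abort("`eps` must be > 0.")
  if (min_pts < 1) abort("`min_pts` must be >= 1.")
  n <- nrow(data)
  dmat <- as.matrix(dist(data))
  neighbors <- lapply(seq_len(n), function(i) which(dmat[i, ] <= eps))

  assign <- rep(UNASSIGNED, n)
  visited <- rep(FALSE, n)
  cluster_id <- 0L
  snapshots <- list()   # assignment after each expansion round
  deal_flags <- integer(0)

  for (o in seq_len(n)) {
    if (visited[o]) next
    visited[o] <- TRUE
    if (length(neighbors[[o]]) < min_pts) next  # noise (may be claimed later)
    cluster_id <- cluster_id + 1L
    assign[o] <- cluster_id
    queue <- setdiff(neighbors[[o]], o)
    while (length(queue)) {
      q <- queue[[1]]
      queue <- queue[-1]
      if (assign[q] == UNASSIGNED) assign[q] <- cluster_id
      if (!visited[q]) {
        visited[q] <- TRUE
        if (length(neighbors[[q]]) >= min_pts) {
          queue <- c(queue, setdiff(neighbors[[q]], queue))
        }
      }
    }
    # all objects after this round that can never start a new cluster and are
    # already visited count as examined; deal = 1 once no unvisited remain
    snapshots[[length(snapshots) + 1L]] <- assign
    deal_flags[length(snapshots)] <- as.integer(all(
      visited | vapply(seq_len(n), function(i)
        length(neighbors[[i]]) < min_pts, logical(1))))
  }

  if (length(snapshots) == 0) {
    snapshots <- list(assign)
    deal_flags <- 1L
  } else if (deal_flags[length(deal_flags)] != 1L) {
    # trailing noise objects examined after the last expansion
    snapshots[[length(snapshots) + 1L]] <- assign
    deal_flags[length(snapshots)] <- 1L
  }

  k <- cluster_id
  prev <- NULL
  records <- lapply(seq_along(snapshots), function(i) {
    a <- snapshots[[i]]
    rec <- list(
      index = i, assignment = as.integer(a),
      rs = compute_rs(prev, a, max(k, 1L))[seq_len(max(k, 1L))],
      conv = 1L, deal = deal_flags[i],
      dunn = dunn_index(data, a), diam = max_diameter(data, a),
      criterion = sum(a != UNASSIGNED)
    )
    prev <<- a
    rec
  })
  if (k == 0) {
    records <- lapply(records, function(r) { r$rs <- integer(0); r })
  }

  new_trace(
    algorithm = "dbscan",
    parameters = list(eps = eps, min_pts = min_pts),
    n_objects = n, k = k, records = records
  )
}
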