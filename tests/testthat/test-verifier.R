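# Formula-set verdicts, satisfying-trace extraction, cause computation and
# object-level blame.

test_that("the property set holds the two validity formulas plus the AG variant", {
  fs <- validity_formulas()
  expect_equal(vapply(fs, `[[`, character(1), "name"),
               c("phi1", "phi1_effective", "phi2"))
  expect_equal(format(fs[[1]]$formula),
               "EF ((converge & handled) -> (maxDunn & minDiam))")
  expect_equal(format(fs[[3]]$formula),
               "E[DunnUp U maxDunn] & E[diamDown U minDiam]")
  expect_false(fs[[1]]$verdict)
  expect_true(fs[[2]]$verdict && fs[[3]]$verdict)
})

test_that("obligations hold everywhere on a monotone run and break at the dip", {
  fs <- validity_formulas()
  mono <- trace_to_ts(make_synthetic_trace("monotone", length = 8, seed = 1))
  for (entry in fs) {
    expect_equal(ctl_sat(mono, entry$obligation), paste0("S", 1:8))
  }
  dip <- trace_to_ts(make_synthetic_trace("dip", length = 8, t_star = 5,
                                          seed = 1))
  ok <- ctl_sat(dip, fs[[3]]$obligation)
  expect_equal(ok, paste0("S", 1:4))
})

test_that("the rise-then-fall counterexample yields T, C and cause as worked by hand", {
  tr <- make_synthetic_trace("dip", length = 8, t_star = 5, seed = 2)
  report <- verify_trace(tr)
  expect_false(report$valid)
  phi2 <- report$results$phi2
  expect_false(phi2$holds)
  expect_equal(phi2$T, paste0("S", 1:8))
  expect_equal(phi2$C_states, paste0("S", 1:4))
  expect_equal(phi2$cause, paste0("S", 5:8))
  expect_equal(report$real_causes, paste0("S", 5:8))
  # the literal EF implication formula holds vacuously and is flagged as
  # verdict-free
  expect_true(report$results$phi1$holds)
})

test_that("monotone and plateau runs are valid with empty causes", {
  for (pattern in c("monotone", "plateau")) {
    report <- verify_trace(make_synthetic_trace(pattern, length = 8, seed = 4))
    expect_true(report$valid)
    expect_length(report$real_causes, 0)
    expect_length(report$blamed_objects, 0)
  }
})

test_that("an empty formula list verifies as valid", {
  tr <- make_synthetic_trace("dip", length = 6, t_star = 4, seed = 1)
  expect_true(verify_trace(tr, formulas = list())$valid)
})

test_that("getSatisfyTrace collects the satisfying prefix and its transitions", {
  tr <- make_synthetic_trace("dip", length = 8, t_star = 5, seed = 1)
  ts <- trace_to_ts(tr)
  obligation <- validity_formulas()[[3]]$obligation
  got <- get_satisfy_trace(ts, obligation)
  expect_equal(got$states, paste0("S", 1:4))
  expect_equal(got$transitions[order(got$transitions[, 1]), , drop = FALSE],
               cbind(from = paste0("S", 1:3), to = paste0("S", 2:4)))
})

test_that("getSatisfyTrace handles the degenerate obligation regions", {
  ts <- trace_to_ts(make_synthetic_trace("monotone", length = 5, seed = 1))
  none <- get_satisfy_trace(ts, "false")
  expect_length(none$states, 0)
  expect_equal(nrow(none$transitions), 0)
  all_of_it <- get_satisfy_trace(ts, "true")
  expect_equal(all_of_it$states, paste0("S", 1:5))
  expect_equal(nrow(all_of_it$transitions), 5)  # 4 chain edges + self-loop
})

# hand-built trace for the blame algorithm: 6 iterations, 14 objects in two
# clusters; objects 7 and 12 switch at t = 5, object 3 additionally at t = 6
blame_fixture <- function() {
  base <- rep(c(1L, 2L), each = 7)
  assignments <- list(base, base, base, base)
  a5 <- base; a5[c(7, 12)] <- 3L - a5[c(7, 12)]
  a6 <- a5; a6[3] <- 3L - a6[3]
  assignments <- c(assignments, list(a5, a6))
  prev <- NULL
  records <- lapply(1:6, function(t) {
    rec <- list(index = t, assignment = assignments[[t]],
                rs = compute_rs(prev, assignments[[t]], 2),
                conv = as.integer(t == 6), deal = 1L,
                dunn = c(1, 2, 3, 4, 2, 1)[t],
                diam = c(6, 5, 4, 3, 5, 6)[t], criterion = 0)
    prev <<- assignments[[t]]
    rec
  })
  new_trace("synthetic", list(), 14, 2, records)
}

test_that("blame follows the movers through abnormal iterations to the last one", {
  tr <- blame_fixture()
  report <- verify_trace(tr)
  expect_false(report$valid)
  expect_equal(report$results$phi2$cause, paste0("S", 5:6))
  expect_true(all(c(7, 12, 3) %in% report$blamed_objects))
})

test_that("blame is empty when nothing moves in the violating suffix", {
  # indices dip at t = 3 but the assignments never change after t = 1
  base <- rep(c(1L, 2L), each = 2)
  records <- lapply(1:4, function(t) list(
    index = t, assignment = base,
    rs = if (t == 1) c(1L, 1L) else c(0L, 0L),
    conv = as.integer(t == 4), deal = 1L,
    dunn = c(1, 2, 1.5, 1)[t], diam = c(3, 2, 2.5, 3)[t], criterion = 0))
  tr <- new_trace("synthetic", list(), 4, 2, records)
  report <- verify_trace(tr)
  expect_false(report$valid)
  expect_length(report$blamed_objects, 0)
})

test_that("movers that settle under a recovered trend are judged beneficial", {
  # objects 1 and 2 move at t = 3 (the only violating iteration), the trend is
  # normal again at t = 4 and they stay put: no blame
  base <- rep(c(1L, 2L), each = 3)
  a3 <- base; a3[1:2] <- 3L - a3[1:2]
  assignments <- list(base, base, a3, a3, a3)
  prev <- NULL
  records <- lapply(1:5, function(t) {
    rec <- list(index = t, assignment = assignments[[t]],
                rs = compute_rs(prev, assignments[[t]], 2),
                conv = as.integer(t == 5), deal = 1L,
                dunn = c(1, 2, 1.5, 2.5, 3)[t],
                diam = c(4, 3, 3.5, 2.5, 2)[t], criterion = 0)
    prev <<- assignments[[t]]
    rec
  })
  tr <- new_trace("synthetic", list(), 6, 2, records)
  ok <- paste0("S", c(1, 2, 4, 5)) # obligation truth by construction
  ts <- trace_to_ts(tr)
  expect_equal(ctl_sat(ts, validity_formulas()[[3]]$obligation), ok)
  blamed <- check_iteration(tr, violating_iterations = 3,
                            obligation_ok = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_length(blamed, 0)
})

test_that("a violating first iteration seeds blame from the whole initial allocation", {
  base <- rep(c(1L, 2L), each = 2)
  blamed <- check_iteration(
    new_trace("synthetic", list(), 4, 2, lapply(1:2, function(t) list(
      index = t, assignment = base,
      rs = if (t == 1) c(1L, 1L) else c(0L, 0L),
      conv = as.integer(t == 2), deal = 1L, dunn = c(2, 1)[t],
      diam = c(1, 2)[t], criterion = 0))),
    violating_iterations = 1,
    obligation_ok = c(FALSE, FALSE)
  )
  expect_equal(blamed, 1:4)
})

test_that("cause states and satisfying states partition the error trace on linear runs", {
  set.seed(67)
  for (t_star in c(3, 5, 7)) {
    tr <- make_synthetic_trace("dip", length = 8, t_star = t_star,
                               seed = t_star)
    report <- verify_trace(tr)
    phi2 <- report$results$phi2
    expect_setequal(c(phi2$C_states, phi2$cause), phi2$T)
    expect_length(intersect(phi2$C_states, phi2$cause), 0)
    # verdict consistency
    expect_false(report$valid)
    expect_gt(length(phi2$cause), 0)
  }
})

test_that("reports render to schema-stable JSON and readable text", {
  tr <- make_synthetic_trace("dip", length = 8, t_star = 5, seed = 2)
  report <- verify_trace(tr)
  path <- withr::local_tempfile(fileext = ".json")
  render_report(report, "json", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_false(obj$valid)
  expect_equal(unlist(obj$real_causes), paste0("S", 5:8))
  expect_equal(length(obj$properties), 3)

  txt <- render_report(report, "text")
  expect_match(txt, "verdict: invalid")
  expect_match(txt, "phi2: fails")

  valid_report <- verify_trace(make_synthetic_trace("monotone", 6, seed = 1))
  obj2 <- jsonlite::fromJSON(render_report(valid_report, "json"),
                             simplifyVector = FALSE)
  expect_true(obj2$valid)
  expect_length(obj2$real_causes, 0)

  expect_error(render_report(report, "xml"))
})

test_that("tidy and glance summarize verification reports", {
  report <- verify_trace(make_synthetic_trace("dip", length = 8, t_star = 5,
                                              seed = 2))
  td <- tidy(report)
  expect_equal(nrow(td), 3)
  expect_named(td, c("property", "formula", "holds", "verdict_bearing",
                     "cause"))
  gl <- glance(report)
  expect_false(gl$valid)
  expect_equal(gl$n_failing, 2)
  expect_equal(gl$n_cause_states, 4)
})

test_that("blame runtime grows linearly with iterations times objects", {
  mk <- function(L, n) {
    base <- rep(c(1L, 2L), length.out = n)
    prev <- NULL
    records <- lapply(seq_len(L), function(t) {
      a <- base
      if (t > 1) a[(t %% n) + 1] <- 3L - a[(t %% n) + 1]
      rec <- list(index = t, assignment = a, rs = compute_rs(prev, a, 2),
                  conv = as.integer(t == L), deal = 1L,
                  dunn = 1, diam = 1, criterion = 0)
      prev <<- a
      rec
    })
    new_trace("synthetic", list(), n, 2, records)
  }
  time_of <- function(L, n) {
    tr <- mk(L, n)
    ok <- rep(FALSE, L)
    min(vapply(1:3, function(i)
      system.time(check_iteration(tr, 2, ok))[["elapsed"]], numeric(1)))
  }
  t_small <- time_of(50, 50)
  t_big <- time_of(500, 50)
  expect_lt(t_big, max(0.25, 40 * t_small))
})
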