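# Seeded synthetic inputs: Gaussian-blob datasets, fabricated index-series
# traces (monotone / dip / plateau patterns), and traces with planted
# misbehaving objects carrying ground-truth blame sets.  Pattern fixtures
# generate their index series directly, for exact control over the trend the
# verifier sees; planted-blame traces recompute every index from the
# perturbed geometry, for end-to-end realism.

#' Specification of a Gaussian-blob dataset
#'
#' @param k Number of clusters (>= 1).
#' @param n Objects per cluster (>= 1).
#' @param d Dimension (>= 1).
#' @param sigma Within-cluster spread (standard deviation per coordinate,
#'   > 0).
#' @param sep Separation between the closest pair of cluster centers, in
#'   units of `sigma` (>= 0).
#' @param seed Integer seed.
#' @return A `"blob_spec"` list.
#' @export
blob_spec <- function(k, n, d = 2, sigma = 1, sep = 10, seed = NULL) {
  stopifnot(k >= 1, n >= 1, d >= 1, sigma > 0, sep >= 0)
  structure(list(k = k, n = n, d = d, sigma = sigma, sep = sep, seed = seed),
            class = "blob_spec")
}

#' Generate Gaussian blobs
#'
#' Draws `k` isotropic Gaussian clusters of `n` points each.  Cluster centers
#' sit on a circle in the first two coordinates (a line for `d = 1`) with
#' radius chosen so the closest pair of centers is `sep * sigma` apart;
#' reproducible under `seed`.
#'
#' @param spec A [blob_spec()].
#' @return A list with `data` (numeric `(k*n) x d` matrix) and `truth`
#'   (integer labels 1..k).
#' @examples
#' b <- make_blobs(blob_spec(k = 3, n = 20, seed = 1))
#' dim(b$data)
#' @export
make_blobs <- function(spec) {
  stopifnot(inherits(spec, "blob_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  centers <- matrix(0, spec$k, spec$d)
  gap <- spec$sep * spec$sigma
  if (spec$k > 1) {
    if (spec$d == 1) {
      centers[, 1] <- (seq_len(spec$k) - 1) * gap
    } else {
      radius <- gap / (2 * sin(pi / spec$k))
      theta <- 2 * pi * (seq_len(spec$k) - 1) / spec$k
      centers[, 1] <- radius * cos(theta)
      centers[, 2] <- radius * sin(theta)
    }
  }
  data <- do.call(rbind, lapply(seq_len(spec$k), function(c) {
    matrix(rnorm(spec$n * spec$d, sd = spec$sigma), spec$n, spec$d) +
      matrix(centers[c, ], spec$n, spec$d, byrow = TRUE)
  }))
  list(data = data, truth = rep(seq_len(spec$k), each = spec$n))
}

#' Fabricate an iteration trace with a controlled index trend
#'
#' Builds a trace whose Dunn series follows the requested pattern, with the
#' diameter series mirrored (falling where Dunn rises): `"monotone"` rises
#' strictly to the end, `"dip"` rises through `t_star - 1` and falls strictly
#' from `t_star`, `"plateau"` rises and then holds its maximum.  The final
#' record carries `conv = 1` and `deal = 1`; assignments are fabricated (one
#' object oscillates between clusters on intermediate iterations, and for
#' dips two extra objects switch clusters at `t_star`) so the rs flags are
#' consistent with real membership changes.
#'
#' @param pattern `"monotone"`, `"dip"` or `"plateau"`.
#' @param length Number of iterations (>= 2).
#' @param t_star Dip onset (2 <= t_star <= length), dip pattern only.
#' @param seed Integer seed for the series jitter.
#' @param n_objects,k Shape of the fabricated assignments.
#' @return A `"cluster_trace"`.
#' @export
make_synthetic_trace <- function(pattern = c("monotone", "dip", "plateau"),
                                 length = 8, t_star = NULL, seed = NULL,
                                 n_objects = 8, k = 2) {
  pattern <- match.arg(pattern)
  L <- as.integer(length)
  if (L < 2) abort("`length` must be >= 2.")
  if (pattern == "dip") {
    if (is.null(t_star)) t_star <- max(2L, L - 3L)
    if (t_star < 2 || t_star > L) {
      abort(sprintf("`t_star` must be in 2..%d.", L))
    }
  }
  if (!is.null(seed)) set.seed(seed)

  rise <- function(m) cumsum(stats::runif(m, 0.05, 0.15))
  dunn <- switch(pattern,
    monotone = 0.5 + rise(L),
    plateau = {
      top <- ceiling(L / 2)
      up <- 0.5 + rise(top)
      c(up, rep(up[top], L - top))
    },
    dip = {
      up <- 0.5 + rise(t_star - 1)
      fall <- numeric(L - t_star + 1)
      remaining <- up[t_star - 1]
      for (i in seq_along(fall)) {
        remaining <- remaining * stats::runif(1, 0.6, 0.8)
        fall[i] <- remaining
      }
      c(up, fall)
    }
  )
  diam <- max(dunn) * 1.2 + 0.5 - dunn

  base <- rep(seq_len(k), length.out = n_objects)
  assignments <- vector("list", L)
  assignments[[1]] <- base
  for (t in 2:L) {
    a <- assignments[[t - 1]]
    if (t < L) {
      a[1] <- if (a[1] == 1) 2L else 1L         # one oscillating object
      if (pattern == "dip" && t == t_star && n_objects >= 3) {
        a[2:3] <- ifelse(a[2:3] == 1, 2L, 1L)   # the dip's movers
      }
    }
    assignments[[t]] <- a
  }

  prev <- NULL
  records <- lapply(seq_len(L), function(t) {
    rec <- list(index = t, assignment = as.integer(assignments[[t]]),
                rs = compute_rs(prev, assignments[[t]], k),
                conv = as.integer(t == L), deal = 1L,
                dunn = dunn[t], diam = diam[t],
                criterion = diam[t])
    prev <<- assignments[[t]]
    rec
  })
  new_trace(
    algorithm = "synthetic",
    parameters = list(pattern = pattern, t_star = t_star, seed = seed),
    n_objects = n_objects, k = k, records = records
  )
}

#' Plant misbehaving objects into a K-Means trace
#'
#' Takes a clustering trace over a data matrix and perturbs it from iteration
#' `t_star` onward by moving the given objects to the next cluster; by
#' default the planted objects oscillate (move on every second iteration,
#' ending displaced on the final one), the signature of objects a distance
#' metric cannot settle.  All index series, criterion values and rs flags are
#' recomputed from the perturbed assignments over `data`, the trace is padded
#' with converged iterations if it is shorter than `t_star + 2`, and the
#' final record carries `conv = 1`.  The planted objects' assignments always
#' differ between `t_star - 1` and `t_star`.
#'
#' @param trace A `"cluster_trace"` (typically from [kmeans_trace()]).
#' @param data The numeric data matrix the trace was computed on.
#' @param t_star First perturbed iteration (>= 2).
#' @param objects Object identifiers to displace (may be empty, in which case
#'   the trace is returned unperturbed).
#' @param oscillate If `TRUE` (default) the planted objects alternate between
#'   displaced and home clusters; if `FALSE` they move once and stay.
#' @return A `"planted_trace"`: list with `trace` (the perturbed
#'   `"cluster_trace"`), `t_star`, and `planted` (the ground-truth blame
#'   set).
#' @export
plant_blame <- function(trace, data, t_star, objects, oscillate = TRUE) {
  validate_trace(trace)
  if (length(objects) == 0) {
    return(structure(list(trace = trace, t_star = t_star, planted = integer(0)),
                     class = "planted_trace"))
  }
  if (t_star < 2) abort("`t_star` must be >= 2.")
  data <- as.matrix(data)
  if (!all(objects %in% trace$object_ids)) {
    abort("`objects` must be existing object identifiers.")
  }
  k <- trace$k
  L <- max(base::length(trace$records), t_star + 2L)
  if ((L - t_star) %% 2 == 1) L <- L + 1L  # end on a displaced iteration

  base_assign <- function(t) {
    recs <- trace$records
    recs[[min(t, base::length(recs))]]$assignment
  }
  rows <- match(objects, trace$object_ids)
  assignments <- vector("list", L)
  for (t in seq_len(L)) {
    a <- base_assign(t)
    flipped <- t >= t_star && (!oscillate || (t - t_star) %% 2 == 0)
    if (flipped) {
      for (r in rows) {
        src <- a[r]
        if (sum(a == src) == 1) {
          abort(sprintf("moving object %d at iteration %d would empty cluster %d.",
                        trace$object_ids[r], t, src))
        }
        a[r] <- (src %% k) + 1L
      }
    }
    assignments[[t]] <- as.integer(a)
  }

  prev <- NULL
  records <- lapply(seq_len(L), function(t) {
    a <- assignments[[t]]
    centers <- t(vapply(seq_len(k), function(c)
      colMeans(data[a == c, , drop = FALSE]), numeric(ncol(data))))
    rec <- list(index = t, assignment = a,
                rs = compute_rs(prev, a, k),
                conv = as.integer(t == L), deal = 1L,
                dunn = dunn_index(data, a), diam = max_diameter(data, a),
                criterion = sum((data - centers[a, , drop = FALSE])^2))
    prev <<- a
    rec
  })
  perturbed <- new_trace(
    algorithm = trace$algorithm,
    parameters = c(trace$parameters,
                   list(planted_at = t_star, oscillate = oscillate)),
    n_objects = trace$n_objects, k = k, records = records,
    object_ids = trace$object_ids
  )
  structure(list(trace = perturbed, t_star = t_star,
                 planted = sort(as.integer(objects))),
            class = "planted_trace")
}

#' @export
print.planted_trace <- function(x, ...) {
  cat(sprintf("<planted_trace: %d planted objects from iteration %d>\n",
              base::length(x$planted), x$t_star))
  print(x$trace)
  invisible(x)
}
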