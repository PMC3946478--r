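# Iteration traces: the verifier's raw input.
#
# A trace is an ordered list of per-iteration snapshots of a clustering run.
# Instrumented K-Means and DBSCAN produce traces natively; any other
# algorithm can be verified by writing the versioned JSON interchange format
# read by `read_trace()`.

TRACE_SCHEMA_VERSION <- "1.0"

#' Construct an iteration trace
#'
#' Low-level constructor; most users obtain traces from [kmeans_trace()],
#' [dbscan_trace()], [read_trace()] or the synthetic generators.  Each record
#' is a list with fields `index` (1-based ordinal), `assignment` (cluster id
#' per object, `-1` = unassigned), `rs` (k binary flags, `rs[i] = 1` iff
#' cluster i's member set changed versus the previous record; in the first
#' record every non-empty cluster is flagged, matching the initial condition
#' that no object has yet been disposed of), `conv` and `deal` (binary
#' convergence / all-objects-allocated flags), `dunn` and `diam` (index
#' values, `NA` = undefined), and `criterion` (the algorithm's objective).
#'
#' @param algorithm Name of the producing algorithm.
#' @param parameters Named list of run parameters.
#' @param n_objects,k Number of objects and clusters.
#' @param records List of iteration records.
#' @param object_ids Stable object identifiers (default 1-based row ordinals).
#' @return An object of class `"cluster_trace"`.
#' @export
new_trace <- function(algorithm, parameters, n_objects, k, records,
                      object_ids = seq_len(n_objects)) {
  tr <- structure(
    list(algorithm = algorithm, parameters = parameters,
         n_objects = as.integer(n_objects), k = as.integer(k),
         object_ids = as.integer(object_ids), records = records),
    class = "cluster_trace"
  )
  validate_trace(tr)
  tr
}

record_fields <- c("index", "assignment", "rs", "conv", "deal",
                   "dunn", "diam", "criterion")

#' Validate the structure of an iteration trace
#'
#' Checks field presence, types and lengths for every record; errors name the
#' offending field and record index.
#'
#' @param trace A `"cluster_trace"` object (or plain list in the same shape).
#' @return The trace, invisibly.
#' @export
validate_trace <- function(trace) {
  for (f in c("algorithm", "parameters", "n_objects", "k", "object_ids",
              "records")) {
    if (is.null(trace[[f]])) abort(sprintf("trace is missing field `%s`.", f))
  }
  if (length(trace$records) < 1) abort("trace has no records.")
  if (length(trace$object_ids) != trace$n_objects) {
    abort("`object_ids` length does not match `n_objects`.")
  }
  for (i in seq_along(trace$records)) {
    rec <- trace$records[[i]]
    for (f in record_fields) {
      if (is.null(rec[[f]])) {
        abort(sprintf("record %d is missing field `%s`.", i, f))
      }
    }
    if (length(rec$assignment) != trace$n_objects) {
      abort(sprintf("record %d: `assignment` has length %d, expected %d.",
                    i, length(rec$assignment), trace$n_objects))
    }
    if (length(rec$rs) != trace$k) {
      abort(sprintf("record %d: `rs` has length %d, expected k = %d.",
                    i, length(rec$rs), trace$k))
    }
    for (f in c("conv", "deal")) {
      if (!rec[[f]] %in% c(0, 1)) {
        abort(sprintf("record %d: `%s` must be 0 or 1.", i, f))
      }
    }
    if (i > 1) {
      prev <- trace$records[[i - 1]]
      if (rec$conv < prev$conv) {
        abort(sprintf("record %d: `conv` decreases along the trace.", i))
      }
      if (rec$deal < prev$deal) {
        abort(sprintf("record %d: `deal` decreases along the trace.", i))
      }
    }
  }
  invisible(trace)
}

#' @export
print.cluster_trace <- function(x, ...) {
  last <- x$records[[length(x$records)]]
  cat(sprintf(
    "<cluster_trace: %s, %d objects, k = %d, %d iterations (conv=%d, deal=%d)>\n",
    x$algorithm, x$n_objects, x$k, length(x$records), last$conv, last$deal))
  print(tidy(x), ...)
  invisible(x)
}

#' @export
length.cluster_trace <- function(x) length(x$records)

#' Tidy an iteration trace
#'
#' One row per iteration: the binary flags, index series, objective, and the
#' number of objects whose cluster changed versus the previous record.
#'
#' @param x A `"cluster_trace"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cluster_trace
#' @export
tidy.cluster_trace <- function(x, ...) {
  prev <- c(list(NULL), lapply(x$records[-length(x$records)], `[[`, "assignment"))
  purrr::map2_dfr(x$records, prev, function(rec, pa) {
    tibble(
      iteration = rec$index,
      conv = as.integer(rec$conv), deal = as.integer(rec$deal),
      dunn = as.numeric(rec$dunn), diam = as.numeric(rec$diam),
      criterion = as.numeric(rec$criterion),
      n_changed = if (is.null(pa)) sum(!is_unassigned(rec$assignment))
                  else sum(rec$assignment != pa),
      clusters_changed = sum(rec$rs == 1)
    )
  })
}

# rs flags: rs[i] = 1 iff cluster i's member set differs from the previous
# record; first record flags every non-empty cluster.
compute_rs <- function(prev_assignment, assignment, k, cluster_ids = seq_len(k)) {
  vapply(cluster_ids, function(c) {
    now <- which(assignment == c)
    if (is.null(prev_assignment)) {
      as.integer(length(now) > 0)
    } else {
      before <- which(prev_assignment == c)
      as.integer(!identical(now, before))
    }
  }, integer(1))
}

#' Recompute rs flags from the assignment history
#'
#' Used to check the rs-consistency invariant of any trace.
#'
#' @param trace A `"cluster_trace"`.
#' @return A list of integer vectors, one per record.
#' @export
recompute_rs <- function(trace) {
  prev <- NULL
  out <- vector("list", length(trace$records))
  for (i in seq_along(trace$records)) {
    a <- trace$records[[i]]$assignment
    out[[i]] <- compute_rs(prev, a, trace$k)
    prev <- a
  }
  out
}

#' Write / read a trace in the JSON interchange format
#'
#' The schema is versioned and intentionally algorithm-agnostic so that runs
#' of third-party algorithms (BIRCH, SOM, ...) can be verified: top-level
#' fields `schema_version`, `algorithm`, `parameters`, `n_objects`, `k`,
#' `object_ids`, and `records`, each record with `index`, `assignment`, `rs`,
#' `conv`, `deal`, `dunn`, `diam`, `criterion`.  Unassigned objects are
#' encoded as `-1`; undefined index values as `null`.
#'
#' @param trace A `"cluster_trace"`.
#' @param path File path.
#' @return `read_trace()` returns a validated `"cluster_trace"`.
#' @export
write_trace <- function(trace, path) {
  validate_trace(trace)
  obj <- list(
    schema_version = TRACE_SCHEMA_VERSION,
    algorithm = trace$algorithm,
    parameters = trace$parameters,
    n_objects = trace$n_objects,
    k = trace$k,
    object_ids = trace$object_ids,
    records = lapply(trace$records, function(rec) {
      list(index = rec$index,
           assignment = as.integer(rec$assignment),
           rs = as.integer(rec$rs),
           conv = as.integer(rec$conv), deal = as.integer(rec$deal),
           dunn = if (is.na(rec$dunn)) NA else as.numeric(rec$dunn),
           diam = if (is.na(rec$diam)) NA else as.numeric(rec$diam),
           criterion = as.numeric(rec$criterion))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("algorithm", "n_objects", "k", "object_ids", "records")) {
    if (is.null(obj[[f]])) abort(sprintf("trace file is missing field `%s`.", f))
  }
  records <- lapply(seq_along(obj$records), function(i) {
    rec <- obj$records[[i]]
    for (f in record_fields) {
      if (!f %in% names(rec) ||
          (is.null(rec[[f]]) && !f %in% c("dunn", "diam"))) {
        abort(sprintf("record %d is missing field `%s`.", i, f))
      }
    }
    num_or_na <- function(x) {
      if (is.null(x) || (length(x) == 1 && is.na(x))) NA_real_ else as.numeric(x)
    }
    list(index = as.integer(rec$index),
         assignment = vapply(rec$assignment, as.integer, integer(1)),
         rs = if (length(rec$rs)) vapply(rec$rs, as.integer, integer(1))
              else integer(0),
         conv = as.integer(rec$conv), deal = as.integer(rec$deal),
         dunn = num_or_na(rec$dunn), diam = num_or_na(rec$diam),
         criterion = as.numeric(rec$criterion))
  })
  new_trace(algorithm = obj$algorithm,
            parameters = obj$parameters %||% list(),
            n_objects = as.integer(obj$n_objects), k = as.integer(obj$k),
            records = records,
            object_ids = vapply(obj$object_ids, as.integer, integer(1)))
}
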