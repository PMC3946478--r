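# The verifier: formula-set verdict, satisfying-trace extraction, cause
# computation (error trace minus satisfying sub-trace), and object-level
# blame by iteration comparison.

#' The CTL validity property set
#'
#' Three entries, each pairing a CTL formula with the per-state obligation
#' used for counterexample localization:
#' \describe{
#'   \item{phi1}{`EF ((converge & handled) -> (maxDunn & minDiam))` -- when
#'     the run has converged and every object is disposed of, the Dunn index
#'     attains its maximum and the diameter its minimum.  Reported for
#'     fidelity but excluded from the verdict: an `EF` over an implication is
#'     satisfied by any state falsifying the antecedent, so it holds
#'     vacuously on almost every trace.}
#'   \item{phi1_effective}{The `AG` form of the same implication, which is
#'     the universal reading of the convergence requirement; used for the
#'     verdict.}
#'   \item{phi2}{`E[DunnUp U maxDunn] & E[diamDown U minDiam]` -- the Dunn
#'     index rises until it peaks and the diameter falls until it bottoms
#'     out; used for the verdict.}
#' }
#' Obligations are propositional: for the implication formulas the
#' implication itself; for phi2,
#' `(DunnUp | maxDunn) & (diamDown | minDiam)`.
#'
#' @return A list of entries with elements `name`, `formula`
#'   (`"ctl_formula"`), `obligation` (`"ctl_formula"`), and `verdict`
#'   (does a failure invalidate the run?).
#' @export
validity_formulas <- function() {
  obligation1 <- ctl_parse("(converge & handled) -> (maxDunn & minDiam)")
  obligation2 <- ctl_parse("(DunnUp | maxDunn) & (diamDown | minDiam)")
  list(
    list(name = "phi1",
         formula = ctl_parse("EF ((converge & handled) -> (maxDunn & minDiam))"),
         obligation = obligation1, verdict = FALSE),
    list(name = "phi1_effective",
         formula = ctl_parse("AG ((converge & handled) -> (maxDunn & minDiam))"),
         obligation = obligation1, verdict = TRUE),
    list(name = "phi2",
         formula = ctl_parse("E[DunnUp U maxDunn] & E[diamDown U minDiam]"),
         obligation = obligation2, verdict = TRUE)
  )
}

#' Satisfying sub-trace of an obligation (backward closure)
#'
#' Seeds with the states of `V` where the obligation holds, then repeatedly
#' pops an unvisited seed and collects every incoming transition, enqueueing
#' its source (backward closure over the whole graph, per the literal
#' worklist formulation).  On the linear systems the verifier builds, with a
#' prefix-closed obligation region, the collected states are exactly the
#' maximal satisfying prefix.
#'
#' @param ts A `"transition_system"`.
#' @param obligation A propositional `"ctl_formula"` (or string).
#' @param V State ids to seed from (default: all states).
#' @return A list with `transitions` (two-column character matrix) and
#'   `states` (seed states plus endpoints of collected transitions, in state
#'   order).
#' @export
get_satisfy_trace <- function(ts, obligation, V = ts$states) {
  if (is.character(obligation)) obligation <- ctl_parse(obligation)
  seeds <- intersect(V, ctl_sat(ts, obligation))
  idx <- setNames(seq_along(ts$states), ts$states)
  worklist <- as.integer(idx[seeds])
  visited <- logical(length(ts$states))
  transitions <- matrix(character(0), ncol = 2,
                        dimnames = list(NULL, c("from", "to")))
  while (length(worklist)) {
    vj <- worklist[[1]]
    worklist <- worklist[-1]
    if (visited[vj]) next
    visited[vj] <- TRUE
    for (vi in ts$pred[[vj]]) {
      worklist <- c(worklist, vi)
      transitions <- rbind(transitions, c(ts$states[vi], ts$states[vj]))
    }
  }
  states <- ts$states[ts$states %in% union(seeds, as.vector(transitions))]
  list(transitions = transitions, states = states)
}

#' Blame objects for violating iterations
#'
#' Starting at the first violating iteration t, collects the objects whose
#' cluster at t differs from t-1 (at t = 1, against the empty initial
#' allocation, so every assigned object counts).  If the index trend is
#' normal again at t+1 (the obligation holds there), objects whose cluster
#' does not change again between t and t+1 are dropped -- their move is
#' judged beneficial.  If the trend is still abnormal at t+1, the procedure
#' recurses on t+1 and unions the results, except that when t+1 is the final
#' iteration the objects newly changed there are added instead.  Runs in
#' O(r n) for r iterations examined and n objects.
#'
#' @param trace A `"cluster_trace"`.
#' @param violating_iterations Integer iteration ordinals that violate the
#'   property (typically the cause states of [verify_trace()]).
#' @param obligation_ok Logical vector, one entry per iteration: does the
#'   per-state obligation hold there?
#' @return Sorted integer vector of blamed object identifiers.
#' @export
check_iteration <- function(trace, violating_iterations, obligation_ok) {
  L <- length(trace$records)
  stopifnot(length(obligation_ok) == L)
  if (length(violating_iterations) == 0) return(integer(0))
  assignment <- function(t) trace$records[[t]]$assignment
  changed_at <- function(t) {
    a <- assignment(t)
    if (t == 1) {
      # against the empty initial allocation: every assigned object changed
      trace$object_ids[!is_unassigned(a)]
    } else {
      trace$object_ids[a != assignment(t - 1)]
    }
  }
  acc <- integer(0)
  t <- min(violating_iterations)
  repeat {   # forward walk, one step per abnormal iteration
    object_set <- changed_at(t)
    if (t >= L) {
      acc <- union(acc, object_set)
      break
    }
    if (obligation_ok[t + 1]) {
      # trend normal next: keep only objects that move again
      acc <- union(acc, intersect(object_set, changed_at(t + 1)))
      break
    }
    if (t + 1 < L) {
      acc <- union(acc, object_set)
      t <- t + 1
    } else {
      acc <- union(acc, union(object_set, changed_at(t + 1)))
      break
    }
  }
  sort(unique(acc))
}

#' Verify a clustering run against the CTL validity properties
#'
#' Builds the labelled linear transition system of the trace, checks every
#' property, and on violation localizes the cause: the error trace T is the
#' execution path, the satisfying sub-trace C comes from
#' [get_satisfy_trace()] with the property's per-state obligation, and the
#' cause is T minus C.  The verdict is valid iff every verdict-bearing
#' property holds; when it is not, the objects driving the violation are
#' blamed with [check_iteration()].  A failed property whose cause set is
#' empty is flagged as an initial-allocation error (a misallocation present
#' from the very first iteration and never corrected), which iteration
#' comparison cannot localize.
#'
#' @param trace A `"cluster_trace"`.
#' @param formulas Property set in the shape of [validity_formulas()].
#' @param blame Run object-level blame on violating iterations?
#' @return An object of class `"cluster_verification"`: fields `valid`,
#'   `results` (per-formula), `real_causes` (state ids), `blamed_objects`,
#'   and `notes` (narrative log).
#' @examples
#' tr <- make_synthetic_trace("dip", length = 8, t_star = 5, seed = 1)
#' verify_trace(tr)
#' @export
verify_trace <- function(trace, formulas = validity_formulas(), blame = TRUE) {
  validate_trace(trace)
  ts <- trace_to_ts(trace)
  notes <- character(0)
  results <- list()
  real_causes <- character(0)
  blamed <- integer(0)
  for (entry in formulas) {
    holds <- ctl_check(ts, entry$formula)
    res <- list(name = entry$name, formula = format(entry$formula),
                verdict = entry$verdict, holds = holds,
                T = character(0), C_states = character(0),
                C_transitions = matrix(character(0), ncol = 2),
                cause = character(0), initial_allocation = FALSE)
    if (!holds) {
      res$T <- ts$states
      satisfy <- get_satisfy_trace(ts, entry$obligation, ts$states)
      res$C_states <- satisfy$states
      res$C_transitions <- satisfy$transitions
      res$cause <- setdiff(ts$states, satisfy$states)
      notes <- c(notes, sprintf(
        "%s fails: T = (%s); C = (%s); cause = T - C = (%s).",
        entry$name, paste(res$T, collapse = ","),
        paste(res$C_states, collapse = ","),
        paste(res$cause, collapse = ",")))
      if (length(res$cause) == 0) {
        res$initial_allocation <- TRUE
        notes <- c(notes, sprintf(
          "%s: empty cause with the obligation holding everywhere -- an initial-allocation error, outside the scope of iteration comparison.",
          entry$name))
      }
      if (entry$verdict) {
        real_causes <- union(real_causes, res$cause)
        if (blame && length(res$cause)) {
          ok <- ts$states %in% ctl_sat(ts, entry$obligation)
          blamed <- union(blamed, check_iteration(
            trace, match(res$cause, ts$states), ok))
        }
      }
    }
    results[[entry$name]] <- res
  }
  real_causes <- ts$states[ts$states %in% real_causes]
  valid <- all(vapply(results, function(r) r$holds || !r$verdict, logical(1)))
  structure(
    list(valid = valid, results = results, real_causes = real_causes,
         blamed_objects = sort(blamed), notes = notes,
         n_iterations = length(trace$records), algorithm = trace$algorithm),
    class = "cluster_verification"
  )
}

#' @export
print.cluster_verification <- function(x, ...) {
  cat(sprintf("<cluster_verification: %s run, %d iterations -- %s>\n",
              x$algorithm, x$n_iterations,
              if (x$valid) "VALID" else "INVALID"))
  print(tidy(x))
  if (length(x$real_causes)) {
    cat("causes:", paste(x$real_causes, collapse = ", "), "\n")
  }
  if (length(x$blamed_objects)) {
    cat("blamed objects:", paste(x$blamed_objects, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a verification report
#'
#' @param x A `"cluster_verification"`.
#' @param ... Unused.
#' @return A tibble with one row per property: name, formula, whether it
#'   holds, whether it bears on the verdict, and the cause states.
#' @method tidy cluster_verification
#' @export
tidy.cluster_verification <- function(x, ...) {
  purrr::map_dfr(x$results, function(r) {
    tibble(property = r$name, formula = r$formula, holds = r$holds,
           verdict_bearing = r$verdict,
           cause = paste(r$cause, collapse = ","))
  })
}

#' @rdname tidy.cluster_verification
#' @return `glance()` returns a one-row tibble: verdict, number of failing
#'   properties, cause and blame counts.
#' @method glance cluster_verification
#' @export
glance.cluster_verification <- function(x, ...) {
  tibble(
    valid = x$valid,
    n_properties = length(x$results),
    n_failing = sum(!vapply(x$results, `[[`, logical(1), "holds")),
    n_cause_states = length(x$real_causes),
    n_blamed_objects = length(x$blamed_objects)
  )
}

#' Serialize a verification report
#'
#' @param report A `"cluster_verification"`.
#' @param format `"json"` or `"text"`.
#' @param path Optional output file; otherwise the rendition is returned.
#' @return A character scalar (text) or JSON string, invisibly if written.
#' @export
render_report <- function(report, format = c("json", "text"), path = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      schema_version = "1.0",
      valid = report$valid,
      algorithm = report$algorithm,
      n_iterations = report$n_iterations,
      properties = lapply(unname(report$results), function(r) {
        list(name = r$name, formula = r$formula, holds = r$holds,
             verdict_bearing = r$verdict,
             error_trace = as.list(r$T),
             satisfying_states = as.list(r$C_states),
             cause = as.list(r$cause),
             initial_allocation = r$initial_allocation)
      }),
      real_causes = as.list(report$real_causes),
      blamed_objects = as.list(report$blamed_objects),
      notes = as.list(report$notes)
    )
    out <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    out <- paste(c(
      sprintf("verdict: %s", if (report$valid) "valid" else "invalid"),
      vapply(report$results, function(r)
        sprintf("  %s: %s", r$name, if (r$holds) "holds" else "fails"),
        character(1)),
      if (length(report$real_causes))
        sprintf("causes: %s", paste(report$real_causes, collapse = ", ")),
      if (length(report$blamed_objects))
        sprintf("blamed objects: %s",
                paste(report$blamed_objects, collapse = ", ")),
      report$notes
    ), collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(as.character(out), path)
    return(invisible(out))
  }
  out
}
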