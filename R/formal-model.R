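# Program graphs and Kripke-style transition systems.
#
# A clustering run is abstracted as a program graph over binary variables
# (guarded transitions fired by the two core clustering actions, `compare`
# and `allocate`), which unfolds into a finite transition system; the actual
# run is one path in that system.  `trace_to_ts()` builds the labelled linear
# system the verifier checks, with six atomic propositions over the
# convergence flags and the Dunn/diameter series.

ATOMIC_PROPS <- c("converge", "handled", "DunnUp", "maxDunn", "diamDown",
                  "minDiam")

#' Construct a program graph
#'
#' A program graph is a directed graph over locations whose edges carry a
#' guard on a finite (here binary) variable valuation and an action; firing
#' an enabled edge applies the action's effect to the valuation.  Effects may
#' list several possible outcome valuations, modelling data-dependent
#' branches (e.g. whether the criterion converges after an allocation).
#'
#' @param locations Character vector of location names.
#' @param actions Character vector of action names.
#' @param variables Named list: variable name -> vector of admissible values
#'   (all binary here).
#' @param transitions List of edges, each a list with `from`, `to`, `action`,
#'   `guard` (function(valuation) -> logical), `effect`
#'   (function(valuation) -> list of outcome valuations), and a human-readable
#'   `label`.
#' @param loc0 Initial locations.
#' @param g0 Initial condition, function(valuation) -> logical.
#' @return An object of class `"program_graph"`.
#' @export
program_graph <- function(locations, actions, variables, transitions, loc0,
                          g0) {
  vars <- names(variables)
  for (tr in transitions) {
    stopifnot(tr$from %in% locations, tr$to %in% locations,
              tr$action %in% actions)
  }
  structure(list(locations = locations, actions = actions,
                 variables = variables, transitions = transitions,
                 loc0 = loc0, g0 = g0),
            class = "program_graph")
}

#' @export
print.program_graph <- function(x, ...) {
  cat(sprintf("<program_graph: %d locations, %d guarded transitions, vars: %s>\n",
              length(x$locations), length(x$transitions),
              paste(names(x$variables), collapse = ", ")))
  invisible(x)
}

#' Program graph of the K-Means iteration loop
#'
#' Variables are the k change flags `rs[i]` (1 iff cluster i's members
#' changed) and the convergence flag `conv`, all binary.  The initial
#' condition is `rs[i] = 0` for every i and `conv = 0`: no object has been
#' disposed of and no cluster holds any object.  `compare` never changes the
#' valuation; `allocate` under `conv = 0` flips change flags on (and may or
#' may not converge the criterion, a data-dependent branch); once `conv = 1`
#' the clusters are frozen and `allocate` clears the change flags.
#'
#' @param k Number of clusters (>= 1).
#' @return A `"program_graph"`.
#' @export
kmeans_program_graph <- function(k) {
  if (k < 1) abort("`k` must be >= 1.")
  rs_names <- paste0("rs", seq_len(k))
  vars <- c(setNames(rep(list(0:1), k), rs_names), list(conv = 0:1))
  set_rs <- function(eta, val) { eta[rs_names] <- val; eta }
  transitions <- list(
    list(from = "loop", to = "loop", action = "compare",
         guard = function(eta) TRUE,
         effect = function(eta) list(eta),
         label = "compare: valuation unchanged"),
    list(from = "loop", to = "loop", action = "allocate",
         guard = function(eta) eta$conv == 0,
         effect = function(eta) {
           changed <- set_rs(eta, 1)
           converged <- changed
           converged$conv <- 1
           list(changed, converged)
         },
         label = "allocate [conv=0]: clusters change; criterion may converge"),
    list(from = "loop", to = "loop", action = "allocate",
         guard = function(eta) eta$conv == 1,
         effect = function(eta) list(set_rs(eta, 0)),
         label = "allocate [conv=1]: clusters frozen")
  )
  program_graph(
    locations = "loop", actions = c("compare", "allocate"),
    variables = vars, transitions = transitions, loc0 = "loop",
    g0 = function(eta) all(unlist(eta[rs_names]) == 0) && eta$conv == 0
  )
}

#' Program graph of the DBSCAN expansion loop
#'
#' Variables: `conv` (all density-reachable objects of the current core
#' object found) and `deal` (all objects allocated), both binary.  Under
#' `deal = 0`, `allocate` grows the current cluster and may exhaust the
#' current core object's reachable set (`conv = 1`) or finish all objects
#' (`deal = 1`); with `conv = 1, deal = 0` a new core object starts a new
#' round; once `conv = 1` and `deal = 1` the locations never change.
#'
#' @return A `"program_graph"`.
#' @export
dbscan_program_graph <- function() {
  transitions <- list(
    list(from = "expand", to = "expand", action = "compare",
         guard = function(eta) TRUE,
         effect = function(eta) list(eta),
         label = "compare: valuation unchanged"),
    list(from = "expand", to = "expand", action = "allocate",
         guard = function(eta) eta$deal == 0,
         effect = function(eta) list(
           list(conv = 0, deal = 0),          # reachable set still growing
           list(conv = 1, deal = 0),          # current core exhausted
           list(conv = 1, deal = 1)           # all objects allocated
         ),
         label = "allocate [deal=0]: grow cluster / exhaust core / finish"),
    list(from = "expand", to = "expand", action = "allocate",
         guard = function(eta) eta$conv == 1 && eta$deal == 0,
         effect = function(eta) list(list(conv = 0, deal = 0)),
         label = "allocate [conv=1, deal=0]: start next core object"),
    list(from = "expand", to = "expand", action = "allocate",
         guard = function(eta) eta$conv == 1 && eta$deal == 1,
         effect = function(eta) list(eta),
         label = "allocate [conv=1, deal=1]: frozen")
  )
  program_graph(
    locations = "expand", actions = c("compare", "allocate"),
    variables = list(conv = 0:1, deal = 0:1),
    transitions = transitions, loc0 = "expand",
    g0 = function(eta) eta$conv == 0 && eta$deal == 0
  )
}

# ---- transition systems -----------------------------------------------------

#' Construct a transition system (Kripke structure)
#'
#' @param states Character vector of state ids.
#' @param edges Two-column matrix (from, to) of state ids.
#' @param initial Character vector of initial state ids.
#' @param ap Character vector: the atomic propositions.
#' @param labels Named list: state id -> character vector of propositions
#'   true there.
#' @param enforce_totality Add a self-loop to states with no successor
#'   (terminal states of a finished run).
#' @return An object of class `"transition_system"`.
#' @export
transition_system <- function(states, edges, initial, ap, labels,
                              enforce_totality = TRUE) {
  stopifnot(all(initial %in% states))
  edges <- matrix(as.character(edges), ncol = 2)
  if (nrow(edges) > 0 &&
      (!all(edges[, 1] %in% states) || !all(edges[, 2] %in% states))) {
    abort("edge endpoints must be declared states.")
  }
  succ <- rep(list(integer(0)), length(states))
  if (nrow(edges) > 0) {
    from <- match(edges[, 1], states)
    to <- match(edges[, 2], states)
    by_from <- split(to, from)
    succ[as.integer(names(by_from))] <- lapply(by_from, unique)
  }
  if (enforce_totality) {
    for (i in seq_along(states)) {
      if (length(succ[[i]]) == 0) succ[[i]] <- i
    }
  }
  pred <- rep(list(integer(0)), length(states))
  src <- rep(seq_along(succ), lengths(succ))
  dst <- unlist(succ)
  if (length(dst)) {
    by_to <- split(src, dst)
    pred[as.integer(names(by_to))] <- by_to
  }
  lab_at <- match(states, names(labels))
  labels <- lapply(seq_along(states), function(i) {
    l <- if (is.na(lab_at[i])) character(0) else labels[[lab_at[i]]]
    if (!all(l %in% ap)) {
      abort(sprintf("state %s labelled with unknown proposition.", states[i]))
    }
    sort(unique(l))
  })
  names(labels) <- states
  structure(list(states = states, succ = succ, pred = pred,
                 initial = initial, ap = ap, labels = labels),
            class = "transition_system")
}

#' @export
print.transition_system <- function(x, ...) {
  cat(sprintf("<transition_system: %d states, %d transitions, AP = {%s}>\n",
              length(x$states), sum(lengths(x$succ)),
              paste(x$ap, collapse = ", ")))
  invisible(x)
}

n_states <- function(ts) length(ts$states)

ts_edges <- function(ts) {
  from <- rep(seq_along(ts$succ), lengths(ts$succ))
  to <- unlist(ts$succ)
  cbind(from = ts$states[from], to = ts$states[to])
}

#' Tidy a transition system into a state table
#'
#' @param x A `"transition_system"`.
#' @param ... Unused.
#' @return A tibble with one row per state: id, initial flag, successor ids,
#'   and one logical column per atomic proposition.
#' @method tidy transition_system
#' @export
tidy.transition_system <- function(x, ...) {
  base <- tibble(
    state = x$states,
    initial = x$states %in% x$initial,
    successors = purrr::map_chr(x$succ, ~ paste(x$states[.x], collapse = ","))
  )
  for (p in x$ap) {
    base[[p]] <- purrr::map_lgl(x$labels, ~ p %in% .x)
  }
  base
}

#' Unfold a program graph into a transition system
#'
#' Reachable states are (location, valuation) pairs, starting from the
#' initial locations with every valuation satisfying the initial condition
#' and closed under enabled guarded transitions.  Terminal states self-loop
#' so the result is total.  With all variable domains binary the state count
#' per location can never exceed \eqn{2^t \cdot 2^k} where t and k count the
#' condition and cluster-flag variables; `cap` guards that bound.
#'
#' @param pg A `"program_graph"`.
#' @param cap Safety cap on the state count (default: locations x full
#'   valuation space, the theoretical maximum).
#' @return A `"transition_system"` whose atomic propositions are the location
#'   names plus `"<var>=1"` for every variable.
#' @export
unfold <- function(pg, cap = NULL) {
  vars <- names(pg$variables)
  grid <- expand.grid(pg$variables, KEEP.OUT.ATTRS = FALSE)
  valuations <- lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
  max_states <- length(pg$locations) * length(valuations)
  if (is.null(cap)) cap <- max_states

  state_id <- function(loc, eta) {
    paste0(loc, "|", paste(vars, unlist(eta[vars]), sep = "=", collapse = ","))
  }
  init <- list()
  for (loc in pg$loc0) {
    for (eta in valuations) {
      if (pg$g0(eta)) init[[state_id(loc, eta)]] <- list(loc = loc, eta = eta)
    }
  }
  frontier <- init
  seen <- init
  edges <- NULL
  while (length(frontier)) {
    nxt <- list()
    for (sid in names(frontier)) {
      st <- frontier[[sid]]
      for (tr in pg$transitions) {
        if (tr$from != st$loc || !isTRUE(tr$guard(st$eta))) next
        for (eta2 in tr$effect(st$eta)) {
          sid2 <- state_id(tr$to, eta2)
          edges <- rbind(edges, c(sid, sid2))
          if (is.null(seen[[sid2]])) {
            seen[[sid2]] <- list(loc = tr$to, eta = eta2)
            nxt[[sid2]] <- seen[[sid2]]
            if (length(seen) > cap) {
              abort(sprintf("unfolding exceeded the state cap of %d.", cap))
            }
          }
        }
      }
    }
    frontier <- nxt
  }
  states <- names(seen)
  ap <- c(pg$locations, paste0(vars, "=1"))
  labels <- lapply(seen, function(st) {
    c(st$loc, paste0(vars, "=1")[unlist(st$eta[vars]) == 1])
  })
  names(labels) <- states
  transition_system(states, edges %||% matrix(character(0), ncol = 2),
                    initial = names(init), ap = ap, labels = labels)
}

# ---- trace labelling --------------------------------------------------------

#' Atomic-proposition labels of an iteration trace
#'
#' Computes, for every iteration t, the subset of
#' \{converge, handled, DunnUp, maxDunn, diamDown, minDiam\} true there:
#' `converge` iff `conv = 1`; `handled` iff `deal = 1`; `DunnUp` iff t = 1,
#' or the Dunn value at t is undefined, or it is >= the value at t-1
#' (non-strict, so converged plateaus and early rounds with an undefined
#' index never spuriously violate the trend); `diamDown` symmetric with <=;
#' `maxDunn` iff `converge` and `handled` hold at t and the Dunn value equals
#' the maximum defined value over the whole trace (ties all labelled);
#' `minDiam` symmetric with the trace-wide minimum.
#'
#' @param trace A `"cluster_trace"`.
#' @return A list, one character vector of proposition names per iteration.
#' @export
label_atomic_props <- function(trace) {
  recs <- trace$records
  dunn <- vapply(recs, function(r) as.numeric(r$dunn), numeric(1))
  diam <- vapply(recs, function(r) as.numeric(r$diam), numeric(1))
  conv <- vapply(recs, function(r) as.integer(r$conv), integer(1))
  deal <- vapply(recs, function(r) as.integer(r$deal), integer(1))
  dunn_max <- if (all(is.na(dunn))) NA_real_ else max(dunn, na.rm = TRUE)
  diam_min <- if (all(is.na(diam))) NA_real_ else min(diam, na.rm = TRUE)
  lapply(seq_along(recs), function(t) {
    l <- character(0)
    if (conv[t] == 1) l <- c(l, "converge")
    if (deal[t] == 1) l <- c(l, "handled")
    up <- t == 1 || is.na(dunn[t]) || is.na(dunn[t - 1]) ||
      dunn[t] >= dunn[t - 1]
    down <- t == 1 || is.na(diam[t]) || is.na(diam[t - 1]) ||
      diam[t] <= diam[t - 1]
    if (up) l <- c(l, "DunnUp")
    if (down) l <- c(l, "diamDown")
    if (conv[t] == 1 && deal[t] == 1) {
      if (!is.na(dunn[t]) && !is.na(dunn_max) && dunn[t] == dunn_max) {
        l <- c(l, "maxDunn")
      }
      if (!is.na(diam[t]) && !is.na(diam_min) && diam[t] == diam_min) {
        l <- c(l, "minDiam")
      }
    }
    sort(l)
  })
}

#' Linear transition system of an iteration trace
#'
#' States S_1 ... S_T in trace order, chained in sequence with a self-loop at
#' the terminal state (the run's locations never change once finished, and
#' CTL semantics require a total transition relation); the single initial
#' state is S_1.  Labels come from [label_atomic_props()].
#'
#' @param trace A `"cluster_trace"`.
#' @return A `"transition_system"`.
#' @export
trace_to_ts <- function(trace) {
  n <- length(trace$records)
  if (n < 1) abort("trace has no records.")
  states <- paste0("S", seq_len(n))
  edges <- if (n > 1) cbind(states[-n], states[-1]) else
    matrix(character(0), ncol = 2)
  edges <- rbind(edges, c(states[n], states[n]))
  labels <- setNames(label_atomic_props(trace), states)
  transition_system(states, edges, initial = states[1], ap = ATOMIC_PROPS,
                    labels = labels)
}

# ---- export -----------------------------------------------------------------

#' Export a transition system for inspection
#'
#' `ts_to_dot()` writes GraphViz DOT with labels shown as sorted proposition
#' lists; `ts_to_json()` writes states, labels and edges as JSON.
#'
#' @param ts A `"transition_system"`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
ts_to_dot <- function(ts, path) {
  lines <- c("digraph ts {")
  for (s in ts$states) {
    shape <- if (s %in% ts$initial) "doublecircle" else "circle"
    lines <- c(lines, sprintf(
      "  \"%s\" [shape=%s, label=\"%s\\n{%s}\"];", s, shape, s,
      paste(ts$labels[[s]], collapse = ",")))
  }
  e <- ts_edges(ts)
  for (r in seq_len(nrow(e))) {
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", e[r, 1], e[r, 2]))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname ts_to_dot
#' @export
ts_to_json <- function(ts, path) {
  e <- ts_edges(ts)
  obj <- list(
    states = ts$states,
    initial = ts$initial,
    ap = ts$ap,
    labels = ts$labels,
    edges = lapply(seq_len(nrow(e)), function(r)
      list(from = e[r, 1], to = e[r, 2]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
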