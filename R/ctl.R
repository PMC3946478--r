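# CTL: abstract syntax, parser, adequate-set rewriting, and the
# explicit-state fixpoint labelling model checker.
#
# Concrete syntax: atoms are identifiers; `true`/`false`; `!`, `&`, `|`, `->`
# with precedence ! > & > | > -> (implication right-associative); unary path
# operators EX AX EF AF EG AG; until in bracket form E[p U q] / A[p U q].

ctl_node <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "ctl_formula")
}

#' Build CTL formula nodes programmatically
#'
#' Constructors mirroring the grammar: `ctl_atom("p")`, `ctl_true()`,
#' `ctl_not(f)`, `ctl_and(f, g)`, `ctl_or(f, g)`, `ctl_implies(f, g)`,
#' `ctl_op("EX", f)` for the unary path operators, and `ctl_until("E", f, g)`
#' for E\[f U g\] / A\[f U g\].
#'
#' @param name Atom name.
#' @return A `"ctl_formula"`.
#' @export
ctl_atom <- function(name) ctl_node("atom", name = name)

#' @rdname ctl_atom
#' @export
ctl_true <- function() ctl_node("true")

#' @rdname ctl_atom
#' @export
ctl_false <- function() ctl_node("false")

#' @rdname ctl_atom
#' @param f,g Subformulas.
#' @export
ctl_not <- function(f) ctl_node("not", sub = f)

#' @rdname ctl_atom
#' @export
ctl_and <- function(f, g) ctl_node("and", left = f, right = g)

#' @rdname ctl_atom
#' @export
ctl_or <- function(f, g) ctl_node("or", left = f, right = g)

#' @rdname ctl_atom
#' @export
ctl_implies <- function(f, g) ctl_node("implies", left = f, right = g)

#' @rdname ctl_atom
#' @param op One of `"EX"`, `"AX"`, `"EF"`, `"AF"`, `"EG"`, `"AG"`.
#' @export
ctl_op <- function(op, f) {
  stopifnot(op %in% c("EX", "AX", "EF", "AF", "EG", "AG"))
  ctl_node(op, sub = f)
}

#' @rdname ctl_atom
#' @param quantifier `"E"` or `"A"`.
#' @export
ctl_until <- function(quantifier, f, g) {
  stopifnot(quantifier %in% c("E", "A"))
  ctl_node(paste0(quantifier, "U"), left = f, right = g)
}

#' @export
format.ctl_formula <- function(x, ...) {
  switch(paste0("k_", x$kind),
    k_atom = x$name,
    k_true = "true",
    k_false = "false",
    k_not = paste0("!", wrap(x$sub)),
    k_and = paste0(wrap(x$left), " & ", wrap(x$right)),
    k_or = paste0(wrap(x$left), " | ", wrap(x$right)),
    k_implies = paste0(wrap(x$left), " -> ", wrap(x$right)),
    k_EU = paste0("E[", format(x$left), " U ", format(x$right), "]"),
    k_AU = paste0("A[", format(x$left), " U ", format(x$right), "]"),
    paste0(x$kind, " ", wrap(x$sub))
  )
}

wrap <- function(f) {
  # unary operators bind tighter than the binary connectives, so only the
  # binary connectives need parentheses
  if (f$kind %in% c("and", "or", "implies")) paste0("(", format(f), ")")
  else format(f)
}

#' @export
print.ctl_formula <- function(x, ...) {
  cat("<CTL> ", format(x), "\n", sep = "")
  invisible(x)
}

# ---- parser -----------------------------------------------------------------

ctl_tokenize <- function(text) {
  tokens <- list()
  i <- 1
  n <- nchar(text)
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1; next }
    rest <- substr(text, i, n)
    if (grepl("^->", rest)) { push("op", "->", i); i <- i + 2; next }
    if (ch %in% c("(", ")", "[", "]", "!", "&", "|")) {
      push("op", ch, i); i <- i + 1; next
    }
    m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
    if (length(m) == 1) {
      push(if (m %in% c("EX", "AX", "EF", "AF", "EG", "AG", "E", "A", "U",
                        "true", "false")) "kw" else "ident", m, i)
      i <- i + nchar(m)
      next
    }
    abort(sprintf("CTL syntax error at position %d: unexpected `%s`.", i, ch))
  }
  tokens
}

#' Parse a CTL formula
#'
#' @param text Formula string, e.g.
#'   `"EF ((converge & handled) -> (maxDunn & minDiam))"` or
#'   `"E[DunnUp U maxDunn] & E[diamDown U minDiam]"`.
#' @return A `"ctl_formula"` syntax tree.
#' @export
ctl_parse <- function(text) {
  tokens <- ctl_tokenize(text)
  pos <- 1
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  take <- function() { t <- peek(); pos <<- pos + 1; t }
  fail <- function(t, what) {
    abort(sprintf("CTL syntax error at position %s: expected %s, got `%s`.",
                  if (is.null(t)) "end of input" else t$pos, what,
                  if (is.null(t)) "" else t$value))
  }
  expect <- function(value) {
    t <- take()
    if (is.null(t) || t$value != value) fail(t, sprintf("`%s`", value))
    t
  }

  parse_implies <- function() {
    left <- parse_or()
    t <- peek()
    if (!is.null(t) && t$value == "->") {
      take()
      return(ctl_implies(left, parse_implies()))
    }
    left
  }
  parse_or <- function() {
    left <- parse_and()
    repeat {
      t <- peek()
      if (is.null(t) || t$value != "|") return(left)
      take()
      left <- ctl_or(left, parse_and())
    }
  }
  parse_and <- function() {
    left <- parse_unary()
    repeat {
      t <- peek()
      if (is.null(t) || t$value != "&") return(left)
      take()
      left <- ctl_and(left, parse_unary())
    }
  }
  parse_unary <- function() {
    t <- peek()
    if (is.null(t)) fail(t, "a formula")
    if (t$value == "!") { take(); return(ctl_not(parse_unary())) }
    if (t$type == "kw" && t$value %in% c("EX", "AX", "EF", "AF", "EG", "AG")) {
      take()
      return(ctl_op(t$value, parse_unary()))
    }
    if (t$type == "kw" && t$value %in% c("E", "A")) {
      take()
      expect("[")
      left <- parse_implies()
      u <- take()
      if (is.null(u) || u$value != "U") fail(u, "`U`")
      right <- parse_implies()
      expect("]")
      return(ctl_until(t$value, left, right))
    }
    if (t$value == "(") {
      take()
      f <- parse_implies()
      expect(")")
      return(f)
    }
    if (t$type == "kw" && t$value == "true") { take(); return(ctl_true()) }
    if (t$type == "kw" && t$value == "false") { take(); return(ctl_false()) }
    if (t$type == "ident") { take(); return(ctl_atom(t$value)) }
    fail(t, "a formula")
  }

  f <- parse_implies()
  t <- peek()
  if (!is.null(t)) fail(t, "end of input")
  f
}

# ---- adequate set -----------------------------------------------------------

#' Rewrite a formula over the adequate set \{EX, EU, AF\}
#'
#' Semantics-preserving rewrite into atoms, `true`, `!`, `&`, `EX`,
#' `E[. U .]` and `AF`: `EF p -> E[true U p]`, `AX p -> !EX !p`,
#' `EG p -> !AF !p`, `AG p -> !E[true U !p]`,
#' `A[p U q] -> !E[!q U (!p & !q)] & AF q`, with `|`, `->` and `false`
#' eliminated through `!`/`&`.  Idempotent.
#'
#' @param f A `"ctl_formula"`.
#' @return A `"ctl_formula"` over the adequate set.
#' @export
ctl_to_adequate <- function(f) {
  rec <- ctl_to_adequate
  switch(paste0("k_", f$kind),
    k_atom = f,
    k_true = f,
    k_false = ctl_not(ctl_true()),
    k_not = ctl_not(rec(f$sub)),
    k_and = ctl_and(rec(f$left), rec(f$right)),
    k_or = ctl_not(ctl_and(ctl_not(rec(f$left)), ctl_not(rec(f$right)))),
    k_implies = ctl_not(ctl_and(rec(f$left), ctl_not(rec(f$right)))),
    k_EX = ctl_op("EX", rec(f$sub)),
    k_AX = ctl_not(ctl_op("EX", ctl_not(rec(f$sub)))),
    k_EF = ctl_until("E", ctl_true(), rec(f$sub)),
    k_AF = ctl_op("AF", rec(f$sub)),
    k_EG = ctl_not(ctl_op("AF", ctl_not(rec(f$sub)))),
    k_AG = ctl_not(ctl_until("E", ctl_true(), ctl_not(rec(f$sub)))),
    k_EU = ctl_until("E", rec(f$left), rec(f$right)),
    k_AU = {
      l <- rec(f$left)
      r <- rec(f$right)
      ctl_and(
        ctl_not(ctl_until("E", ctl_not(r), ctl_and(ctl_not(l), ctl_not(r)))),
        ctl_op("AF", r)
      )
    },
    abort(sprintf("unknown formula kind `%s`.", f$kind))
  )
}

#' Atom names referenced by a formula
#' @param f A `"ctl_formula"`.
#' @return Character vector.
#' @export
ctl_atoms <- function(f) {
  switch(paste0("k_", f$kind),
    k_atom = f$name,
    k_true = , k_false = character(0),
    k_not = , k_EX = , k_AX = , k_EF = , k_AF = , k_EG = ,
    k_AG = ctl_atoms(f$sub),
    unique(c(ctl_atoms(f$left), ctl_atoms(f$right)))
  )
}

# ---- model checking ---------------------------------------------------------

assert_total <- function(ts) {
  if (any(lengths(ts$succ) == 0)) {
    abort("transition system is not total: some state has no successor.")
  }
}

# Least fixpoints computed with linear-time worklist algorithms: EU grows the
# target set backwards through predecessor lists; AF/AU use the standard
# successor-counting scheme, so each temporal operator is O(|S| + |E|).
sat_indices <- function(ts, f) {
  n <- n_states(ts)
  rec <- function(f) {
    switch(paste0("k_", f$kind),
      k_atom = {
        if (!f$name %in% ts$ap) {
          abort(sprintf("unknown atomic proposition `%s`.", f$name))
        }
        which(vapply(ts$labels, function(l) f$name %in% l, logical(1)))
      },
      k_true = seq_len(n),
      k_false = integer(0),
      k_not = setdiff(seq_len(n), rec(f$sub)),
      k_and = intersect(rec(f$left), rec(f$right)),
      k_or = union(rec(f$left), rec(f$right)),
      k_implies = union(setdiff(seq_len(n), rec(f$left)), rec(f$right)),
      k_EX = pre_exists(ts, rec(f$sub)),
      k_AX = pre_forall(ts, rec(f$sub)),
      k_EF = lfp_eu(ts, seq_len(n), rec(f$sub)),
      k_EU = lfp_eu(ts, rec(f$left), rec(f$right)),
      k_AF = lfp_au(ts, seq_len(n), rec(f$sub)),
      k_AU = lfp_au(ts, rec(f$left), rec(f$right)),
      k_EG = setdiff(seq_len(n), lfp_au(ts, seq_len(n),
                                        setdiff(seq_len(n), rec(f$sub)))),
      k_AG = setdiff(seq_len(n), lfp_eu(ts, seq_len(n),
                                        setdiff(seq_len(n), rec(f$sub)))),
      abort(sprintf("unknown formula kind `%s`.", f$kind))
    )
  }
  sort(rec(f))
}

pre_exists <- function(ts, target) {
  inset <- logical(n_states(ts))
  inset[target] <- TRUE
  which(vapply(ts$succ, function(s) any(inset[s]), logical(1)))
}

pre_forall <- function(ts, target) {
  inset <- logical(n_states(ts))
  inset[target] <- TRUE
  which(vapply(ts$succ, function(s) all(inset[s]), logical(1)))
}

# sat(E[phi U psi]): seed with psi, grow backwards through phi states.
lfp_eu <- function(ts, phi, psi) {
  n <- n_states(ts)
  in_phi <- logical(n); in_phi[phi] <- TRUE
  inset <- logical(n); inset[psi] <- TRUE
  work <- psi
  while (length(work)) {
    v <- work[[length(work)]]
    work <- work[-length(work)]
    for (p in ts$pred[[v]]) {
      if (!inset[p] && in_phi[p]) {
        inset[p] <- TRUE
        work <- c(work, p)
      }
    }
  }
  which(inset)
}

# sat(A[phi U psi]): successor-counting least fixpoint; a state enters when
# all of its successors are in and it satisfies phi.
lfp_au <- function(ts, phi, psi) {
  n <- n_states(ts)
  in_phi <- logical(n); in_phi[phi] <- TRUE
  inset <- logical(n); inset[psi] <- TRUE
  count <- lengths(ts$succ)
  work <- psi
  while (length(work)) {
    v <- work[[length(work)]]
    work <- work[-length(work)]
    for (p in ts$pred[[v]]) {
      count[p] <- count[p] - 1L
      if (count[p] == 0L && !inset[p] && in_phi[p]) {
        inset[p] <- TRUE
        work <- c(work, p)
      }
    }
  }
  which(inset)
}

#' Satisfaction set of a CTL formula
#'
#' Explicit-state labelling algorithm: computes, bottom-up over the formula
#' tree, the exact set of states satisfying each subformula, using backward
#' least-fixpoint iterations for the temporal operators (each linear in the
#' number of states plus transitions).  The transition relation must be
#' total.
#'
#' @param ts A `"transition_system"`.
#' @param f A `"ctl_formula"` or formula string (parsed with [ctl_parse()]).
#' @return Character vector of satisfying state ids, in state order.
#' @export
ctl_sat <- function(ts, f) {
  if (is.character(f)) f <- ctl_parse(f)
  assert_total(ts)
  ts$states[sat_indices(ts, f)]
}

#' Does a transition system satisfy a CTL formula?
#'
#' True iff every initial state is in the satisfaction set.
#'
#' @inheritParams ctl_sat
#' @return Logical scalar.
#' @export
ctl_check <- function(ts, f) {
  if (is.character(f)) f <- ctl_parse(f)
  all(ts$initial %in% ctl_sat(ts, f))
}
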