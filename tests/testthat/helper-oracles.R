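# Independent oracles used to freeze expected values: brute-force pair
# enumeration, direct-formula index computations, and a forward path-search
# CTL semantics.  Deliberately naive and structurally different from the
# package's implementations.

# ---- pair / external index oracles ------------------------------------------

oracle_pair_counts <- function(predicted, truth) {
  keep <- predicted != -1
  predicted <- predicted[keep]
  truth <- truth[keep]
  n <- length(predicted)
  a <- b <- c <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_cl <- predicted[i] == predicted[j]
      same_tr <- truth[i] == truth[j]
      if (same_cl && same_tr) a <- a + 1
      else if (same_cl && !same_tr) b <- b + 1
      else if (!same_cl && same_tr) c <- c + 1
      else d <- d + 1
    }
  }
  list(a = a, b = b, c = c, d = d, n = n)
}

oracle_purity <- function(cm) {
  best <- 0
  for (j in seq_len(ncol(cm))) best <- best + max(cm[, j])
  best / sum(cm)
}

oracle_entropy <- function(cm) {
  n <- sum(cm)
  l <- nrow(cm)
  if (l <= 1) return(0)
  total <- 0
  for (j in seq_len(ncol(cm))) {
    nj <- sum(cm[, j])
    if (nj == 0) next
    h <- 0
    for (i in seq_len(l)) {
      p <- cm[i, j] / nj
      if (p > 0) h <- h - p * log(p)
    }
    total <- total + nj / n * h / log(l)
  }
  total
}

# ---- relative index oracles (direct formulas, all-pairs loops) --------------

euclid <- function(x, y) sqrt(sum((x - y)^2))

oracle_dunn <- function(data, partition) {
  keep <- partition != -1
  data <- data[keep, , drop = FALSE]
  partition <- partition[keep]
  cl <- unique(partition)
  if (length(cl) < 2) return(NA_real_)
  diam <- oracle_max_diameter(data, partition)
  inter <- Inf
  for (ci in cl) {
    for (cj in cl) {
      if (ci == cj) next
      for (i in which(partition == ci)) {
        for (j in which(partition == cj)) {
          inter <- min(inter, euclid(data[i, ], data[j, ]))
        }
      }
    }
  }
  if (diam == 0) return(Inf)
  inter / diam
}

oracle_max_diameter <- function(data, partition) {
  keep <- partition != -1
  data <- data[keep, , drop = FALSE]
  partition <- partition[keep]
  if (length(partition) == 0) return(NA_real_)
  worst <- 0
  for (c in unique(partition)) {
    idx <- which(partition == c)
    for (i in idx) {
      for (j in idx) {
        worst <- max(worst, euclid(data[i, ], data[j, ]))
      }
    }
  }
  worst
}

oracle_davies_bouldin <- function(data, partition) {
  cl <- sort(unique(partition))
  cent <- lapply(cl, function(c) colMeans(data[partition == c, , drop = FALSE]))
  s <- vapply(seq_along(cl), function(i) {
    idx <- which(partition == cl[i])
    mean(vapply(idx, function(r) euclid(data[r, ], cent[[i]]), numeric(1)))
  }, numeric(1))
  mean(vapply(seq_along(cl), function(i) {
    max(vapply(seq_along(cl)[-i], function(j)
      (s[i] + s[j]) / euclid(cent[[i]], cent[[j]]), numeric(1)))
  }, numeric(1)))
}

oracle_rmsstd <- function(data, partition) {
  ss <- 0
  df <- 0
  for (c in unique(partition)) {
    rows <- data[partition == c, , drop = FALSE]
    ctr <- colMeans(rows)
    for (r in seq_len(nrow(rows))) ss <- ss + sum((rows[r, ] - ctr)^2)
    df <- df + ncol(rows) * (nrow(rows) - 1)
  }
  if (df == 0) return(0)
  sqrt(ss / df)
}

# ---- CTL path-semantics oracle ----------------------------------------------
# Forward graph searches over the transition relation; no backward fixpoints.

oracle_sat <- function(ts, f) {
  n <- length(ts$states)
  succ <- ts$succ
  has <- function(p) which(vapply(ts$labels, function(l) p %in% l, logical(1)))
  all_states <- seq_len(n)

  # exists path from s through `via` states reaching a `target` state
  reach_through <- function(s, via, target) {
    intarget <- logical(n); intarget[target] <- TRUE
    invia <- logical(n); invia[via] <- TRUE
    seen <- logical(n)
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      if (intarget[v]) return(TRUE)
      if (!invia[v]) next
      stack <- c(stack, succ[[v]])
    }
    FALSE
  }

  # states reachable from s stepping only through `inside` states (s included
  # if inside); exploration stops at states outside `inside`
  closure_within <- function(s, inside) {
    inset <- logical(n); inset[inside] <- TRUE
    if (!inset[s]) return(integer(0))
    seen <- logical(n)
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (seen[v] || !inset[v]) next
      seen[v] <- TRUE
      stack <- c(stack, succ[[v]])
    }
    which(seen)
  }

  has_cycle <- function(nodes) {
    inset <- logical(n); inset[nodes] <- TRUE
    color <- integer(n)  # 0 white, 1 grey, 2 black
    found <- FALSE
    visit <- function(v) {
      if (found || !inset[v]) return()
      color[v] <<- 1L
      for (w in succ[[v]]) {
        if (!inset[w]) next
        if (color[w] == 1L) { found <<- TRUE; return() }
        if (color[w] == 0L) visit(w)
      }
      color[v] <<- 2L
    }
    for (v in nodes) if (color[v] == 0L) visit(v)
    found
  }

  sat_eu <- function(phi, psi) {
    Filter(function(s) reach_through(s, phi, psi), all_states)
  }
  sat_eg <- function(phi) {
    Filter(function(s) {
      r <- closure_within(s, phi)
      length(r) > 0 && has_cycle(r)
    }, all_states)
  }
  sat_au <- function(phi, psi) {
    not_psi <- setdiff(all_states, psi)
    Filter(function(s) {
      if (s %in% psi) return(TRUE)
      if (!s %in% phi) return(FALSE)
      r <- closure_within(s, not_psi)   # the region a violating path lives in
      if (any(!r %in% phi)) return(FALSE)
      !has_cycle(r)
    }, all_states)
  }

  rec <- function(f) {
    switch(paste0("k_", f$kind),
      k_atom = has(f$name),
      k_true = all_states,
      k_false = integer(0),
      k_not = setdiff(all_states, rec(f$sub)),
      k_and = intersect(rec(f$left), rec(f$right)),
      k_or = union(rec(f$left), rec(f$right)),
      k_implies = union(setdiff(all_states, rec(f$left)), rec(f$right)),
      k_EX = { sub <- rec(f$sub)
               Filter(function(s) any(succ[[s]] %in% sub), all_states) },
      k_AX = { sub <- rec(f$sub)
               Filter(function(s) all(succ[[s]] %in% sub), all_states) },
      k_EF = sat_eu(all_states, rec(f$sub)),
      k_EU = sat_eu(rec(f$left), rec(f$right)),
      k_AF = sat_au(all_states, rec(f$sub)),
      k_AU = sat_au(rec(f$left), rec(f$right)),
      k_EG = sat_eg(rec(f$sub)),
      k_AG = {
        inside <- rec(f$sub)
        Filter(function(s)
          !reach_through(s, all_states, setdiff(all_states, inside)),
          all_states)
      },
      stop("unknown kind")
    )
  }
  sort(ts$states[unlist(rec(f))])
}

# ---- random generators -------------------------------------------------------

random_kripke <- function(n_states = sample(2:8, 1), atoms = c("p", "q", "r")) {
  states <- paste0("s", seq_len(n_states))
  edges <- do.call(rbind, lapply(seq_len(n_states), function(i) {
    k <- sample.int(min(3, n_states), 1)
    cbind(states[i], sample(states, k))
  }))
  labels <- lapply(states, function(s) atoms[stats::runif(length(atoms)) < 0.5])
  names(labels) <- states
  transition_system(states, edges, initial = sample(states, 1), ap = atoms,
                    labels = labels)
}

random_ctl_formula <- function(depth = 3, atoms = c("p", "q", "r")) {
  if (depth == 0 || stats::runif(1) < 0.3) {
    r <- stats::runif(1)
    if (r < 0.8) return(ctl_atom(sample(atoms, 1)))
    if (r < 0.9) return(ctl_true())
    return(ctl_false())
  }
  kind <- sample(c("not", "and", "or", "implies", "EX", "AX", "EF", "AF",
                   "EG", "AG", "EU", "AU"), 1)
  sub <- function() random_ctl_formula(depth - 1, atoms)
  switch(kind,
    not = ctl_not(sub()),
    and = ctl_and(sub(), sub()),
    or = ctl_or(sub(), sub()),
    implies = ctl_implies(sub(), sub()),
    EU = ctl_until("E", sub(), sub()),
    AU = ctl_until("A", sub(), sub()),
    ctl_op(kind, sub())
  )
}

random_partition <- function(n, k) {
  k <- min(k, n)
  repeat {
    p <- sample.int(k, n, replace = TRUE)
    if (length(unique(p)) == k) return(p)
  }
}
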