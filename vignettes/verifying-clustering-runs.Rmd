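---
title: "Verifying clustering runs by CTL model checking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying clustering runs by CTL model checking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustmc)
```

## The problem

Cluster validity is usually judged from the final partition alone: external
indices (Purity, Entropy, Rand, Jaccard, Fowlkes-Mallows) compare it with a
priori class labels, and relative indices (Dunn, diameter, Davies-Bouldin,
RMSSTD) score its geometry. Both have blind spots. External indices need
labels that unsupervised analyses — expression-profile clustering in
particular — rarely have, and their verdict depends on an arbitrary
threshold; relative indices only rank alternatives and say nothing about
whether a single run is trustworthy. Neither says *where* a run went wrong.

`clustmc` takes a different route: it watches the run itself. An iterative
crisp clustering algorithm (K-Means, DBSCAN, or anything that can export the
trace format) is instrumented to record one snapshot per iteration — the
assignment vector, per-cluster change flags, convergence flags, and the Dunn
and maximum-diameter indices. A healthy run should tighten clusters
monotonically: Dunn rising to a maximum attained at convergence, diameter
falling to a minimum. That expectation is stated formally in branching-time
temporal logic and checked mechanically, and when it fails the verifier
reports which iterations — and which data objects — broke it.

## From run to Kripke structure

A clustering process is first abstracted as a *program graph*: a directed
graph over binary variables whose edges carry guards and one of the two core
clustering actions, `compare` (distance comparison; never changes any
variable) and `allocate` (cluster assignment). For K-Means the variables are
the per-cluster change flags `rs[1..k]` and the convergence flag `conv`,
with initial condition `rs[i] = 0, conv = 0` — no object has been disposed
of yet. For DBSCAN they are `conv` (the current core object's
density-reachable set is exhausted) and `deal` (every object allocated).
Unfolding the graph over its variable valuations yields a finite transition
system; with `t` binary condition variables and `k` cluster flags the
reachable states per location can never exceed `2^t * 2^k`, which
`unfold()` enforces as a hard cap. Algorithms that do not iterate (SVM-based
clustering) or iterate stochastically (EM) have no such graph and are out of
scope; BIRCH- or SOM-style algorithms enter through the trace format
instead, with iteration granularity left to the producer.

An actual run is one path through that system. `trace_to_ts()` builds the
corresponding linear Kripke structure `S_1 -> S_2 -> ... -> S_T` (terminal
self-loop, so the transition relation is total as CTL semantics require) and
labels each state with six atomic propositions:

* `converge`, `handled` — the record's `conv` / `deal` flags;
* `DunnUp` — the Dunn value did not fall since the previous state
  (non-strict, and vacuously true at the first state and wherever the index
  is undefined);
* `diamDown` — symmetric, with the diameter not rising;
* `maxDunn`, `minDiam` — the state is converged and fully handled *and* its
  index value attains the trace-wide extremum (ties all labelled).

Two labelling conventions deserve comment, because the design was genuinely
open. First, `DunnUp`/`diamDown` are non-strict: converged runs end on a
plateau, and early DBSCAN rounds have fewer than two clusters (undefined
Dunn), and neither should count as a trend violation. Second, `maxDunn` and
`minDiam` demand the *trace-wide* extremum at a converged state rather than
a running maximum: under the running-maximum reading a rise-then-fall series
would still satisfy the "rises until its maximum" property through its early
states and every degrading run would verify as valid, which is exactly the
wrong answer.

## The validity properties

The property set bundled in `validity_formulas()` is:

* `phi1 = EF ((converge & handled) -> (maxDunn & minDiam))` — at
  convergence, with all objects handled, the indices attain their extrema;
* `phi2 = E[DunnUp U maxDunn] & E[diamDown U minDiam]` — Dunn rises until
  its maximum, diameter falls until its minimum.

`phi1` is reported but does not bear on the verdict: an `EF` wrapped around
an implication is satisfied by *any* reachable state that falsifies the
antecedent, and on almost every trace some early state has `conv = 0`, so
the literal formula is vacuously true regardless of run quality. The
intended reading — a universal claim about the converged state — is the `AG`
form, included as `phi1_effective` and used for the verdict together with
`phi2`. On a single linear trace the conjunction of two E-untils coincides
with one E-until over the conjunction, so only the former is implemented.

The checker itself (`ctl_sat()`) is a conventional explicit-state labelling
algorithm: satisfaction sets are computed bottom-up over the formula tree
with backward least-fixpoint iterations for `EU` and `AF` (worklist and
successor-counting forms, each linear in states plus transitions) and `EX`
as a pre-image; `EG`/`AG`/`EF`/`AU` are computed through their standard
dualities, and `ctl_to_adequate()` exposes the textbook rewriting into the
adequate operator set `{EX, EU, AF}`. The parser accepts the usual textbook
syntax (`!`, `&`, `|`, `->`, `EX ... AG`, `E[p U q]`, `A[p U q]`) with
`!` binding tightest and `->` loosest, right-associative. The test suite
pins the semantics to an independent oracle that evaluates formulas by
forward path searches (reachability, cycle detection) on thousands of random
Kripke structures.

## Counterexamples and blame

When a verdict formula fails on a trace, the error trace `T` is the whole
execution path. The satisfying sub-trace `C` is extracted by seeding with
every state where the formula's *per-state obligation* holds — the
implication itself for `phi1`, `(DunnUp | maxDunn) & (diamDown | minDiam)`
for `phi2` — and closing backwards over incoming transitions. The worklist
closes regardless of the obligation at the predecessor, following the
literal formulation; on linear traces with a prefix-shaped obligation region
(the only shape the verifier produces) this is identical to stopping at the
first violation, and the cause `T - C` is the violating suffix. A failed
formula whose cause is empty is flagged as an initial-allocation error — a
misallocation present from the first iteration and never corrected — which
iteration comparison cannot localize and the report says so.

Object-level blame (`check_iteration()`) then compares violating iterations
with their successors: collect the objects whose cluster changed at the
first violating iteration; if the trend is normal again at the next
iteration, drop the objects that settled (their move was beneficial); if it
is still abnormal, walk forward and accumulate, adding at the final
iteration the objects newly displaced there. The walk costs `O(r n)` for
`r` iterations examined and `n` objects.

## Tunable parameters

| parameter | where | default | why |
|---|---|---|---|
| `tol` | `kmeans_trace()` | `1e-6` | absolute criterion difference (squared-distance units) declaring convergence |
| `max_iter` | `kmeans_trace()` | `100` | Lloyd iteration cap |
| `init` | `kmeans_trace()` | seeded random points | explicit centers and a farthest-point heuristic are available; farthest-point is the right choice when cross-checking against other Lloyd implementations |
| `eps`, `min_pts` | `dbscan_trace()` | — | the usual DBSCAN radius (data units) and core threshold (count, self included) |
| `method` | index functions | `"euclidean"` | any `stats::dist()` metric; every default and test uses Euclidean |
| `sep` | `blob_spec()` | `10` | closest center pair distance in units of `sigma`; 10 gives unambiguous blobs, 2 gives heavy overlap |

Distances are Euclidean throughout unless overridden. Cluster identifiers
are 1-based; unassigned objects (DBSCAN noise, unreached objects) are coded
`-1`, excluded from every index computation, and serialized as `-1` in the
JSON trace format.

## Numerical choices and degenerate inputs

* Dunn with fewer than two clusters is *undefined* (`NA`), not an error:
  early DBSCAN rounds legitimately have one cluster, and the labelling
  treats undefined as trend-neutral. All-singleton clusters give `Inf`
  (zero maximum diameter).
* Jaccard and Fowlkes-Mallows return 0 with a warning on a zero denominator.
* Entropy uses natural logarithms normalized by `log(l)` so the index lies
  in [0, 1] regardless of the class count `l`; a single class gives 0 by
  convention. The bounded scale is what makes threshold comparisons (e.g.
  "entropy below 0.25") meaningful.
* RMSSTD pools within-cluster sums of squares over `d * sum(n_i - 1)`
  degrees of freedom and returns 0 when every cluster is a singleton or a
  point mass.
* K-Means assignment ties go to the lowest-index centroid; an empty cluster
  is reseeded with the point farthest from its own cluster's centroid
  (donor clusters with one member are protected), keeping runs
  deterministic under a fixed seed.
* Davies-Bouldin refuses coincident centroids, naming the cluster pair.

## What the synthetic generators emulate — and what they do not

`make_blobs()` draws isotropic Gaussian clusters on a circle of centers;
`make_synthetic_trace()` fabricates monotone, dip and plateau index series
directly (exact control over the trend, for fixture-grade tests of the
labelling and cause extraction); `plant_blame()` perturbs a real K-Means
trace by displacing chosen objects from a chosen iteration onward —
oscillating by default, ending displaced — and recomputes every index from
the perturbed geometry, so blame tests run end-to-end. Planted runs pad the
base trace with converged iterations when it converges before the planting
point, and refuse displacements that would empty a cluster.

The test and acceptance workloads use desk-scale sizes chosen once: blobs of
k = 2 clusters x 15 points at separation 10 sigma for blame replicates (100
runs, 5 planted objects each), random Kripke structures of at most 8 states
with formulas of depth at most 3 (1,000 model/formula pairs), and chains of
10^3–10^4 states for the linear-scaling check. Passing them shows the
algorithms are implemented faithfully on controlled inputs; it does *not*
show that real expression data produce monotone index series, that blame
recall on overlapping clusters matches the clean-blob figure, or anything
about algorithms whose traces violate the rs-flag or monotone-flag
invariants. Real microarray or UCI-style datasets enter only through the
CSV reader and the trace format, deliberately outside the test surface.

## Worked example

```{r example}
dip <- make_synthetic_trace("dip", length = 8, t_star = 5, seed = 1)
report <- verify_trace(dip)
tidy(report)
glance(report)
```

The rise-then-fall run fails both verdict formulas; the satisfying sub-trace
is `S1..S4`, the cause `S5..S8`, and the blamed objects are the ones whose
cluster switches coincide with the dip.

```{r plot, fig.width = 6, fig.height = 3}
plot_verification(dip, report)
```

## Known limitations

* Initial-allocation errors — objects misplaced at the very first iteration
  and never moved again — are detected as such but cannot be localized by
  iteration comparison; the report flags them and stops there.
* The verdict inspects the Dunn/diameter pair only. Runs that degrade in a
  way those two indices do not see (e.g. density pathologies at constant
  diameter) verify as valid.
* Comparing *different* clustering schemes, as relative indices do, is out
  of scope: the verifier judges one run at a time.
* Fuzzy memberships, probabilistic iterations (EM) and non-iterative
  algorithms have no program graph and no trace, hence no verdict.
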