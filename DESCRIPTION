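Package: clustmc
Title: Formal Verification of Clustering Runs by CTL Model Checking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Verifies the validity of crisp clustering runs (K-Means, DBSCAN,
    or any algorithm exporting an iteration trace) by model checking.  Each
    run is instrumented into an ordered iteration trace carrying cluster
    assignments and the Dunn and maximum-diameter validity indices; the trace
    is unfolded into a finite Kripke transition system labelled with atomic
    propositions about convergence and index trends, and checked against CTL
    validity properties with an explicit-state fixpoint labelling algorithm.
    On violation the offending iterations are localized by subtracting the
    satisfying sub-trace from the error trace, and the data objects whose
    cluster switches drove the violation are blamed by iteration comparison.
    Also provides the external (Purity, Entropy, Rand, Jaccard,
    Fowlkes-Mallows) and relative (Dunn, diameter, Davies-Bouldin, RMSSTD)
    cluster validity indices, program-graph models of K-Means and DBSCAN, and
    seeded synthetic generators (Gaussian blobs, monotone/dip index traces,
    planted misbehaving objects) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
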