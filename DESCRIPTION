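Package: cognisys
Title: Deterministic Cognizers-System Worlds, Observer-Dependent Probability,
    Entropy, and Inverse-Causality Realization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates finite deterministic multi-agent state-transition
    systems ("cognizers systems") in which every entity, observer or observed,
    is a cognizer with a finite state set and a motion rule over the joint
    state.  Provides relative-frequency probability estimators that depend on
    the observer's standpoint (meta, external, internal) and on whether events
    are conditioned on an earlier cognition (P_cog) or pooled over all
    cognitions (P_overall), with exact rational counting so that the
    total-probability identity holds as an integer-arithmetic fact.  Shannon
    entropies of the resulting event distributions (H_cog, H_overall) and
    entropy differences as amounts of information are computed in bits.  Also
    implements the inverse-causality realization algorithm (ICM/ICW), which
    annotates a perceptual symbol sequence with foreign symbols until every
    element has a unique successor, deriving an internal model of external
    reality; plus canonical scenario generators (repeated coin tosses watched
    by a perfectly discriminating observer, a Maxwell's-demon lattice gas toy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
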