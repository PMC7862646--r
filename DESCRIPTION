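Package: netswitch
Title: Regime-Switching Analysis of Densification in Temporal Contact Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies whether densification and sparsification of a temporal
    contact network at each point in time is driven by changes in the latent
    population or by changes in the overall contact activity. Implements the
    closed-form moments of a dynamic hidden-variable (fitness) random-graph
    model, the two regime curves linking active nodes to edge counts and their
    inverse maps, the Hamilton filter and Kim smoother for a two-state Markov
    regime-switching observation model, Bayesian parameter estimation by
    adaptive Markov chain Monte Carlo, per-window regime classification with
    an undetermined gray area, reconstruction of the time-varying population
    and activity paths with credible bands, a generative simulator with ground
    truth for validation, and readers for SocioPatterns-style contact event
    lists aggregated into fixed-width snapshot windows.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
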