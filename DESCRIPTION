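Package: jmscan
Title: Fast Semiparametric Joint Models for Longitudinal and Competing Risks
    Data via Linear Scan Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a shared random effects joint model for a Gaussian
    longitudinal outcome and a competing risks time-to-event outcome with
    completely unspecified cause-specific baseline hazards.  Estimation is by
    a customized EM algorithm whose E-step integrals are evaluated with
    standard or pseudo-adaptive Gauss-Hermite quadrature and whose
    per-iteration cost is linear in the number of subjects thanks to three
    scan algorithms over the descending-time subject ordering: a merged scan
    for step-function cumulative hazard lookup, a suffix-sum recursion for
    risk-set aggregates, and an event-prefix mapping for the profiled-
    likelihood score terms that feed the empirical Fisher information.
    Includes a simulator for the joint design, deliberately naive quadratic
    reference implementations for certifying the linear algorithms, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
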