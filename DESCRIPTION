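Package: rfctx
Title: Context and Multifilter Linear-Nonlinear Receptive-Field Models for
    Spiking Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation and comparison of receptive-field models for spiking
    sensory neurons driven by binary bar stimuli. Implements context models
    (a receptive field whose elements are multiplicatively gated by local
    stimulus context fields), fitted by an alternating convex-subproblem
    algorithm with linear, logistic, or Poisson nonlinearities, and
    multifilter linear-nonlinear models estimated by spike-triggered
    covariance, information-theoretic spike-triggered average and covariance,
    maximum-noise-entropy low-rank quadratic models, and direct information
    maximization. Includes bias-corrected single-spike information
    evaluation, a five-fold evaluation protocol, and a
    leaky-integrate-and-fire complex-cell network simulator with short-term
    synaptic depression for generating test data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
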