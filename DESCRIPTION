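Package: cleansig
Title: Bayesian Baseline Correction for Mutational Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes background (baseline) mutational patterns from
    exposure-derived mutation-count spectra by Bayesian inference. The joint
    model combines a Dirichlet likelihood on the observed spectrum
    proportions, a truncated Conway-Maxwell-Poisson likelihood on the
    per-channel mutation counts, Gamma priors on signature activities, and a
    smooth cosine-similarity reward on reconstruction fidelity. Posterior
    sampling uses an adaptive Hamiltonian Monte Carlo sampler with analytic
    gradients. Includes comparator cleaning methods (simple subtraction and
    shrinkage-regularized non-negative least squares), evaluation metrics
    (cosine similarity, Jensen-Shannon divergence, count accuracy, injection
    precision/sensitivity/F1), and a synthetic-spectrum generator with a
    signature-injection benchmark protocol. Supports SBS96, SBS288, DBS78,
    and ID83 mutation classifications in SigProfiler-style matrix files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
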