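Package: splithmm
Title: Split Hidden Markov Models of Social Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and fitting a two-level discrete Bayesian
    ("split") hidden Markov model of social inference, in which latent all-Bad,
    all-Good and Integrated person representations supply dispositional and
    situational priors over another agent's intentions and circumstances.
    Includes mean-field variational inference over categorical state
    trajectories, trial-to-trial Dirichlet learning, scripted simulation
    scenarios reproducing idealization, devaluation and bistable belief
    dynamics, derived metrics (learning rate, posterior entropy), a
    harm-aversion choice model for moral-inference tasks, maximum-likelihood
    fitting with nested model comparison, and a parameter-recovery harness
    driven by a synthetic-cohort generator.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    lhs,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
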