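# Within-trial mean-field inference against enumeration oracles.

test_that("uninformative likelihoods leave posteriors at the priors", {
  m <- sim_model(pi_o1 = 1e-6, pi_o2 = 1e-6, psi_split = 0)
  # single epoch: with a near-flat likelihood the posterior is the prior
  b <- infer_trial(m, trial_observations(o1 = 6L, o2 = 3L))
  pri <- prior_expectations(m)
  expect_equal(b$q_internal[, 1], unname(pri$disp["Integrated", ]),
               tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(b$q_external[, 1], rep(0.2, 5), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_true(b$converged)
})

test_that("posteriors are normalized and the free energy is finite", {
  set.seed(11)
  for (i in 1:10) {
    m <- sim_model(psi_split = runif(1), psi_bad = runif(1),
                   pi_o1 = runif(1, 0.1, 2), pi_o2 = runif(1, 0.001, 2))
    obs <- trial_observations(sample(1:11, 2, TRUE), sample(1:5, 2, TRUE))
    b <- infer_trial(m, obs)
    expect_equal(colSums(b$q_internal), rep(1, 2), tolerance = 1e-8)
    expect_equal(colSums(b$q_external), rep(1, 2), tolerance = 1e-8)
    expect_equal(sum(b$q_person), 1, tolerance = 1e-8)
    expect_true(is.finite(b$free_energy))
  }
})

test_that("single-epoch posterior matches exact enumeration when the external state is pinned", {
  # a near-deterministic cue pins q(s2), making the factorization exact
  m <- sim_model(psi_split = 0, pi_o1 = 1, pi_o2 = 100)
  obs <- trial_observations(o1 = 2L, o2 = 3L)
  b <- infer_trial(m, obs)
  ex <- enumerate_posterior(m, prior_expectations(m), obs)
  expect_lt(tv_distance(b$q_internal[, 1], ex$q1[, 1]), 1e-6)
  expect_lt(tv_distance(b$q_external[, 1], ex$q2[, 1]), 1e-6)
})

test_that("mean-field marginals match enumeration in the near-deterministic regime", {
  # near-deterministic regime: precise behaviour and cue likelihoods, modal
  # observations generated at neutral circumstances, where the exact
  # posterior itself concentrates. Outside this regime (degenerate
  # likelihood maps via the floor/ceiling rule, or contradictory
  # observations) the exact posterior is graded and the mean-field solution
  # is overconfident; that divergence is characterized in the test below.
  set.seed(21)
  worst <- 0
  for (i in 1:120) {
    m <- sim_model(psi_split = runif(1, 0, 0.5), psi_bad = runif(1),
                   psi_ext = runif(1), pi_o1 = runif(1, 10, 16),
                   pi_o2 = runif(1, 16, 24), pi_s1 = runif(1, 0.3, 3))
    T_ <- sample(1:2, 1)
    s1 <- rep(sample(1:5, 1), T_)
    o1 <- vapply(seq_len(T_), function(t) which.max(m$A1[, s1[t], 3]),
                 integer(1))
    obs <- trial_observations(o1, rep(3L, T_))
    b <- infer_trial(m, obs)
    ex <- enumerate_posterior(m, prior_expectations(m), obs)
    for (t in seq_len(T_)) {
      worst <- max(worst, tv_distance(b$q_internal[, t], ex$q1[, t]),
                   tv_distance(b$q_external[, t], ex$q2[, t]))
    }
    worst <- max(worst, tv_distance(b$q_person, ex$q_person))
  }
  expect_lt(worst, 0.02)
})

test_that("outside the near-deterministic regime mean-field is overconfident, not biased", {
  # with moderate precisions the exact marginals stay graded while the
  # coordinate-ascent solution commits; the approximation loses entropy but
  # still respects the evidence bound
  set.seed(22)
  n_overconfident <- 0
  n <- 40
  for (i in seq_len(n)) {
    m <- sim_model(psi_split = runif(1, 0, 0.5), psi_bad = runif(1),
                   psi_ext = runif(1), pi_o1 = runif(1, 1, 4),
                   pi_o2 = runif(1, 1, 4), pi_s1 = runif(1, 0.3, 3))
    obs <- trial_observations(sample(1:11, 1), sample(1:5, 1))
    b <- infer_trial(m, obs)
    ex <- enumerate_posterior(m, prior_expectations(m), obs)
    expect_gte(b$free_energy, -ex$log_evidence - 1e-9)
    ent <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
    if (ent(b$q_internal[, 1]) <= ent(ex$q1[, 1]) + 1e-9)
      n_overconfident <- n_overconfident + 1
  }
  expect_gte(n_overconfident / n, 0.9)
})

test_that("free energy decreases over sweeps and upper-bounds the negative log evidence", {
  set.seed(31)
  for (i in 1:20) {
    m <- sim_model(psi_split = runif(1), psi_bad = runif(1),
                   pi_o1 = runif(1, 0.2, 3), pi_o2 = runif(1, 0.01, 3))
    obs <- trial_observations(sample(1:11, 2, TRUE), sample(1:5, 2, TRUE))
    b <- infer_trial(m, obs)
    expect_true(all(diff(b$free_energy_trace) <= 1e-9))
    ex <- enumerate_posterior(m, prior_expectations(m), obs)
    expect_gte(b$free_energy, -ex$log_evidence - 1e-9)
  }
})

test_that("free_energy() agrees with the engine and ranks candidate posteriors", {
  m <- sim_model(psi_split = 0.2, pi_o1 = 1, pi_o2 = 1)
  obs <- trial_observations(c(3L, 4L), c(2L, 2L))
  pri <- prior_expectations(m)
  b <- infer_trial(m, obs)
  expect_equal(free_energy(m, pri, b, obs), b$free_energy, tolerance = 1e-8)
  # any other normalized posterior has equal or higher free energy
  unif <- list(q_internal = matrix(1 / 5, 5, 2),
               q_external = matrix(1 / 5, 5, 2), q_person = rep(1 / 3, 3))
  expect_gte(free_energy(m, pri, unif, obs), b$free_energy)
  # exact posterior of a factorized (pinned-cue) problem attains -log evidence
  mp <- sim_model(psi_split = 0, pi_o1 = 1, pi_o2 = 200)
  obs1 <- trial_observations(o1 = 9L, o2 = 4L)
  bp <- infer_trial(mp, obs1)
  exp_ <- enumerate_posterior(mp, prior_expectations(mp), obs1)
  expect_equal(bp$free_energy, -exp_$log_evidence, tolerance = 1e-4)
})

test_that("repeated worst-bin behaviour activates the Bad person state", {
  m <- sim_model(psi_split = 0.25, psi_bad = 1)
  obs <- lapply(1:6, function(t) trial_observations(c(1L, 1L)))
  run <- run_trials(m, obs)
  expect_gt(max(run$q_person["Bad", ]), 0.5)
  expect_gt(run$q_person["Bad", 6], 0.5)
})

test_that("the split-free model reduces to the Integrated-only model", {
  set.seed(41)
  for (i in 1:20) {
    params <- split_params(psi_split = 0, psi_bad = runif(1),
                           psi_ext = runif(1), pi_o1 = runif(1, 0.2, 2),
                           pi_o2 = runif(1, 0.01, 2), pi_s1 = runif(1, 0.3, 3))
    full <- split_hmm(params)
    reduced <- split_hmm(params, person_states = "integrated_only")
    obs <- trial_observations(sample(1:11, 2, TRUE), sample(1:5, 2, TRUE))
    bf <- infer_trial(full, obs)
    br <- infer_trial(reduced, obs)
    expect_equal(bf$q_internal, br$q_internal, tolerance = 1e-8)
    expect_equal(bf$q_external, br$q_external, tolerance = 1e-8)
  }
})

test_that("valence mirror: flipped observations give mirrored posteriors", {
  set.seed(51)
  for (i in 1:10) {
    pb <- runif(1)
    params <- split_params(psi_split = runif(1), psi_bad = pb,
                           psi_ext = runif(1), pi_o1 = runif(1, 0.2, 2),
                           pi_o2 = runif(1, 0.01, 2))
    mirror <- split_params(psi_split = params$psi_split, psi_bad = 1 - pb,
                           psi_ext = params$psi_ext, pi_o1 = params$pi_o1,
                           pi_o2 = params$pi_o2)
    o1 <- sample(1:11, 2, TRUE)
    o2 <- sample(1:5, 2, TRUE)
    b1 <- infer_trial(split_hmm(params), trial_observations(o1, o2))
    b2 <- infer_trial(split_hmm(mirror),
                      trial_observations(12L - o1, 6L - o2))
    expect_equal(b1$q_internal, b2$q_internal[5:1, ], tolerance = 1e-7,
                 ignore_attr = TRUE)
    expect_equal(b1$q_external, b2$q_external[5:1, ], tolerance = 1e-7,
                 ignore_attr = TRUE)
    expect_equal(b1$q_person, rev(b2$q_person), tolerance = 1e-7,
                 ignore_attr = TRUE)
  }
})

test_that("predictive distribution mixes the behaviour likelihood over beliefs", {
  m <- sim_model(pi_o1 = 0.75)
  # degenerate beliefs return the matching likelihood column
  pd <- predict_next_behavior(m, list(q_internal = c(0, 0, 1, 0, 0),
                                      q_external = c(0, 0, 1, 0, 0)))
  expect_equal(pd$over_behavior, m$A1[, 3, 3], tolerance = 1e-12)
  expect_equal(pd$map_value, 0.5)
  # uniform beliefs give the equal mixture of all columns
  pu <- predict_next_behavior(m, list(q_internal = rep(0.2, 5),
                                      q_external = rep(0.2, 5)))
  expect_equal(pu$over_behavior, apply(m$A1, 1, mean), tolerance = 1e-12)
  expect_equal(sum(pu$over_behavior), 1, tolerance = 1e-10)
})

test_that("an informative unfavorable cue lowers the predicted behaviour", {
  m <- sim_model(pi_o1 = 0.75, pi_o2 = 2)
  beliefs <- list(q_internal = c(0, 0, 1, 0, 0), q_external = rep(0.2, 5))
  no_cue <- predict_next_behavior(m, beliefs)
  cue <- predict_next_behavior(m, beliefs, cue_observed = 1L)
  mean_val <- function(p) sum(p * m$space$behavior_values)
  expect_lt(mean_val(cue$over_behavior), mean_val(no_cue$over_behavior))
  # enumeration cross-check of the cue-updated mixture
  q2c <- m$A2[1, ] * 0.2
  q2c <- q2c / sum(q2c)
  manual <- rowSums(sapply(1:5, function(k) m$A1[, 3, k] * q2c[k]))
  expect_equal(cue$over_behavior, manual, tolerance = 1e-10)
})

test_that("observation indices are validated", {
  m <- sim_model()
  expect_error(infer_trial(m, trial_observations(12L)), "out of range")
  expect_error(infer_trial(m, trial_observations(3L, 9L)), "out of range")
  bad_priors <- prior_expectations(m)
  bad_priors$person <- c(2, 1, 1)
  expect_error(infer_trial(m, trial_observations(3L), priors = bad_priors),
               "normalized")
})
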