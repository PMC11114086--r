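# Model construction: parameters, likelihood tensors, transitions, priors.

test_that("person prior concentrations follow the splitting weights", {
  expect_equal(unname(person_prior_concentrations(0, 0.7)), c(0, 1, 0))
  expect_equal(unname(person_prior_concentrations(1, 0.5)), c(0.5, 0, 0.5))
  expect_equal(unname(person_prior_concentrations(0.25, 1)), c(0.25, 0.75, 0))
  # components always sum to one and lie in [0, 1]
  for (ps in seq(0, 1, 0.2)) for (pb in seq(0, 1, 0.25)) {
    d <- person_prior_concentrations(ps, pb)
    expect_equal(sum(d), 1)
    expect_true(all(d >= 0 & d <= 1))
  }
  expect_error(person_prior_concentrations(1.2, 0.5), "0, 1")
})

test_that("parameter constructor validates ranges", {
  expect_error(split_params(psi_split = -0.1), "psi_split")
  expect_error(split_params(pi_o1 = 0), "pi_o1")
  p <- split_params()
  expect_equal(p$pi_split_fixed, 3)
})

test_that("behaviour likelihood peaks at each internal state's own level", {
  space <- state_space("simulation")
  A1 <- build_behavior_likelihood(space, 0.75)
  neutral <- 3L
  for (i in 1:5)
    expect_equal(which.max(A1[, i, neutral]), space$mode_bins[i])
  # all 25 columns are normalized distributions
  for (i in 1:5) for (k in 1:5) {
    expect_equal(sum(A1[, i, k]), 1, tolerance = 1e-10)
    expect_true(all(A1[, i, k] >= 0))
  }
  expect_error(build_behavior_likelihood(space, -1), "positive")
})

test_that("external states shift the behaviour mode with floor and ceiling", {
  space <- state_space("simulation")
  A1 <- build_behavior_likelihood(space, 0.75)
  # Unfavorable shifts down one level, floored at level 2
  expect_equal(which.max(A1[, 5, 2]), space$mode_bins[4])
  expect_equal(which.max(A1[, 3, 1]), space$mode_bins[2])  # very unfavorable, floor
  expect_equal(which.max(A1[, 2, 1]), space$mode_bins[2])  # already at floor
  expect_equal(which.max(A1[, 1, 2]), space$mode_bins[1])  # below floor: unshifted
  # Favorable shifts up, capped at level 4
  expect_equal(which.max(A1[, 1, 5]), space$mode_bins[3])
  expect_equal(which.max(A1[, 3, 5]), space$mode_bins[4])  # ceiling
  expect_equal(which.max(A1[, 5, 4]), space$mode_bins[5])  # above ceiling: unshifted
})

test_that("behaviour likelihood column matches an independent kernel oracle", {
  space <- state_space("simulation")
  A1 <- build_behavior_likelihood(space, 0.75)
  # (s1 = Good, s2 = Unfavorable): effective level 4, mode bin 9
  expect_equal(A1[, 5, 2], kernel_oracle(11, 9, 0.75), tolerance = 1e-12)
  expect_equal(A1[, 3, 3], kernel_oracle(11, 6, 0.75), tolerance = 1e-12)
})

test_that("cue likelihood spans uninformative to deterministic regimes", {
  space <- state_space("simulation")
  A2u <- build_cue_likelihood(space, 0.001)
  expect_true(all(abs(A2u - 0.2) < 0.02))
  A2i <- build_cue_likelihood(space, 2)
  for (k in 1:5) expect_equal(which.max(A2i[, k]), k)
  A2d <- build_cue_likelihood(space, 100)
  expect_equal(A2d, diag(5), tolerance = 1e-6, ignore_attr = TRUE)
  for (k in 1:5) expect_equal(sum(A2i[, k]), 1, tolerance = 1e-10)
})

test_that("dispositional priors are extreme for split and broad for Integrated", {
  space <- state_space("simulation")
  d <- build_dispositional_priors(space, 2)
  expect_equal(unname(which.max(d["Integrated", ])), 3L)
  expect_equal(unname(which.max(d["Bad", ])), 1L)
  expect_equal(unname(which.max(d["Good", ])), 5L)
  expect_equal(unname(rowSums(d)), rep(1, 3), tolerance = 1e-12)
  # Integrated row equals the index-scale kernel oracle
  expect_equal(unname(d["Integrated", ]), kernel_oracle(5, 3, 2),
               tolerance = 1e-12)
  # split rows are much more concentrated than the Integrated row
  expect_gt(d["Bad", 1], 0.99)
  expect_gt(d["Good", 5], 0.99)
  expect_error(build_dispositional_priors(space, 0), "positive")
})

test_that("situational priors encode one-sided non-neutral support", {
  space <- state_space("simulation")
  d0 <- build_situational_priors(space, 0)
  expect_equal(unname(d0["Bad", ]), c(0, 0, 1, 0, 0))
  expect_equal(unname(d0["Good", ]), c(0, 0, 1, 0, 0))
  d <- build_situational_priors(space, 0.6)
  expect_equal(unname(d["Bad", ]), c(0, 0, 0.4, 0.3, 0.3))
  expect_equal(unname(d["Good", ]), c(0.3, 0.3, 0.4, 0, 0))
  expect_equal(unname(d["Integrated", ]), rep(0.2, 5))
  expect_error(build_situational_priors(space, 1.5), "0, 1")
})

test_that("transition matrices are sticky ordinal walks", {
  space <- state_space("simulation")
  B <- build_transitions(space, 1)
  expect_equal(B$B1, diag(5))
  B <- build_transitions(space, 0.9)
  expect_equal(unname(B$B1[, 2]), c(0.05, 0.9, 0.05, 0, 0))
  expect_equal(unname(B$B1[, 1]), c(0.9, 0.1, 0, 0, 0))
  expect_equal(unname(B$B1[, 5]), c(0, 0, 0, 0.1, 0.9))
  # hand-computed full 5x5 comparison
  Bh <- matrix(0, 5, 5)
  diag(Bh) <- 0.9
  Bh[2, 1] <- Bh[4, 5] <- 0.1
  for (j in 2:4) Bh[c(j - 1, j + 1), j] <- 0.05
  expect_equal(B$B1, Bh)
  expect_equal(colSums(B$B2), rep(1, 5))
  expect_error(build_transitions(space, 0), "0, 1")
})

test_that("mirror symmetry: reversing the valence axis swaps Bad and Good", {
  space <- state_space("simulation")
  d <- build_dispositional_priors(space, 0.7)
  expect_equal(unname(d["Bad", ]), unname(rev(d["Good", ])))
  expect_equal(unname(d["Integrated", ]), unname(rev(d["Integrated", ])))
  s <- build_situational_priors(space, 0.4)
  expect_equal(unname(s["Bad", ]), unname(rev(s["Good", ])))
  A1 <- build_behavior_likelihood(space, 0.5)
  # flipping both the internal and external axes mirrors the behaviour bins
  for (i in 1:5) for (k in 1:5)
    expect_equal(A1[, i, k], rev(A1[, 6 - i, 6 - k]), tolerance = 1e-12)
})

test_that("precision monotonically sharpens every distribution", {
  space <- state_space("simulation")
  ent <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  pis <- c(0.1, 0.5, 1, 2, 5)
  for (i in 1:5) for (k in 1:5) {
    e <- vapply(pis, function(p) ent(build_behavior_likelihood(space, p)[, i, k]),
                numeric(1))
    expect_true(all(diff(e) < 0))
  }
  e2 <- vapply(pis, function(p) ent(build_cue_likelihood(space, p)[, 3]),
               numeric(1))
  expect_true(all(diff(e2) < 0))
  eI <- vapply(pis, function(p)
    ent(build_dispositional_priors(space, p)["Integrated", ]), numeric(1))
  expect_true(all(diff(eI) < 0))
})

test_that("assembled model applies base counts and rigidity flags", {
  m <- split_hmm(split_params(psi_split = 0.2, psi_bad = 0.75))
  expect_equal(sum(m$d_disp["Integrated", ]), 10)
  expect_equal(sum(m$d_sit), 30)
  expect_equal(sum(m$d_disp["Bad", ]), 1e6)
  expect_equal(unname(m$d_person), c(0.15, 0.8, 0.05))
  expect_true(all(m$rigid_mask[c("Bad", "Good")]))
  mr <- split_hmm(split_params(), base_count_split = 10, rigid_split = FALSE)
  expect_equal(sum(mr$d_disp["Bad", ]), 10)
  expect_false(any(mr$rigid_mask))
  mi <- split_hmm(split_params(), person_states = "integrated_only")
  expect_equal(nrow(mi$d_disp), 1L)
})

test_that("task mode uses the 11-level harm-aversion grid", {
  space <- state_space("task")
  expect_equal(space$n_internal, 11L)
  expect_equal(space$internal_values, seq(0, 1, 0.1))
  m <- split_hmm(split_params(), mode = "task")
  expect_null(m$A1)
  expect_equal(ncol(m$d_disp), 11L)
})
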