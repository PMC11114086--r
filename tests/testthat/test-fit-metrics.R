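# Derived metrics, likelihood identities, fitting and model comparison.

test_that("learning rate recovers canonical updating regimes", {
  o <- c(0.2, 0.8, 0.4, 0.6, 0.3)
  # full updating: next prediction equals the last outcome
  p_full <- c(0.5, o[-5])
  expect_equal(learning_rate(p_full, o)$alpha, 1)
  # frozen predictions
  expect_equal(learning_rate(rep(0.5, 5), o)$alpha, 0)
  # three-point toy sequence against the closed-form slope
  p <- c(0.1, 0.3, 0.4)
  oo <- c(0.9, 0.5, 0.2)
  pe <- oo[1:2] - p[1:2]
  dp <- diff(p)
  expect_equal(learning_rate(p, oo)$alpha, sum(dp * pe) / sum(pe^2))
  # degenerate case: zero prediction errors
  r <- learning_rate(c(0.5, 0.5), c(0.5, 0.7))
  expect_false(r$defined)
  expect_true(is.na(r$alpha))
  # intercept variant matches lm
  set.seed(8)
  p2 <- runif(6)
  o2 <- runif(6)
  fit <- lm(diff(p2) ~ I(o2[1:5] - p2[1:5]))
  expect_equal(learning_rate(p2, o2, intercept = TRUE)$alpha,
               unname(coef(fit)[2]))
})

test_that("posterior entropy follows the Shannon formula", {
  expect_equal(posterior_entropy(rep(1 / 11, 11)), log(11))
  expect_equal(posterior_entropy(c(1, rep(0, 10))), 0)
  expect_equal(posterior_entropy(c(0.5, 0.5, rep(0, 9))), log(2))
  expect_error(posterior_entropy(c(0.5, 0.2)), "not")
})

test_that("fit results satisfy the BIC and pseudo-R2 identities", {
  p <- split_params(psi_split = 0.4, psi_bad = 0.7, pi_o1 = 9, pi_s1 = 1)
  ds <- simulate_task_participant(p, seed = 6)
  f <- fit_participant(ds, spec = fit_spec(free = c("psi_bad", "psi_split")),
                       settings = fit_settings(n_starts = 3, seed = 2))
  expect_equal(f$bic, f$k * log(f$n_obs) - 2 * f$log_likelihood)
  expect_equal(f$pseudo_r2, 1 - f$log_likelihood / (f$n_obs * log(1 / 11)))
  expect_equal(f$n_obs, 34)  # prior + 16 posterior ratings per agent
  expect_equal(f$k, 2)
  expect_true(f$converged)
  # deterministic given seed and data
  f2 <- fit_participant(ds, spec = fit_spec(free = c("psi_bad", "psi_split")),
                        settings = fit_settings(n_starts = 3, seed = 2))
  expect_identical(unclass(f$estimates), unclass(f2$estimates))
  expect_identical(f$log_likelihood, f2$log_likelihood)
})

test_that("excluding the prior rating drops two likelihood points", {
  p <- split_params(psi_split = 0.2, pi_o1 = 9)
  ds <- simulate_task_participant(p, seed = 7)
  st <- fit_settings(n_starts = 2, seed = 1, include_prior_rating = FALSE)
  f <- fit_participant(ds, spec = fit_spec(free = "psi_bad"), settings = st)
  expect_equal(f$n_obs, 32)
})

test_that("the full model's likelihood dominates its restrictions", {
  p <- split_params(psi_split = 0.5, psi_bad = 0.8, pi_o1 = 9, pi_s1 = 1)
  ds <- simulate_task_participant(p, seed = 9)
  st <- fit_settings(n_starts = 4, seed = 3)
  full <- fit_participant(ds, fit_spec(), st)
  restricted <- fit_participant(
    ds, fit_spec(free = c("pi_o1", "pi_s1", "psi_ext"),
                 fixed = list(psi_split = 0)), st)
  expect_gte(full$log_likelihood, restricted$log_likelihood - 1e-6)
})

test_that("model comparison statistics follow the stated conventions", {
  p1 <- split_params(psi_split = 0.6, psi_bad = 0.9, pi_o1 = 9, pi_s1 = 1)
  p2 <- split_params(psi_split = 0.3, psi_bad = 0.2, pi_o1 = 9, pi_s1 = 1)
  ds <- rbind(simulate_task_participant(p1, seed = 1, participant_id = "a"),
              simulate_task_participant(p2, seed = 2, participant_id = "b"))
  st <- fit_settings(n_starts = 3, seed = 5)
  full <- fit_cohort(ds, fit_spec(free = c("psi_bad", "psi_split")), st)
  restr <- fit_cohort(ds, fit_spec(free = "psi_bad",
                                   fixed = list(psi_split = 0)), st)
  cmp <- compare_models(full, restr)
  expect_equal(cmp$df, 1)
  expect_equal(cmp$n, 2)
  expect_equal(cmp$chisq_mean, 2 * mean(cmp$table$log_lr))
  expect_equal(cmp$chisq_sum, 2 * sum(cmp$table$log_lr))
  # spreadsheet check of the BIC arithmetic per participant
  for (i in 1:2) {
    expect_equal(cmp$table$delta_bic[i],
                 (1 * log(34) - 2 * cmp$table$ll_restricted[i]) -
                   (2 * log(34) - 2 * cmp$table$ll_full[i]))
  }
  expect_true(all(cmp$table$log_lr >= -1e-6))
  # identical fit sets give zero log LR and a pure complexity-penalty dBIC
  same <- compare_models(full, full, df = 0)
  expect_equal(same$mean_log_lr, 0)
  expect_equal(same$mean_delta_bic, 0)
  expect_error(compare_models(full, restr[1]), "different participants")
})

test_that("extreme splitting separates cleanly in a degenerate recovery check", {
  # participants generated at the two poles of psi_split must be perfectly
  # rank-separated by the recovered values
  mk <- function(ps, id, seed) simulate_task_participant(
    split_params(psi_split = ps, psi_bad = 0.5, pi_o1 = 9, pi_s1 = 1),
    seed = seed, participant_id = id)
  ds <- rbind(mk(0, "lo1", 11), mk(0, "lo2", 12), mk(1, "hi1", 13),
              mk(1, "hi2", 14))
  st <- fit_settings(n_starts = 4, seed = 7)
  fits <- fit_cohort(ds, fit_spec(free = c("psi_bad", "psi_split")), st)
  est <- vapply(fits, function(f) f$estimates$psi_split, numeric(1))
  expect_lt(max(est[c("lo1", "lo2")]), min(est[c("hi1", "hi2")]))
})

test_that("shuffled truths decorrelate from recoveries", {
  # null check on the correlation computation itself
  set.seed(15)
  true_v <- runif(30)
  est_v <- true_v + rnorm(30, 0, 0.1)
  expect_gt(cor(true_v, est_v), 0.8)
  shuffled <- sample(true_v)
  expect_lt(abs(cor(shuffled, est_v)), 0.4)
})

test_that("cohort learning metrics show the agent asymmetry for optimistic observers", {
  # observers with a prominent latent Good mode (psi_bad well below 0.5)
  # idealize the good agent, freezing beliefs about it: learning rate and
  # uncertainty are higher for the bad than the good agent
  gs <- list(control = list(n = 10, params = list(
    psi_split = list(dist = "beta", mean = 0.3, conc = 20),
    psi_bad = list(dist = "beta", mean = 0.2, conc = 20),
    psi_ext = 0.6, pi_o1 = 9, pi_s1 = 1, pi_o2 = 0.001)))
  ds <- generate_cohort(gs, seed = 21)
  met <- cohort_learning_metrics(ds)
  wide <- function(col) reshape(met[, c("participant_id", "agent", col)],
                                idvar = "participant_id", timevar = "agent",
                                direction = "wide")
  wa <- wide("alpha")
  expect_gt(mean(wa$alpha.bad - wa$alpha.good, na.rm = TRUE), 0)
  we <- wide("mean_entropy")
  expect_gt(mean(we$mean_entropy.bad - we$mean_entropy.good), 0)
})
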