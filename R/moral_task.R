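# Moral-inference task: harm-aversion choice rule, 11-level harm-aversion
# grid, truncated-Gaussian emission, choice and rating likelihoods, and the
# synthetic cohort generator.

#' A money-shocks choice option
#'
#' The harmful option of a pair yields `delta_money` extra currency units for
#' the agent at the cost of `delta_shocks` extra shocks for a third person.
#' The indifference threshold is `theta = delta_money / (delta_money +
#' delta_shocks)`: an agent with harm aversion below `theta` prefers the
#' harmful option.
#'
#' @param delta_money,delta_shocks non-negative differences between the two
#'   options (not both zero).
#' @return An object of class `choice_option`.
#' @export
choice_option <- function(delta_money, delta_shocks) {
  if (delta_money < 0 || delta_shocks < 0 || delta_money + delta_shocks <= 0)
    stop("deltas must be non-negative and not both zero")
  structure(list(delta_money = delta_money, delta_shocks = delta_shocks,
                 threshold = delta_money / (delta_money + delta_shocks)),
            class = "choice_option")
}

#' Subjective value of the harmful choice
#'
#' `V_harm(kappa) = (1 - kappa) * delta_money - kappa * delta_shocks`:
#' positive exactly when the agent's harm aversion is below the option's
#' threshold.
#'
#' @param kappa harm aversion in \[0, 1\].
#' @param option a [choice_option()].
#' @return Scalar subjective value.
#' @examples
#' harm_value(0.3, choice_option(5, 4)) # 2.3
#' @export
harm_value <- function(kappa, option) {
  stopifnot(kappa >= 0, kappa <= 1)
  (1 - kappa) * option$delta_money - kappa * option$delta_shocks
}

#' An observed agent
#'
#' @param label `"bad"` or `"good"`; canonical harm aversions are 0.3 and
#'   0.7.
#' @param kappa harm aversion; defaults to the canonical value for the label.
#' @return An object of class `agent_spec`.
#' @export
agent_spec <- function(label = c("bad", "good"), kappa = NULL) {
  label <- match.arg(label)
  if (is.null(kappa)) kappa <- if (label == "bad") 0.3 else 0.7
  stopifnot(kappa >= 0, kappa <= 1)
  structure(list(label = label, kappa = kappa), class = "agent_spec")
}

# external-state shift of expected harm aversion on the kappa scale
.KAPPA_SHIFT <- c(-0.2, -0.1, 0, 0.1, 0.2)

#' Probability of the harmful choice under the subject's model
#'
#' Each internal state emits a harm-aversion setting from a Gaussian with
#' mean equal to the state's expected harm aversion (shifted by the external
#' state: +0.1 per favorable level, -0.1 per unfavorable level, doubled for
#' "Very", clipped to \[0, 1\]) and precision `pi_o1`, truncated to (0, 1).
#' Given the emitted value the agent deterministically selects the option
#' with the highest subjective value, so the harmful-choice probability is
#' the truncated-Gaussian mass below the option's threshold.
#'
#' @param internal_level internal state index (1..11; may be a vector).
#' @param external_level external state index (1..5).
#' @param option a [choice_option()].
#' @param pi_o1 emission precision (> 0).
#' @param space the task [state_space()].
#' @return Probability (vectorized over `internal_level`).
#' @export
choice_probability <- function(internal_level, external_level, option, pi_o1,
                               space = state_space("task")) {
  stopifnot(pi_o1 > 0)
  mu <- space$internal_values[internal_level] + .KAPPA_SHIFT[external_level]
  mu <- pmin(pmax(mu, 0), 1)
  sdv <- 1 / sqrt(pi_o1)
  z <- pnorm(1, mu, sdv) - pnorm(0, mu, sdv)
  p <- (pnorm(option$threshold, mu, sdv) - pnorm(0, mu, sdv)) / z
  pmin(pmax(p, 0), 1)
}

#' Deterministic agent choices
#'
#' The programmed agent picks the harmful option exactly when its subjective
#' value is positive (ties resolved helpful).
#'
#' @param agent an [agent_spec()].
#' @param options data.frame with columns `delta_money`, `delta_shocks` (one
#'   row per choice).
#' @param seed unused placeholder for API symmetry (choices are
#'   deterministic given the agent).
#' @return Character vector of `"harmful"` / `"helpful"`.
#' @export
simulate_agent_choices <- function(agent, options, seed = NULL) {
  v <- (1 - agent$kappa) * options$delta_money -
    agent$kappa * options$delta_shocks
  ifelse(v > 0, "harmful", "helpful")
}

#' Canonical synthetic option set
#'
#' `n_choices` money-shocks pairs whose thresholds cover `theta_range`
#' evenly, so each agent makes both harmful and helpful choices; presentation
#' order is shuffled per seed.
#'
#' @param design a [task_design()].
#' @param seed integer seed for the shuffle.
#' @return data.frame with columns `delta_money`, `delta_shocks`,
#'   `threshold`.
#' @export
task_options <- function(design = task_design(), seed = 1L) {
  theta <- seq(design$theta_range[1], design$theta_range[2],
               length.out = design$n_choices)
  dm <- theta * design$option_total
  ds <- design$option_total - dm
  set.seed(seed)
  ord <- sample.int(design$n_choices)
  data.frame(delta_money = dm[ord], delta_shocks = ds[ord],
             threshold = theta[ord])
}

#' Moral-inference task design
#'
#' @param n_choices choices observed per agent (48, with a moral-character
#'   rating before any observation and after every third choice).
#' @param epochs_per_trial model epochs per trial (3; one trial per rating
#'   block).
#' @param theta_range range of option thresholds.
#' @param option_total combined money + shocks magnitude of each option pair.
#' @param kappa_bad,kappa_good canonical agent harm aversions.
#' @return A list of class `task_design`.
#' @export
task_design <- function(n_choices = 48, epochs_per_trial = 3,
                        theta_range = c(0.05, 0.95), option_total = 20,
                        kappa_bad = 0.3, kappa_good = 0.7) {
  if (n_choices %% epochs_per_trial != 0)
    stop("n_choices must be a multiple of epochs_per_trial")
  structure(list(n_choices = n_choices, epochs_per_trial = epochs_per_trial,
                 theta_range = theta_range, option_total = option_total,
                 kappa_bad = kappa_bad, kappa_good = kappa_good),
            class = "task_design")
}

#' Discretize a 0-100 rating onto the internal-state grid
#'
#' Bin k (1..11, value (k-1)/10) covers \[10(k-1) - 5, 10(k-1) + 5), with the
#' end bins clipped to the scale.
#'
#' @param rating rating(s) in \[0, 100\].
#' @return Integer bin indices.
#' @export
rating_bin <- function(rating) {
  if (any(rating < 0 | rating > 100)) stop("ratings must lie in [0, 100]")
  pmin(pmax(floor((rating + 5) / 10) + 1, 1), 11)
}

#' Likelihood of a reported moral-character rating
#'
#' Treats the discretized rating as a sample from the subject's posterior
#' over internal states: the likelihood is the posterior mass of the rating's
#' bin, floored at `eps` and renormalized so every rating has positive
#' probability.
#'
#' @param posterior_over_s1 normalized posterior over the 11 internal states.
#' @param rating rating in \[0, 100\].
#' @param eps floor applied to each bin before renormalization.
#' @return Probability of the rating.
#' @export
rating_likelihood <- function(posterior_over_s1, rating, eps = 1e-6) {
  stopifnot(length(posterior_over_s1) == 11,
            abs(sum(posterior_over_s1) - 1) < 1e-6)
  qf <- pmax(posterior_over_s1, eps)
  qf <- qf / sum(qf)
  qf[rating_bin(rating)]
}

# per-epoch floored-log likelihood arrays for a choice sequence (vectorized
# over all epochs: columns of ph are P(harmful | s1, s2) per option)
.task_loglik_arrays <- function(model, options, choices) {
  n1 <- model$space$n_internal
  n2 <- model$space$n_external
  E <- nrow(options)
  stopifnot(length(choices) == E)
  sdv <- 1 / sqrt(model$params$pi_o1)
  mu <- as.numeric(pmin(pmax(
    outer(model$space$internal_values, .KAPPA_SHIFT, `+`), 0), 1))
  p0 <- pnorm(0, mu, sdv)
  z <- pnorm(1, mu, sdv) - p0
  thr <- matrix(rep(options$threshold, each = n1 * n2), nrow = n1 * n2)
  ph <- (pnorm(thr, mu, sdv) - p0) / z
  ph[ph < 0] <- 0
  ph[ph > 1] <- 1
  harmful <- choices == "harmful"
  L <- ph
  L[, !harmful] <- 1 - L[, !harmful, drop = FALSE]
  list(lL1 = as.numeric(.flog(L)), lL2 = numeric(n2 * E))
}

#' Run the subject model over one agent's choice sequence
#'
#' Observed choices enter as per-epoch likelihood messages over the joint
#' internal x external state; no cues are observed. Priors are updated after
#' every trial (rating block).
#'
#' @param model a task-mode [split_hmm()].
#' @param options option data.frame (one row per choice).
#' @param choices `"harmful"` / `"helpful"` per choice.
#' @param design a [task_design()].
#' @param settings an [infer_settings()] list.
#' @return A `split_hmm_run`, plus element `rating_posteriors`: a matrix
#'   whose first column is the prior-mixture belief (used for the initial
#'   rating) and subsequent columns the internal-state posterior at each
#'   rating point (trial end).
#' @export
run_task_sequence <- function(model, options, choices,
                              design = task_design(),
                              settings = infer_settings()) {
  stopifnot(model$mode == "task")
  ll <- .task_loglik_arrays(model, options, choices)
  pri <- prior_expectations(model)
  prior_mix <- drop(pri$person %*% pri$disp)
  run <- .run_sequence(model, ll, design$epochs_per_trial, settings,
                       learn = TRUE, config = learning_config())
  last_cols <- design$epochs_per_trial * seq_len(run$n_trials)
  run$rating_posteriors <- cbind(prior = prior_mix,
                                 run$q_internal[, last_cols, drop = FALSE])
  run
}

#' Simulate one synthetic participant on the two-agent task
#'
#' The participant observes each agent's 48 programmed choices in turn
#' (independent runs from the same initial priors) and reports moral
#' character by sampling an internal state from their current belief at each
#' rating point (bin centres, no added jitter): once before any observation
#' and after every third choice. Certainty is reported descriptively as one
#' minus the normalized posterior entropy.
#'
#' @param params a [split_params()] (with `pi_o2` typically 0.001; the task
#'   provides no context cues).
#' @param design a [task_design()].
#' @param seed integer seed.
#' @param participant_id,group identifiers for the output table.
#' @return data.frame in the task schema (one row per event): participant_id,
#'   group, agent, trial, epoch, delta_money, delta_shocks, choice, rating,
#'   certainty, rating_type.
#' @export
simulate_task_participant <- function(params, design = task_design(),
                                      seed = 1L, participant_id = "p1",
                                      group = "synthetic") {
  rows <- list()
  for (agent_label in c("bad", "good")) {
    agent <- agent_spec(agent_label,
                        if (agent_label == "bad") design$kappa_bad
                        else design$kappa_good)
    options <- task_options(design,
                            seed = seed + 1000L * match(agent_label,
                                                        c("bad", "good")))
    choices <- simulate_agent_choices(agent, options)
    model <- split_hmm(params, mode = "task")
    run <- run_task_sequence(model, options, choices, design)
    set.seed(seed + 17L * match(agent_label, c("bad", "good")))
    qr <- run$rating_posteriors
    sampled <- apply(qr, 2, function(q) sample.int(11, 1, prob = q))
    ratings <- 10 * (sampled - 1)
    certainty <- 1 - apply(qr, 2, posterior_entropy) / log(11)
    n_trials <- run$n_trials
    T_ <- design$epochs_per_trial
    choice_rows <- data.frame(
      participant_id = participant_id, group = group, agent = agent_label,
      trial = rep(seq_len(n_trials), each = T_),
      epoch = rep(seq_len(T_), times = n_trials),
      delta_money = options$delta_money, delta_shocks = options$delta_shocks,
      choice = choices, rating = NA_real_, certainty = NA_real_,
      rating_type = NA_character_)
    rating_rows <- data.frame(
      participant_id = participant_id, group = group, agent = agent_label,
      trial = c(0L, seq_len(n_trials)), epoch = NA_integer_,
      delta_money = NA_real_, delta_shocks = NA_real_,
      choice = NA_character_, rating = ratings, certainty = certainty,
      rating_type = c("prior", rep("posterior", n_trials)))
    rows[[agent_label]] <- rbind(rating_rows[1, ], choice_rows, rating_rows[-1, ])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# sample one parameter value from a distribution spec
.sample_param <- function(spec) {
  if (is.numeric(spec) && length(spec) == 1) return(spec)
  if (is.numeric(spec) && length(spec) == 2)
    return(runif(1, spec[1], spec[2]))
  if (is.list(spec) && identical(spec$dist, "beta")) {
    k <- if (is.null(spec$conc)) 10 else spec$conc
    return(rbeta(1, spec$mean * k, (1 - spec$mean) * k))
  }
  if (is.list(spec) && identical(spec$dist, "lognormal"))
    return(rlnorm(1, spec$meanlog, spec$sdlog))
  stop("invalid parameter distribution spec")
}

#' Group specifications for the synthetic cohort generator
#'
#' `cohort_groups_default()` emulates a control-like group (optimistic,
#' moderate splitting: mean psi_bad 0.3) and a BPD-like group (symmetric and
#' more prominent splitting: mean psi_bad near 0.5, higher psi_split).
#' `cohort_uniform()` draws every free parameter uniformly over the fitting
#' bounds, as used by the parameter-recovery harness.
#'
#' @param n_control,n_bpd,n group sizes.
#' @return Named list of group specs for [generate_cohort()].
#' @export
cohort_groups_default <- function(n_control = 25, n_bpd = 25) {
  list(
    control = list(n = n_control, params = list(
      psi_split = list(dist = "beta", mean = 0.15, conc = 10),
      psi_bad = list(dist = "beta", mean = 0.30, conc = 10),
      psi_ext = list(dist = "beta", mean = 0.5, conc = 8),
      pi_o1 = list(dist = "lognormal", meanlog = log(8), sdlog = 0.5),
      pi_s1 = list(dist = "lognormal", meanlog = log(1), sdlog = 0.5),
      pi_o2 = 0.001)),
    bpd = list(n = n_bpd, params = list(
      psi_split = list(dist = "beta", mean = 0.35, conc = 10),
      psi_bad = list(dist = "beta", mean = 0.47, conc = 10),
      psi_ext = list(dist = "beta", mean = 0.5, conc = 8),
      pi_o1 = list(dist = "lognormal", meanlog = log(8), sdlog = 0.5),
      pi_s1 = list(dist = "lognormal", meanlog = log(1), sdlog = 0.5),
      pi_o2 = 0.001))
  )
}

#' @rdname cohort_groups_default
#' @param bounds fitting bounds (see [fit_bounds()]).
#' @export
cohort_uniform <- function(n = 40, bounds = fit_bounds()) {
  list(uniform = list(n = n, params = list(
    psi_split = bounds$psi_split, psi_bad = bounds$psi_bad,
    psi_ext = bounds$psi_ext, pi_o1 = bounds$pi_o1, pi_s1 = bounds$pi_s1,
    pi_o2 = 0.001)))
}

#' Generate a synthetic task cohort
#'
#' Samples subject-level parameters per group, simulates every participant on
#' the canonical two-agent design, and returns the combined event table with
#' the generating parameters attached (for parameter recovery).
#'
#' @param group_specs named list of group specs (see
#'   [cohort_groups_default()]).
#' @param design a [task_design()].
#' @param seed integer seed.
#' @return data.frame in the task schema with attribute `true_params` (one
#'   row per participant).
#' @export
generate_cohort <- function(group_specs = cohort_groups_default(),
                            design = task_design(), seed = 1L) {
  datasets <- list()
  truths <- list()
  idx <- 0L
  for (g in names(group_specs)) {
    gs <- group_specs[[g]]
    if (is.null(gs$n) || is.null(gs$params))
      stop("each group spec needs elements n and params")
    for (i in seq_len(gs$n)) {
      idx <- idx + 1L
      set.seed(seed + 1009L * idx)
      vals <- lapply(gs$params, .sample_param)
      params <- do.call(split_params, vals)
      pid <- sprintf("%s_%02d", g, i)
      datasets[[idx]] <- simulate_task_participant(
        params, design, seed = seed + 2003L * idx,
        participant_id = pid, group = g)
      truths[[idx]] <- data.frame(participant_id = pid, group = g,
                                  as.data.frame(unclass(params)[1:6]))
    }
  }
  out <- do.call(rbind, datasets)
  rownames(out) <- NULL
  attr(out, "true_params") <- do.call(rbind, truths)
  out
}
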