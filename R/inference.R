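# Within-trial posterior inference by mean-field free-energy minimization.

#' Observations for a single trial
#'
#' One trial consists of ordered epochs; within an epoch the cue is observed
#' before the behaviour. Either observation may be missing (`NA`), in which
#' case it contributes no likelihood message.
#'
#' @param o1 integer behaviour-bin indices (1..n_behavior) or `NA`, one per
#'   epoch.
#' @param o2 integer cue indices (1..n_cue) or `NA`, one per epoch.
#' @param trial_index optional trial counter.
#' @return An object of class `trial_observations`.
#' @export
trial_observations <- function(o1, o2 = rep(NA_integer_, length(o1)),
                               trial_index = NA_integer_) {
  if (length(o1) != length(o2)) stop("o1 and o2 must have one entry per epoch")
  structure(list(o1 = as.integer(o1), o2 = as.integer(o2),
                 n_epochs = length(o1), trial_index = trial_index),
            class = "trial_observations")
}

#' Inference settings
#'
#' @param tol convergence tolerance on the change in free energy (nats).
#' @param max_iter maximum number of mean-field sweeps per trial.
#' @param damping step size on the log-belief updates; 1 (the default) is pure
#'   sequential coordinate ascent, which guarantees a non-increasing free
#'   energy.
#' @return A list of settings.
#' @export
infer_settings <- function(tol = 1e-4, max_iter = 64, damping = 1) {
  stopifnot(tol > 0, max_iter >= 1, damping > 0, damping <= 1)
  list(tol = tol, max_iter = max_iter, damping = damping)
}

.integrated_index <- function(model) {
  idx <- match("Integrated", rownames(model$d_disp))
  if (is.na(idx)) stop("model has no Integrated person state")
  idx - 1L
}

.check_obs <- function(model, obs) {
  stopifnot(inherits(obs, "trial_observations"))
  if (any(!is.na(obs$o1) & (obs$o1 < 1 | obs$o1 > model$space$n_behavior)))
    stop("behaviour index out of range")
  if (any(!is.na(obs$o2) & (obs$o2 < 1 | obs$o2 > model$space$n_cue)))
    stop("cue index out of range")
}

# flattened floored-log likelihood arrays for a sequence of epochs
.sim_loglik_arrays <- function(model, o1, o2) {
  n1 <- model$space$n_internal
  n2 <- model$space$n_external
  E <- length(o1)
  lL1 <- numeric(n1 * n2 * E)
  lL2 <- numeric(n2 * E)
  lA2 <- .flog(model$A2)
  for (e in seq_len(E)) {
    if (!is.na(o1[e]))
      lL1[(n1 * n2 * (e - 1) + 1):(n1 * n2 * e)] <- .flog(model$A1[o1[e], , ])
    if (!is.na(o2[e]))
      lL2[(n2 * (e - 1) + 1):(n2 * e)] <- lA2[o2[e], ]
  }
  list(lL1 = lL1, lL2 = lL2)
}

.as_belief_state <- function(res, model, trial = 1L, epochs_per_trial = NULL) {
  T_ <- if (is.null(epochs_per_trial)) ncol(res$q_internal) else epochs_per_trial
  cols <- (T_ * (trial - 1) + 1):(T_ * trial)
  structure(list(
    q_internal = res$q_internal[, cols, drop = FALSE],
    q_external = res$q_external[, cols, drop = FALSE],
    q_person = res$q_person[, trial],
    free_energy = res$free_energy[trial],
    free_energy_trace = if (!is.null(res$free_energy_trace))
      res$free_energy_trace[[trial]] else NULL,
    n_iterations = res$n_iterations[trial],
    converged = res$converged[trial]
  ), class = "belief_state")
}

#' Within-trial mean-field inference
#'
#' Computes approximate posteriors over the internal-state and external-state
#' trajectories and the person state for a single trial, by iterating
#' sequential coordinate (mean-field) updates until the variational free
#' energy changes by less than `tol`. The posterior over the person state is
#' updated jointly with the within-trial factors (once-per-trial, iterated to
#' the shared fixed point).
#'
#' @param model a [split_hmm()].
#' @param observations a [trial_observations()].
#' @param priors optional list with elements `person`, `disp`, `sit`
#'   (normalized prior expectations); defaults to [prior_expectations()] of
#'   `model`. Each row/vector must be a probability distribution.
#' @param settings an [infer_settings()] list.
#' @return A `belief_state`: per-epoch posteriors `q_internal`, `q_external`,
#'   the person posterior `q_person`, the converged `free_energy` (nats) and
#'   its per-sweep trace, `n_iterations` and a `converged` flag (failure to
#'   converge within `max_iter` is flagged, not an error).
#' @export
infer_trial <- function(model, observations, priors = NULL,
                        settings = infer_settings()) {
  .check_obs(model, observations)
  if (is.null(priors)) priors <- prior_expectations(model)
  .check_priors(priors)
  ll <- .sim_loglik_arrays(model, observations$o1, observations$o2)
  res <- mf_run_sequence_cpp(
    priors$disp, priors$sit, priors$person, model$B1, model$B2,
    ll$lL1, ll$lL2, observations$n_epochs,
    eta = 0, learn = FALSE, rigid_split = TRUE,
    integrated_index = .integrated_index(model),
    tol = settings$tol, max_iter = settings$max_iter,
    damp = settings$damping, lfloor = .LOG_FLOOR,
    predict = FALSE, A1flat = numeric(0), n_o1 = 0L, keep_trace = TRUE)
  if (!res$converged[1])
    warning("mean-field inference did not converge within max_iter")
  .as_belief_state(res, model)
}

.check_priors <- function(priors) {
  ok <- function(x) all(x >= 0) && all(abs(rowSums(rbind(x)) - 1) < 1e-6)
  if (!ok(priors$disp) || !ok(priors$sit) || abs(sum(priors$person) - 1) > 1e-6)
    stop("priors must be normalized distributions")
  invisible(TRUE)
}

#' Variational free energy of a candidate posterior
#'
#' Evaluates `E_q[log q - log p(o, s)]` for a factorized posterior under the
#' floored-log generative model, i.e. the quantity minimized by
#' [infer_trial()]. It upper-bounds the negative log evidence, with equality
#' when `q` is the exact posterior of a factorized problem.
#'
#' @param model a [split_hmm()].
#' @param priors normalized prior expectations as in [infer_trial()].
#' @param q a `belief_state` or list with `q_internal` (matrix, one column
#'   per epoch), `q_external`, `q_person`.
#' @param observations a [trial_observations()].
#' @return Free energy in nats.
#' @export
free_energy <- function(model, priors, q, observations) {
  .check_obs(model, observations)
  .check_priors(priors)
  q1 <- rbind(q$q_internal)
  q2 <- rbind(q$q_external)
  q3 <- q$q_person
  if (any(abs(colSums(q1) - 1) > 1e-8) || any(abs(colSums(q2) - 1) > 1e-8) ||
      abs(sum(q3) - 1) > 1e-8)
    stop("q factors must be normalized")
  T_ <- observations$n_epochs
  lD <- .flog(priors$disp)
  lS <- .flog(priors$sit)
  lP <- .flog(priors$person)
  lB1 <- .flog(model$B1)
  lB2 <- .flog(model$B2)
  xlx <- function(p) sum(ifelse(p > 0, p * log(p), 0))
  elogp <- sum(q3 * lP) +
    sum(q3 * (lD %*% q1[, 1])) + sum(q3 * (lS %*% q2[, 1]))
  for (t in seq_len(T_)) {
    if (t > 1) {
      elogp <- elogp + drop(t(q1[, t]) %*% lB1 %*% q1[, t - 1]) +
        drop(t(q2[, t]) %*% lB2 %*% q2[, t - 1])
    }
    if (!is.na(observations$o1[t])) {
      lL1 <- .flog(model$A1[observations$o1[t], , ])
      elogp <- elogp + drop(t(q1[, t]) %*% lL1 %*% q2[, t])
    }
    if (!is.na(observations$o2[t]))
      elogp <- elogp + sum(q2[, t] * .flog(model$A2[observations$o2[t], ]))
  }
  elogq <- xlx(q3) + sum(apply(q1, 2, xlx)) + sum(apply(q2, 2, xlx))
  elogq - elogp
}

#' Predictive distribution over upcoming behaviour
#'
#' Mixes the behaviour likelihood over current beliefs about the upcoming
#' epoch's internal and external states,
#' `P(o1) = sum_{s1, s2} P(o1 | s1, s2) q(s1) q(s2)`. If a cue has already
#' been observed for the epoch, the external belief is first updated by the
#' cue likelihood.
#'
#' @param model a [split_hmm()] (simulation mode).
#' @param beliefs list with `q_internal` and `q_external` vectors for the
#'   upcoming epoch.
#' @param cue_observed optional cue index already seen this epoch.
#' @return An object of class `predictive_distribution` with the distribution
#'   `over_behavior`, its modal bin `map_bin` and value `map_value`.
#' @export
predict_next_behavior <- function(model, beliefs, cue_observed = NULL) {
  q1 <- beliefs$q_internal
  q2 <- beliefs$q_external
  stopifnot(abs(sum(q1) - 1) < 1e-6, abs(sum(q2) - 1) < 1e-6)
  if (!is.null(cue_observed) && !is.na(cue_observed))
    q2 <- .normalize(q2 * model$A2[cue_observed, ])
  p <- numeric(model$space$n_behavior)
  for (k in seq_len(model$space$n_external))
    p <- p + model$A1[, , k] %*% q1 * q2[k]
  p <- .normalize(drop(p))
  map_bin <- which.max(p)
  structure(list(over_behavior = p, map_bin = map_bin,
                 map_value = model$space$behavior_values[map_bin]),
            class = "predictive_distribution")
}
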