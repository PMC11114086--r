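# Running the full inference + learning loop over a sequence of trials.

#' Run inference and learning over a sequence of trials
#'
#' Alternates within-trial mean-field inference with trial-to-trial Dirichlet
#' learning over a whole observation sequence (the core loop behind every
#' simulation scenario and the task likelihood). Optionally computes, for
#' every epoch, the predictive distribution over upcoming behaviour after
#' observing that epoch's cue but before its behaviour.
#'
#' @param model a [split_hmm()].
#' @param observations list of [trial_observations()] (all with the same
#'   number of epochs), or a single `trial_observations` spanning the whole
#'   sequence together with `epochs_per_trial`.
#' @param epochs_per_trial required when `observations` is a single flat
#'   observation stream.
#' @param settings an [infer_settings()] list.
#' @param learn update the Dirichlet priors after each trial (default TRUE).
#' @param config a [learning_config()].
#' @param predict also return per-epoch behaviour predictions (simulation
#'   mode only).
#' @param keep_trace keep per-trial free-energy traces.
#' @return An object of class `split_hmm_run`: matrices `q_internal`,
#'   `q_external` (one column per epoch), `q_person` (one column per trial),
#'   vectors `free_energy`, `n_iterations`, `converged`, the person-prior
#'   concentration trajectory `person_trace`, the updated `model`, and
#'   (if requested) a `predictions` matrix (behaviour bins x epochs).
#' @export
run_trials <- function(model, observations, epochs_per_trial = NULL,
                       settings = infer_settings(), learn = TRUE,
                       config = learning_config(), predict = FALSE,
                       keep_trace = FALSE) {
  if (inherits(observations, "trial_observations")) {
    o1 <- observations$o1
    o2 <- observations$o2
    if (is.null(epochs_per_trial)) epochs_per_trial <- observations$n_epochs
  } else {
    T_ <- unique(vapply(observations, function(o) o$n_epochs, integer(1)))
    if (length(T_) != 1) stop("all trials must have the same number of epochs")
    epochs_per_trial <- T_
    o1 <- unlist(lapply(observations, `[[`, "o1"))
    o2 <- unlist(lapply(observations, `[[`, "o2"))
  }
  .check_obs(model, trial_observations(o1, o2))
  if (length(o1) %% epochs_per_trial != 0)
    stop("epoch count is not a multiple of epochs_per_trial")
  if (predict && is.null(model$A1))
    stop("predictions require a simulation-mode model")
  ll <- .sim_loglik_arrays(model, o1, o2)
  res <- .run_sequence(model, ll, epochs_per_trial, settings, learn, config,
                       predict, keep_trace)
  res$o1 <- o1
  res$o2 <- o2
  res
}

# shared backend over precomputed flattened log-likelihood arrays
.run_sequence <- function(model, ll, epochs_per_trial, settings, learn,
                          config, predict = FALSE, keep_trace = FALSE) {
  priors <- prior_expectations(model)
  res <- mf_run_sequence_cpp(
    model$d_disp, model$d_sit, model$d_person, model$B1, model$B2,
    ll$lL1, ll$lL2, epochs_per_trial,
    eta = config$eta, learn = learn, rigid_split = model$rigid_split,
    integrated_index = .integrated_index(model),
    tol = settings$tol, max_iter = settings$max_iter,
    damp = settings$damping, lfloor = .LOG_FLOOR,
    predict = predict,
    A1flat = if (predict) as.numeric(model$A1) else numeric(0),
    n_o1 = if (predict) model$space$n_behavior else 0L,
    keep_trace = keep_trace)
  model$d_disp <- res$d_disp
  dimnames(model$d_disp) <- dimnames(priors$disp)
  model$d_sit <- res$d_sit
  dimnames(model$d_sit) <- dimnames(priors$sit)
  model$d_person <- drop(res$d_person)
  names(model$d_person) <- names(priors$person)
  rownames(res$q_internal) <- model$space$internal_labels
  rownames(res$q_external) <- model$space$external_labels
  rownames(res$q_person) <- rownames(model$d_disp)
  rownames(res$person_trace) <- rownames(model$d_disp)
  out <- list(
    q_internal = res$q_internal, q_external = res$q_external,
    q_person = res$q_person, free_energy = res$free_energy,
    n_iterations = res$n_iterations, converged = res$converged,
    person_trace = res$person_trace,
    predictions = res$predictions,
    predictive_internal = res$predictive_internal,
    free_energy_trace = res$free_energy_trace,
    epochs_per_trial = epochs_per_trial,
    n_trials = ncol(res$q_person),
    model = model)
  class(out) <- "split_hmm_run"
  out
}

#' Extract one trial's beliefs from a sequence run
#'
#' @param run a `split_hmm_run` from [run_trials()].
#' @param trial trial number.
#' @return A `belief_state` for that trial.
#' @export
trial_beliefs <- function(run, trial) {
  .as_belief_state(run, NULL, trial = trial,
                   epochs_per_trial = run$epochs_per_trial)
}

#' Tidy per-epoch belief trajectories
#'
#' @param run a `split_hmm_run`.
#' @return A long data.frame with columns trial, epoch, factor, state,
#'   probability.
#' @export
beliefs_long <- function(run) {
  T_ <- run$epochs_per_trial
  E <- ncol(run$q_internal)
  tidy_factor <- function(q, factor) {
    data.frame(
      trial = rep(ceiling(seq_len(E) / T_), each = nrow(q)),
      epoch = rep((seq_len(E) - 1) %% T_ + 1, each = nrow(q)),
      factor = factor,
      state = rep(seq_len(nrow(q)), times = E),
      probability = as.numeric(q))
  }
  q3 <- run$q_person
  person <- data.frame(
    trial = rep(seq_len(ncol(q3)), each = nrow(q3)),
    epoch = NA_integer_,
    factor = "person",
    state = rep(seq_len(nrow(q3)), times = ncol(q3)),
    probability = as.numeric(q3))
  rbind(tidy_factor(run$q_internal, "internal"),
        tidy_factor(run$q_external, "external"),
        person)
}
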