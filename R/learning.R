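# Trial-to-trial Dirichlet learning of the second-level priors.

#' Learning configuration
#'
#' @param eta concentration increment per unit posterior mass per trial
#'   (one pseudo-observation per trial by default).
#' @return A list of class `learning_config`.
#' @export
learning_config <- function(eta = 1) {
  if (!is.numeric(eta) || length(eta) != 1 || is.na(eta) || eta <= 0)
    stop("eta must be a single strictly positive value")
  structure(list(eta = eta), class = "learning_config")
}

#' Update second-level Dirichlet priors from a trial's posteriors
#'
#' All learning takes place at the second level: the person prior accumulates
#' the person-state posterior, the Integrated dispositional row accumulates
#' the trial-initial internal-state posterior weighted by the Integrated
#' responsibility, and every situational row accumulates the trial-initial
#' external-state posterior weighted by its person state's responsibility.
#' The Bad and Good dispositional rows are left untouched when the model's
#' split priors are rigid (the default); in the relaxed variant they
#' accumulate counts like the Integrated row.
#'
#' Learning uses the trial-initial (first-epoch) state posteriors because the
#' dispositional and situational priors are priors over starting states.
#'
#' @param model a [split_hmm()].
#' @param beliefs a `belief_state` from [infer_trial()] for the completed
#'   trial.
#' @param config a [learning_config()].
#' @return The model with updated concentration parameters.
#' @export
update_priors <- function(model, beliefs, config = learning_config()) {
  stopifnot(inherits(config, "learning_config"))
  eta <- config$eta
  q3 <- beliefs$q_person
  q1_0 <- beliefs$q_internal[, 1]
  q2_0 <- beliefs$q_external[, 1]
  labels <- rownames(model$d_disp)
  for (s in seq_along(labels)) {
    model$d_person[s] <- model$d_person[s] + eta * q3[s]
    if (labels[s] == "Integrated" || !model$rigid_split)
      model$d_disp[s, ] <- model$d_disp[s, ] + eta * q3[s] * q1_0
    model$d_sit[s, ] <- model$d_sit[s, ] + eta * q3[s] * q2_0
  }
  model
}

#' Per-trial Dirichlet count trajectories
#'
#' Steps through an observation sequence trial by trial (inference followed
#' by learning) and records every concentration parameter after each trial,
#' for auditing how the person, dispositional and situational priors evolve.
#'
#' @param model a [split_hmm()].
#' @param observations a [trial_observations()] stream or list, as in
#'   [run_trials()].
#' @param epochs_per_trial epochs per trial for a flat stream.
#' @param config a [learning_config()].
#' @param settings an [infer_settings()] list.
#' @return A long data.frame with columns trial (0 = initial), block
#'   (`person`, `disp`, `sit`), person_state, state and count.
#' @export
count_trajectories <- function(model, observations, epochs_per_trial = 2,
                               config = learning_config(),
                               settings = infer_settings()) {
  if (inherits(observations, "trial_observations")) {
    o1 <- observations$o1
    o2 <- observations$o2
  } else {
    o1 <- unlist(lapply(observations, `[[`, "o1"))
    o2 <- unlist(lapply(observations, `[[`, "o2"))
  }
  n_trials <- length(o1) %/% epochs_per_trial
  snap <- function(m, trial) {
    labels <- rownames(m$d_disp)
    rbind(
      data.frame(trial = trial, block = "person", person_state = labels,
                 state = NA_integer_, count = unname(m$d_person)),
      data.frame(trial = trial, block = "disp",
                 person_state = rep(labels, each = ncol(m$d_disp)),
                 state = rep(seq_len(ncol(m$d_disp)), length(labels)),
                 count = as.numeric(t(m$d_disp))),
      data.frame(trial = trial, block = "sit",
                 person_state = rep(labels, each = ncol(m$d_sit)),
                 state = rep(seq_len(ncol(m$d_sit)), length(labels)),
                 count = as.numeric(t(m$d_sit))))
  }
  out <- list(snap(model, 0L))
  for (tr in seq_len(n_trials)) {
    idx <- (epochs_per_trial * (tr - 1) + 1):(epochs_per_trial * tr)
    b <- infer_trial(model, trial_observations(o1[idx], o2[idx]),
                     settings = settings)
    model <- update_priors(model, b, config)
    out[[tr + 1]] <- snap(model, tr)
  }
  do.call(rbind, out)
}

#' Normalized prior expectations for the next trial
#'
#' Normalizes each Dirichlet block to its mean: the person prior over
#' Bad/Integrated/Good and the row-wise dispositional and situational priors
#' that will be mixed over the person posterior during the next trial's
#' inference.
#'
#' @param model a [split_hmm()].
#' @return List with `person` (length-3 distribution), `disp` and `sit`
#'   (row-normalized matrices).
#' @export
prior_expectations <- function(model) {
  list(person = .normalize(model$d_person),
       disp = model$d_disp / rowSums(model$d_disp),
       sit = model$d_sit / rowSums(model$d_sit))
}
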