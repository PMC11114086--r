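# Model construction: state spaces, parameters, likelihood tensors,
# transition matrices and Dirichlet priors of the split-HMM.

#' Subject-level parameters of the split-HMM
#'
#' Bundles the six subject-level parameters of the model together with the
#' fixed precision of the split dispositional priors. `psi_split` weights the
#' split (all-Bad / all-Good) person representations relative to the
#' Integrated one; `psi_bad` weights Bad relative to Good within the split
#' mass; `psi_ext` weights non-neutral relative to neutral external states in
#' the situational priors. `pi_o1`, `pi_o2` and `pi_s1` are the precisions
#' (inverse variances, model-scale units) of the behaviour likelihood, the
#' cue likelihood and the Integrated dispositional prior.
#'
#' @param psi_split,psi_bad,psi_ext unitless weights in \[0, 1\].
#' @param pi_o1,pi_o2,pi_s1 strictly positive precisions.
#' @return An object of class `split_params`.
#' @examples
#' split_params(psi_split = 0.25, psi_bad = 1, pi_o2 = 0.001)
#' @export
split_params <- function(psi_split = 0, psi_bad = 0.5, psi_ext = 0.6,
                         pi_o1 = 0.25, pi_o2 = 0.001, pi_s1 = 0.5) {
  for (nm in c("psi_split", "psi_bad", "psi_ext")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop(nm, " must be a single value in [0, 1]")
  }
  for (nm in c("pi_o1", "pi_o2", "pi_s1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop(nm, " must be a single strictly positive value")
  }
  structure(list(psi_split = psi_split, psi_bad = psi_bad, psi_ext = psi_ext,
                 pi_o1 = pi_o1, pi_o2 = pi_o2, pi_s1 = pi_s1,
                 pi_split_fixed = 3),
            class = "split_params")
}

#' State space of the split-HMM
#'
#' In `"simulation"` mode the internal (intention) dimension has five ordinal
#' states (Bad, Moderately Bad, Neutral, Moderately Good, Good); in `"task"`
#' mode it has eleven states mapped one-to-one onto expected harm aversion
#' levels 0, 0.1, ..., 1. The external (circumstance) dimension always has
#' five states (Very Unfavorable ... Very Favorable), behaviour is observed
#' on eleven ordinal bins with values 0, 0.1, ..., 1, and cues share the
#' external dimension's five levels.
#'
#' @param mode `"simulation"` or `"task"`.
#' @return An object of class `state_space` with element `internal_values`
#'   giving each internal state's expected behaviour / harm-aversion level on
#'   \[0, 1\], and (simulation mode) `mode_bins` giving the behaviour bin at
#'   which each internal state's likelihood peaks under neutral circumstances.
#' @export
state_space <- function(mode = c("simulation", "task")) {
  mode <- match.arg(mode)
  behavior_values <- seq(0, 1, by = 0.1)
  if (mode == "simulation") {
    internal_labels <- c("Bad", "Moderately Bad", "Neutral",
                         "Moderately Good", "Good")
    mode_bins <- c(1L, 3L, 6L, 9L, 11L)
    internal_values <- behavior_values[mode_bins]
  } else {
    internal_labels <- sprintf("s1_%02d", 1:11)
    mode_bins <- 1:11
    internal_values <- behavior_values
  }
  structure(list(
    mode = mode,
    n_internal = length(internal_values),
    n_external = 5L,
    n_person = 3L,
    n_behavior = 11L,
    n_cue = 5L,
    internal_values = internal_values,
    mode_bins = mode_bins,
    behavior_values = behavior_values,
    internal_labels = internal_labels,
    external_labels = c("Very Unfavorable", "Unfavorable", "Neutral",
                        "Favorable", "Very Favorable"),
    person_labels = c("Bad", "Integrated", "Good")
  ), class = "state_space")
}

# discretized squared-exponential kernel on an ordinal index scale:
# P(i | mode) propto exp(-precision * (i - mode)^2 / 2), renormalized
.ordinal_kernel <- function(n, mode_index, precision) {
  idx <- seq_len(n)
  .normalize(exp(-precision * (idx - mode_index)^2 / 2))
}

#' Person-prior Dirichlet concentrations
#'
#' Maps the splitting weights onto the initial concentrations of the Dirichlet
#' prior over person states: `delta_bad = psi_bad * psi_split`,
#' `delta_integrated = 1 - psi_split`,
#' `delta_good = (1 - psi_bad) * psi_split`. The three components sum to 1.
#'
#' @param psi_split,psi_bad weights in \[0, 1\].
#' @return Named numeric vector `(bad, integrated, good)`.
#' @examples
#' person_prior_concentrations(0.25, 1) # c(0.25, 0.75, 0)
#' @export
person_prior_concentrations <- function(psi_split, psi_bad) {
  if (psi_split < 0 || psi_split > 1 || psi_bad < 0 || psi_bad > 1)
    stop("psi_split and psi_bad must lie in [0, 1]")
  c(bad = psi_bad * psi_split,
    integrated = 1 - psi_split,
    good = (1 - psi_bad) * psi_split)
}

# effective internal level after an external shift, with the floor/ceiling
# rule: unfavorable shifts never push below level 2, favorable shifts never
# above level n-1; states already at or beyond the bound are left unshifted
.shifted_level <- function(level, shift, n_levels) {
  floor_lv <- 2L
  ceil_lv <- n_levels - 1L
  if (shift < 0) {
    if (level <= floor_lv) return(level)
    max(level + shift, floor_lv)
  } else if (shift > 0) {
    if (level >= ceil_lv) return(level)
    min(level + shift, ceil_lv)
  } else level
}

#' Behaviour likelihood tensor P(o1 | s1, s2)
#'
#' Internal and external states jointly generate observed behaviour: each
#' internal state peaks at its own behaviour level, and external states shift
#' that peak along the internal-level scale (Unfavorable down one level, Very
#' Unfavorable two; Favorable up one, Very Favorable two), with unfavorable
#' shifts floored at the second level and favorable shifts capped at the
#' second-to-last. The spread around the peak is a discretized
#' squared-exponential kernel on the behaviour-bin index scale with precision
#' `pi_o1`, truncated to the eleven bins and renormalized (hence more peaked
#' at the scale ends).
#'
#' @param space a [state_space()] (simulation mode).
#' @param pi_o1 behaviour likelihood precision (> 0).
#' @param support `"both"` keeps both external effects; `"favorable_only"`
#'   removes the effect of unfavorable external states on behaviour (good
#'   people's lapses cannot be excused: a negativity-bias configuration);
#'   `"unfavorable_only"` removes the favorable effect (no ulterior motives:
#'   a positivity-bias configuration).
#' @return Array of dim `c(n_behavior, n_internal, n_external)`; each column
#'   `[, s1, s2]` is a distribution over behaviour bins.
#' @export
build_behavior_likelihood <- function(space, pi_o1,
                                      support = c("both", "favorable_only",
                                                  "unfavorable_only")) {
  if (pi_o1 <= 0) stop("pi_o1 must be strictly positive")
  support <- match.arg(support)
  n1 <- space$n_internal
  n2 <- space$n_external
  shifts <- switch(support,
                   both = c(-2L, -1L, 0L, 1L, 2L),
                   favorable_only = c(0L, 0L, 0L, 1L, 2L),
                   unfavorable_only = c(-2L, -1L, 0L, 0L, 0L))
  A1 <- array(0, dim = c(space$n_behavior, n1, n2))
  for (k in seq_len(n2)) {
    for (i in seq_len(n1)) {
      eff <- .shifted_level(i, shifts[k], n1)
      A1[, i, k] <- .ordinal_kernel(space$n_behavior, space$mode_bins[eff], pi_o1)
    }
  }
  A1
}

#' Cue likelihood matrix P(o2 | s2)
#'
#' External states generate contextual cues through a squared-exponential
#' kernel on the cue index scale centred on the true external state. Large
#' `pi_o2` approaches the identity (fully informative cues); `pi_o2 = 0.001`
#' is effectively uninformative.
#'
#' @param space a [state_space()].
#' @param pi_o2 cue likelihood precision (> 0).
#' @return `n_cue` x `n_external` column-stochastic matrix.
#' @export
build_cue_likelihood <- function(space, pi_o2) {
  if (pi_o2 <= 0) stop("pi_o2 must be strictly positive")
  vapply(seq_len(space$n_external),
         function(k) .ordinal_kernel(space$n_cue, k, pi_o2),
         numeric(space$n_cue))
}

#' Dispositional priors P(s1 | s3)
#'
#' Three rows of expectations over internal states, one per person state. The
#' Integrated row is a unimodal kernel centred on the Neutral state with
#' precision `pi_s1` (learnable); the Bad and Good rows are extreme, precise
#' kernels centred on the lowest and highest internal states with the fixed
#' split precision (default 3). The Integrated kernel is measured on the
#' internal-state index scale (a graded representation spanning the grid),
#' while the split kernels are measured on the behaviour-bin scale via each
#' state's behaviour anchor, making them genuinely extreme and precise; on
#' the 11-state task grid the two scales coincide.
#'
#' @param space a [state_space()].
#' @param pi_s1 precision of the Integrated row (> 0).
#' @param pi_split fixed precision of the split rows.
#' @return 3 x `n_internal` row-normalized matrix (rows Bad, Integrated,
#'   Good).
#' @export
build_dispositional_priors <- function(space, pi_s1, pi_split = 3) {
  if (pi_s1 <= 0) stop("pi_s1 must be strictly positive")
  n1 <- space$n_internal
  mid <- as.integer((n1 + 1) / 2)
  value_kernel <- function(center_state, precision) {
    dist <- space$mode_bins - space$mode_bins[center_state]
    .normalize(exp(-precision * dist^2 / 2))
  }
  d <- rbind(
    Bad = value_kernel(1L, pi_split),
    Integrated = .ordinal_kernel(n1, mid, pi_s1),
    Good = value_kernel(n1, pi_split)
  )
  colnames(d) <- space$internal_labels
  d
}

#' Situational priors P(s2 | s3)
#'
#' Expectations over external circumstances per person state. With weight
#' `psi_ext` on non-neutral states, the Bad row supports Neutral plus the two
#' favorable states (bad people may behave well for ulterior reasons), the
#' Good row supports Neutral plus the two unfavorable states (good people may
#' behave badly in adverse contexts), and the Integrated row is uniform.
#' `psi_ext = 0` collapses the split rows to a point mass on Neutral.
#'
#' @param space a [state_space()].
#' @param psi_ext weight in \[0, 1\] on non-neutral external states.
#' @return 3 x `n_external` row-normalized matrix (rows Bad, Integrated,
#'   Good).
#' @export
build_situational_priors <- function(space, psi_ext) {
  if (psi_ext < 0 || psi_ext > 1) stop("psi_ext must lie in [0, 1]")
  n2 <- space$n_external
  bad <- c(0, 0, 1 - psi_ext, psi_ext / 2, psi_ext / 2)
  good <- c(psi_ext / 2, psi_ext / 2, 1 - psi_ext, 0, 0)
  d <- rbind(Bad = bad, Integrated = rep(1 / n2, n2), Good = good)
  colnames(d) <- space$external_labels
  d
}

#' Ordinal random-walk transition matrices
#'
#' Hidden states persist with probability `stay_prob` and otherwise move to an
#' adjacent state (mass split equally between neighbours; all of it to the
#' single neighbour at the boundaries). This gives intentions and
#' circumstances a small probability of changing between epochs within a
#' trial.
#'
#' @param space a [state_space()].
#' @param stay_prob probability in (0, 1\] of remaining in the current state.
#' @return List with column-stochastic matrices `B1` (internal) and `B2`
#'   (external), entry `[i, j] = P(state i at tau | state j at tau - 1)`.
#' @export
build_transitions <- function(space, stay_prob = 0.9) {
  if (stay_prob <= 0 || stay_prob > 1) stop("stay_prob must lie in (0, 1]")
  walk <- function(n) {
    B <- matrix(0, n, n)
    for (j in seq_len(n)) {
      B[j, j] <- stay_prob
      nb <- c(j - 1, j + 1)
      nb <- nb[nb >= 1 & nb <= n]
      B[nb, j] <- (1 - stay_prob) / length(nb)
    }
    B
  }
  list(B1 = walk(space$n_internal), B2 = walk(space$n_external))
}

#' Assemble a split-HMM generative model
#'
#' Builds the full generative model: behaviour and cue likelihoods, transition
#' matrices, and the Dirichlet concentration blocks for the dispositional,
#' situational and person priors. Row-normalized prior kernels are scaled to
#' base counts: `base_count` (default 10) for learnable blocks and
#' `base_count_split` (default 1e6, i.e. effectively rigid) for the Bad and
#' Good dispositional rows. Setting `rigid_split = FALSE` together with
#' `base_count_split = 10` gives the relaxed-split variant in which the split
#' rows themselves are modified through learning.
#'
#' @param params a [split_params()] object.
#' @param mode `"simulation"` (5 internal states, behaviour-bin likelihood) or
#'   `"task"` (11 internal states; behaviour likelihoods are supplied per
#'   choice by the moral-inference task model).
#' @param stay_prob transition stickiness for both hidden chains.
#' @param base_count total concentration of each learnable Dirichlet row.
#' @param base_count_split total concentration of the Bad/Good dispositional
#'   rows.
#' @param rigid_split if `TRUE` (default) the Bad/Good dispositional rows are
#'   never updated by learning.
#' @param external_support passed to [build_behavior_likelihood()]
#'   (one-sided variants give the negativity/positivity-bias
#'   configurations).
#' @param person_states `"full"` (Bad/Integrated/Good) or `"integrated_only"`
#'   (the reduced comparison model with no split representations).
#' @return An object of class `split_hmm`.
#' @export
split_hmm <- function(params = split_params(), mode = c("simulation", "task"),
                      stay_prob = 0.9, base_count = 10,
                      base_count_split = 1e6, rigid_split = TRUE,
                      external_support = "both",
                      person_states = c("full", "integrated_only")) {
  mode <- match.arg(mode)
  person_states <- match.arg(person_states)
  stopifnot(inherits(params, "split_params"))
  space <- state_space(mode)
  A1 <- if (mode == "simulation")
    build_behavior_likelihood(space, params$pi_o1, external_support) else NULL
  A2 <- build_cue_likelihood(space, params$pi_o2)
  B <- build_transitions(space, stay_prob)
  disp <- build_dispositional_priors(space, params$pi_s1, params$pi_split_fixed)
  sit <- build_situational_priors(space, params$psi_ext)
  d_disp <- disp * c(base_count_split, base_count, base_count_split)
  d_sit <- sit * base_count
  d_person <- person_prior_concentrations(params$psi_split, params$psi_bad)
  rigid_mask <- c(Bad = rigid_split, Integrated = FALSE, Good = rigid_split)
  if (person_states == "integrated_only") {
    d_disp <- d_disp["Integrated", , drop = FALSE]
    d_sit <- d_sit["Integrated", , drop = FALSE]
    d_person <- c(integrated = 1)
    rigid_mask <- c(Integrated = FALSE)
  }
  structure(list(
    params = params, space = space, mode = mode,
    A1 = A1, A2 = A2, B1 = B$B1, B2 = B$B2,
    d_disp = d_disp, d_sit = d_sit, d_person = d_person,
    rigid_mask = rigid_mask, rigid_split = rigid_split,
    stay_prob = stay_prob, base_count = base_count,
    base_count_split = base_count_split,
    external_support = external_support,
    person_states = person_states
  ), class = "split_hmm")
}

#' @export
print.split_hmm <- function(x, ...) {
  p <- x$params
  cat("Split-HMM generative model (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  psi_split = %.3g, psi_bad = %.3g, psi_ext = %.3g\n",
              p$psi_split, p$psi_bad, p$psi_ext))
  cat(sprintf("  pi_o1 = %.3g, pi_o2 = %.3g, pi_s1 = %.3g\n",
              p$pi_o1, p$pi_o2, p$pi_s1))
  cat(sprintf("  states: %d internal x %d external x %d person; split rows %s\n",
              x$space$n_internal, x$space$n_external, x$space$n_person,
              if (x$rigid_split) "rigid" else "learnable"))
  pp <- .normalize(x$d_person)
  cat("  person prior:",
      paste(sprintf("%s %.3f", rownames(x$d_disp), pp), collapse = " / "),
      "\n")
  invisible(x)
}

#' @export
print.split_params <- function(x, ...) {
  cat("split_params:",
      sprintf("psi_split=%.3g psi_bad=%.3g psi_ext=%.3g pi_o1=%.3g pi_o2=%.3g pi_s1=%.3g",
              x$psi_split, x$psi_bad, x$psi_ext, x$pi_o1, x$pi_o2, x$pi_s1), "\n")
  invisible(x)
}
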