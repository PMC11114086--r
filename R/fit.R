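# Derived metrics, maximum-likelihood fitting, nested model comparison and
# the parameter-recovery harness.

#' Learning rate from point predictions
#'
#' The canonical prediction-error definition: with point predictions `p_t`
#' made before each outcome `o_t`, the prediction error is `PE_t = o_t -
#' p_t` and the prediction change `dp_t = p_{t+1} - p_t`; the learning rate
#' is the least-squares slope of `dp` on `PE` through the origin (an
#' intercept variant is available). Full updating (`p_{t+1} = o_t`) gives
#' slope 1; frozen predictions give 0.
#'
#' @param map_predictions numeric vector of MAP point predictions.
#' @param observations outcomes on the same scale, aligned with the
#'   predictions (the final outcome does not enter the slope).
#' @param intercept if `TRUE`, fit an ordinary regression with intercept and
#'   return its slope.
#' @return List of class `learning_rate_result` with `alpha`, `n_points` and
#'   a `defined` flag (`FALSE` when every prediction error is zero).
#' @export
learning_rate <- function(map_predictions, observations, intercept = FALSE) {
  n <- length(map_predictions)
  stopifnot(length(observations) == n, n >= 2)
  pe <- observations[seq_len(n - 1)] - map_predictions[seq_len(n - 1)]
  dp <- diff(map_predictions)
  if (all(pe == 0))
    return(structure(list(alpha = NA_real_, n_points = n - 1, defined = FALSE),
                     class = "learning_rate_result"))
  alpha <- if (intercept) {
    unname(coef(lm(dp ~ pe))[2])
  } else {
    sum(dp * pe) / sum(pe^2)
  }
  structure(list(alpha = alpha, n_points = n - 1, defined = TRUE),
            class = "learning_rate_result")
}

#' Shannon entropy of a posterior
#'
#' `-sum(q * log(q))` in nats, with `0 * log(0) = 0`.
#'
#' @param q_internal normalized distribution.
#' @return Entropy in nats.
#' @export
posterior_entropy <- function(q_internal) {
  stopifnot(abs(sum(q_internal) - 1) < 1e-6, all(q_internal >= 0))
  -sum(ifelse(q_internal > 0, q_internal * log(q_internal), 0))
}

#' Fitting bounds
#'
#' Box bounds for the bounded multi-start optimization; precisions are
#' searched on the log scale internally.
#'
#' @param pi_o1,pi_s1,psi_bad,psi_split,psi_ext length-2 `c(lower, upper)`
#'   vectors.
#' @return Named list of bounds.
#' @export
fit_bounds <- function(pi_o1 = c(0.1, 200), pi_s1 = c(0.1, 20),
                       psi_bad = c(0, 1), psi_split = c(0, 1),
                       psi_ext = c(0, 1)) {
  list(pi_o1 = pi_o1, pi_s1 = pi_s1, psi_bad = psi_bad,
       psi_split = psi_split, psi_ext = psi_ext)
}

#' Model specification for fitting
#'
#' Names the free parameters (a subset of pi_o1, pi_s1, psi_bad, psi_split,
#' psi_ext) and fixes the rest; the cue precision is fixed at 0.001 because
#' the task provides no context cues. The restrictions `psi_split = 0`
#' (integrated-only) and `psi_split = 1` (split-only) give the nested
#' comparison models.
#'
#' @param free character vector of free parameter names.
#' @param fixed named list of fixed parameter values (merged over the
#'   defaults `pi_o2 = 0.001` plus [split_params()] defaults for non-free
#'   parameters).
#' @param bounds a [fit_bounds()] list.
#' @return A list of class `fit_spec` with element `k` (number of free
#'   parameters).
#' @export
fit_spec <- function(free = c("pi_o1", "pi_s1", "psi_bad", "psi_split",
                              "psi_ext"),
                     fixed = list(), bounds = fit_bounds()) {
  allowed <- c("pi_o1", "pi_s1", "psi_bad", "psi_split", "psi_ext")
  if (!all(free %in% allowed)) stop("free parameters must be among: ",
                                    paste(allowed, collapse = ", "))
  fixed <- modifyList(list(pi_o2 = 0.001), fixed)
  structure(list(free = free, fixed = fixed, bounds = bounds,
                 k = length(free)),
            class = "fit_spec")
}

#' Fitting settings
#'
#' @param n_starts number of Latin-hypercube starting points.
#' @param seed integer seed controlling the starting points (fits are
#'   deterministic given seed and data).
#' @param include_prior_rating include the pre-observation rating in the
#'   likelihood.
#' @param eval_max,iter_max optimizer budget per restart.
#' @param infer an [infer_settings()] list used inside the likelihood.
#' @return A list of settings.
#' @export
fit_settings <- function(n_starts = 10, seed = 1L,
                         include_prior_rating = TRUE,
                         eval_max = 200, iter_max = 100,
                         infer = infer_settings()) {
  list(n_starts = n_starts, seed = seed,
       include_prior_rating = include_prior_rating,
       eval_max = eval_max, iter_max = iter_max, infer = infer)
}

.PRECISION_PARAMS <- c("pi_o1", "pi_s1")

.to_optim_scale <- function(x, names) {
  ifelse(names %in% .PRECISION_PARAMS, log(x), x)
}
.from_optim_scale <- function(x, names) {
  ifelse(names %in% .PRECISION_PARAMS, exp(x), x)
}

# split one participant's event table into per-agent components
.participant_pieces <- function(dataset, design) {
  pid <- unique(dataset$participant_id)
  if (length(pid) != 1) stop("dataset must contain exactly one participant")
  pieces <- list()
  for (agent in unique(dataset$agent)) {
    da <- dataset[dataset$agent == agent, ]
    ch <- da[!is.na(da$choice), ]
    ch <- ch[order(ch$trial, ch$epoch), ]
    rt <- da[!is.na(da$rating_type), ]
    rt <- rt[order(rt$trial), ]
    if (nrow(ch) == 0 || nrow(rt) == 0) stop("agent block missing choices or ratings")
    pieces[[agent]] <- list(
      options = data.frame(delta_money = ch$delta_money,
                           delta_shocks = ch$delta_shocks,
                           threshold = ch$delta_money /
                             (ch$delta_money + ch$delta_shocks)),
      choices = ch$choice,
      ratings = rt$rating,
      rating_type = rt$rating_type)
  }
  pieces
}

# summed rating log-likelihood across both agents for one parameter setting
.participant_loglik <- function(params, pieces, design, settings,
                                eps = 1e-6) {
  ll <- 0
  n_obs <- 0
  for (agent in names(pieces)) {
    pc <- pieces[[agent]]
    model <- split_hmm(params, mode = "task")
    run <- run_task_sequence(model, pc$options, pc$choices, design,
                             settings$infer)
    qr <- run$rating_posteriors
    use <- seq_along(pc$ratings)
    if (!settings$include_prior_rating)
      use <- use[pc$rating_type != "prior"]
    qf <- pmax(qr[, use, drop = FALSE], eps)
    qf <- sweep(qf, 2, colSums(qf), `/`)
    bins <- rating_bin(pc$ratings[use])
    ll <- ll + sum(log(qf[cbind(bins, seq_along(use))]))
    n_obs <- n_obs + length(use)
  }
  list(loglik = ll, n_obs = n_obs)
}

#' Maximum-likelihood fit of one participant
#'
#' Maximizes the summed rating log-likelihood across both agents (the model
#' is run independently per agent from the same initial priors, with one
#' parameter set for both) by bounded local optimization from Latin-hypercube
#' starting points. Deterministic given `settings$seed` and the data.
#'
#' @param dataset one participant's rows of a task-schema data.frame.
#' @param spec a [fit_spec()].
#' @param settings a [fit_settings()] list.
#' @param design a [task_design()].
#' @return An object of class `fit_result`: `estimates` (full
#'   [split_params()]), `free`, `log_likelihood`, `n_obs`, `k`, `bic`,
#'   `pseudo_r2` (McFadden, against a uniform 11-bin null), `restarts`,
#'   `converged`, and the per-restart table `starts`.
#' @export
fit_participant <- function(dataset, spec = fit_spec(),
                            settings = fit_settings(),
                            design = task_design()) {
  stopifnot(inherits(spec, "fit_spec"))
  pieces <- .participant_pieces(dataset, design)
  free <- spec$free
  lower <- .to_optim_scale(vapply(spec$bounds[free], `[`, numeric(1), 1), free)
  upper <- .to_optim_scale(vapply(spec$bounds[free], `[`, numeric(1), 2), free)

  make_params <- function(theta) {
    vals <- as.list(.from_optim_scale(theta, free))
    names(vals) <- free
    all_vals <- modifyList(spec$fixed, vals)
    defaults <- list(psi_split = 0, psi_bad = 0.5, psi_ext = 0.6,
                     pi_o1 = 0.25, pi_o2 = 0.001, pi_s1 = 0.5)
    do.call(split_params, modifyList(defaults, all_vals))
  }
  objective <- function(theta) {
    params <- make_params(theta)
    -.participant_loglik(params, pieces, design, settings)$loglik
  }

  set.seed(settings$seed)
  grid <- lhs::randomLHS(settings$n_starts, length(free))
  starts <- sweep(sweep(grid, 2, upper - lower, `*`), 2, lower, `+`)

  fits <- vector("list", settings$n_starts)
  for (r in seq_len(settings$n_starts)) {
    fits[[r]] <- tryCatch(
      nlminb(starts[r, ], objective, lower = lower, upper = upper,
             control = list(eval.max = settings$eval_max,
                            iter.max = settings$iter_max)),
      error = function(e) list(objective = Inf, par = starts[r, ],
                               convergence = 1L, message = conditionMessage(e)))
  }
  objs <- vapply(fits, function(f) f$objective, numeric(1))
  best <- which.min(objs)
  best_fit <- fits[[best]]
  params <- make_params(best_fit$par)
  li <- .participant_loglik(params, pieces, design, settings)
  ll_null <- li$n_obs * log(1 / 11)
  start_tab <- data.frame(restart = seq_len(settings$n_starts),
                          objective = objs,
                          converged = vapply(fits, function(f)
                            identical(f$convergence, 0L), logical(1)))
  structure(list(
    estimates = params, free = free,
    log_likelihood = li$loglik, n_obs = li$n_obs, k = spec$k,
    bic = spec$k * log(li$n_obs) - 2 * li$loglik,
    pseudo_r2 = 1 - li$loglik / ll_null,
    null_log_likelihood = ll_null,
    restarts = settings$n_starts,
    converged = any(start_tab$converged) && is.finite(li$loglik),
    starts = start_tab,
    participant_id = unique(dataset$participant_id)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result for", x$participant_id, "\n")
  est <- unclass(x$estimates)[x$free]
  cat("  ", paste(sprintf("%s=%.3g", names(est), unlist(est)),
                  collapse = ", "), "\n")
  cat(sprintf("  logLik %.2f on %d ratings (k = %d), BIC %.2f, pseudo-R2 %.3f\n",
              x$log_likelihood, x$n_obs, x$k, x$bic, x$pseudo_r2))
  invisible(x)
}

#' Fit every participant in a cohort
#'
#' @param dataset a task-schema data.frame (multiple participants).
#' @inheritParams fit_participant
#' @return List of `fit_result`, named by participant.
#' @export
fit_cohort <- function(dataset, spec = fit_spec(), settings = fit_settings(),
                       design = task_design()) {
  ids <- unique(dataset$participant_id)
  fits <- lapply(ids, function(id)
    fit_participant(dataset[dataset$participant_id == id, ], spec, settings,
                    design))
  names(fits) <- ids
  fits
}

#' Nested model comparison
#'
#' Likelihood-ratio comparison of a full and a restricted (nested) model fit
#' to the same participants: per-participant log likelihood ratios and BIC
#' differences, the mean log LR with a chi-squared statistic `2 * mean(log
#' LR)` on `df` degrees of freedom (and the summed-LR variant on `df * n`),
#' plus the full model's mean McFadden pseudo-R2.
#'
#' @param fits_full,fits_restricted lists of `fit_result` over the same
#'   participants.
#' @param df degrees of freedom of the restriction; defaults to the
#'   difference in free-parameter counts.
#' @return A list of class `model_comparison` with the per-participant table
#'   and group statistics.
#' @export
compare_models <- function(fits_full, fits_restricted, df = NULL) {
  ids_f <- vapply(fits_full, `[[`, character(1), "participant_id")
  ids_r <- vapply(fits_restricted, `[[`, character(1), "participant_id")
  if (!identical(sort(ids_f), sort(ids_r)))
    stop("fit sets cover different participants")
  fits_restricted <- fits_restricted[match(ids_f, ids_r)]
  if (is.null(df)) df <- fits_full[[1]]$k - fits_restricted[[1]]$k
  tab <- data.frame(
    participant_id = ids_f,
    ll_full = vapply(fits_full, `[[`, numeric(1), "log_likelihood"),
    ll_restricted = vapply(fits_restricted, `[[`, numeric(1),
                           "log_likelihood"),
    bic_full = vapply(fits_full, `[[`, numeric(1), "bic"),
    bic_restricted = vapply(fits_restricted, `[[`, numeric(1), "bic"))
  tab$log_lr <- tab$ll_full - tab$ll_restricted
  tab$delta_bic <- tab$bic_restricted - tab$bic_full
  n <- nrow(tab)
  chisq_mean <- 2 * mean(tab$log_lr)
  chisq_sum <- 2 * sum(tab$log_lr)
  structure(list(
    table = tab, df = df, n = n,
    mean_log_lr = mean(tab$log_lr),
    mean_delta_bic = mean(tab$delta_bic),
    chisq_mean = chisq_mean,
    p_mean = pchisq(max(chisq_mean, 0), df, lower.tail = FALSE),
    chisq_sum = chisq_sum,
    p_sum = pchisq(max(chisq_sum, 0), df * n, lower.tail = FALSE),
    mean_pseudo_r2_full = mean(vapply(fits_full, `[[`, numeric(1),
                                      "pseudo_r2"))
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("model comparison over %d participants (df = %d)\n", x$n, x$df))
  cat(sprintf("  mean log LR %.2f, mean dBIC %.2f\n",
              x$mean_log_lr, x$mean_delta_bic))
  cat(sprintf("  chi2(mean) = %.2f, p = %.3g; chi2(sum) = %.2f, p = %.3g\n",
              x$chisq_mean, x$p_mean, x$chisq_sum, x$p_sum))
  cat(sprintf("  full-model mean pseudo-R2 %.3f\n", x$mean_pseudo_r2_full))
  invisible(x)
}

#' Parameter recovery on a synthetic cohort
#'
#' Generates a cohort with known parameters, fits every participant, and
#' reports, per free parameter, the Pearson correlation between generating
#' and recovered values together with bias and RMSE.
#'
#' @param cohort_spec group specs for [generate_cohort()] (default: the
#'   uniform-over-bounds cohort used for recovery).
#' @param spec a [fit_spec()].
#' @param settings a [fit_settings()] list.
#' @param design a [task_design()].
#' @param seed integer seed for cohort generation.
#' @return A list of class `recovery_report`: `report` (param, r, bias,
#'   rmse), the paired `values` table, and the fits.
#' @export
recover_parameters <- function(cohort_spec = cohort_uniform(40),
                               spec = fit_spec(),
                               settings = fit_settings(),
                               design = task_design(), seed = 1L) {
  dataset <- generate_cohort(cohort_spec, design, seed)
  truths <- attr(dataset, "true_params")
  fits <- fit_cohort(dataset, spec, settings, design)
  est <- do.call(rbind, lapply(fits, function(f) {
    data.frame(participant_id = f$participant_id,
               as.data.frame(unclass(f$estimates)[spec$free]))
  }))
  values <- merge(truths, est, by = "participant_id",
                  suffixes = c("_true", "_est"))
  report <- do.call(rbind, lapply(spec$free, function(p) {
    tv <- values[[paste0(p, "_true")]]
    ev <- values[[paste0(p, "_est")]]
    data.frame(param = p,
               r = if (sd(tv) > 0 && sd(ev) > 0) cor(tv, ev) else NA_real_,
               bias = mean(ev - tv),
               rmse = sqrt(mean((ev - tv)^2)))
  }))
  structure(list(report = report, values = values, fits = fits, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("parameter recovery over %d participants\n", nrow(x$values)))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Per-agent learning-rate and uncertainty metrics for a task cohort
#'
#' For every participant and agent, runs the subject model (at the supplied
#' or generating parameters) over the agent's choices, takes the MAP belief
#' at each rating point as the model's point prediction and the participant's
#' next reported rating as the outcome, and computes the learning rate and
#' the mean posterior entropy at rating points.
#'
#' @param dataset a task-schema data.frame.
#' @param params_table data.frame with `participant_id` and parameter
#'   columns; defaults to the dataset's `true_params` attribute.
#' @param design a [task_design()].
#' @return data.frame with one row per participant x agent: `alpha`,
#'   `mean_entropy`.
#' @export
cohort_learning_metrics <- function(dataset, params_table = NULL,
                                    design = task_design()) {
  if (is.null(params_table)) params_table <- attr(dataset, "true_params")
  if (is.null(params_table)) stop("no parameter table available")
  rows <- list()
  for (i in seq_len(nrow(params_table))) {
    pid <- params_table$participant_id[i]
    params <- do.call(split_params, as.list(
      params_table[i, c("psi_split", "psi_bad", "psi_ext",
                        "pi_o1", "pi_o2", "pi_s1")]))
    pieces <- .participant_pieces(dataset[dataset$participant_id == pid, ],
                                  design)
    for (agent in names(pieces)) {
      pc <- pieces[[agent]]
      model <- split_hmm(params, mode = "task")
      run <- run_task_sequence(model, pc$options, pc$choices, design)
      qr <- run$rating_posteriors
      map_vals <- model$space$internal_values[apply(qr, 2, which.max)]
      n_pts <- length(pc$ratings)
      preds <- map_vals[seq_len(n_pts - 1)]
      outs <- pc$ratings[-1] / 100
      lr <- learning_rate(preds, outs)
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = pid, group = params_table$group[i], agent = agent,
        alpha = lr$alpha,
        mean_entropy = mean(apply(qr, 2, posterior_entropy)))
    }
  }
  do.call(rbind, rows)
}
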