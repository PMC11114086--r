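# Configuration, serialization and the command dispatcher behind the
# exec/splithmm command-line entry point.

#' Load or save an experiment configuration
#'
#' Configurations are flat named lists serialized as YAML or JSON (chosen by
#' file extension) and round-trip exactly (`load_config(save_config(x))`
#' equals `x`).
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @param config named list to save.
#' @return `load_config` returns the named list; `save_config` returns the
#'   path invisibly.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config format: ", ext)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(config, path)
  else if (ext == "json")
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else stop("unsupported config format: ", ext)
  invisible(path)
}

# stable hash of a config for output provenance
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  ord <- config[order(names(config))]
  jsonlite::write_json(ord, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.write_sidecar <- function(path, config, files) {
  meta <- list(
    config = config,
    config_hash = .config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("splithmm")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = files)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Export belief trajectories as tidy CSV
#'
#' @param run a `split_hmm_run`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
export_beliefs_csv <- function(run, path) {
  write.csv(beliefs_long(run), path, row.names = FALSE)
  invisible(path)
}

.default_params <- function(config) {
  keep <- intersect(names(config),
                    c("psi_split", "psi_bad", "psi_ext", "pi_o1", "pi_o2",
                      "pi_s1"))
  do.call(split_params, config[keep])
}

#' Run a command from a configuration
#'
#' Dispatches the commands exposed by the `splithmm` command-line script:
#' `simulate-scenario` (run a named scripted scenario and export the belief
#' trajectories), `simulate-cohort` (generate a synthetic task cohort),
#' `fit` (fit every participant of a task CSV), `compare` (fit full and
#' restricted models and compare them), `recover` (parameter recovery) and
#' `metrics` (the learning-rate/entropy grid experiment). Every stochastic
#' command requires an explicit `seed`; outputs are tidy CSV files plus a
#' JSON sidecar recording the configuration, its hash, the seed, package
#' version and timestamp. On error, partial outputs are removed.
#'
#' @param config named list with at least `command`, `seed` and `out`
#'   (output directory); remaining entries are command-specific (`name` for
#'   scenarios, `n` for cohorts, `input` for fitting, model parameters by
#'   name).
#' @param verbose print one-line progress messages.
#' @return Invisibly, the list of files written.
#' @export
run_command <- function(config, verbose = FALSE) {
  if (is.null(config$command)) stop("config$command is required")
  if (is.null(config$seed)) stop("an explicit seed is required")
  if (is.null(config$out)) stop("config$out (output directory) is required")
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  say <- function(...) if (verbose) message(sprintf(...))
  out <- function(f) file.path(config$out, f)
  on_fail <- function(e) {
    unlink(written)
    stop("command failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    cmd <- config$command
    if (cmd == "simulate-scenario") {
      name <- if (is.null(config$name)) "devaluation" else config$name
      scn <- scripted_scenarios(name)
      model <- split_hmm(.default_params(config))
      say("running scenario %s (48 trials)", name)
      run <- run_scenario(scn, model, seed = config$seed)
      written <- c(written, export_beliefs_csv(run, out("beliefs.csv")))
    } else if (cmd == "simulate-cohort") {
      n <- if (is.null(config$n)) 40 else config$n
      spec_name <- if (is.null(config$cohort)) "groups" else config$cohort
      gs <- if (spec_name == "uniform") cohort_uniform(n)
            else cohort_groups_default(ceiling(n / 2), floor(n / 2))
      say("simulating %d participants (%s cohort)", n, spec_name)
      ds <- generate_cohort(gs, seed = config$seed)
      f <- out("cohort.csv")
      write.csv(ds, f, row.names = FALSE)
      ft <- out("cohort_true_params.csv")
      write.csv(attr(ds, "true_params"), ft, row.names = FALSE)
      written <- c(written, f, ft)
    } else if (cmd == "fit") {
      if (is.null(config$input)) stop("fit requires config$input (task CSV)")
      ds <- read.csv(config$input)
      fits <- fit_cohort(ds, settings = fit_settings(seed = config$seed))
      tab <- do.call(rbind, lapply(fits, function(f)
        data.frame(participant_id = f$participant_id,
                   as.data.frame(unclass(f$estimates)[f$free]),
                   log_likelihood = f$log_likelihood, bic = f$bic,
                   pseudo_r2 = f$pseudo_r2)))
      f <- out("fits.csv")
      write.csv(tab, f, row.names = FALSE)
      written <- c(written, f)
    } else if (cmd == "compare") {
      if (is.null(config$input)) stop("compare requires config$input")
      ds <- read.csv(config$input)
      st <- fit_settings(seed = config$seed)
      full <- fit_cohort(ds, fit_spec(), st)
      restricted <- fit_cohort(ds, fit_spec(
        free = c("pi_o1", "pi_s1", "psi_ext"),
        fixed = list(psi_split = 0)), st)
      cmp <- compare_models(full, restricted)
      f <- out("comparison.csv")
      write.csv(cmp$table, f, row.names = FALSE)
      fj <- out("comparison.json")
      jsonlite::write_json(cmp[c("df", "n", "mean_log_lr", "mean_delta_bic",
                                 "chisq_mean", "p_mean", "chisq_sum",
                                 "p_sum", "mean_pseudo_r2_full")],
                           fj, auto_unbox = TRUE, digits = NA)
      written <- c(written, f, fj)
    } else if (cmd == "recover") {
      n <- if (is.null(config$n)) 40 else config$n
      say("parameter recovery with %d participants", n)
      rec <- recover_parameters(cohort_uniform(n),
                                settings = fit_settings(seed = config$seed),
                                seed = config$seed)
      f <- out("recovery.csv")
      write.csv(rec$values, f, row.names = FALSE)
      fj <- out("recovery.json")
      jsonlite::write_json(
        stats::setNames(as.list(rec$report$r), rec$report$param),
        fj, auto_unbox = TRUE, digits = NA)
      written <- c(written, f, fj)
    } else if (cmd == "metrics") {
      n_reps <- if (is.null(config$n_reps)) 40 else config$n_reps
      res <- simulate_learning_rate_experiment(n_reps = n_reps,
                                               seed = config$seed)
      f <- out("learning_rate_summary.csv")
      write.csv(res$summary, f, row.names = FALSE)
      written <- c(written, f)
    } else stop("unknown command: ", cmd)
    written <- c(written,
                 .write_sidecar(out("metadata.json"), config, basename(written)))
    say("wrote %d file(s) to %s", length(written), config$out)
    invisible(written)
  }, error = on_fail)
}
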