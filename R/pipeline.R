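# Pipeline orchestration: YAML configuration, CSV/JSON I/O contracts, and
# the simulate / estimate / fit / recover stages. CSV is the interchange
# format for trial-level data, JSON for model summaries, YAML for config.
# Every stage writes a manifest (config hash, seed, package version) from
# which outputs can be reproduced byte-identically.

#' Default pipeline configuration
#'
#' One nested list materializing every stage's defaults: `environment`
#' (per-character noise/hazard and assignment), `learner` (observer
#' parameters), `coding` (inclusion rule), `models` (standardization and
#' formula options), `simulation` (cohort size and policy coefficients),
#' plus `seed` and `out_dir`.
#'
#' @return Nested list.
#' @export
hs_default_config <- function() {
  env <- environment_config()
  pats <- lapply(env$patterns, function(p)
    list(noise_sd = p$noise_sd, hazard = p$hazard, margin = p$margin))
  pol <- agent_policy()
  list(
    environment = list(patterns = pats,
                       character_assignment = as.list(env$character_assignment)),
    learner = list(hazard_belief = 0.1, noise_sd = 0.08, tau_reset = 0.5,
                   lambda = 0.5),
    coding = list(min_trials_per_character = 10, apply_inclusion = TRUE),
    models = list(standardize = TRUE, include_performance_main = TRUE,
                  min_choice_events = 20),
    simulation = list(n_children = 87, counterbalance = TRUE,
                      n_trials_fixed = NA,
                      motor_sd = pol$motor_sd, heterogeneity = pol$heterogeneity,
                      intercept_sd = pol$intercept_sd,
                      quit_prob = pol$quit_prob,
                      min_quit_trial = pol$min_quit_trial,
                      max_char_trials = pol$max_char_trials,
                      leave = as.list(pol$leave), choice = as.list(pol$choice)),
    seed = 1L,
    out_dir = "hideseek-output"
  )
}

# Recursively check user keys against the defaults; unknown keys are errors.
check_config_keys <- function(user, defaults, path = "") {
  if (!is.list(user)) return(invisible(NULL))
  # open mappings whose key names are user-chosen (pattern names, characters)
  open <- c("patterns", "character_assignment")
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) {
    stop("unknown config key(s): ",
         paste0(sub("^/", "", paste0(path, "/", extra)), collapse = ", "),
         call. = FALSE)
  }
  for (k in intersect(names(user), names(defaults))) {
    if (is.list(defaults[[k]]) && !k %in% open) {
      check_config_keys(user[[k]], defaults[[k]], paste0(path, "/", k))
    }
  }
  invisible(NULL)
}

merge_config <- function(user, defaults) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(defaults[[k]])) {
      defaults[[k]] <- merge_config(user[[k]], defaults[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read and validate a pipeline configuration
#'
#' @param path YAML file path, or `NULL` for the defaults. User values are
#'   merged over [hs_default_config()]; unknown keys are rejected.
#' @return Validated configuration list.
#' @export
hs_read_config <- function(path = NULL) {
  defaults <- hs_default_config()
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  check_config_keys(user, defaults)
  merge_config(user, defaults)
}

config_environment <- function(config) {
  pats <- lapply(names(config$environment$patterns), function(nm) {
    p <- config$environment$patterns[[nm]]
    pattern_config(p$noise_sd, p$hazard, label = nm,
                   margin = p$margin %||% 0.1)
  })
  names(pats) <- names(config$environment$patterns)
  environment_config(pats, unlist(config$environment$character_assignment))
}

config_policy <- function(config) {
  s <- config$simulation
  agent_policy(hazard_belief = config$learner$hazard_belief,
               noise_sd_belief = config$learner$noise_sd,
               motor_sd = s$motor_sd, leave = unlist(s$leave),
               choice = unlist(s$choice), intercept_sd = s$intercept_sd,
               heterogeneity = s$heterogeneity, quit_prob = s$quit_prob,
               min_quit_trial = s$min_quit_trial,
               max_char_trials = s$max_char_trials,
               n_trials_fixed = if (is.null(s$n_trials_fixed) ||
                                    is.na(s$n_trials_fixed)) NULL
                                else s$n_trials_fixed)
}

config_learner <- function(config) {
  l <- config$learner
  learner_config(hazard_belief = l$hazard_belief, noise_sd = l$noise_sd,
                 tau_reset = l$tau_reset, lambda = l$lambda)
}

#' Validate a trial-log data.frame against the interchange schema
#'
#' Required columns (exact names): `participant_id`, `trial`,
#' `character_id`, `predicted_loc`, `actual_loc`; an optional `timestamp_s`
#' is allowed. Locations must lie in `[0, 1]` and trial indices must be
#' strictly increasing within participant. Violations raise an error
#' addressing the offending column or rows.
#'
#' @param data data.frame to validate.
#' @return The data, invisibly, when valid.
#' @export
validate_trial_log <- function(data) {
  req <- c("participant_id", "trial", "character_id", "predicted_loc", "actual_loc")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("trial log is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (cl in c("predicted_loc", "actual_loc")) {
    bad <- which(!is.finite(data[[cl]]) | data[[cl]] < 0 | data[[cl]] > 1)
    if (length(bad)) {
      stop(sprintf("column '%s' outside [0, 1] at row(s) %s", cl,
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
  }
  for (p in split(data, data$participant_id)) {
    if (anyDuplicated(p$trial) || is.unsorted(p$trial, strictly = TRUE)) {
      stop(sprintf("trial indices not strictly increasing for participant '%s'",
                   p$participant_id[1]), call. = FALSE)
    }
  }
  invisible(data)
}

write_manifest <- function(out_dir, config, seed, stage) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  manifest <- list(stage = stage, seed = seed,
                   config_md5 = unname(tools::md5sum(tf)),
                   package = "hideseek",
                   version = as.character(utils::packageVersion("hideseek")))
  jsonlite::write_json(manifest, file.path(out_dir, paste0("manifest-", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a cohort and write the dataset files
#'
#' @param config Configuration list from [hs_read_config()].
#' @param seed Integer seed (overrides `config$seed` when non-`NULL`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the path of the trial-log CSV. Also writes
#'   `ground_truth.json` and a stage manifest.
#' @export
pipeline_simulate <- function(config = hs_read_config(), seed = NULL,
                              out_dir = config$out_dir) {
  seed <- seed %||% config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config$simulation$n_children, config_policy(config),
                         config_environment(config), seed = seed,
                         counterbalance = isTRUE(config$simulation$counterbalance))
  path <- file.path(out_dir, "trials.csv")
  utils::write.csv(sim$data, path, row.names = FALSE)
  jsonlite::write_json(
    list(policy = unclass(sim$truth$policy)[c("leave", "choice", "hazard_belief",
                                              "noise_sd_belief", "motor_sd",
                                              "heterogeneity", "intercept_sd")],
         agents = sim$truth$agents),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  write_manifest(out_dir, config, seed, "simulate")
  invisible(path)
}

#' Compute model-derived trial estimates for a dataset
#'
#' @param dataset Trial-log CSV path or data.frame (validated against the
#'   schema).
#' @param config Configuration list.
#' @param out_dir Output directory; `estimates.csv` (input columns joined
#'   with the estimate columns) and `snapshot.csv` are written there.
#' @return Invisibly, the list from [estimate_dataset()].
#' @export
pipeline_estimate <- function(dataset, config = hs_read_config(),
                              out_dir = config$out_dir) {
  data <- if (is.character(dataset)) utils::read.csv(dataset) else dataset
  data$participant_id <- as.character(data$participant_id)
  data$character_id <- as.character(data$character_id)
  validate_trial_log(data)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  est <- estimate_dataset(data, config_learner(config),
                          characters = sort(unique(data$character_id)))
  est$estimates <- code_behavior(est$estimates)
  utils::write.csv(est$estimates, file.path(out_dir, "estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(est$snapshot, file.path(out_dir, "snapshot.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, config, config$seed, "estimate")
  invisible(est)
}

hs_fit_to_list <- function(fit) {
  if (is.null(fit)) return(NULL)
  list(coefficients = fit$coefficients, logLik = fit$logLik, k = fit$k,
       n = fit$n, aic = fit$aic, bic = fit$bic, vif = as.list(fit$vif),
       converged = fit$converged, dropped_rows = fit$dropped_rows)
}

#' Fit the decision models for an estimated dataset
#'
#' Applies the inclusion rule, fits per-child performance slopes, the
#' leave-stay model (with marginal effects of novelty and LP at plus/minus
#' 1 SD of performance), the exploratory-choice model on differential
#' expectations, its history variant, and the AIC/BIC comparison. Model
#' summaries are serialized to `models.json` and a readable `models.txt`.
#'
#' @param estimates Path to `estimates.csv` / `snapshot.csv` directory, or
#'   the list returned by [pipeline_estimate()].
#' @param config Configuration list.
#' @param out_dir Output directory.
#' @param seed Seed for the choice-option randomization.
#' @return Invisibly, a list with `slopes`, `leave`, `marginal`, `choice`,
#'   `choice_history`, `comparison`, `included`.
#' @export
pipeline_fit <- function(estimates, config = hs_read_config(),
                         out_dir = config$out_dir, seed = NULL) {
  seed <- seed %||% config$seed
  if (is.character(estimates)) {
    estimates <- list(
      estimates = utils::read.csv(file.path(estimates, "estimates.csv"),
                                  colClasses = c(participant_id = "character",
                                                 character_id = "character")),
      snapshot = utils::read.csv(file.path(estimates, "snapshot.csv"),
                                 colClasses = c(participant_id = "character",
                                                character_id = "character")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  coded <- estimates$estimates
  chars <- sort(unique(coded$character_id))
  if (isTRUE(config$coding$apply_inclusion)) {
    keep <- vapply(split(coded, coded$participant_id), apply_inclusion,
                   logical(1), characters = chars,
                   min_trials = config$coding$min_trials_per_character)
    included <- names(keep)[keep]
  } else {
    included <- unique(coded$participant_id)
  }
  if (!length(included)) stop("no participants pass the inclusion rule", call. = FALSE)
  coded <- coded[coded$participant_id %in% included, , drop = FALSE]
  snap <- estimates$snapshot
  snap <- snap[snap$participant_id %in% included, , drop = FALSE]

  slopes <- fit_performance_slopes(coded)
  std <- isTRUE(config$models$standardize)
  leave <- fit_leave_stay(coded, slopes, standardize = std,
                          include_performance_main =
                            isTRUE(config$models$include_performance_main))
  marg <- marginal_effects(leave)
  events <- do.call(rbind, lapply(split(coded, coded$participant_id),
                                  extract_choice_events, characters = chars))
  tab <- build_choice_table(events, snap, slopes, seed = seed)
  min_ev <- config$models$min_choice_events
  choice <- fit_choice_model(tab, "expectation", standardize = std,
                             min_events = min_ev)
  choice_hist <- fit_choice_model(tab, "history", standardize = std,
                                  min_events = min_ev)
  comparison <- compare_models(choice, choice_hist)

  res <- list(slopes = slopes, leave = leave, marginal = marg, choice = choice,
              choice_history = choice_hist, comparison = comparison,
              included = included)
  jsonlite::write_json(
    list(included_participants = included,
         performance = list(group_slope = slopes$fixed[["estimate"]],
                            se = slopes$fixed[["se"]], t = slopes$fixed[["t"]],
                            method = slopes$method),
         leave_stay = hs_fit_to_list(leave),
         marginal_effects = marg,
         choice_expectation = hs_fit_to_list(choice),
         choice_history = hs_fit_to_list(choice_hist),
         comparison = c(as.list(comparison),
                        preferred = attr(comparison, "preferred"))),
    file.path(out_dir, "models.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  txt <- file.path(out_dir, "models.txt")
  sink(txt); on.exit(sink(), add = TRUE)
  cat("== Performance slopes ==\n"); print(slopes)
  cat("\n== Leave-stay model ==\n"); print(leave)
  cat("\n== Marginal effects (performance at -1/+1 SD) ==\n"); print(marg)
  cat("\n== Choice model (expectations) ==\n"); print(choice)
  cat("\n== Choice model (history) ==\n"); print(choice_hist)
  cat("\n== Comparison ==\n"); print(comparison)
  sink(); on.exit()
  write_manifest(out_dir, config, seed, "fit")
  invisible(res)
}

#' Run a recovery experiment from a configuration
#'
#' @param config Configuration list.
#' @param out_dir Output directory (`recovery.csv` with the per-replicate
#'   draws and `recovery_summary.csv` are written there).
#' @param R,n_children,n_trials Experiment size.
#' @param seed Integer seed.
#' @return Invisibly, the `"hs_recovery"` object.
#' @export
pipeline_recover <- function(config = hs_read_config(), out_dir = config$out_dir,
                             R = 10, n_children = 50, n_trials = 40,
                             seed = NULL) {
  seed <- seed %||% config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pol <- config_policy(config)
  pol$heterogeneity <- 0
  rec <- recovery_experiment(R, n_children = n_children, n_trials = n_trials,
                             policy = pol, env = config_environment(config),
                             seed = seed)
  utils::write.csv(rec$draws, file.path(out_dir, "recovery.csv"),
                   row.names = FALSE)
  utils::write.csv(rec$summary, file.path(out_dir, "recovery_summary.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, config, seed, "recover")
  invisible(rec)
}
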