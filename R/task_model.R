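# Generative model of the hide-and-seek environment: each character hides at
# locations drawn from a Gaussian whose mean occasionally jumps (volatility,
# a per-trial hazard) and whose SD is the noise level. Locations live on the
# unit interval: 0 is the far-left corner of the hedge, 1 the far right.

#' Hiding-pattern configuration for one character
#'
#' A hiding pattern is a Gaussian over 1-D screen location whose mean is
#' redrawn with probability `hazard` on each trial (a changepoint) and whose
#' standard deviation `noise_sd` is the irreducible noise. New means are drawn
#' uniformly on `[margin, 1 - margin]` so the bulk of the Gaussian stays
#' on-screen; outcomes are truncated to `[0, 1]` by rejection sampling rather
#' than clipping, which would pile point mass at the edges and bias
#' prediction errors.
#'
#' @param noise_sd Standard deviation of hiding locations around the latent
#'   mean, in screen widths. Must be `>= 0` (0 is a degenerate pattern useful
#'   only for testing).
#' @param hazard Per-trial probability in `[0, 1]` that the latent mean jumps
#'   to a new uniform draw.
#' @param mean_init Initial latent mean in `[0, 1]`, or `"random"` to draw it
#'   uniformly on `[margin, 1 - margin]` when the pattern is initialised.
#' @param label Descriptive label, conventionally one of
#'   `"high_noise_low_vol"`, `"low_noise_high_vol"`, `"intermediate"`.
#' @param margin Edge margin for uniform mean redraws (default 0.1).
#' @param mean_schedule Optional explicit vector of latent means, one per
#'   trial, overriding the hazard process (for hand-crafted schedules).
#' @return An object of class `"hs_pattern"`.
#' @seealso [environment_config()], [generate_outcome_sequence()]
#' @export
pattern_config <- function(noise_sd, hazard, mean_init = "random",
                           label = "intermediate", margin = 0.1,
                           mean_schedule = NULL) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("'noise_sd' must be a single non-negative number", call. = FALSE)
  }
  assert_probability(hazard, "hazard")
  if (!identical(mean_init, "random")) {
    if (!is.numeric(mean_init) || length(mean_init) != 1L) {
      stop("'mean_init' must be a location or \"random\"", call. = FALSE)
    }
    assert_location(mean_init, "mean_init")
  }
  if (margin < 0 || margin >= 0.5) stop("'margin' must be in [0, 0.5)", call. = FALSE)
  if (!is.null(mean_schedule)) assert_location(mean_schedule, "mean_schedule")
  structure(
    list(noise_sd = noise_sd, hazard = hazard, mean_init = mean_init,
         label = label, margin = margin, mean_schedule = mean_schedule),
    class = "hs_pattern"
  )
}

#' Environment configuration: three characters, three hiding patterns
#'
#' The default reproduces the task structure: the first character has high
#' noise and low volatility, the second low noise and high volatility, and the
#' third intermediate noise and volatility. The task itself prints no numeric
#' levels, so the defaults (`noise_sd` 0.12 / 0.04 / 0.08 screen widths,
#' `hazard` 0.04 / 0.25 / 0.12) order the characters as described while
#' keeping each pattern learnable within a short session.
#'
#' @param patterns Named list of exactly three [pattern_config()] objects.
#' @param character_assignment Character vector mapping character ids (names)
#'   to pattern names. Defaults to characters `"1"`, `"2"`, `"3"` in the
#'   canonical order.
#' @return An object of class `"hs_environment"`.
#' @export
environment_config <- function(patterns = NULL, character_assignment = NULL) {
  if (is.null(patterns)) {
    patterns <- list(
      high_noise_low_vol = pattern_config(0.12, 0.04, label = "high_noise_low_vol"),
      low_noise_high_vol = pattern_config(0.04, 0.25, label = "low_noise_high_vol"),
      intermediate       = pattern_config(0.08, 0.12, label = "intermediate")
    )
  }
  if (length(patterns) != 3L || is.null(names(patterns)) ||
      anyDuplicated(names(patterns))) {
    stop("'patterns' must be a named list of three distinct patterns", call. = FALSE)
  }
  if (!all(vapply(patterns, inherits, logical(1), "hs_pattern"))) {
    stop("every element of 'patterns' must come from pattern_config()", call. = FALSE)
  }
  if (is.null(character_assignment)) {
    character_assignment <- stats::setNames(names(patterns), c("1", "2", "3"))
  }
  if (!all(character_assignment %in% names(patterns))) {
    stop("character_assignment refers to unknown pattern names", call. = FALSE)
  }
  structure(list(patterns = patterns, character_assignment = character_assignment),
            class = "hs_environment")
}

#' @export
print.hs_environment <- function(x, ...) {
  cat("Hide-and-seek environment (3 characters)\n")
  for (ch in names(x$character_assignment)) {
    p <- x$patterns[[x$character_assignment[[ch]]]]
    cat(sprintf("  character %s: %-20s noise_sd = %.3f, hazard = %.3f\n",
                ch, p$label, p$noise_sd, p$hazard))
  }
  invisible(x)
}

init_pattern <- function(config) {
  m <- if (identical(config$mean_init, "random")) {
    stats::runif(1, config$margin, 1 - config$margin)
  } else {
    config$mean_init
  }
  list(current_mean = m, trials_since_change = 0L)
}

#' Advance a hiding pattern by one trial
#'
#' With probability `hazard` the latent mean is redrawn uniformly on
#' `[margin, 1 - margin]` and the trials-since-change counter resets;
#' otherwise the mean is unchanged and the counter increments.
#'
#' @param state List with `current_mean` and `trials_since_change`, as
#'   produced internally or by a previous call.
#' @param config A [pattern_config()] object.
#' @return List with elements `state` (the new state) and `changed` (logical).
#' @export
step_pattern <- function(state, config) {
  assert_probability(config$hazard, "hazard")
  changed <- stats::runif(1) < config$hazard
  if (changed) {
    state$current_mean <- stats::runif(1, config$margin, 1 - config$margin)
    state$trials_since_change <- 0L
  } else {
    state$trials_since_change <- state$trials_since_change + 1L
  }
  list(state = state, changed = changed)
}

#' Sample a hiding location from the current pattern state
#'
#' Draws from Normal(`current_mean`, `noise_sd^2`) truncated to `[0, 1]` by
#' rejection sampling. With `noise_sd = 0` the latent mean is returned.
#'
#' @inheritParams step_pattern
#' @return A location in `[0, 1]`.
#' @export
sample_location <- function(state, config) {
  if (config$noise_sd == 0) return(state$current_mean)
  repeat {
    x <- stats::rnorm(1, state$current_mean, config$noise_sd)
    if (x >= 0 && x <= 1) return(x)
  }
}

#' Generate a hiding-location sequence for one character
#'
#' Alternates [step_pattern()] and [sample_location()] for `n_trials` trials.
#' The first trial never carries a changepoint (initialisation). When the
#' pattern carries an explicit `mean_schedule`, that schedule overrides the
#' hazard process.
#'
#' @param env An [environment_config()] object.
#' @param character Character id present in `env$character_assignment`.
#' @param n_trials Number of trials (`>= 1`).
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame with columns `trial`, `latent_mean`, `location`,
#'   `changepoint`.
#' @export
generate_outcome_sequence <- function(env, character, n_trials, seed = NULL) {
  character <- as.character(character)
  if (!character %in% names(env$character_assignment)) {
    stop(sprintf("unknown character id '%s'", character), call. = FALSE)
  }
  if (n_trials < 1) stop("'n_trials' must be >= 1", call. = FALSE)
  set_seed_if(seed)
  config <- env$patterns[[env$character_assignment[[character]]]]
  state <- init_pattern(config)
  out <- data.frame(trial = seq_len(n_trials), latent_mean = NA_real_,
                    location = NA_real_, changepoint = FALSE)
  sched <- config$mean_schedule
  for (t in seq_len(n_trials)) {
    if (!is.null(sched)) {
      idx <- min(t, length(sched))
      changed <- t > 1L && sched[idx] != state$current_mean
      state$current_mean <- sched[idx]
      state$trials_since_change <-
        if (changed) 0L else state$trials_since_change + (t > 1L)
    } else if (t > 1L) {
      st <- step_pattern(state, config)
      state <- st$state
      changed <- st$changed
    } else {
      changed <- FALSE
    }
    out$latent_mean[t] <- state$current_mean
    out$location[t] <- sample_location(state, config)
    out$changepoint[t] <- changed
  }
  out
}
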