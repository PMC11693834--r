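# Reduced-Bayesian changepoint observer. Turns (prediction, outcome) pairs
# into the trial-wise covariates the decision analyses need: signed error,
# prediction error (PE), learning progress (LP), changepoint probability
# (omega), adaptive learning rate (alpha), relative uncertainty (tau),
# expected PE, expected LP and novelty.
#
# The observer is a two-hypothesis approximation to full Bayesian changepoint
# inference (the Nassar-style reduced model): each outcome either continues
# the current run (Gaussian predictive density) or follows a changepoint
# (uniform over the hedge). Relative uncertainty tau is the variance of the
# belief about the latent mean divided by (that variance + noise variance),
# propagated through the omega-weighted mixture of the two hypotheses.

#' Learner configuration
#'
#' @param hazard_belief Subjective per-trial changepoint probability. The
#'   observer is not told the true per-character hazards, so a single value
#'   (default 0.1) is used for all characters.
#' @param noise_sd Assumed outcome noise SD in screen widths (default 0.08,
#'   the intermediate level). Held fixed rather than estimated online, which
#'   keeps the filter identifiable on short sessions.
#' @param tau_reset Relative uncertainty immediately after a certain
#'   changepoint (default 0.5, the conjugate value after a single
#'   observation under a flat prior).
#' @param lambda Decay of the exponential moving average of PE that feeds
#'   expected LP (default 0.5, a two-to-three-trial memory).
#' @param domain_width Width of the outcome domain (default 1, the
#'   normalized hedge).
#' @param b_init Initial belief location (default 0.5, the centre).
#' @param tau_init Initial relative uncertainty. Defaults to the value
#'   implied by a uniform prior over the hedge:
#'   `(1/12) / (1/12 + noise_sd^2)`.
#' @param alpha_gain Multiplier in `[0, 1]` applied to the learning rate
#'   before the belief update; 1 is the normative observer. Used by the
#'   synthetic-cohort generator to create impaired learners.
#' @param noise_est `"online"` (default) tracks each character's noise SD
#'   from its own residuals (an exponentially weighted estimate of
#'   `delta^2 * (1 - tau)`, down-weighted when a changepoint is likely,
#'   initialised at `noise_sd`); `"fixed"` holds the noise SD at `noise_sd`
#'   throughout. Online estimation lets expected PE reflect the characters'
#'   different noise levels, so expected LP isolates the reducible part of
#'   the error.
#' @param noise_lr Learning rate of the online noise estimate (default
#'   0.2).
#' @return An object of class `"hs_learner_config"`.
#' @export
learner_config <- function(hazard_belief = 0.1, noise_sd = 0.08,
                           tau_reset = 0.5, lambda = 0.5, domain_width = 1,
                           b_init = 0.5, tau_init = NULL, alpha_gain = 1,
                           noise_est = c("online", "fixed"), noise_lr = 0.2) {
  assert_probability(hazard_belief, "hazard_belief")
  if (noise_sd <= 0) stop("'noise_sd' must be positive", call. = FALSE)
  assert_probability(tau_reset, "tau_reset")
  assert_probability(lambda, "lambda")
  if (domain_width <= 0) stop("'domain_width' must be positive", call. = FALSE)
  if (is.null(tau_init)) tau_init <- (1 / 12) / (1 / 12 + noise_sd^2)
  assert_probability(tau_init, "tau_init")
  if (alpha_gain < 0 || alpha_gain > 1) stop("'alpha_gain' must be in [0, 1]", call. = FALSE)
  noise_est <- match.arg(noise_est)
  assert_probability(noise_lr, "noise_lr")
  structure(
    list(hazard_belief = hazard_belief, noise_sd = noise_sd,
         tau_reset = tau_reset, lambda = lambda, domain_width = domain_width,
         b_init = b_init, tau_init = tau_init, alpha_gain = alpha_gain,
         noise_est = noise_est, noise_lr = noise_lr),
    class = "hs_learner_config"
  )
}

#' Signed and unsigned prediction error
#'
#' PE is the distance between the location the participant predicted and the
#' location where the character actually appeared. The signed error
#' `delta = actual - predicted` drives belief updates; its magnitude `pe` is
#' the regression covariate.
#'
#' @param predicted,actual Locations in `[0, 1]`.
#' @return List with `delta` (signed) and `pe` (`abs(delta)`).
#' @export
prediction_error <- function(predicted, actual) {
  assert_location(predicted, "predicted")
  assert_location(actual, "actual")
  delta <- actual - predicted
  list(delta = delta, pe = abs(delta))
}

#' Learning progress between two consecutive trials
#'
#' LP is the decrease in PE over two consecutive trials with the same
#' character: positive when performance improves, negative when it worsens,
#' and missing (`NA`) on the first trial with a character, where there is no
#' previous PE.
#'
#' @param prev_pe PE on the previous trial with this character (or `NA`).
#' @param pe PE on the current trial.
#' @return `prev_pe - pe`, or `NA` when `prev_pe` is missing.
#' @export
learning_progress <- function(prev_pe, pe) {
  if (is.na(prev_pe)) return(NA_real_)
  prev_pe - pe
}

#' Posterior changepoint probability for one outcome
#'
#' Two-hypothesis Bayes: the outcome came either from a fresh uniform draw
#' over the domain (changepoint, prior `hazard_belief`) or from the Gaussian
#' predictive distribution around the current belief (no changepoint).
#'
#' @param delta Signed prediction error.
#' @param predictive_sd SD of the predictive distribution (belief
#'   uncertainty plus outcome noise); must be positive.
#' @param hazard_belief Prior changepoint probability.
#' @param domain_width Width of the uniform changepoint hypothesis.
#' @return Changepoint probability in `[0, 1]`.
#' @export
changepoint_probability <- function(delta, predictive_sd, hazard_belief,
                                    domain_width = 1) {
  if (any(predictive_sd <= 0)) stop("'predictive_sd' must be positive", call. = FALSE)
  assert_probability(hazard_belief, "hazard_belief")
  u <- 1 / domain_width
  num <- hazard_belief * u
  den <- num + (1 - hazard_belief) * stats::dnorm(delta, 0, predictive_sd)
  ifelse(den == 0, 1, num / den)
}

#' Adaptive learning rate
#'
#' Combines the changepoint probability and the relative uncertainty:
#' `alpha = omega + (1 - omega) * tau`. After a certain changepoint the
#' belief fully resets (`alpha = 1`); with no changepoint evidence the update
#' is proportional to how uncertain the belief already is.
#'
#' @param omega Changepoint probability in `[0, 1]`.
#' @param tau Relative uncertainty in `[0, 1]`.
#' @return Learning rate in `[0, 1]`.
#' @export
learning_rate <- function(omega, tau) {
  omega + (1 - omega) * tau
}

#' Delta-rule belief update
#'
#' @param b Current belief location.
#' @param delta Signed prediction error.
#' @param alpha Learning rate in `[0, 1]`.
#' @return Updated belief, projected into `[0, 1]`.
#' @export
update_belief <- function(b, delta, alpha) {
  clamp01(b + alpha * delta)
}

#' Relative-uncertainty update
#'
#' Propagates the belief variance through the omega-weighted mixture of the
#' changepoint hypothesis (variance resets to the value implied by
#' `tau_reset`) and the no-changepoint hypothesis (conjugate Gaussian
#' shrinkage), including the between-hypothesis mean spread
#' `omega * (1 - omega) * (delta * (1 - tau))^2`. The result is re-expressed
#' as relative uncertainty `var / (var + noise_sd^2)`.
#'
#' @param tau Current relative uncertainty.
#' @param omega Changepoint probability for the outcome just observed.
#' @param delta Signed prediction error.
#' @param noise_sd Assumed outcome noise SD.
#' @param tau_reset Relative uncertainty after a certain changepoint.
#' @return Updated relative uncertainty in `[0, 1)`.
#' @export
update_uncertainty <- function(tau, omega, delta, noise_sd, tau_reset = 0.5) {
  var_n <- noise_sd^2
  var_cp <- var_n * tau_reset / (1 - tau_reset)
  var_stay <- tau * var_n
  var_mix <- omega * var_cp + (1 - omega) * var_stay +
    omega * (1 - omega) * (delta * (1 - tau))^2
  var_mix / (var_mix + var_n)
}

#' Expected prediction error on the next trial
#'
#' Under the predictive distribution Normal(`B`, `sigma_tot^2`) with
#' `sigma_tot^2` = belief variance + noise variance, the expected absolute
#' error is the folded-normal mean `sqrt(2/pi) * sigma_tot`. In terms of
#' relative uncertainty, `sigma_tot = noise_sd / sqrt(1 - tau)`.
#'
#' @param tau Relative uncertainty.
#' @param noise_sd Assumed outcome noise SD.
#' @return Expected PE in location units.
#' @export
expected_pe <- function(tau, noise_sd) {
  sigma_tot <- noise_sd / sqrt(pmax(1 - tau, 1e-12))
  sqrt(2 / pi) * sigma_tot
}

#' Expected learning progress on the next trial
#'
#' The improvement the observer anticipates: the recent (exponentially
#' smoothed) PE minus the PE expected on the next trial. Zero at
#' convergence, positive while errors are still expected to shrink.
#'
#' @param smoothed_pe Exponential moving average of recent PE.
#' @param exp_pe Expected PE from [expected_pe()].
#' @return Expected LP (signed, location units).
#' @export
expected_lp <- function(smoothed_pe, exp_pe) {
  smoothed_pe - exp_pe
}

#' Novelty score from pick counts
#'
#' Novelty is negative familiarity: the more a character has been picked,
#' the less novel it is. The score is the population-SD z-score of
#' `-pick_count` among the characters' counts, so it is strictly decreasing
#' in the count and all scores are zero when counts are equal.
#'
#' @param pick_count Count(s) to score.
#' @param all_counts Counts for all characters in the sample.
#' @return Standardized novelty score(s).
#' @export
novelty <- function(pick_count, all_counts) {
  if (any(all_counts < 0) || any(pick_count < 0)) {
    stop("pick counts must be non-negative", call. = FALSE)
  }
  m <- mean(-all_counts)
  s <- sqrt(mean((-all_counts - m)^2))
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(pick_count)))
  (-pick_count - m) / s
}

# Fresh per-character learner state.
learner_init_state <- function(config) {
  list(b = config$b_init, tau = config$tau_init, last_pe = NA_real_,
       smoothed_pe = NA_real_, n_obs = 0L, sigma2 = config$noise_sd^2)
}

# One observation for one character. `predicted` is the operative belief for
# this trial (the participant's logged prediction, or the model's own belief
# when it predicts for itself). Shared verbatim by the analysis pipeline and
# the synthetic-agent simulator so model-derived covariates agree exactly.
learner_step <- function(state, predicted, actual, config) {
  # hot path: the exported ops are inlined here (scalar arithmetic only);
  # oracle tests pin this function to the op-by-op composition
  delta <- actual - predicted
  pe <- abs(delta)
  first <- state$n_obs == 0L
  lp <- if (first) NA_real_ else state$last_pe - pe
  tau <- state$tau
  var_n <- state$sigma2
  pred_sd <- sqrt(var_n / max(1 - tau, 1e-12))
  h <- config$hazard_belief
  num <- h / config$domain_width
  den <- num + (1 - h) * stats::dnorm(delta, 0, pred_sd)
  omega <- if (den == 0) 1 else num / den
  alpha <- omega + (1 - omega) * tau
  b <- predicted + alpha * config$alpha_gain * delta
  state$b <- if (b < 0) 0 else if (b > 1) 1 else b
  var_mix <- omega * var_n * config$tau_reset / (1 - config$tau_reset) +
    (1 - omega) * tau * var_n +
    omega * (1 - omega) * (delta * (1 - tau))^2
  state$tau <- var_mix / (var_mix + var_n)
  if (config$noise_est == "online") {
    # residual-based noise tracking: E[delta^2] = sigma_n^2 / (1 - tau) when
    # no changepoint occurred, so delta^2 * (1 - tau) estimates sigma_n^2;
    # down-weighted by (1 - omega) to avoid learning noise from changepoints
    lr <- config$noise_lr * (1 - omega)
    s2 <- (1 - lr) * var_n + lr * delta^2 * (1 - tau)
    state$sigma2 <- min(max(s2, 1e-4), 0.09)
  }
  state$smoothed_pe <- if (first) pe else {
    config$lambda * state$smoothed_pe + (1 - config$lambda) * pe
  }
  state$last_pe <- pe
  state$n_obs <- state$n_obs + 1L
  epe <- sqrt(2 / pi) * sqrt(state$sigma2 / max(1 - state$tau, 1e-12))
  list(state = state,
       est = list(delta = delta, pe = pe, lp = lp, omega = omega,
                  alpha = alpha, expected_pe = epe,
                  expected_lp = state$smoothed_pe - epe))
}

#' Run the observer through one participant's session
#'
#' Processes trials in order, maintaining a separate learner state per
#' character that persists across leave/return visits (switching away does
#' not erase memory). Returns one row of model-derived covariates per trial
#' plus a per-trial snapshot of every character's state, which downstream
#' choice models use to value the two alternatives at each switch.
#'
#' Pick counts (for novelty) are incremented at selection time, i.e. the
#' count for the current character includes the current trial.
#'
#' @param trials data.frame with columns `participant_id`, `trial`,
#'   `character_id`, `predicted_loc`, `actual_loc` for a single participant,
#'   sorted by `trial`.
#' @param config A [learner_config()].
#' @param characters Vector of all character ids in the task (default: the
#'   ids observed in `trials`). Unvisited characters still enter novelty
#'   standardization with count 0.
#' @return List with `estimates` (the input rows plus columns
#'   `within_character_trial`, `delta`, `pe`, `lp`, `omega`, `alpha`, `tau`,
#'   `expected_pe`, `expected_lp`, `novelty`, `pick_count`) and `snapshot`
#'   (long data.frame: per trial and character, `expected_pe`,
#'   `expected_lp`, `last_pe`, `last_lp`, `pick_count`, `visited`).
#' @export
process_session <- function(trials, config = learner_config(),
                            characters = NULL) {
  req <- c("participant_id", "trial", "character_id", "predicted_loc", "actual_loc")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (length(unique(trials$participant_id)) > 1L) {
    stop("process_session() expects a single participant", call. = FALSE)
  }
  n <- nrow(trials)
  if (n == 0L) stop("empty session", call. = FALSE)
  if (is.unsorted(trials$trial, strictly = TRUE)) {
    stop("trial indices must be strictly increasing within participant", call. = FALSE)
  }
  assert_location(trials$predicted_loc, "predicted_loc")
  assert_location(trials$actual_loc, "actual_loc")

  chars <- as.character(characters %||% sort(unique(trials$character_id)))
  states <- stats::setNames(
    replicate(length(chars), learner_init_state(config), simplify = FALSE), chars)
  counts <- stats::setNames(integer(length(chars)), chars)
  last_lp <- stats::setNames(rep(NA_real_, length(chars)), chars)

  est <- data.frame(within_character_trial = integer(n), delta = NA_real_,
                    pe = NA_real_, lp = NA_real_, omega = NA_real_,
                    alpha = NA_real_, tau = NA_real_, expected_pe = NA_real_,
                    expected_lp = NA_real_, novelty = NA_real_,
                    pick_count = NA_integer_)
  nc <- length(chars)
  sn_epe <- sn_elp <- sn_lpe <- sn_llp <- numeric(n * nc)
  sn_cnt <- integer(n * nc)
  sn_vis <- logical(n * nc)
  epe_prior <- expected_pe(config$tau_init, config$noise_sd)
  prev_char <- NA_character_

  for (t in seq_len(n)) {
    ch <- as.character(trials$character_id[t])
    if (!ch %in% chars) stop(sprintf("unknown character id '%s'", ch), call. = FALSE)
    counts[ch] <- counts[ch] + 1L
    wct <- if (!identical(ch, prev_char)) 1L else est$within_character_trial[t - 1L] + 1L
    step <- learner_step(states[[ch]], trials$predicted_loc[t],
                         trials$actual_loc[t], config)
    states[[ch]] <- step$state
    if (!is.na(step$est$lp)) last_lp[ch] <- step$est$lp

    est$within_character_trial[t] <- wct
    est$delta[t] <- step$est$delta
    est$pe[t] <- step$est$pe
    est$lp[t] <- step$est$lp
    est$omega[t] <- step$est$omega
    est$alpha[t] <- step$est$alpha
    est$tau[t] <- step$state$tau
    est$expected_pe[t] <- step$est$expected_pe
    est$expected_lp[t] <- step$est$expected_lp
    est$novelty[t] <- novelty(counts[ch], counts)
    est$pick_count[t] <- counts[ch]

    off <- (t - 1L) * nc
    for (j in seq_len(nc)) {
      s <- states[[j]]
      vis <- s$n_obs > 0L
      epe_j <- if (vis) expected_pe(s$tau, sqrt(s$sigma2)) else epe_prior
      sn_epe[off + j] <- epe_j
      sn_elp[off + j] <- if (vis) expected_lp(s$smoothed_pe, epe_j) else NA_real_
      sn_lpe[off + j] <- s$last_pe
      sn_llp[off + j] <- last_lp[[j]]
      sn_cnt[off + j] <- counts[[j]]
      sn_vis[off + j] <- vis
    }
    prev_char <- ch
  }
  snapshot <- data.frame(
    participant_id = rep(trials$participant_id, each = nc),
    trial = rep(trials$trial, each = nc),
    character_id = rep(chars, times = n),
    expected_pe = sn_epe, expected_lp = sn_elp, last_pe = sn_lpe,
    last_lp = sn_llp, pick_count = sn_cnt, visited = sn_vis)
  list(estimates = cbind(trials, est), snapshot = snapshot)
}

#' Run the observer on an outcome sequence, predicting for itself
#'
#' The model's own belief serves as each trial's prediction, optionally with
#' a fixed learning rate replacing the adaptive one. Used for learner
#' diagnostics and policy comparisons.
#'
#' @param outcomes Numeric vector of observed locations in `[0, 1]`.
#' @param config A [learner_config()].
#' @param alpha_fixed If non-`NULL`, use this constant learning rate instead
#'   of the adaptive `omega + (1 - omega) * tau`.
#' @return data.frame with per-trial `predicted`, `outcome`, `delta`, `pe`,
#'   `omega`, `alpha`, `tau`, `b`.
#' @export
run_filter <- function(outcomes, config = learner_config(), alpha_fixed = NULL) {
  assert_location(outcomes, "outcomes")
  n <- length(outcomes)
  state <- learner_init_state(config)
  out <- data.frame(trial = seq_len(n), predicted = NA_real_, outcome = outcomes,
                    delta = NA_real_, pe = NA_real_, omega = NA_real_,
                    alpha = NA_real_, tau = NA_real_, b = NA_real_)
  for (t in seq_len(n)) {
    pred <- state$b
    step <- learner_step(state, pred, outcomes[t], config)
    if (!is.null(alpha_fixed)) {
      # redo the belief update with the fixed rate; uncertainty bookkeeping
      # retains the adaptive machinery so tau stays interpretable
      step$state$b <- update_belief(pred, step$est$delta, alpha_fixed)
      step$est$alpha <- alpha_fixed
    }
    state <- step$state
    out$predicted[t] <- pred
    out$delta[t] <- step$est$delta
    out$pe[t] <- step$est$pe
    out$omega[t] <- step$est$omega
    out$alpha[t] <- step$est$alpha
    out$tau[t] <- state$tau
    out$b[t] <- state$b
  }
  out
}
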