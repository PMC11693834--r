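# Simulated child cohorts with known ground truth. Agents carry the same
# reduced-Bayesian learner the analysis uses (fed with their own emitted,
# motor-noisy predictions, exactly as the analysis recomputes covariates
# from the logged data), a logistic stay-leave policy on the analysis's
# covariate definitions, and a softmax choice policy on the two options'
# expected-LP / expected-PE / novelty values. This makes the downstream
# models correctly specified under the generator -- a deliberate best case
# for calibration and recovery; heterogeneity (impaired learners) can be
# switched on to emulate the graded individual differences seen in real
# cohorts.

#' Fixed reference scales for generator-side covariates
#'
#' Policy coefficients apply to covariates divided by these nominal scales
#' (roughly one SD of each covariate under the default environment), so
#' generating coefficients live on the same per-SD scale as standardized
#' regression coefficients, and recovery experiments can fit on exactly the
#' generator's scale by passing these as `scales`.
#'
#' @return Named numeric vector.
#' @export
hs_reference_scales <- function() {
  c(pe = 0.12, lp = 0.17, novelty = 0.9, time = 10, performance = 1,
    d_explp = 0.10, d_exppe = 0.015, d_nov = 1.7, d_lp = 0.22, d_pe = 0.17)
}

#' Agent policy for the synthetic-cohort generator
#'
#' @param hazard_belief,noise_sd_belief The agent's learner parameters (the
#'   agent, like a child, is not told the true hazards).
#' @param motor_sd SD of motor/lapse noise added to the agent's belief when
#'   it taps a predicted location (screen widths).
#' @param leave Named coefficients of the stay-leave logistic policy on
#'   reference-scaled covariates: `intercept`, `pe`, `lp`, `novelty`,
#'   `time`, `performance`, `perf_pe`, `perf_lp`, `perf_nov`. Defaults use
#'   the fitted leave-stay magnitudes of the study this task reproduces
#'   (novelty and LP acting through their performance interactions).
#' @param choice Named coefficients of the softmax exploratory-choice
#'   policy: `explp`, `exppe`, `novelty` (defaults 0.35, -0.21, 0.30, the
#'   fitted magnitudes of the study this task reproduces: explored
#'   characters promise learning progress and low expected error, and are
#'   novel).
#' @param intercept_sd SD of per-agent deviations around the leave
#'   intercept (participant random intercept in the generating process).
#' @param heterogeneity Scale of per-agent learning impairment. Each agent
#'   draws a latent score `p ~ N(0, 1)` (higher = worse); its learning-rate
#'   multiplier is `min(1, exp(-heterogeneity * p))` and its motor noise is
#'   inflated by `1 + 0.5 * heterogeneity * max(0, p)`. Zero gives a
#'   homogeneous, normative cohort.
#' @param quit_prob Per-trial probability of ending the session once
#'   `min_quit_trial` trials have been played (calibrated so default
#'   sessions average about 28 trials).
#' @param min_quit_trial First trial from which quitting is possible.
#' @param max_char_trials Hard stop once any character has been played this
#'   many times (default 35, the session rule).
#' @param max_trials Safety cap on total trials.
#' @param n_trials_fixed If non-`NULL`, every session has exactly this many
#'   trials and the quit rules are disabled (used by calibration and
#'   recovery designs with fixed cohort sizes).
#' @return An object of class `"hs_policy"`.
#' @export
agent_policy <- function(hazard_belief = 0.1, noise_sd_belief = 0.08,
                         motor_sd = 0.06,
                         leave = c(intercept = -1.1, pe = 0, lp = 0,
                                   novelty = 0, time = 0, performance = 0,
                                   perf_pe = 0, perf_lp = 0.49, perf_nov = 0.73),
                         choice = c(explp = 0.35, exppe = -0.21, novelty = 0.30),
                         intercept_sd = 0.3, heterogeneity = 0.7,
                         quit_prob = 0.05, min_quit_trial = 10,
                         max_char_trials = 35, max_trials = 150,
                         n_trials_fixed = NULL) {
  leave_def <- c(intercept = -1.1, pe = 0, lp = 0, novelty = 0, time = 0,
                 performance = 0, perf_pe = 0, perf_lp = 0.49, perf_nov = 0.73)
  choice_def <- c(explp = 0.35, exppe = -0.21, novelty = 0.30)
  leave_def[names(leave)] <- leave
  choice_def[names(choice)] <- choice
  if (any(!names(leave) %in% names(leave_def)) ||
      any(!names(choice) %in% names(choice_def))) {
    stop("unknown policy coefficient name", call. = FALSE)
  }
  if (heterogeneity < 0) stop("'heterogeneity' must be >= 0", call. = FALSE)
  assert_probability(quit_prob, "quit_prob")
  structure(
    list(hazard_belief = hazard_belief, noise_sd_belief = noise_sd_belief,
         motor_sd = motor_sd, leave = leave_def, choice = choice_def,
         intercept_sd = intercept_sd, heterogeneity = heterogeneity,
         quit_prob = quit_prob, min_quit_trial = min_quit_trial,
         max_char_trials = max_char_trials, max_trials = max_trials,
         n_trials_fixed = n_trials_fixed, scales = hs_reference_scales()),
    class = "hs_policy"
  )
}

#' Simulate one child's session
#'
#' Trial loop: the agent predicts through its (possibly impaired) learner
#' plus motor noise; the environment reveals the hiding location; the agent
#' updates on its own emitted prediction; a logistic function of the policy
#' covariates decides leave vs stay; on a leave, a softmax over the two
#' alternatives' expected LP, expected PE and novelty picks the next
#' character.
#'
#' @param policy An [agent_policy()].
#' @param env An [environment_config()].
#' @param seed Optional integer seed (sessions are deterministic given it).
#' @param participant_id Id recorded in the log.
#' @param perf Latent performance score `p` (higher = worse); drawn
#'   `N(0, 1)` if `NULL`.
#' @param intercept_dev Per-agent leave-intercept deviation; drawn
#'   `N(0, intercept_sd)` if `NULL`.
#' @return List with `log` (TrialRecord data.frame: `participant_id`,
#'   `trial`, `character_id`, `predicted_loc`, `actual_loc`) and `truth`
#'   (the agent's latent parameters).
#' @export
simulate_child <- function(policy, env = environment_config(), seed = NULL,
                           participant_id = "c01", perf = NULL,
                           intercept_dev = NULL) {
  set_seed_if(seed)
  if (is.null(perf)) perf <- stats::rnorm(1)
  if (is.null(intercept_dev)) intercept_dev <- stats::rnorm(1, 0, policy$intercept_sd)
  het <- policy$heterogeneity
  kappa <- min(1, exp(-het * perf))
  motor_sd <- policy$motor_sd * (1 + 0.5 * het * max(0, perf))
  cfg <- learner_config(hazard_belief = policy$hazard_belief,
                        noise_sd = policy$noise_sd_belief,
                        alpha_gain = kappa)
  sc <- policy$scales
  g <- policy$leave
  th <- policy$choice
  chars <- names(env$character_assignment)
  states <- stats::setNames(
    replicate(length(chars), learner_init_state(cfg), simplify = FALSE), chars)
  pstates <- lapply(chars, function(ch)
    init_pattern(env$patterns[[env$character_assignment[[ch]]]]))
  names(pstates) <- chars
  counts <- stats::setNames(integer(length(chars)), chars)

  n_max <- policy$n_trials_fixed %||% policy$max_trials
  log <- data.frame(participant_id = rep(participant_id, n_max),
                    trial = seq_len(n_max), character_id = NA_character_,
                    predicted_loc = NA_real_, actual_loc = NA_real_)
  cur <- sample(chars, 1L)
  t <- 0L
  repeat {
    t <- t + 1L
    pcfg <- env$patterns[[env$character_assignment[[cur]]]]
    if (counts[cur] > 0L) {  # pattern evolves per trial played with it
      st <- step_pattern(pstates[[cur]], pcfg)
      pstates[[cur]] <- st$state
    }
    outcome <- sample_location(pstates[[cur]], pcfg)
    predicted <- clamp01(states[[cur]]$b + stats::rnorm(1, 0, motor_sd))
    log$character_id[t] <- cur
    log$predicted_loc[t] <- predicted
    log$actual_loc[t] <- outcome
    counts[cur] <- counts[cur] + 1L
    step <- learner_step(states[[cur]], predicted, outcome, cfg)
    states[[cur]] <- step$state
    est <- step$est

    # session termination
    if (!is.null(policy$n_trials_fixed)) {
      if (t >= policy$n_trials_fixed) break
    } else {
      if (counts[cur] >= policy$max_char_trials || t >= policy$max_trials) break
      if (t >= policy$min_quit_trial && stats::runif(1) < policy$quit_prob) break
    }

    # leave-stay decision on the analysis's covariate definitions
    nov_cur <- novelty(counts[cur], counts)
    lp_use <- if (is.na(est$lp)) 0 else est$lp
    eta <- g[["intercept"]] + intercept_dev +
      g[["pe"]] * est$pe / sc[["pe"]] +
      g[["lp"]] * lp_use / sc[["lp"]] +
      g[["novelty"]] * nov_cur / sc[["novelty"]] +
      g[["time"]] * t / sc[["time"]] +
      g[["performance"]] * perf / sc[["performance"]] +
      perf * (g[["perf_pe"]] * est$pe / sc[["pe"]] +
              g[["perf_lp"]] * lp_use / sc[["lp"]] +
              g[["perf_nov"]] * nov_cur / sc[["novelty"]])
    if (stats::runif(1) < stats::plogis(eta)) {
      alts <- setdiff(chars, cur)
      val <- vapply(alts, function(ch) {
        s <- states[[ch]]
        epe <- if (s$n_obs > 0L) expected_pe(s$tau, sqrt(s$sigma2)) else
          expected_pe(cfg$tau_init, cfg$noise_sd)
        elp <- if (s$n_obs > 0L)
          expected_lp(s$smoothed_pe, expected_pe(s$tau, sqrt(s$sigma2))) else 0
        nov <- novelty(counts[ch], counts)
        th[["explp"]] * elp / sc[["d_explp"]] +
          th[["exppe"]] * epe / sc[["d_exppe"]] +
          th[["novelty"]] * nov / sc[["d_nov"]]
      }, numeric(1))
      p1 <- stats::plogis(val[1] - val[2])
      cur <- if (stats::runif(1) < p1) alts[1] else alts[2]
    }
  }
  list(log = log[seq_len(t), ],
       truth = list(participant_id = participant_id, perf = perf,
                    kappa = kappa, motor_sd = motor_sd,
                    intercept_dev = intercept_dev))
}

#' Simulate a cohort of children
#'
#' @param n_children Number of children (default 87, a full-study-sized
#'   sample).
#' @param policy An [agent_policy()] shared by the cohort (agent-level
#'   heterogeneity is drawn inside).
#' @param env An [environment_config()]. With `counterbalance = TRUE` the
#'   character-to-pattern assignment is rotated across children.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @param counterbalance Rotate pattern assignment across children
#'   (default `TRUE`).
#' @return List with `data` (row-bound trial logs in the trial-log CSV
#'   schema) and `truth` (generating policy plus per-agent latents, class
#'   `"hs_ground_truth"`).
#' @export
simulate_cohort <- function(n_children = 87, policy = agent_policy(),
                            env = environment_config(), seed = NULL,
                            counterbalance = TRUE) {
  if (n_children < 1) stop("'n_children' must be >= 1", call. = FALSE)
  set_seed_if(seed)
  perf <- stats::rnorm(n_children)
  idev <- stats::rnorm(n_children, 0, policy$intercept_sd)
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_children)
  ids <- sprintf("c%03d", seq_len(n_children))
  logs <- vector("list", n_children)
  truths <- vector("list", n_children)
  pat_names <- names(env$patterns)
  for (i in seq_len(n_children)) {
    env_i <- env
    if (counterbalance) {
      rot <- (i - 1L) %% 3L
      env_i$character_assignment <- stats::setNames(
        pat_names[((seq_len(3) - 1L + rot) %% 3L) + 1L],
        names(env$character_assignment))
    }
    ch <- simulate_child(policy, env_i, seed = child_seeds[i],
                         participant_id = ids[i], perf = perf[i],
                         intercept_dev = idev[i])
    logs[[i]] <- ch$log
    truths[[i]] <- data.frame(participant_id = ids[i], perf = perf[i],
                              kappa = ch$truth$kappa,
                              motor_sd = ch$truth$motor_sd,
                              intercept_dev = idev[i])
  }
  truth <- structure(list(policy = policy, agents = do.call(rbind, truths)),
                     class = "hs_ground_truth")
  list(data = do.call(rbind, logs), truth = truth)
}

#' Run the observer over every participant in a dataset
#'
#' @param data Trial-log data.frame (multiple participants).
#' @param config A [learner_config()].
#' @param characters All character ids (default: observed in `data`).
#' @return List with row-bound `estimates` and `snapshot` tables (see
#'   [process_session()]).
#' @export
estimate_dataset <- function(data, config = learner_config(), characters = NULL) {
  chars <- characters %||% sort(unique(data$character_id))
  parts <- split(data, data$participant_id)
  res <- lapply(parts, process_session, config = config, characters = chars)
  list(estimates = do.call(rbind, c(lapply(res, `[[`, "estimates"),
                                    list(make.row.names = FALSE))),
       snapshot = do.call(rbind, c(lapply(res, `[[`, "snapshot"),
                                   list(make.row.names = FALSE))))
}

# True coefficient value for each fitted model term, from the policy.
truth_for_terms <- function(terms, policy, model) {
  g <- policy$leave; th <- policy$choice
  map <- if (model == "leave") {
    c("(Intercept)" = g[["intercept"]], pe = g[["pe"]], lp = g[["lp"]],
      novelty = g[["novelty"]], time = g[["time"]],
      performance = g[["performance"]],
      "pe:performance" = g[["perf_pe"]], "lp:performance" = g[["perf_lp"]],
      "novelty:performance" = g[["perf_nov"]])
  } else {
    c("(Intercept)" = 0, d_explp = th[["explp"]], d_exppe = th[["exppe"]],
      d_nov = th[["novelty"]])
  }
  out <- map[terms]
  out[is.na(out)] <- 0  # interactions absent from the generator are truly 0
  stats::setNames(out, terms)
}

#' Simulate-estimate-fit parameter-recovery experiment
#'
#' Runs the full pipeline `R` times on fresh cohorts, fits the requested
#' models on the generator's covariate scale (fixed reference scales, so
#' estimates are directly comparable with the generating coefficients), and
#' reports per-coefficient bias and 2-SE coverage.
#'
#' The default design is the correctly-specified best case: homogeneous
#' normative learners (`heterogeneity = 0`), fixed-length sessions, no
#' inclusion filtering, and the generating latent performance supplied to
#' the fits (so recovery isolates the estimation machinery rather than
#' slope-estimation error).
#'
#' @param R Number of replicates (0 gives an empty report).
#' @param n_children,n_trials Cohort size and fixed session length.
#' @param policy An [agent_policy()]; `n_trials_fixed` is overridden by
#'   `n_trials`.
#' @param env An [environment_config()].
#' @param seed Integer seed; replicate `r` uses `seed + r`.
#' @param models Subset of `c("choice", "leave")`.
#' @param use_true_performance Use the generating latent performance as the
#'   performance covariate (default `TRUE`).
#' @param fast Fit with `nAGQ = 0` (default `TRUE` for Monte-Carlo speed).
#' @return List of class `"hs_recovery"`: `draws` (one row per replicate x
#'   model x term: `replicate`, `model`, `term`, `true`, `est`, `se`) and
#'   `summary` (per term: mean estimate, bias, mean SE, 2-SE coverage).
#' @export
recovery_experiment <- function(R, n_children = 100, n_trials = 40,
                                policy = agent_policy(heterogeneity = 0),
                                env = environment_config(), seed = 1L,
                                models = "choice",
                                use_true_performance = TRUE, fast = TRUE) {
  empty <- data.frame(replicate = integer(0), model = character(0),
                      term = character(0), true = numeric(0), est = numeric(0),
                      se = numeric(0))
  if (R < 1) {
    return(structure(list(draws = empty, summary = empty[0, ]),
                     class = "hs_recovery"))
  }
  policy$n_trials_fixed <- n_trials
  sc <- policy$scales
  draws <- vector("list", R)
  for (r in seq_len(R)) {
    sim <- simulate_cohort(n_children, policy, env, seed = seed + r)
    fits <- fit_cohort_models(sim, models = models, scales = sc,
                              use_true_performance = use_true_performance,
                              fast = fast, seed = seed + r)
    fits <- fits[intersect(names(fits), models)]
    rows <- lapply(names(fits), function(m) {
      tab <- fits[[m]]$coefficients
      data.frame(replicate = r, model = m, term = tab$term,
                 true = unname(truth_for_terms(tab$term, policy, m)),
                 est = tab$beta, se = tab$se)
    })
    draws[[r]] <- do.call(rbind, rows)
  }
  draws <- do.call(rbind, draws)
  summ <- do.call(rbind, lapply(split(draws, list(draws$model, draws$term),
                                      drop = TRUE), function(d) {
    data.frame(model = d$model[1], term = d$term[1], true = d$true[1],
               mean_est = mean(d$est), bias = mean(d$est) - d$true[1],
               mean_se = mean(d$se),
               coverage_2se = mean(abs(d$est - d$true) <= 2 * d$se))
  }))
  rownames(summ) <- NULL
  structure(list(draws = draws, summary = summ), class = "hs_recovery")
}

#' @export
print.hs_recovery <- function(x, digits = 3, ...) {
  cat(sprintf("Recovery experiment: %d replicates\n",
              if (nrow(x$draws)) max(x$draws$replicate) else 0L))
  if (nrow(x$summary)) {
    s <- x$summary
    num <- vapply(s, is.numeric, logical(1))
    s[num] <- lapply(s[num], round, digits = digits)
    print(s, row.names = FALSE)
  }
  invisible(x)
}

# Shared simulate->estimate->code->fit path used by recovery_experiment and
# the calibration studies: returns the requested hs_fit objects for one
# simulated cohort.
fit_cohort_models <- function(sim, models = c("choice", "leave"), scales = NULL,
                              use_true_performance = TRUE, fast = TRUE,
                              seed = 1L, inclusion_min = 0,
                              standardize = is.null(scales), history = FALSE) {
  chars <- sort(unique(sim$data$character_id))
  data <- sim$data
  if (inclusion_min > 0) {
    keep <- vapply(split(data, data$participant_id), apply_inclusion,
                   logical(1), characters = chars, min_trials = inclusion_min)
    data <- data[data$participant_id %in% names(keep)[keep], , drop = FALSE]
  }
  est <- estimate_dataset(data, characters = chars)
  coded <- code_behavior(est$estimates)
  perf <- if (use_true_performance) {
    data.frame(participant_id = sim$truth$agents$participant_id,
               slope = sim$truth$agents$perf)
  } else {
    fit_performance_slopes(coded)
  }
  out <- list()
  if ("leave" %in% models) {
    out$leave <- fit_leave_stay(coded, perf, standardize = standardize,
                                scales = scales, fast = fast)
  }
  if ("choice" %in% models) {
    events <- do.call(rbind, lapply(split(coded, coded$participant_id),
                                    extract_choice_events, characters = chars))
    tab <- build_choice_table(events, est$snapshot, perf, seed = seed)
    out$choice <- fit_choice_model(tab, "expectation", standardize = standardize,
                                   scales = scales, fast = fast)
    if (history) {
      out$choice_history <- fit_choice_model(tab, "history",
                                             standardize = standardize,
                                             scales = scales, fast = fast)
    }
  }
  out
}
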