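# Statistical layer: per-child performance slopes, the leave-stay logistic
# mixed model with performance interactions, marginal effects, collinearity
# diagnostics, the exploratory-choice model on differential predictors, and
# expectation-vs-history model comparison. Mixed models are estimated with
# lme4 (Laplace approximation, participant random intercepts); inference is
# Wald z. All fits are wrapped in a light S3 class, "hs_fit".

# ---- hs_fit -----------------------------------------------------------------

# Wrap an (g)lmer / glm fit into the summary object the pipeline serializes.
as_hs_fit <- function(fit, data = NULL, dropped = 0L) {
  sm <- summary(fit)
  co <- sm$coefficients
  is_binomial <- inherits(fit, "glmerMod") || (inherits(fit, "glm") &&
    stats::family(fit)$family == "binomial")
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  zc <- stats::qnorm(0.975)
  beta <- co[, 1]
  se <- co[, 2]
  tab <- data.frame(
    term = rownames(co), beta = beta, se = se,
    z = beta / se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    ci_lo = beta - zc * se, ci_hi = beta + zc * se,
    row.names = NULL
  )
  if (is_binomial) {
    tab$or <- exp(tab$beta)
    tab$or_lo <- exp(tab$ci_lo)
    tab$or_hi <- exp(tab$ci_hi)
  }
  X <- stats::model.matrix(fit)
  vif <- tryCatch(compute_vif(X), error = function(e) NULL)
  conv <- TRUE
  if (inherits(fit, "merMod")) {
    msgs <- fit@optinfo$conv$lme4$messages
    conv <- is.null(msgs) && fit@optinfo$conv$opt == 0
  }
  structure(
    list(coefficients = tab, logLik = as.numeric(ll), k = k, n = n,
         aic = 2 * k - 2 * as.numeric(ll),
         bic = k * log(n) - 2 * as.numeric(ll),
         vif = vif, converged = conv, family = if (is_binomial) "binomial" else "gaussian",
         dropped_rows = dropped, model = fit),
    class = "hs_fit"
  )
}

#' @export
print.hs_fit <- function(x, digits = 3, ...) {
  cat(sprintf("hs_fit (%s): n = %d, k = %d, logLik = %.2f, AIC = %.1f, BIC = %.1f\n",
              x$family, x$n, x$k, x$logLik, x$aic, x$bic))
  if (!x$converged) cat("  (convergence warnings were reported)\n")
  tab <- x$coefficients
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$vif)) {
    cat("max VIF:", round(max(x$vif), 2), "\n")
  }
  invisible(x)
}

#' @export
summary.hs_fit <- function(object, ...) object

#' @export
coef.hs_fit <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

#' @export
vcov.hs_fit <- function(object, ...) as.matrix(stats::vcov(object$model))

# ---- VIF --------------------------------------------------------------------

#' Variance inflation factors from a design matrix
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor
#' `j` on all other predictors. An intercept column is used for centering
#' but not scored. Rank-deficient designs are an error naming the aliased
#' columns rather than a number.
#'
#' @param X Numeric design matrix (a model matrix; an `"(Intercept)"` column
#'   is handled).
#' @return Named vector of VIFs, one per non-intercept column.
#' @export
compute_vif <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  p <- ncol(X)
  if (p == 0L) stop("design matrix has no predictors", call. = FALSE)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1L) {
    aliased <- colnames(cbind(`(Intercept)` = 1, X))[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (p == 1L) return(stats::setNames(1, colnames(X)))
  out <- vapply(seq_len(p), function(j) {
    res <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])$residuals
    sst <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - sum(res^2) / sst
    1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(X))
}

# ---- performance slopes -----------------------------------------------------

#' Per-child learning-performance slopes
#'
#' Fits the linear mixed model `pe ~ within_character_trial` with
#' by-participant random slopes (and intercepts). Each child's performance
#' score is the fixed slope plus their empirical-Bayes deviation; negative
#' slopes index successful learning (PEs shrinking over consecutive trials
#' with the same character). If the mixed fit fails, per-child least-squares
#' slopes are used instead and the `method` field records the fallback.
#'
#' @param estimates data.frame with columns `participant_id`, `pe`,
#'   `within_character_trial` (e.g. from [process_session()] +
#'   [code_behavior()]).
#' @return An object of class `"hs_slopes"`: list with `scores`
#'   (`participant_id`, `slope`), `fixed` (group-level estimate, SE, t),
#'   `model`, `method`.
#' @export
fit_performance_slopes <- function(estimates) {
  d <- estimates[is.finite(estimates$pe), , drop = FALSE]
  d$participant_id <- factor(d$participant_id)
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(pe ~ within_character_trial + (within_character_trial | participant_id),
                 data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    )),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    fe <- lme4::fixef(fit)
    re <- lme4::ranef(fit)$participant_id
    slopes <- fe[["within_character_trial"]] + re[, "within_character_trial"]
    scores <- data.frame(participant_id = rownames(re), slope = slopes,
                         row.names = NULL)
    sm <- summary(fit)$coefficients
    fixed <- c(estimate = unname(fe[["within_character_trial"]]),
               se = sm["within_character_trial", "Std. Error"],
               t = sm["within_character_trial", "t value"])
    method <- "lmm"
  } else {
    per <- split(d, d$participant_id)
    slopes <- vapply(per, function(s) {
      if (nrow(s) < 2L || stats::var(s$within_character_trial) == 0) return(NA_real_)
      stats::coef(stats::lm(pe ~ within_character_trial, data = s))[2]
    }, numeric(1))
    scores <- data.frame(participant_id = names(per), slope = unname(slopes),
                         row.names = NULL)
    fixed <- c(estimate = mean(slopes, na.rm = TRUE),
               se = stats::sd(slopes, na.rm = TRUE) / sqrt(sum(is.finite(slopes))),
               t = NA_real_)
    method <- "per-child OLS fallback"
    fit <- NULL
  }
  structure(list(scores = scores, fixed = fixed, model = fit, method = method),
            class = "hs_slopes")
}

#' @export
print.hs_slopes <- function(x, ...) {
  cat(sprintf("Performance slopes (%s): group slope %.4f (SE %.4f, t %.2f), %d children\n",
              x$method, x$fixed["estimate"], x$fixed["se"], x$fixed["t"],
              nrow(x$scores)))
  invisible(x)
}

#' @export
coef.hs_slopes <- function(object, ...) {
  stats::setNames(object$scores$slope, object$scores$participant_id)
}

# ---- covariate scaling ------------------------------------------------------

# Standardize selected columns: sample z-scores (standardize = TRUE), fixed
# reference scales (named vector `scales`, divide only), or leave raw.
scale_covariates <- function(d, cols, standardize = TRUE, scales = NULL) {
  for (cl in cols) {
    if (!cl %in% names(d)) next
    if (!is.null(scales) && cl %in% names(scales)) {
      d[[cl]] <- d[[cl]] / scales[[cl]]
    } else if (isTRUE(standardize)) {
      d[[cl]] <- zscore_sample(d[[cl]])
    }
  }
  d
}

# ---- leave-stay model -------------------------------------------------------

#' Leave-stay logistic mixed model
#'
#' Predicts, on each trial, whether the child left the current character,
#' from PE, LP and novelty, controlling for time (session trial index), with
#' each child's performance slope entered in interaction with PE, LP and
#' novelty, and participant random intercepts:
#' `leave ~ pe + lp + novelty + time + performance + performance:(pe + lp + novelty) + (1 | participant_id)`.
#' Continuous predictors are z-scored across the analysis sample by default,
#' so coefficients are per-SD and odds ratios comparable. Censored final
#' trials and trials with undefined LP (each character's first trial) are
#' dropped listwise; the count is recorded in the returned object.
#'
#' @param data Coded estimates table: needs `participant_id`, `trial`,
#'   `stay_leave`, `pe`, `lp`, `novelty`.
#' @param performance An `"hs_slopes"` object or a data.frame
#'   (`participant_id`, `slope`).
#' @param standardize z-score continuous predictors (default `TRUE`).
#' @param scales Optional named vector of fixed reference scales that
#'   override z-scoring for the named covariates (divide only; used by
#'   recovery experiments so fitted coefficients live on the generator's
#'   scale).
#' @param include_performance_main Include performance's main effect
#'   alongside its interactions (default `TRUE`).
#' @param fast Use `nAGQ = 0` for speed in Monte-Carlo loops (default
#'   `FALSE`, Laplace).
#' @return An `"hs_fit"` object.
#' @export
fit_leave_stay <- function(data, performance, standardize = TRUE, scales = NULL,
                           include_performance_main = TRUE, fast = FALSE) {
  if (inherits(performance, "hs_slopes")) performance <- performance$scores
  d <- merge(data, performance, by = "participant_id")
  d$time <- d$trial
  d$performance <- d$slope
  d$leave <- ifelse(d$stay_leave == "leave", 1L,
                    ifelse(d$stay_leave == "stay", 0L, NA_integer_))
  n0 <- nrow(d)
  d <- d[!is.na(d$leave) & is.finite(d$lp) & is.finite(d$pe) &
           is.finite(d$novelty) & is.finite(d$performance), , drop = FALSE]
  dropped <- n0 - nrow(d)
  if (nrow(d) == 0L) stop("no usable leave-stay rows after listwise deletion",
                          call. = FALSE)
  d <- scale_covariates(d, c("pe", "lp", "novelty", "time", "performance"),
                        standardize, scales)
  d$participant_id <- factor(d$participant_id)
  rhs <- "pe + lp + novelty + time"
  if (include_performance_main) rhs <- paste(rhs, "+ performance")
  rhs <- paste(rhs, "+ pe:performance + lp:performance + novelty:performance",
               "+ (1 | participant_id)")
  form <- stats::as.formula(paste("leave ~", rhs))
  fit <- suppressWarnings(suppressMessages(
    lme4::glmer(form, data = d, family = stats::binomial(),
                nAGQ = if (fast) 0L else 1L,
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             calc.derivs = !fast))
  ))
  out <- as_hs_fit(fit, dropped = dropped)
  out$data <- d
  out
}

# ---- marginal effects -------------------------------------------------------

#' Marginal effects of a predictor at levels of a moderator
#'
#' For a model containing `term` and `term:moderator`, the slope of `term`
#' on the link scale at moderator level `m` is `beta_term + m * beta_int`,
#' with delta-method standard errors
#' `sqrt(V[term,term] + m^2 V[int,int] + 2 m V[term,int])`. Default levels
#' are plus/minus 1 SD of the (standardized) moderator.
#'
#' @param fit An `"hs_fit"` from [fit_leave_stay()].
#' @param terms Predictors whose conditional slopes are wanted (default
#'   novelty and LP, the effects of interest).
#' @param moderator Moderating variable (default `"performance"`).
#' @param at Numeric moderator levels (default `c(-1, 1)`).
#' @return data.frame with `term`, `at`, `slope`, `se`, `z`, `p`, `ci_lo`,
#'   `ci_hi`.
#' @export
marginal_effects <- function(fit, terms = c("novelty", "lp"),
                             moderator = "performance", at = c(-1, 1)) {
  beta <- coef(fit)
  V <- vcov(fit)
  zc <- stats::qnorm(0.975)
  rows <- list()
  for (tm in terms) {
    int <- intersect(c(paste0(tm, ":", moderator), paste0(moderator, ":", tm)),
                     names(beta))
    if (!tm %in% names(beta) || length(int) != 1L) {
      stop(sprintf("model does not contain '%s' moderated by '%s'", tm, moderator),
           call. = FALSE)
    }
    for (m in at) {
      slope <- beta[[tm]] + m * beta[[int]]
      se <- sqrt(V[tm, tm] + m^2 * V[int, int] + 2 * m * V[tm, int])
      rows[[length(rows) + 1L]] <- data.frame(
        term = tm, at = m, slope = slope, se = se, z = slope / se,
        p = 2 * stats::pnorm(-abs(slope / se)),
        ci_lo = slope - zc * se, ci_hi = slope + zc * se)
    }
  }
  do.call(rbind, rows)
}

# ---- choice model -----------------------------------------------------------

#' Build the exploratory-choice table with differential predictors
#'
#' For every leave event, the two available characters are put in a random
#' (seeded) order; the response is whether option 1 was chosen, and every
#' predictor is the option-1 value minus the option-2 value: differential
#' expected LP, differential expected PE, differential novelty, plus the
#' history analogues (differential LP and PE actually experienced last).
#' This framing makes the fit invariant (up to sign) to how options are
#' labelled. Events where the chosen character is visited for the first
#' time, or where either option has not been visited, are excluded
#' (expectations are undefined there).
#'
#' @param events Choice events from [extract_choice_events()] (all
#'   participants row-bound).
#' @param snapshot Per-trial all-character state snapshot from
#'   [process_session()] (all participants row-bound).
#' @param performance An `"hs_slopes"` object or data.frame
#'   (`participant_id`, `slope`).
#' @param seed Integer seed for the option-order randomization.
#' @return data.frame with one row per usable event: `participant_id`,
#'   `at_trial`, `time`, `chose1`, `d_explp`, `d_exppe`, `d_nov`, `d_lp`,
#'   `d_pe`, `performance`.
#' @export
build_choice_table <- function(events, snapshot, performance, seed = 1L) {
  if (inherits(performance, "hs_slopes")) performance <- performance$scores
  if (nrow(events) == 0L) {
    return(data.frame(participant_id = character(0), at_trial = integer(0),
                      time = integer(0), chose1 = integer(0),
                      d_explp = numeric(0), d_exppe = numeric(0),
                      d_nov = numeric(0), d_lp = numeric(0), d_pe = numeric(0),
                      performance = numeric(0)))
  }
  set_seed_if(seed)
  flip <- stats::runif(nrow(events)) < 0.5
  key <- function(p, t, c) paste(p, t, c, sep = "\r")
  snap_key <- key(snapshot$participant_id, snapshot$trial, snapshot$character_id)
  # option 1 = chosen unless flipped
  opt1 <- ifelse(flip, events$alternative_character, events$chosen_character)
  opt2 <- ifelse(flip, events$chosen_character, events$alternative_character)
  i1 <- match(key(events$participant_id, events$at_trial, opt1), snap_key)
  i2 <- match(key(events$participant_id, events$at_trial, opt2), snap_key)
  i0 <- match(key(events$participant_id, events$at_trial, events$from_character),
              snap_key)
  ok <- !events$is_first_visit_to_chosen & !is.na(i1) & !is.na(i2) &
    snapshot$visited[i1] & snapshot$visited[i2]
  # novelty z-scores within the three characters' pick counts at the event
  cnt <- cbind(snapshot$pick_count[i1], snapshot$pick_count[i2],
               snapshot$pick_count[i0])
  mu <- rowMeans(-cnt)
  sdev <- sqrt(rowMeans((-cnt - mu)^2))
  nov1 <- ifelse(sdev < 1e-12, 0, (-cnt[, 1] - mu) / sdev)
  nov2 <- ifelse(sdev < 1e-12, 0, (-cnt[, 2] - mu) / sdev)
  tab <- data.frame(
    participant_id = events$participant_id, at_trial = events$at_trial,
    time = events$at_trial, chose1 = as.integer(!flip),
    d_explp = snapshot$expected_lp[i1] - snapshot$expected_lp[i2],
    d_exppe = snapshot$expected_pe[i1] - snapshot$expected_pe[i2],
    d_nov = nov1 - nov2,
    d_lp = snapshot$last_lp[i1] - snapshot$last_lp[i2],
    d_pe = snapshot$last_pe[i1] - snapshot$last_pe[i2])[which(ok), , drop = FALSE]
  rownames(tab) <- NULL
  perf <- stats::setNames(performance$slope, performance$participant_id)
  tab$performance <- unname(perf[as.character(tab$participant_id)])
  tab
}

#' Exploratory-choice logistic mixed model on differential predictors
#'
#' Models which of the two available characters was chosen after a leave,
#' as a function of the differential (option 1 minus option 2) predictors.
#' The expectation variant uses differential expected LP and expected PE;
#' the history variant replaces them with the LP and PE actually
#' experienced. Both include differential novelty, interactions of every
#' differential predictor with time and with performance, and participant
#' random intercepts.
#'
#' @param tab Choice table from [build_choice_table()].
#' @param type `"expectation"` (default) or `"history"`.
#' @param standardize,scales,fast As in [fit_leave_stay()].
#' @param min_events Minimum usable events required (default 20).
#' @return An `"hs_fit"` object.
#' @export
fit_choice_model <- function(tab, type = c("expectation", "history"),
                             standardize = TRUE, scales = NULL, fast = FALSE,
                             min_events = 20) {
  type <- match.arg(type)
  vars <- if (type == "expectation") c("d_explp", "d_exppe") else c("d_lp", "d_pe")
  use <- c(vars, "d_nov", "time", "performance")
  # listwise deletion on the union of both variants' predictors, so the
  # expectation and history models are fitted to the same response vector
  all_vars <- c("d_explp", "d_exppe", "d_lp", "d_pe", "d_nov", "time", "performance")
  d <- tab[stats::complete.cases(tab[, all_vars]), , drop = FALSE]
  if (nrow(d) < min_events) {
    stop(sprintf("only %d usable choice events (minimum %d)", nrow(d), min_events),
         call. = FALSE)
  }
  d <- scale_covariates(d, use, standardize, scales)
  d$participant_id <- factor(d$participant_id)
  main <- c(vars, "d_nov")
  rhs <- paste(c(main,
                 paste0(vars, ":time"),
                 paste0(main, ":performance")), collapse = " + ")
  form <- stats::as.formula(paste("chose1 ~", rhs, "+ (1 | participant_id)"))
  fit <- suppressWarnings(suppressMessages(
    lme4::glmer(form, data = d, family = stats::binomial(),
                nAGQ = if (fast) 0L else 1L,
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             calc.derivs = !fast))
  ))
  out <- as_hs_fit(fit, dropped = nrow(tab) - nrow(d))
  out$type <- type
  out$data <- d
  out
}

#' Compare two fitted choice models by information criteria
#'
#' @param fit_expect,fit_history `"hs_fit"` objects fitted to the same
#'   response vector (equal `n` is enforced).
#' @return data.frame with one row per model (`model`, `logLik`, `k`,
#'   `aic`, `bic`) and attribute `preferred` naming the lower-AIC model.
#' @export
compare_models <- function(fit_expect, fit_history) {
  if (fit_expect$n != fit_history$n) {
    stop("models were fitted to different numbers of observations", call. = FALSE)
  }
  out <- data.frame(
    model = c("expectation", "history"),
    logLik = c(fit_expect$logLik, fit_history$logLik),
    k = c(fit_expect$k, fit_history$k),
    aic = c(fit_expect$aic, fit_history$aic),
    bic = c(fit_expect$bic, fit_history$bic))
  attr(out, "preferred") <- out$model[which.min(out$aic)]
  out
}
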