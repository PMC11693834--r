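test_that("VIF matches the closed form and rejects degenerate designs", {
  set.seed(11)
  # exactly orthogonal predictors via QR
  Q <- qr.Q(qr(matrix(rnorm(300), 100, 3)))
  Q <- scale(Q, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Q))
  expect_equal(unname(compute_vif(Q)), rep(1, 3), tolerance = 1e-8)

  # two predictors with sample correlation exactly 0.8
  u <- Q[, 1] / sqrt(sum(Q[, 1]^2))
  v <- Q[, 2] / sqrt(sum(Q[, 2]^2))
  X <- cbind(x1 = u, x2 = 0.8 * u + 0.6 * v)
  expect_equal(unname(compute_vif(X)), rep(1 / (1 - 0.64), 2), tolerance = 1e-8)

  expect_error(compute_vif(cbind(a = u, b = u)), "collinear")
})

test_that("VIF agrees with the standard regression-package implementation", {
  skip_if_not_installed("car")
  set.seed(12)
  n <- 200
  x1 <- rnorm(n); x2 <- 0.6 * x1 + rnorm(n); x3 <- rnorm(n)
  y <- rnorm(n)
  fit <- lm(y ~ x1 + x2 + x3)
  expect_equal(unname(compute_vif(model.matrix(fit))),
               unname(car::vif(fit)), tolerance = 1e-8)
})

test_that("information criteria identities hold and match stats::AIC", {
  sim <- simulate_cohort(15, agent_policy(n_trials_fixed = 35, heterogeneity = 0),
                         seed = 21)
  fits <- hideseek:::fit_cohort_models(sim, models = c("leave", "choice"),
                                       scales = hs_reference_scales(),
                                       seed = 21, fast = FALSE, history = TRUE)
  for (f in fits) {
    expect_equal(f$aic, 2 * f$k - 2 * f$logLik)
    expect_equal(f$bic, f$k * log(f$n) - 2 * f$logLik)
    expect_equal(f$aic, AIC(f$model))
    expect_equal(f$bic, BIC(f$model))
    # odds ratios are exactly exp(beta); OR CI excludes 1 iff beta CI excludes 0
    expect_equal(f$coefficients$or, exp(f$coefficients$beta))
    expect_identical(f$coefficients$or_lo > 1 | f$coefficients$or_hi < 1,
                     f$coefficients$ci_lo > 0 | f$coefficients$ci_hi < 0)
  }
  cmp <- compare_models(fits$choice, fits$choice_history)
  expect_equal(cmp$aic, 2 * cmp$k - 2 * cmp$logLik)
  expect_identical(compare_models(fits$choice, fits$choice)$aic[1],
                   compare_models(fits$choice, fits$choice)$aic[2])
  small <- fits$choice; small$n <- small$n - 1L
  expect_error(compare_models(fits$choice, small), "different numbers")
})

test_that("performance slopes recover known per-child learning rates", {
  # constructed cohort: half improve at -0.01 PE/trial, half are flat
  set.seed(13)
  nkid <- 40; ntr <- 30
  rows <- lapply(seq_len(nkid), function(i) {
    slope <- if (i <= nkid / 2) -0.01 else 0
    data.frame(participant_id = sprintf("k%02d", i),
               pe = pmax(0, 0.4 + slope * (1:ntr) + rnorm(ntr, 0, 0.03)),
               within_character_trial = 1:ntr)
  })
  est <- do.call(rbind, rows)
  sl <- fit_performance_slopes(est)
  expect_equal(nrow(sl$scores), nkid)
  learners <- sl$scores$slope[order(sl$scores$participant_id)][1:(nkid / 2)]
  flats <- sl$scores$slope[order(sl$scores$participant_id)][(nkid / 2 + 1):nkid]
  se <- sl$fixed[["se"]]
  expect_lt(abs(mean(learners) - (-0.01)), 2 * se + 0.002)
  expect_lt(abs(mean(flats) - 0), 2 * se + 0.002)
  expect_lt(mean(learners), mean(flats))
  # sign convention: halving PE over a run gives a negative slope
  expect_true(all(learners < 0))
})

test_that("marginal effects reduce to coefficient arithmetic and bootstrap CIs", {
  skip_if_not_installed("MASS")
  sim <- simulate_cohort(30, agent_policy(n_trials_fixed = 35), seed = 22)
  fits <- hideseek:::fit_cohort_models(sim, models = "leave",
                                       scales = hs_reference_scales(),
                                       seed = 22, fast = FALSE)
  fit <- fits$leave
  beta <- coef(fit)
  me0 <- marginal_effects(fit, terms = "novelty", at = 0)
  expect_equal(me0$slope, unname(beta["novelty"]))
  me1 <- marginal_effects(fit, terms = "novelty", at = 1)
  expect_equal(me1$slope, unname(beta["novelty"] + beta["novelty:performance"]))

  # delta-method CI vs parametric bootstrap from the coefficient sampling dist
  set.seed(23)
  draws <- MASS::mvrnorm(2000, beta, vcov(fit))
  for (m in c(-1, 1)) {
    slopes <- draws[, "novelty"] + m * draws[, "novelty:performance"]
    boot_w <- diff(quantile(slopes, c(0.025, 0.975)))
    me <- marginal_effects(fit, terms = "novelty", at = m)
    expect_lt(abs((me$ci_hi - me$ci_lo) - boot_w) / boot_w, 0.05)
  }
  expect_error(marginal_effects(fit, terms = "nonexistent"), "does not contain")
})

test_that("choice-model fits are invariant to option relabelling", {
  sim <- simulate_cohort(40, agent_policy(n_trials_fixed = 35, heterogeneity = 0),
                         seed = 24)
  est <- estimate_dataset(sim$data)
  coded <- code_behavior(est$estimates)
  chars <- sort(unique(coded$character_id))
  perf <- data.frame(participant_id = sim$truth$agents$participant_id,
                     slope = sim$truth$agents$perf)
  events <- do.call(rbind, lapply(split(coded, coded$participant_id),
                                  extract_choice_events, characters = chars))
  tab <- build_choice_table(events, est$snapshot, perf, seed = 25)
  flipped <- tab
  flipped$chose1 <- 1L - flipped$chose1
  for (cl in c("d_explp", "d_exppe", "d_nov", "d_lp", "d_pe")) {
    flipped[[cl]] <- -flipped[[cl]]
  }
  sc <- hs_reference_scales()
  f1 <- fit_choice_model(tab, scales = sc, standardize = FALSE, fast = FALSE)
  f2 <- fit_choice_model(flipped, scales = sc, standardize = FALSE, fast = FALSE)
  b1 <- coef(f1); b2 <- coef(f2)
  diffs <- names(b1)[names(b1) != "(Intercept)"]
  expect_equal(unname(b1[diffs]), unname(b2[diffs]), tolerance = 1e-3)
  expect_equal(unname(b1["(Intercept)"]), -unname(b2["(Intercept)"]),
               tolerance = 1e-3)
})

test_that("a pure expected-LP chooser is recovered as such", {
  # agent choosing by expected LP alone; expected-PE effect should be null
  pol <- agent_policy(choice = c(explp = 0.9, exppe = 0, novelty = 0),
                      heterogeneity = 0, n_trials_fixed = 40)
  ests <- ses <- matrix(NA_real_, 5, 2)
  for (r in 1:5) {
    sim <- simulate_cohort(60, pol, seed = 500 + r)
    fits <- hideseek:::fit_cohort_models(sim, models = "choice",
                                         scales = hs_reference_scales(),
                                         seed = 500 + r)
    tabc <- fits$choice$coefficients
    ests[r, ] <- tabc$beta[match(c("d_explp", "d_exppe"), tabc$term)]
    ses[r, ] <- tabc$se[match(c("d_explp", "d_exppe"), tabc$term)]
  }
  expect_gt(mean(ests[, 1]), 0)
  expect_lt(abs(mean(ests[, 1]) - 0.9), 2 * mean(ses[, 1]) / sqrt(5))
  expect_lt(abs(mean(ests[, 2])), 2 * mean(ses[, 2]) / sqrt(5))
})

test_that("leave-stay fit recovers a generating performance-novelty interaction", {
  pol <- agent_policy(leave = c(perf_lp = 0, perf_nov = 0.7),
                      choice = c(explp = 0, exppe = 0, novelty = 0.3),
                      heterogeneity = 0, n_trials_fixed = 40)
  ests <- ses <- numeric(4)
  for (r in 1:4) {
    sim <- simulate_cohort(100, pol, seed = 700 + r)
    fits <- hideseek:::fit_cohort_models(sim, models = "leave",
                                         scales = hs_reference_scales(),
                                         seed = 700 + r)
    tabl <- fits$leave$coefficients
    i <- match("novelty:performance", tabl$term)
    ests[r] <- tabl$beta[i]; ses[r] <- tabl$se[i]
  }
  expect_lt(abs(mean(ests) - 0.7), 0.1)
})
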