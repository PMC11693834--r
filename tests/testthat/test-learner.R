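test_that("prediction error is definitional signed/unsigned arithmetic", {
  expect_equal(prediction_error(0.30, 0.55), list(delta = 0.25, pe = 0.25))
  expect_equal(prediction_error(0.5, 0.5), list(delta = 0, pe = 0))
  expect_equal(prediction_error(0.9, 0.1), list(delta = -0.8, pe = 0.8))
  expect_error(prediction_error(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("learning progress is the decrease in PE, missing without history", {
  expect_equal(learning_progress(0.40, 0.15), 0.25)
  expect_equal(learning_progress(0.10, 0.30), -0.20)
  expect_equal(learning_progress(0.27, 0.27), 0)
  expect_true(is.na(learning_progress(NA_real_, 0.1)))
})

test_that("changepoint probability matches an independent Bayes computation", {
  expect_equal(changepoint_probability(0.5, 0.1, 0), 0)
  # symmetric evidence: Gaussian density equals the uniform density
  sd_sym <- 1 / sqrt(2 * pi)
  expect_equal(changepoint_probability(0, sd_sym, 0.5, 1), 0.5)

  set.seed(7)
  for (i in 1:200) {
    d <- runif(1, -1, 1); s <- runif(1, 0.01, 0.3); h <- runif(1, 0.01, 0.99)
    expect_lt(abs(changepoint_probability(d, s, h, 1) - oracle_omega(d, s, h, 1)),
              1e-10)
  }
  expect_error(changepoint_probability(0.1, 0, 0.1), "positive")
})

test_that("learning rate combines omega and uncertainty and stays bounded", {
  expect_equal(learning_rate(1, 0.3), 1)
  expect_equal(learning_rate(0, 0), 0)
  expect_equal(learning_rate(0.2, 0.5), 0.6)
  set.seed(8)
  om <- runif(200); ta <- runif(200)
  al <- learning_rate(om, ta)
  expect_true(all(al >= 0 & al <= 1))
  # monotone nondecreasing in both arguments
  expect_true(all(learning_rate(om + (1 - om) * 0.1, ta) >= al))
  expect_true(all(learning_rate(om, ta + (1 - ta) * 0.1) >= al))
})

test_that("belief update is the delta rule with projection", {
  expect_equal(update_belief(0.4, 0.2, 1), 0.6)
  expect_equal(update_belief(0.4, 0.2, 0), 0.4)
  expect_equal(update_belief(0.4, 0.2, 0.5), 0.5)
  expect_equal(update_belief(0.95, 0.2, 1), 1)
})

test_that("uncertainty resets after certain changepoints and shrinks when stable", {
  expect_equal(update_uncertainty(0.2, 1, 0.4, 0.08, tau_reset = 0.5), 0.5)
  expect_equal(update_uncertainty(0.2, 1, 0.4, 0.08, tau_reset = 0.7), 0.7)
  tau <- 0.9
  taus <- numeric(30)
  for (i in 1:30) {
    tau <- update_uncertainty(tau, 0, 0, 0.08)
    taus[i] <- tau
  }
  expect_true(all(diff(taus) < 0))
  expect_lt(taus[30], 0.05)
  # bounded on random reachable states
  set.seed(9)
  for (i in 1:200) {
    t2 <- update_uncertainty(runif(1), runif(1), runif(1, -1, 1), runif(1, 0.01, 0.3))
    expect_true(t2 >= 0 && t2 < 1)
  }
})

test_that("relative uncertainty tracks a full run-length filter", {
  # reduced-model approximation quality on moderately volatile sequences
  env <- uniform_env(0.08, 0.15)
  cfg <- learner_config(hazard_belief = 0.15, noise_sd = 0.08,
                        noise_est = "fixed")
  for (s in 1:3) {
    seqs <- generate_outcome_sequence(env, "1", 200, seed = 100 + s)
    red <- run_filter(seqs$location, cfg)
    orc <- oracle_runlength_tau(seqs$location, 0.15, 0.08)
    expect_lt(mean(abs(red$tau - orc)), 0.1)
  }
})

test_that("expected PE is the folded-normal mean of the predictive spread", {
  # tau -> 0 leaves only the noise; closed form sqrt(2/pi) * sigma
  expect_equal(expected_pe(0, 0.1), sqrt(2 / pi) * 0.1)
  expect_equal(expected_pe(0.75, 0.1), sqrt(2 / pi) * 0.2)  # sigma_tot doubles
  set.seed(10)
  mc <- oracle_mc_expected_pe(0.1, n = 1e5)
  expect_lt(abs(expected_pe(0, 0.1) - mc) / mc, 0.01)
})

test_that("expected LP is smoothed PE minus expected PE", {
  expect_equal(expected_lp(0.0798, 0.0798), 0)
  expect_equal(expected_lp(0.3, 0.1), 0.2)
})

test_that("novelty is a standardized, strictly decreasing function of picks", {
  nov <- novelty(c(0, 5, 10), c(0, 5, 10))
  expect_equal(nov, c(1.224745, 0, -1.224745), tolerance = 1e-6)
  expect_true(all(diff(nov) < 0))
  expect_equal(novelty(c(4, 4, 4), c(4, 4, 4)), c(0, 0, 0))
})

test_that("process_session bookkeeping: LP missingness and telescoping", {
  n <- 12
  sess <- make_session(rep("A", n))
  out <- process_session(sess)
  est <- out$estimates
  expect_equal(nrow(est), n)
  expect_true(is.na(est$lp[1]))
  expect_true(all(!is.na(est$lp[-1])))
  # telescoping: sum of LP over a single-character run = pe_first - pe_last
  expect_equal(sum(est$lp[-1]), est$pe[1] - est$pe[n])
  expect_equal(est$within_character_trial, seq_len(n))
})

test_that("per-character state persists across leave/return visits", {
  sess <- make_session(c("A", "A", "B", "A"))
  out <- process_session(sess)$estimates
  # the return to A continues A's history: LP defined, against trial 2's PE
  expect_true(is.na(out$lp[3]))  # first B trial
  expect_equal(out$lp[4], out$pe[2] - out$pe[4])
  # pick counts track selections, novelty decreasing in them
  expect_equal(out$pick_count, c(1L, 2L, 1L, 3L))
  expect_error(process_session(sess[c(1, 1, 2), ]), "strictly increasing")
})

test_that("adaptive learning rate beats fixed rates on volatile sequences", {
  env <- uniform_env(0.08, 0.15)
  cfg <- learner_config(hazard_belief = 0.15, noise_sd = 0.08,
                        noise_est = "fixed")
  pe_adapt <- pe_f <- c()
  fixed <- c(0.05, 0.3, 1.0)
  pe_fixed <- matrix(NA_real_, 60, length(fixed))
  for (s in 1:60) {
    seqs <- generate_outcome_sequence(env, "1", 120, seed = 400 + s)
    pe_adapt[s] <- mean(run_filter(seqs$location, cfg)$pe)
    for (j in seq_along(fixed)) {
      pe_fixed[s, j] <- mean(run_filter(seqs$location, cfg, alpha_fixed = fixed[j])$pe)
    }
  }
  for (j in seq_along(fixed)) {
    # equality within Monte-Carlo error is allowed; superiority expected
    se <- sd(pe_adapt - pe_fixed[, j]) / sqrt(length(pe_adapt))
    expect_lt(mean(pe_adapt) - mean(pe_fixed[, j]), 2 * se)
  }
})

test_that("omega, alpha, tau stay in [0,1] along whole simulated sessions", {
  sim <- simulate_child(agent_policy(n_trials_fixed = 60), seed = 17)
  est <- process_session(sim$log)$estimates
  expect_true(all(est$omega >= 0 & est$omega <= 1))
  expect_true(all(est$alpha >= 0 & est$alpha <= 1))
  expect_true(all(est$tau >= 0 & est$tau < 1))
  expect_true(all(est$pe >= 0))
})

test_that("online noise estimation converges toward each pattern's noise", {
  env <- environment_config()
  cfg <- learner_config()
  for (ch in c("1", "2")) {
    p <- env$patterns[[env$character_assignment[[ch]]]]
    seqs <- generate_outcome_sequence(env, ch, 300, seed = 31)
    sess <- data.frame(participant_id = "p", trial = 1:300, character_id = ch,
                       predicted_loc = run_filter(seqs$location, cfg)$predicted,
                       actual_loc = seqs$location)
    est <- process_session(sess, cfg)$estimates
    late <- mean(est$expected_pe[250:300])
    # expected PE should sit near sqrt(2/pi) * sigma_tot for the true noise
    target <- sqrt(2 / pi) * p$noise_sd
    expect_lt(abs(late - target) / target, 0.5)
  }
})
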