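test_that("cohort simulation is deterministic given the seed", {
  a <- simulate_cohort(6, agent_policy(), seed = 42)
  b <- simulate_cohort(6, agent_policy(), seed = 42)
  expect_identical(a$data, b$data)
  expect_identical(a$truth$agents, b$truth$agents)
  c <- simulate_cohort(6, agent_policy(), seed = 43)
  expect_false(identical(a$data, c$data))
})

test_that("synthetic logs satisfy the shared trial-log schema", {
  sim <- simulate_cohort(8, agent_policy(), seed = 44)
  expect_silent(validate_trial_log(sim$data))
  expect_identical(names(sim$data),
                   c("participant_id", "trial", "character_id",
                     "predicted_loc", "actual_loc"))
})

test_that("policy limits: an extreme stay policy never switches", {
  pol <- agent_policy(leave = c(intercept = -50, perf_lp = 0, perf_nov = 0),
                      intercept_sd = 0, n_trials_fixed = 40)
  sim <- simulate_child(pol, seed = 45)
  expect_equal(length(unique(sim$log$character_id)), 1L)
})

test_that("policy limits: a pure novelty chooser picks the less-visited option", {
  pol <- agent_policy(leave = c(intercept = 2, perf_lp = 0, perf_nov = 0),
                      choice = c(explp = 0, exppe = 0, novelty = 60),
                      intercept_sd = 0, heterogeneity = 0, n_trials_fixed = 40)
  sim <- simulate_child(pol, seed = 46)
  est <- process_session(sim$log)
  ev <- extract_choice_events(sim$log, characters = c("1", "2", "3"))
  snap <- est$snapshot
  for (i in seq_len(nrow(ev))) {
    sn <- snap[snap$trial == ev$at_trial[i], ]
    cnt <- setNames(sn$pick_count, sn$character_id)
    expect_lte(cnt[[ev$chosen_character[i]]],
               cnt[[ev$alternative_character[i]]])
  }
})

test_that("default sessions reproduce the observed session-length range", {
  lens <- numeric(300)
  sim <- simulate_cohort(300, agent_policy(), seed = 47)
  lens <- tapply(sim$data$trial, sim$data$participant_id, max)
  expect_lt(abs(mean(lens) - 27.8) / 27.8, 0.2)
  expect_true(all(lens <= 150))
})

test_that("engineered low-exposure children are exactly the ones excluded", {
  sim <- simulate_cohort(12, agent_policy(n_trials_fixed = 40, heterogeneity = 0),
                         seed = 48)
  data <- sim$data
  # force children 1-4 to have fewer than 10 trials with character "2"
  engineered <- sprintf("c%03d", 1:4)
  keep <- !(data$participant_id %in% engineered & data$character_id == "2" &
              ave(seq_len(nrow(data)),
                  paste(data$participant_id, data$character_id),
                  FUN = seq_along) > 5)
  data <- data[keep, ]
  data$trial <- ave(data$trial, data$participant_id, FUN = seq_along)
  chars <- c("1", "2", "3")
  flags <- vapply(split(data, data$participant_id), apply_inclusion,
                  logical(1), characters = chars, min_trials = 10)
  others <- setdiff(names(flags), engineered)
  # engineered children must fail; others fail only if genuinely short
  expect_true(all(!flags[engineered]))
  brute <- vapply(split(data, data$participant_id), function(s)
    all(table(factor(s$character_id, levels = chars)) >= 10), logical(1))
  expect_identical(flags, brute)
})

test_that("recovery experiment handles zero replicates and reports shape", {
  empty <- recovery_experiment(0)
  expect_s3_class(empty, "hs_recovery")
  expect_equal(nrow(empty$draws), 0L)

  rec <- recovery_experiment(2, n_children = 25, n_trials = 35, seed = 49)
  expect_equal(sort(unique(rec$draws$replicate)), 1:2)
  expect_true(all(c("term", "true", "est", "se") %in% names(rec$draws)))
  expect_equal(rec$summary$true[rec$summary$term == "d_explp"], 0.35)
  expect_equal(rec$summary$true[rec$summary$term == "d_nov"], 0.30)
  expect_true(all(is.finite(rec$draws$se)))
})

test_that("heterogeneity produces a continuum of learning performance", {
  sim <- simulate_cohort(120, agent_policy(n_trials_fixed = 35), seed = 50)
  est <- estimate_dataset(sim$data)
  coded <- code_behavior(est$estimates)
  # impaired agents (higher latent score) make larger errors ...
  mpe <- tapply(coded$pe, coded$participant_id, mean)
  merged <- merge(data.frame(participant_id = names(mpe),
                             mpe = as.numeric(mpe)),
                  sim$truth$agents, by = "participant_id")
  expect_gt(cor(merged$mpe, merged$perf), 0.2)
  # ... and their empirical-Bayes PE slopes shift in the same direction,
  # though short within-character runs identify slopes only weakly
  sl <- fit_performance_slopes(coded)
  merged2 <- merge(sl$scores, sim$truth$agents, by = "participant_id")
  expect_gt(cor(merged2$slope, merged2$perf), 0.1)
  expect_gt(sd(merged2$slope), 0)
})
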