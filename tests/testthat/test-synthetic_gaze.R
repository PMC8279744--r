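params <- generator_params(n_participants = 6)

test_that("preference probabilities equal baseline before any onset", {
  cell <- list(occupation_stereotype = "female",
               action_stereotype = "female")
  p <- preference_probabilities(-1200 - 1000, cell, params)
  expect_equal(as.numeric(p), as.numeric(params$baseline))
  # and for cells with no anticipation, at any pre-noun time
  p2 <- preference_probabilities(-50, list(occupation_stereotype = "male",
                                           action_stereotype = "neutral"),
                                 params)
  expect_equal(as.numeric(p2), as.numeric(params$baseline))
})

test_that("preference probabilities approach the asymptote and stay a
           simplex", {
  cell <- list(occupation_stereotype = "female",
               action_stereotype = "female")
  p <- preference_probabilities(c(-1500, -1100, -900, 0, 1e6), cell, params)
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  expect_true(all(p >= 0))
  # monotone ramp toward the asymptote after onset
  expect_true(all(diff(p[, "female"]) >= 0))
  expect_equal(unname(p[nrow(p), "female"]), 0.65, tolerance = 1e-6)
})

test_that("probabilities are mirror symmetric under a full gender swap", {
  p_f <- preference_probabilities(
    c(-1000, -200, 500), list(occupation_stereotype = "female",
                              action_stereotype = "female"),
    params, agent_gender = "female")
  p_m <- preference_probabilities(
    c(-1000, -200, 500), list(occupation_stereotype = "female",
                              action_stereotype = "female"),
    params, agent_gender = "male")
  # swapping the agent swaps the female/male columns of the referential
  # part; anticipation target stays, so compare a no-anticipation cell
  q_f <- preference_probabilities(
    c(300, 800), list(occupation_stereotype = "male",
                      action_stereotype = "neutral"),
    params, agent_gender = "female")
  q_m <- preference_probabilities(
    c(300, 800), list(occupation_stereotype = "male",
                      action_stereotype = "neutral"),
    params, agent_gender = "male")
  expect_equal(q_f[, "female"], q_m[, "male"])
  expect_equal(q_f[, "male"], q_m[, "female"])
  expect_equal(q_f[, "object1"], q_m[, "object1"])
  expect_error(preference_probabilities(0, list(
    occupation_stereotype = "purple", action_stereotype = "female"),
    params), "unknown design cell")
})

test_that("deterministic trial simulation equals a step-by-step oracle", {
  tr <- list(noun_onset = 600, occupation_stereotype = "female",
             action_stereotype = "female", agent_gender = "female")
  p250 <- generator_params(n_participants = 1, dwell_mean = 250)
  fx <- simulate_trial(tr, p250, deterministic = TRUE)
  # oracle: step 250 ms from 0, pick the modal AOI at each step
  t_end <- 600 + p250$post_noun_ms
  starts <- seq(0, t_end - 1e-9, by = 250)
  exp_aoi <- vapply(starts, function(s) {
    pr <- preference_probabilities(s - 600, tr, p250,
                                   agent_gender = "female")
    colnames(pr)[which.max(pr)]
  }, character(1))
  expect_equal(fx$start, round(starts))
  expect_equal(fx$end, c(round(starts[-1]), round(t_end)))
  expect_equal(fx$aoi, exp_aoi)
})

test_that("stochastic fixations are sorted, non-overlapping, positive", {
  tr <- list(noun_onset = 3000, occupation_stereotype = "male",
             action_stereotype = "female", agent_gender = "male")
  for (s in 1:5) {
    set.seed(s)
    fx <- simulate_trial(tr, params)
    expect_true(all(fx$end > fx$start))
    expect_true(!is.unsorted(fx$start))
    expect_true(all(fx$start[-1] >= fx$end[-nrow(fx)]))
  }
})

test_that("AOI choice frequencies match the stated multinomial", {
  cell <- list(occupation_stereotype = "female",
               action_stereotype = "female")
  pr <- preference_probabilities(-300, cell, params,
                                 agent_gender = "female")
  set.seed(42)
  draws <- gazecluster:::sample_rows(pr[rep(1, 10000), ])
  freq <- as.numeric(table(factor(draws, levels = colnames(pr)))) / 10000
  prv <- as.numeric(pr[1, ])
  se <- sqrt(prv * (1 - prv) / 10000)
  expect_true(all(abs(freq - prv) < 3 * se + 1e-12))
})

test_that("verb onset draws reproduce the stated lead-time distribution", {
  set.seed(7)
  x <- rverb_onset(10000)
  expect_true(all(x > 0))
  expect_lt(abs(mean(x) - 1719.26), 3 * 228.75 / sqrt(10000))
  expect_lt(abs(sd(x) - 228.75), 3 * 228.75 / sqrt(2 * 10000))
})

test_that("participants rotate through the six lists", {
  d <- make_design()
  sim <- simulate_experiment(d$lists, d$item_set,
                             generator_params(n_participants = 6), seed = 3)
  lists_used <- unique(sim$trials[, .(participant, list_id)])
  expect_equal(sort(lists_used$list_id), 1:6)
  expect_equal(nrow(sim$trials), 6 * 42)
  expect_equal(nrow(sim$fillers), 6 * 28)
})

test_that("a null generator yields a near-zero grand mean log-ratio", {
  lr <- quick_lr(n_participants = 6, seed = 11,
                 params = null_generator_params(n_participants = 6))
  m <- mean(lr$logratio)
  se <- sd(lr$logratio) / sqrt(length(unique(lr$participant)))
  expect_lt(abs(m), 3 * se)
})

test_that("default parameters produce a post-noun referential preference", {
  lr <- quick_lr(n_participants = 6, seed = 12)
  post <- lr[bin_start >= 500]
  # mentioned-agent preference: positive log-ratio on female-agent trials,
  # negative on male-agent trials
  expect_gt(post[agent_gender == "female", mean(logratio)], 0.5)
  expect_lt(post[agent_gender == "male", mean(logratio)], -0.5)
})

test_that("likert generator recovers the target alpha and its edge cases", {
  x <- simulate_likert(500, likert_params(29, c(1, 7), 0.89), seed = 5)
  expect_true(all(x >= 1 & x <= 7 & x == round(x)))
  expect_lt(abs(cronbach_alpha(x) - 0.89), 0.05)
  a0 <- sapply(1:4, function(i)
    cronbach_alpha(simulate_likert(500, likert_params(29, c(1, 7), 0),
                                   seed = 600 + i)))
  expect_lt(abs(mean(a0)), 0.1)
  dup <- x[, rep(1, 5)]
  expect_equal(cronbach_alpha(dup), 1)
  expect_error(likert_params(29, c(1, 7), 1), "target_alpha")
  expect_error(simulate_likert(1, likert_params()), "2 respondents")
})

test_that("gender mirroring negates the log-ratio series exactly", {
  d <- make_design()
  p6 <- generator_params(n_participants = 3)
  sim <- simulate_experiment(d$lists, d$item_set, p6, seed = 21)
  mir <- mirror_experiment(sim)
  lr <- log_ratio_series(bin_experiment(sim$fixations, sim$trials))
  lr_m <- log_ratio_series(bin_experiment(mir$fixations, mir$trials))
  setkey(lr, participant, trial, bin)
  setkey(lr_m, participant, trial, bin)
  expect_equal(lr_m$logratio, -lr$logratio)
  # cell labels swapped under the mirror
  expect_equal(lr_m$occupation_stereotype,
               ifelse(lr$occupation_stereotype == "female", "male",
                      "female"))
})
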