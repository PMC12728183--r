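test_that("a noiseless attribute maximiser always finds the superior option", {
  set.seed(21)
  for (i in 1:30) {
    tr <- build_trial(session_config("default", 0.5), "treatment")
    expect_identical(attribute_choice(tr, perceptual_sd = 0), tr$superior_position)
  }
})

test_that("perceived-payoff ties break towards the earliest screen position", {
  # two identical best options on middle and right, dominated option left
  tr <- make_toy_trial(areas = c(50, 100, 100), prices = c(40, 20, 20))
  expect_identical(attribute_choice(tr, perceptual_sd = 0), "middle")
})

test_that("large perceptual noise drives choice towards uniform", {
  set.seed(22)
  tr <- make_toy_trial(areas = c(100, 100, 100), prices = c(30, 20, 25))
  picks <- replicate(6000, attribute_choice(tr, perceptual_sd = 50))
  for (pos in c("left", "middle", "right")) {
    expect_within_band(sum(picks == pos), 6000, 1 / 3, alpha = 0.001)
  }
})

test_that("cue-hybrid choice mixes cue following with its fallback at the stated rate", {
  tr <- make_toy_trial(areas = c(90, 120, 100), prices = c(30, 20, 25),
                       cue_position = "right")
  expect_identical(cue_hybrid_choice(tr, w = 1), "right")
  set.seed(23)
  picks <- replicate(30000, cue_hybrid_choice(tr, w = 0.6, fallback = "random"))
  # law of total probability: 0.6 + 0.4/3
  expect_within_band(sum(picks == "right"), 30000, 0.6 + 0.4 / 3, alpha = 0.001)
  picks0 <- replicate(9000, cue_hybrid_choice(tr, w = 0, fallback = "random"))
  for (pos in c("left", "middle", "right")) {
    expect_within_band(sum(picks0 == pos), 9000, 1 / 3, alpha = 0.001)
  }
})

test_that("the matching learner follows the cue at its experienced predictivity", {
  tr <- make_toy_trial(areas = c(90, 120, 100), prices = c(30, 20, 25),
                       cue_position = "left")
  set.seed(24)
  # stationary history at h = 0.7: mixture rate 0.7 + 0.3/3
  hist <- rep(c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0), 4)
  picks <- replicate(20000, matching_learner_choice(tr, hist))
  expect_within_band(sum(picks == "left"), 20000, 0.7 + 0.3 / 3, alpha = 0.001)
  # degenerate histories
  expect_identical(matching_learner_choice(tr, rep(1L, 10)), "left")
  set.seed(25)
  picks0 <- replicate(9000, matching_learner_choice(tr, rep(0L, 10)))
  expect_within_band(sum(picks0 == "left"), 9000, 1 / 3, alpha = 0.001)
})

test_that("simulate_study emits one row per participant and round, reproducibly", {
  d <- simulate_study(2, agent_params("random"), seed = 26)
  expect_equal(nrow(d), 2 * 3 * 43)
  expect_equal(as.vector(table(d$condition)), rep(2L * 43L, 3))
  d2 <- simulate_study(2, agent_params("random"), seed = 26)
  expect_identical(d, d2)
})

test_that("random agents choose the cue option at chance in test rounds", {
  d <- simulate_study(120, agent_params("random"), conditions = "default",
                      seed = 27)
  tst <- d[d$round_kind == "test", ]
  expect_within_band(sum(tst$chose_cue_option), nrow(tst), 1 / 3, alpha = 0.01)
})

test_that("realised payoffs equal the chosen option's area minus price", {
  cfg <- session_config("decoy", 0.6, seed = 28)
  s <- generate_session(cfg, "P1")
  set.seed(29)
  ch <- lenscue:::simulate_session_choices(s, agent_params("attribute",
                                                           perceptual_sd = 0.1))
  long <- session_to_long(s)
  key <- long[match(paste(ch$round_index, ch$chosen_position),
                    paste(long$round_index, long$position)), ]
  expect_equal(ch$realised_payoff, key$area - key$price)
})

test_that("choices never anticipate future rounds", {
  # the history a learner sees at round r is unchanged by permuting later
  # rounds, so the running predictivity at r must be too
  set.seed(30)
  flags <- rbinom(43, 1, 0.6)
  h <- running_predictivity(flags)
  for (r in c(5L, 20L, 40L)) {
    perm <- flags
    tail_idx <- (r + 1):43
    perm[tail_idx] <- sample(perm[tail_idx])
    expect_identical(running_predictivity(perm)[1:r], h[1:r])
  }
})

test_that("the affine cue response reproduces its analytic choice rate", {
  # P(choose cue | h) = v + (1 - v)/3 with v = w0 + w1 h; Monte-Carlo
  # check against direct Bernoulli simulation at a fixed h
  tr <- make_toy_trial(areas = c(90, 120, 100), prices = c(30, 20, 25),
                       cue_position = "middle")
  w0 <- 0.2; w1 <- 0.5; h <- 0.6
  v <- w0 + w1 * h
  target <- v + (1 - v) / 3
  set.seed(31)
  oracle <- mean(rbinom(200000, 1, target))  # direct Bernoulli reference
  picks <- replicate(20000, cue_hybrid_choice(tr, w = v, fallback = "random"))
  expect_lt(abs(mean(picks == "middle") - oracle),
            4 * sqrt(target * (1 - target) / 20000) + 0.003)
})
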