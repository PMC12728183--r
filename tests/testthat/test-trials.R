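test_that("a fully predictive assignment places the cue on the superior option every time", {
  set.seed(11)
  for (cond in c("decoy", "default", "rule")) {
    cfg <- session_config(cond, assigned_predictivity = 1, seed = 21)
    s <- generate_session(cfg)
    expect_true(all(s$cue_predictive[s$round_kind != "test"] == 1L))
  }
})

test_that("at zero predictivity the decoy sits on the second-best option with the worst as decoy", {
  cfg <- session_config("decoy", assigned_predictivity = 0, seed = 31)
  s <- generate_session(cfg)
  tr <- which(s$round_kind != "test")
  expect_true(all(s$cue_predictive[tr] == 0L))
  for (r in tr) {
    trial <- session_trial(s, r)
    o <- trial$options  # ranked, best first
    expect_true(o$has_decoy[2])   # second-best has the decoy
    expect_true(o$is_decoy[3])    # worst option is the decoy
    expect_identical(trial$cue_position, o$position[2])
  }
})

test_that("exactly one cue-indicated option per round in all conditions", {
  set.seed(12)
  for (cond in c("decoy", "default", "rule")) {
    s <- generate_session(session_config(cond, 0.6, seed = 77))
    flag <- switch(cond, decoy = s$has_decoy, default = s$is_default,
                   rule = s$is_indicator)
    expect_true(all(rowSums(flag) == 1L))
    if (cond == "decoy") expect_true(all(rowSums(s$is_decoy) == 1L))
    if (cond == "rule") {
      expect_true(all(rowSums(s$shape == s$indicator_shape) == 1L))
    }
  }
})

test_that("generated decoys are dominated, same-shaped and payoff-conserving", {
  set.seed(13)
  for (i in 1:30) {
    s <- generate_session(session_config("decoy", runif(1), seed = 400 + i))
    for (r in seq_len(s$n_rounds)) {
      tgt <- which(s$has_decoy[r, ])
      dec <- which(s$is_decoy[r, ])
      expect_lte(s$area[r, dec], s$area[r, tgt])
      expect_gte(s$price[r, dec], s$price[r, tgt])
      expect_identical(s$shape[r, dec], s$shape[r, tgt])
      # base payoffs are integers; the adjustment conserves the source's
      # integer payoff up to floating-point error
      expect_lt(abs(s$payoff[r, dec] - round(s$payoff[r, dec])), 1e-9)
      expect_equal(s$payoff[r, dec], s$area[r, dec] - s$price[r, dec])
    }
  }
})

test_that("sessions have the 3 + 28 + 12 round structure with practice first", {
  s <- generate_session(session_config("default", 0.5, seed = 5))
  expect_equal(as.vector(table(s$round_kind)[c("practice", "treatment", "test")]),
               c(3L, 28L, 12L))
  expect_true(all(s$round_kind[1:3] == "practice"))
  expect_equal(s$n_rounds, 43L)
})

test_that("treatment and test rounds are interleaved, not blocked", {
  # across many seeds, test rounds occupy essentially uniform positions 4..43
  set.seed(14)
  pos <- unlist(lapply(1:300, function(i) {
    s <- generate_session(session_config("default", 0.5, seed = 6000 + i))
    which(s$round_kind == "test")
  }))
  expect_true(all(pos >= 4))
  expect_lt(abs(mean(pos) - mean(4:43)), 0.5)
})

test_that("the same seed reproduces a session trial by trial", {
  cfg <- session_config("rule", 0.7, seed = 99)
  a <- generate_session(cfg, "P9")
  b <- generate_session(cfg, "P9")
  expect_identical(session_to_long(a), session_to_long(b))
  expect_identical(a$indicator_shape, b$indicator_shape)
})

test_that("build_trial requires an indicator shape in the rule condition", {
  cfg <- session_config("rule", 0.5)
  expect_error(build_trial(cfg, "treatment"), "indicator")
  set.seed(15)
  tr <- build_trial(cfg, "treatment", indicator_shape = "circle")
  expect_s3_class(tr, "cue_trial")
  expect_equal(sum(tr$options$is_indicator), 1L)
})

test_that("treatment-round cue placement follows the assigned predictivity", {
  set.seed(16)
  shares <- vapply(1:400, function(i) {
    s <- generate_session(session_config("default", 0.8, seed = 9000 + i))
    mean(s$cue_predictive[s$round_kind != "test"])
  }, numeric(1))
  n <- 400 * 31
  expect_within_band(round(mean(shares) * n), n, 0.8, alpha = 0.01)
})

test_that("test rounds place the cue at chance for every condition", {
  chance <- c(decoy = 1 / 2, default = 1 / 3, rule = 1 / 3)
  set.seed(17)
  for (cond in names(chance)) {
    flags <- simulate_test_rounds(cond, p = 0.7, n_sessions = 420,
                                  seed0 = 20000 + 1000 * match(cond, names(chance)))
    expect_within_band(sum(flags), length(flags), chance[[cond]], alpha = 0.01)
  }
})
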