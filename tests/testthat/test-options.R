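test_that("an option's payoff is exactly area minus price", {
  o <- option_spec(area = 183, price = 53)
  expect_identical(o$payoff, 130)
  expect_error(option_spec(area = 0, price = 5))
  expect_error(option_spec(area = 5, price = -1))
  expect_error(option_spec(area = 5, price = 1, has_decoy = TRUE, is_decoy = TRUE))
})

test_that("drawn option sets are ranked, integer-valued and conserve the payoff identity", {
  set.seed(41)
  cfg <- session_config("decoy")
  for (i in 1:50) {
    o <- draw_option_set(cfg)
    expect_equal(nrow(o), 3)
    expect_true(all(diff(o$payoff) < 0))            # strictly ranked, best first
    expect_identical(o$payoff, o$area - o$price)    # conservation by construction
    expect_true(all(o$payoff == round(o$payoff)))   # whole currency units
    expect_true(all(o$price >= 1))
    expect_setequal(o$position, c("left", "middle", "right"))
    expect_true(all(o$shape %in% c("vertical_rectangle", "horizontal_rectangle",
                                   "vertical_ellipse", "horizontal_ellipse",
                                   "square", "circle")))
  }
})

test_that("a degenerate payoff distribution raises the tie error", {
  cfg <- session_config("decoy", payoff_sd = 0)
  expect_error(draw_option_set(cfg, max_tries = 10), "degenerate")
})

test_that("sampled payoffs follow the configured distribution", {
  set.seed(42)
  cfg <- session_config("decoy")
  draws <- replicate(4000, draw_option_set(cfg)$payoff)
  m <- mean(draws)
  # truncation at 1 is ~4.3 sd below the mean, so the mean of N(130, 30)
  # is recovered; Monte-Carlo band at 4 standard errors
  se <- 30 / sqrt(length(draws))
  expect_lt(abs(m - 130), 4 * se + 0.5)  # 0.5 covers integer rounding
})

test_that("make_decoy splits the payoff difference and conserves the source payoff", {
  t <- option_spec(area = 10, price = 4)
  s <- option_spec(area = 7, price = 5, position = "middle")
  d <- make_decoy(t, s, q = 0.5)
  expect_equal(d$area, 8)
  expect_equal(d$price, 6)
  expect_equal(d$payoff, 2)
  expect_identical(d$shape, t$shape)
  expect_identical(d$position, s$position)
  # endpoints: weak dominance in exactly one attribute
  d0 <- make_decoy(t, s, q = 0)
  expect_equal(c(d0$area, d0$price), c(6, 4))
  d1 <- make_decoy(t, s, q = 1)
  expect_equal(c(d1$area, d1$price), c(10, 8))
  # impossible dominance
  expect_error(make_decoy(s, t, q = 0.5), "exceed")
})

test_that("decoy payoff equals the source payoff to machine precision for random inputs", {
  set.seed(7)
  for (i in 1:1000) {
    a_t <- runif(1, 50, 300); p_t <- runif(1, 1, 100)
    a_s <- runif(1, 20, 200); p_s <- runif(1, 1, 100)
    t <- option_spec(area = a_t, price = p_t)
    s <- option_spec(area = a_s, price = p_s, position = "right")
    if (t$payoff <= s$payoff) next
    q <- runif(1)
    d <- make_decoy(t, s, q)
    expect_lt(abs(d$payoff - s$payoff), 1e-9)
    expect_lte(d$area, t$area + 1e-12)
    expect_gte(d$price, t$price - 1e-12)
  }
})
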