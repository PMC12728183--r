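# Independent brute-force oracle for the clustered linear probability
# model: normal equations solved directly, cluster sandwich assembled by
# hand with CR1 scaling G/(G-1) * (n-1)/(n-k).
manual_cluster_ols <- function(y, x, cluster) {
  X <- cbind(1, x)
  n <- length(y)
  k <- ncol(X)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  e <- as.vector(y - X %*% beta)
  ids <- unique(cluster)
  G <- length(ids)
  meat <- matrix(0, k, k)
  for (g in ids) {
    i <- cluster == g
    s <- crossprod(X[i, , drop = FALSE], e[i])
    meat <- meat + s %*% t(s)
  }
  adj <- G / (G - 1) * (n - 1) / (n - k)
  bread <- solve(XtX)
  V <- bread %*% (adj * meat) %*% bread
  list(beta = as.vector(beta), se = sqrt(diag(V)))
}

# Hand-built single round for unit tests of choice policies and the
# cue-predictive flag. Options are given in left/middle/right order.
make_toy_trial <- function(areas, prices, cue_position = "left",
                           round_kind = "test", round_index = 4L) {
  payoff <- areas - prices
  opts <- tibble::tibble(
    shape = c("square", "circle", "vertical_ellipse"),
    area = areas, price = prices, payoff = payoff,
    position = c("left", "middle", "right"),
    has_decoy = FALSE, is_decoy = FALSE,
    is_default = FALSE, is_indicator = FALSE
  )
  structure(
    list(
      round_index = round_index, round_kind = round_kind,
      options = opts[order(opts$payoff, decreasing = TRUE), ],
      cue_position = cue_position,
      superior_position = c("left", "middle", "right")[which.max(payoff)],
      cue_predictive = as.integer(cue_position ==
                                    c("left", "middle", "right")[which.max(payoff)]),
      decoy_proportion = NA_real_
    ),
    class = "cue_trial"
  )
}

# Minimal regression-ready data frame: one row per participant x round.
make_choice_df <- function(participant_id, chose_cue, h,
                           condition = "decoy", round_kind = "test") {
  tibble::tibble(
    participant_id = participant_id,
    condition = condition,
    round_kind = round_kind,
    chose_cue_option = chose_cue,
    historical_predictivity = h
  )
}

# Exact two-sided binomial acceptance band: observed count must fall in
# the central 1 - alpha region of Binomial(n, p0).
binom_band <- function(n, p0, alpha = 0.01) {
  c(qbinom(alpha / 2, n, p0), qbinom(1 - alpha / 2, n, p0))
}

expect_within_band <- function(count, n, p0, alpha = 0.01) {
  band <- binom_band(n, p0, alpha)
  expect_gte(count, band[1])
  expect_lte(count, band[2])
}

# Pool the test rounds of many sessions of one condition.
simulate_test_rounds <- function(condition, p, n_sessions, seed0 = 1000L) {
  flags <- integer(0)
  for (i in seq_len(n_sessions)) {
    cfg <- session_config(condition, assigned_predictivity = p,
                          seed = seed0 + i)
    s <- generate_session(cfg, participant_id = paste0("S", i))
    flags <- c(flags, s$cue_predictive[s$round_kind == "test"])
  }
  flags
}
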