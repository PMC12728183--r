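# Vectorised generator for n rounds of one session. Columns of all
# matrices are screen positions (left, middle, right); because the three
# payoffs are drawn iid per column, the assignment of payoff ranks to
# positions is automatically a uniform permutation.
#
# Cue placement:
#   treatment (and practice) rounds — cue on the superior option with
#     probability p; otherwise decoy: second-best has the decoy (worst
#     option is the decoy); default/rule: one of the two inferior options,
#     uniformly.
#   test rounds — decoy: superior or second-best has the decoy with equal
#     probability, the worst option is the decoy; default/rule: uniform
#     over the three options.
# In the decoy condition the decoy of a superior-cued treatment round is
# the second or third best option with 50% probability each.
generate_trial_matrices <- function(config, kinds, indicator_shape = NULL) {
  n <- length(kinds)
  if (config$condition == "rule" && is.null(indicator_shape)) {
    stop("the rule condition requires an indicator shape")
  }
  m <- draw_attribute_matrices(config, n)
  payoff <- m$payoff; price <- m$price; area <- m$area; shape <- m$shape

  # column index of each payoff rank (1 = best); ties were redrawn, so
  # max.col is unambiguous
  col1 <- max.col(payoff)
  tmp <- payoff
  tmp[cbind(seq_len(n), col1)] <- -Inf
  col2 <- max.col(tmp)
  col3 <- 6L - col1 - col2
  rank_col <- cbind(col1, col2, col3)

  p <- config$assigned_predictivity
  is_test <- kinds == "test"
  on_sup <- runif(n) < p            # treatment-round branch
  coin <- runif(n) < 0.5

  has_decoy <- is_decoy <- is_default <- is_indicator <-
    matrix(FALSE, nrow = n, ncol = 3)
  decoy_prop <- rep(NA_real_, n)

  if (config$condition == "decoy") {
    # ranks of the option that has the decoy (target) and of the decoy
    tgt_rank <- ifelse(is_test, ifelse(coin, 1L, 2L), ifelse(on_sup, 1L, 2L))
    dec_rank <- ifelse(is_test, 3L,
                       ifelse(on_sup, ifelse(coin, 2L, 3L), 3L))
    # a superior-cued treatment round re-uses `coin` for both the p-branch
    # and the decoy identity; draw a fresh coin for the decoy to keep the
    # two randomisations independent
    fresh <- runif(n) < 0.5
    dec_rank[!is_test & on_sup] <- ifelse(fresh[!is_test & on_sup], 2L, 3L)

    tgt_col <- rank_col[cbind(seq_len(n), tgt_rank)]
    dec_col <- rank_col[cbind(seq_len(n), dec_rank)]
    ti <- cbind(seq_len(n), tgt_col)
    di <- cbind(seq_len(n), dec_col)

    q <- runif(n)
    delta <- payoff[ti] - payoff[di]
    price[di] <- price[ti] + q * delta
    area[di] <- area[ti] - (1 - q) * delta
    payoff[di] <- area[di] - price[di]
    shape[di] <- shape[ti]
    has_decoy[ti] <- TRUE
    is_decoy[di] <- TRUE
    decoy_prop <- q
    cue_col <- tgt_col
    cue_rank <- tgt_rank
  } else {
    inf_pick <- ifelse(coin, 2L, 3L)  # uniform over the two inferior options
    cue_rank <- ifelse(is_test,
                       sample.int(3L, n, replace = TRUE),
                       ifelse(on_sup, 1L, inf_pick))
    cue_col <- rank_col[cbind(seq_len(n), cue_rank)]
    ci <- cbind(seq_len(n), cue_col)
    if (config$condition == "default") {
      is_default[ci] <- TRUE
    } else {
      # rule: cue option takes the indicator shape; the other two options
      # are re-randomised over the remaining five shapes so the indicator
      # appears exactly once per round
      others <- setdiff(OPTION_SHAPES, indicator_shape)
      shape[] <- sample(others, n * 3L, replace = TRUE)
      shape[ci] <- indicator_shape
      is_indicator[ci] <- TRUE
    }
  }

  list(
    round_kind = kinds,
    payoff = payoff, price = price, area = area, shape = shape,
    has_decoy = has_decoy, is_decoy = is_decoy,
    is_default = is_default, is_indicator = is_indicator,
    cue_position = OPTION_POSITIONS[cue_col],
    superior_position = OPTION_POSITIONS[col1],
    cue_predictive = as.integer(cue_rank == 1L),
    decoy_proportion = decoy_prop
  )
}

trial_from_matrices <- function(mats, r, round_index) {
  opts <- tibble(
    shape = mats$shape[r, ],
    area = mats$area[r, ],
    price = mats$price[r, ],
    payoff = mats$payoff[r, ],
    position = OPTION_POSITIONS,
    has_decoy = mats$has_decoy[r, ],
    is_decoy = mats$is_decoy[r, ],
    is_default = mats$is_default[r, ],
    is_indicator = mats$is_indicator[r, ]
  )
  structure(
    list(
      round_index = round_index,
      round_kind = mats$round_kind[r],
      options = opts[order(opts$payoff, decreasing = TRUE), ],
      cue_position = mats$cue_position[r],
      superior_position = mats$superior_position[r],
      cue_predictive = mats$cue_predictive[r],
      decoy_proportion = mats$decoy_proportion[r]
    ),
    class = "cue_trial"
  )
}

#' @export
print.cue_trial <- function(x, ...) {
  cat(sprintf("<cue_trial> round %s (%s): cue on %s, superior %s, cue predictive = %d\n",
              x$round_index, x$round_kind, x$cue_position,
              x$superior_position, x$cue_predictive))
  print(x$options)
  invisible(x)
}

#' Generate a single round
#'
#' Draws one three-option round and places the condition's cue (a decoy on
#' one option, a pre-selected default, or the indicator shape) according to
#' the round kind and the assigned predictivity. Uses the current RNG
#' state; seed at the session level for reproducibility.
#'
#' @param config A [session_config()].
#' @param round_kind `"practice"`, `"treatment"` or `"test"`. Practice
#'   rounds are generated exactly like treatment rounds.
#' @param indicator_shape Required in the rule condition: the shape that
#'   marks the cue option.
#' @param round_index Round number stored on the trial.
#' @return A `cue_trial` object: three options (ranked by payoff), the cue
#'   and superior positions, and the cue-predictive flag, which is 1 iff
#'   the cue option is the superior option.
#' @export
build_trial <- function(config, round_kind = c("treatment", "practice", "test"),
                        indicator_shape = NULL, round_index = 1L) {
  stopifnot(inherits(config, "session_config"))
  round_kind <- match.arg(round_kind)
  kind <- if (round_kind == "practice") "treatment" else round_kind
  mats <- generate_trial_matrices(config, kind, indicator_shape)
  mats$round_kind <- round_kind
  trial_from_matrices(mats, 1L, round_index)
}

#' Generate a full session for one synthetic participant
#'
#' Rounds 1 to `n_practice` are practice rounds generated at the
#' participant's treatment level; the remaining treatment and test rounds
#' are interleaved in uniformly random order. In the rule condition the
#' indicator shape is drawn uniformly once per session. The session is
#' fully reproducible from `config$seed`.
#'
#' @param config A [session_config()].
#' @param participant_id Opaque participant identifier.
#' @return A `cue_session` object. Individual rounds are available via
#'   [session_trial()], the long per-option form via [session_to_long()].
#' @export
generate_session <- function(config, participant_id = "P1") {
  stopifnot(inherits(config, "session_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  indicator_shape <- if (config$condition == "rule") sample(OPTION_SHAPES, 1L)
  kinds <- c(
    rep("practice", config$n_practice),
    sample(c(rep("treatment", config$n_treatment), rep("test", config$n_test)))
  )
  gen_kinds <- ifelse(kinds == "practice", "treatment", kinds)
  mats <- generate_trial_matrices(config, gen_kinds, indicator_shape)
  mats$round_kind <- kinds
  structure(
    c(list(participant_id = participant_id, config = config,
           indicator_shape = indicator_shape,
           n_rounds = length(kinds)),
      mats),
    class = "cue_session"
  )
}

#' @export
print.cue_session <- function(x, ...) {
  cat(sprintf("<cue_session> %s: %s condition, p = %g, %d rounds\n",
              x$participant_id, x$config$condition,
              x$config$assigned_predictivity, x$n_rounds))
  if (!is.null(x$indicator_shape)) cat("  indicator shape:", x$indicator_shape, "\n")
  cat(sprintf("  cue predictive in %d/%d rounds\n",
              sum(x$cue_predictive), x$n_rounds))
  invisible(x)
}

#' Extract one round of a session
#'
#' @param session A `cue_session`.
#' @param r Round index (1-based).
#' @return A `cue_trial`.
#' @export
session_trial <- function(session, r) {
  stopifnot(inherits(session, "cue_session"), r >= 1, r <= session$n_rounds)
  trial_from_matrices(session, r, as.integer(r))
}

#' Long-format serialisation of a session
#'
#' One row per round x option, in the canonical column order used by all
#' readers and writers in the package.
#'
#' @param session A `cue_session`.
#' @return A tibble with `3 * n_rounds` rows.
#' @export
session_to_long <- function(session) {
  stopifnot(inherits(session, "cue_session"))
  n <- session$n_rounds
  idx <- rep(seq_len(n), each = 3L)
  pos <- rep(1:3, times = n)
  flat <- function(m) as.vector(t(m))
  tibble(
    participant_id = session$participant_id,
    condition = session$config$condition,
    assigned_predictivity = session$config$assigned_predictivity,
    round_index = idx,
    round_kind = session$round_kind[idx],
    position = OPTION_POSITIONS[pos],
    shape = flat(session$shape),
    area = flat(session$area),
    price = flat(session$price),
    payoff = flat(session$payoff),
    has_decoy = flat(session$has_decoy),
    is_decoy = flat(session$is_decoy),
    is_default = flat(session$is_default),
    is_indicator = flat(session$is_indicator),
    cue_position = session$cue_position[idx],
    superior_position = session$superior_position[idx],
    cue_predictive = session$cue_predictive[idx]
  )
}

#' Round-trip a session through JSON
#'
#' A compact dump of the session metadata and per-round matrices, suitable
#' for archiving single sessions.
#'
#' @param session A `cue_session`.
#' @param path File path.
#' @return `write_session_json()` returns `path` invisibly;
#'   `read_session_json()` the restored `cue_session`.
#' @export
write_session_json <- function(session, path) {
  stopifnot(inherits(session, "cue_session"))
  payload <- list(
    participant_id = session$participant_id,
    config = unclass(session$config),
    indicator_shape = session$indicator_shape,
    n_rounds = session$n_rounds,
    round_kind = session$round_kind,
    cue_position = session$cue_position,
    superior_position = session$superior_position,
    cue_predictive = session$cue_predictive,
    decoy_proportion = session$decoy_proportion,
    payoff = session$payoff, price = session$price,
    area = session$area, shape = session$shape,
    has_decoy = session$has_decoy, is_decoy = session$is_decoy,
    is_default = session$is_default, is_indicator = session$is_indicator
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_session_json
#' @export
read_session_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- x$config
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  config <- do.call(session_config, cfg)
  mat <- function(m) matrix(as.numeric(m), ncol = 3L)
  structure(
    list(
      participant_id = x$participant_id, config = config,
      indicator_shape = x$indicator_shape, n_rounds = as.integer(x$n_rounds),
      round_kind = x$round_kind,
      payoff = mat(x$payoff), price = mat(x$price), area = mat(x$area),
      shape = matrix(as.character(x$shape), ncol = 3L),
      has_decoy = matrix(as.logical(x$has_decoy), ncol = 3L),
      is_decoy = matrix(as.logical(x$is_decoy), ncol = 3L),
      is_default = matrix(as.logical(x$is_default), ncol = 3L),
      is_indicator = matrix(as.logical(x$is_indicator), ncol = 3L),
      cue_position = x$cue_position,
      superior_position = x$superior_position,
      cue_predictive = as.integer(x$cue_predictive),
      decoy_proportion = as.numeric(x$decoy_proportion)
    ),
    class = "cue_session"
  )
}
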