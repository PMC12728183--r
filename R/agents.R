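#' Parameters of a synthetic choice agent
#'
#' Agents stand in for participants when generating choice data. Four
#' policies are available:
#' \describe{
#'   \item{`random`}{uniform over the three positions.}
#'   \item{`attribute`}{picks the option with the largest *perceived*
#'     payoff: the area is read with multiplicative normal noise, the
#'     printed price exactly.}
#'   \item{`cue_hybrid`}{follows the cue with a set probability,
#'     otherwise falls back to another policy. With `intercept_weight`
#'     set, the cue-following probability is affine in the historical
#'     predictivity `h`: `w0 + w1 * h`.}
#'   \item{`matching_learner`}{probability matching: follows the cue with
#'     probability equal to the historical predictivity experienced so
#'     far (chance, 1/3, before any feedback), random fallback.}
#' }
#'
#' @param policy Agent policy.
#' @param cue_weight Cue-following probability `w` (fixed `cue_hybrid`),
#'   or the slope `w1` on historical predictivity when `intercept_weight`
#'   is given.
#' @param intercept_weight Optional intercept `w0` of an affine
#'   cue-response `P(follow cue | h) = w0 + w1 h`; requires
#'   `w0 + w1 <= 1`.
#' @param perceptual_sd Standard deviation of the multiplicative noise on
#'   perceived area (attribute policy and fallbacks).
#' @param fallback Policy used when the cue is not followed: `"random"`
#'   or `"attribute"`.
#' @return An `agent_params` object.
#' @export
agent_params <- function(policy = c("matching_learner", "random",
                                    "attribute", "cue_hybrid"),
                         cue_weight = NULL, intercept_weight = NULL,
                         perceptual_sd = 0,
                         fallback = c("random", "attribute")) {
  policy <- match.arg(policy)
  fallback <- match.arg(fallback)
  stopifnot(perceptual_sd >= 0)
  if (policy == "cue_hybrid") {
    stopifnot(!is.null(cue_weight), cue_weight >= 0, cue_weight <= 1)
    if (!is.null(intercept_weight)) {
      stopifnot(intercept_weight >= 0, intercept_weight + cue_weight <= 1)
    }
  }
  structure(
    list(policy = policy, cue_weight = cue_weight,
         intercept_weight = intercept_weight,
         perceptual_sd = perceptual_sd, fallback = fallback),
    class = "agent_params"
  )
}

pos_index <- function(position) match(position, OPTION_POSITIONS)

# argmax over perceived payoffs, row-wise; ties broken towards the lowest
# position order (left < middle < right)
perceived_argmax <- function(area, price, perceptual_sd) {
  eps <- matrix(rnorm(length(area), 0, perceptual_sd), nrow = nrow(area))
  perceived <- area * (1 + eps) - price
  max.col(perceived, ties.method = "first")
}

#' Attribute-maximising choice
#'
#' Picks the option with the largest perceived payoff. The area of each
#' option is perceived with independent multiplicative normal noise
#' (areas are judged visually); the printed price enters exactly. With
#' `perceptual_sd = 0` this always returns the superior position; exact
#' perceived ties go to the earliest position in left/middle/right order.
#'
#' @param trial A `cue_trial`.
#' @param perceptual_sd Noise scale on perceived area.
#' @return A position: `"left"`, `"middle"` or `"right"`.
#' @export
attribute_choice <- function(trial, perceptual_sd = 0) {
  stopifnot(inherits(trial, "cue_trial"))
  o <- trial$options[order(pos_index(trial$options$position)), ]
  j <- perceived_argmax(matrix(o$area, 1), matrix(o$price, 1), perceptual_sd)
  OPTION_POSITIONS[j]
}

#' Cue-following hybrid choice
#'
#' Follows the cue with probability `w`, otherwise delegates to the
#' fallback policy.
#'
#' @param trial A `cue_trial`.
#' @param w Cue-following probability in \[0, 1\].
#' @param fallback `"random"` or `"attribute"`.
#' @param perceptual_sd Noise scale for the attribute fallback.
#' @return A position.
#' @export
cue_hybrid_choice <- function(trial, w, fallback = c("random", "attribute"),
                              perceptual_sd = 0) {
  stopifnot(inherits(trial, "cue_trial"), w >= 0, w <= 1)
  fallback <- match.arg(fallback)
  if (runif(1) < w) return(trial$cue_position)
  if (fallback == "random") {
    sample(OPTION_POSITIONS, 1L)
  } else {
    attribute_choice(trial, perceptual_sd)
  }
}

#' Probability-matching choice
#'
#' Follows the cue with probability equal to the historical predictivity
#' computed from the supplied feedback history (the cue-predictive flags
#' of all previous rounds), falling back to a uniform random choice
#' otherwise. An empty history uses the chance rate 1/3.
#'
#' @param trial A `cue_trial`.
#' @param history Integer 0/1 vector of cue-predictive flags for rounds
#'   `1 .. r-1`.
#' @return A position.
#' @export
matching_learner_choice <- function(trial, history = integer()) {
  h <- if (length(history) == 0L) 1 / 3 else mean(history)
  cue_hybrid_choice(trial, w = h, fallback = "random")
}

# Vectorised choices of one agent over a whole session. The history a
# learner conditions on is the sequence of the session's own
# cue-predictive flags (full feedback reveals the superior option every
# round, whatever was chosen), so the running predictivity can be computed
# up front; choices at round r depend only on rounds < r.
simulate_session_choices <- function(session, agent) {
  n <- session$n_rounds
  incl <- if (session$config$include_practice_in_history) NULL
          else session$round_kind != "practice"
  h <- running_predictivity(session$cue_predictive, include = incl)
  cue_idx <- pos_index(session$cue_position)
  random_idx <- sample.int(3L, n, replace = TRUE)
  choice <- switch(
    agent$policy,
    random = random_idx,
    attribute = perceived_argmax(session$area, session$price, agent$perceptual_sd),
    cue_hybrid = {
      w <- if (is.null(agent$intercept_weight)) {
        rep(agent$cue_weight, n)
      } else {
        hh <- ifelse(is.na(h), 1 / 3, h)
        pmin(pmax(agent$intercept_weight + agent$cue_weight * hh, 0), 1)
      }
      fb <- if (agent$fallback == "random") random_idx
            else perceived_argmax(session$area, session$price, agent$perceptual_sd)
      ifelse(runif(n) < w, cue_idx, fb)
    },
    matching_learner = {
      w <- ifelse(is.na(h), 1 / 3, h)
      ifelse(runif(n) < w, cue_idx, random_idx)
    },
    stop("unknown policy: ", agent$policy)
  )
  tibble(
    participant_id = session$participant_id,
    condition = session$config$condition,
    assigned_predictivity = session$config$assigned_predictivity,
    round_index = seq_len(n),
    round_kind = session$round_kind,
    cue_position = session$cue_position,
    superior_position = session$superior_position,
    cue_predictive = session$cue_predictive,
    historical_predictivity = h,
    chosen_position = OPTION_POSITIONS[choice],
    chose_cue_option = as.integer(choice == cue_idx),
    realised_payoff = session$payoff[cbind(seq_len(n), choice)]
  )
}

#' Simulate a full study with synthetic participants
#'
#' Generates `n_per_condition` sessions per condition, each with its own
#' assigned predictivity drawn from `predictivity` (uniform on \[0, 1\] by
#' default), runs the agent through every round with its feedback history
#' updated online, and returns the long-format choice dataset consumed by
#' the analysis pipeline.
#'
#' @param n_per_condition Participants per condition.
#' @param agent An [agent_params()].
#' @param conditions Conditions to simulate.
#' @param config Template [session_config()]; its condition, predictivity
#'   and seed are overridden per participant.
#' @param predictivity Function of `n` returning the assigned
#'   predictivities of `n` participants.
#' @param seed Optional integer seed; the run is fully reproducible from
#'   it (per-participant seeds are drawn from this stream and recorded in
#'   the participant id ordering).
#' @return A tibble with one row per participant x round.
#' @export
#' @examples
#' d <- simulate_study(2, agent_params("random"), seed = 1)
#' nrow(d)  # 2 participants x 3 conditions x 43 rounds
simulate_study <- function(n_per_condition,
                           agent = agent_params("matching_learner"),
                           conditions = CUE_CONDITIONS,
                           config = session_config(),
                           predictivity = function(n) runif(n),
                           seed = NULL) {
  stopifnot(n_per_condition >= 1, inherits(agent, "agent_params"),
            all(conditions %in% CUE_CONDITIONS))
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", length(conditions) * n_per_condition)
  k <- 0L
  for (cond in conditions) {
    p_assigned <- predictivity(n_per_condition)
    stopifnot(all(p_assigned >= 0), all(p_assigned <= 1))
    seeds <- sample.int(.Machine$integer.max, n_per_condition)
    for (i in seq_len(n_per_condition)) {
      cfg <- config
      cfg$condition <- cond
      cfg$assigned_predictivity <- p_assigned[i]
      cfg$seed <- seeds[i]
      s <- generate_session(cfg, participant_id = sprintf("%s_%03d", cond, i))
      set.seed(seeds[i] %/% 2L + 1L)  # separate stream for the agent
      k <- k + 1L
      out[[k]] <- simulate_session_choices(s, agent)
    }
  }
  dplyr::bind_rows(out)
}
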