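#' Was the cue predictive on a trial?
#'
#' The cue-predictive dummy: 1 iff the cue-indicated option (the option
#' that has a decoy, is the default, or bears the indicator shape) is the
#' superior option of the round.
#'
#' @param trial A `cue_trial`, or anything with `cue_position` and
#'   `superior_position` fields.
#' @return Integer 0 or 1.
#' @export
cue_predictive <- function(trial) {
  stopifnot(!is.null(trial$cue_position), !is.null(trial$superior_position))
  as.integer(trial$cue_position == trial$superior_position)
}

#' Historical predictivity at a round
#'
#' The share of previous rounds on which the cue was predictive:
#' `mean(flags[1:(r-1)])`. Undefined at `r = 1` (no history); the
#' preregistered regression only ever consumes rounds after the practice
#' block, where it is always defined.
#'
#' @param flags Integer 0/1 cue-predictive flags for rounds `1 .. r-1` (or
#'   longer; only the first `r - 1` are used). Practice rounds count.
#' @param r Round index, `>= 2`.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' historical_predictivity(c(1, 0, 1), r = 4)  # 2/3
historical_predictivity <- function(flags, r) {
  stopifnot(is.numeric(r), length(r) == 1)
  if (r < 2) stop("historical predictivity is undefined at round 1 (no history)")
  if (length(flags) < r - 1) stop("history must cover rounds 1 .. r-1")
  stopifnot(all(flags %in% c(0, 1)))
  mean(flags[seq_len(r - 1)])
}

#' Running historical predictivity over a session
#'
#' Vectorised form: element `r` is the historical predictivity at round
#' `r`, `NA` where no history has accumulated yet.
#'
#' @param flags Integer 0/1 cue-predictive flags, in round order.
#' @param include Optional logical mask of rounds that count towards the
#'   history (used to drop practice rounds); default all.
#' @return Numeric vector, same length as `flags`.
#' @export
running_predictivity <- function(flags, include = NULL) {
  stopifnot(all(flags %in% c(0, 1)))
  if (is.null(include)) include <- rep(TRUE, length(flags))
  num <- c(0, cumsum(flags * include))
  den <- c(0, cumsum(include))
  r <- seq_along(flags)
  h <- ifelse(den[r] > 0, num[r] / den[r], NA_real_)
  h
}

#' Preregistered test-round regression
#'
#' Subsets one condition's test rounds and fits the linear probability
#' model `chose_cue_option ~ historical_predictivity` by OLS, with
#' standard errors cluster-robust at the participant level (CR1 scaling
#' `G/(G-1) * (n-1)/(n-k)`; inference on `G - 1` degrees of freedom). The
#' slope is the estimated cue weight: the change in the probability of
#' choosing the cue-indicated option per unit of historical predictivity.
#'
#' @param data Long-format choice dataset with columns `condition`,
#'   `round_kind`, `participant_id`, `chose_cue_option` and
#'   `historical_predictivity`.
#' @param condition Condition to fit.
#' @return An `lpm_fit` object: coefficients, cluster-robust SEs, t and p
#'   values, observation and cluster counts.
#' @export
preregistered_regression <- function(data, condition = c("decoy", "default", "rule")) {
  condition <- match.arg(condition)
  need <- c("condition", "round_kind", "participant_id",
            "chose_cue_option", "historical_predictivity")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("dataset lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  sub <- data[data$condition == condition & data$round_kind == "test", ]
  if (any(is.na(sub$historical_predictivity))) {
    stop("test-round records with undefined history; cannot regress")
  }
  n_clusters <- length(unique(sub$participant_id))
  if (n_clusters < 2) stop("need at least 2 participants to cluster on")
  if (var(sub$historical_predictivity) == 0) {
    stop("historical predictivity has zero variance; design is singular")
  }
  fit <- lm(chose_cue_option ~ historical_predictivity, data = sub)
  degenerate <- var(resid(fit)) < .Machine$double.eps
  V <- withCallingHandlers(
    sandwich::vcovCL(fit, cluster = sub$participant_id,
                     type = "HC1", cadjust = TRUE),
    # a perfect fit is reported through the degenerate flag instead
    warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
  if (degenerate) {
    warning("residuals are identically zero; standard errors are degenerate")
  }
  b <- coef(fit)
  se <- sqrt(diag(V))
  df <- n_clusters - 1
  tval <- b / se
  structure(
    list(
      condition = condition,
      intercept = unname(b[1]), slope = unname(b[2]),
      se_intercept = unname(se[1]), se_slope = unname(se[2]),
      t_intercept = unname(tval[1]), t_slope = unname(tval[2]),
      p_intercept = unname(2 * pt(-abs(tval[1]), df)),
      p_slope = unname(2 * pt(-abs(tval[2]), df)),
      vcov = V, df = df,
      n_obs = nrow(sub), n_clusters = n_clusters,
      degenerate_se = degenerate
    ),
    class = "lpm_fit"
  )
}

#' @export
print.lpm_fit <- function(x, ...) {
  cat(sprintf("Linear probability model, %s condition (test rounds)\n", x$condition))
  cat(sprintf("  Constant                %.3f  (%.3f)\n", x$intercept, x$se_intercept))
  cat(sprintf("  Historical predictivity %.3f  (%.3f)\n", x$slope, x$se_slope))
  cat(sprintf("  n = %d observations, %d clusters; SEs cluster-robust (participant), t on %d df\n",
              x$n_obs, x$n_clusters, x$df))
  if (x$degenerate_se) cat("  [degenerate: zero residual variance]\n")
  invisible(x)
}

#' Marginal effect of a predictivity change
#'
#' In a linear probability model the effect of a `delta` change in
#' historical predictivity is `slope * delta`, here expressed in
#' percentage points of choice probability.
#'
#' @param fit An `lpm_fit` (or any list with a `slope` field).
#' @param delta Change in historical predictivity (default 0.10, i.e. ten
#'   percentage points).
#' @return Percentage points.
#' @export
#' @examples
#' marginal_effect(list(slope = 0.129), delta = 0.10)  # 1.29
marginal_effect <- function(fit, delta = 0.10) {
  fit$slope * delta * 100
}

#' Local choice rates by binned historical predictivity
#'
#' Groups test-round observations by historical predictivity rounded to
#' two decimal places and returns the local mean rate of choosing the
#' cue-indicated option, with bin counts — the binned scatter used to
#' visualise the regression against its chance benchmarks.
#'
#' @param data Long-format choice dataset.
#' @param condition Optional single condition to subset; default all, with
#'   a `condition` grouping column.
#' @return A tibble with columns `condition`, `predictivity_bin`,
#'   `choice_rate`, `n`. Empty input yields an empty tibble.
#' @export
binned_choice_rates <- function(data, condition = NULL) {
  sub <- data[data$round_kind == "test", ]
  if (!is.null(condition)) sub <- sub[sub$condition == condition, ]
  if (nrow(sub) == 0) {
    return(tibble(condition = character(), predictivity_bin = numeric(),
                  choice_rate = numeric(), n = integer()))
  }
  sub$predictivity_bin <- round(sub$historical_predictivity, 2)
  out <- dplyr::summarise(
    dplyr::group_by(sub, .data$condition, .data$predictivity_bin),
    choice_rate = mean(.data$chose_cue_option),
    n = dplyr::n(), .groups = "drop"
  )
  dplyr::arrange(out, .data$condition, .data$predictivity_bin)
}

#' Chance-level benchmark for test rounds
#'
#' The expected rate of choosing the cue-indicated option on test rounds
#' under a cue-blind chooser. Under `uniform_over_3` every option is
#' chosen with probability 1/3, so the benchmark is 1/3 in all
#' conditions. Under `dominance_respecting` the chooser never picks the
#' dominated decoy; in decoy test rounds the cue sits on one of the two
#' non-dominated options with equal probability, so the benchmark rises
#' to 1/2 there and stays 1/3 elsewhere.
#'
#' @param condition Cue condition.
#' @param chooser_assumption `"uniform_over_3"` or `"dominance_respecting"`.
#' @return A probability.
#' @export
chance_benchmark <- function(condition = c("decoy", "default", "rule"),
                             chooser_assumption = c("uniform_over_3",
                                                    "dominance_respecting")) {
  condition <- match.arg(condition)
  chooser_assumption <- match.arg(chooser_assumption)
  if (chooser_assumption == "dominance_respecting" && condition == "decoy") {
    1 / 2
  } else {
    1 / 3
  }
}

#' Fit all conditions and tabulate
#'
#' Runs [preregistered_regression()] for each condition present in the
#' data and returns one row per condition: coefficient estimates,
#' cluster-robust standard errors and sample sizes.
#'
#' @param data Long-format choice dataset.
#' @param conditions Conditions to fit; default those present.
#' @return A tibble.
#' @export
regression_table <- function(data, conditions = intersect(CUE_CONDITIONS,
                                                          unique(data$condition))) {
  fits <- lapply(conditions, function(cc) preregistered_regression(data, cc))
  tibble(
    condition = conditions,
    intercept = vapply(fits, `[[`, numeric(1), "intercept"),
    se_intercept = vapply(fits, `[[`, numeric(1), "se_intercept"),
    slope = vapply(fits, `[[`, numeric(1), "slope"),
    se_slope = vapply(fits, `[[`, numeric(1), "se_slope"),
    t_slope = vapply(fits, `[[`, numeric(1), "t_slope"),
    p_slope = vapply(fits, `[[`, numeric(1), "p_slope"),
    n_obs = vapply(fits, `[[`, integer(1), "n_obs"),
    n_clusters = vapply(fits, `[[`, integer(1), "n_clusters")
  )
}

#' Plain-text report of the fitted regressions
#'
#' @param tab Output of [regression_table()].
#' @return A character vector of report lines, invisibly printed.
#' @export
format_regression_table <- function(tab) {
  lines <- c(
    "Test-round linear probability models (one per condition)",
    "Dependent variable: cue-indicated option was chosen",
    sprintf("%-10s %10s %12s %10s %12s %8s %9s", "condition", "constant",
            "(se)", "slope", "(se)", "n", "clusters"),
    sprintf("%-10s %10.3f %12s %10.3f %12s %8d %9d",
            tab$condition, tab$intercept, sprintf("(%.3f)", tab$se_intercept),
            tab$slope, sprintf("(%.3f)", tab$se_slope),
            tab$n_obs, tab$n_clusters),
    "Standard errors cluster-robust at the participant level."
  )
  lines
}
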