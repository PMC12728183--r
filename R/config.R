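#' Configuration of one simulated session
#'
#' A session is one synthetic participant: a cue condition, an assigned cue
#' predictivity, and the payoff/price distributions from which the three
#' options of every round are drawn. Payoffs and prices are sampled from
#' normal distributions truncated below at 1 and rounded to integers, so the
#' arithmetic shown to a participant (payoff = area - price) is exact in
#' whole experimental currency units.
#'
#' @param condition Cue condition: `"decoy"`, `"default"` or `"rule"`.
#' @param assigned_predictivity Probability `p` in \[0, 1\] that, on a
#'   treatment round, the cue is placed on the superior (highest-payoff)
#'   option.
#' @param payoff_mean,payoff_sd Mean and standard deviation of the normal
#'   distribution from which the three payoffs of a round are drawn
#'   (experimental currency units).
#' @param price_mean,price_sd Mean and standard deviation of the normal
#'   distribution from which option prices are drawn.
#' @param n_practice,n_treatment,n_test Number of practice, treatment and
#'   test rounds. Defaults 3 + 28 + 12 = 43.
#' @param include_practice_in_history Should practice rounds enter the
#'   running historical-predictivity average? Default `TRUE`: the round
#'   index starts at 1 on the first practice round.
#' @param seed Optional integer seed making the session reproducible.
#'
#' @return An object of class `session_config`.
#' @export
#' @examples
#' session_config("decoy", assigned_predictivity = 0.8, seed = 1)
session_config <- function(condition = c("decoy", "default", "rule"),
                           assigned_predictivity = 0.5,
                           payoff_mean = 130, payoff_sd = 30,
                           price_mean = 55, price_sd = 15,
                           n_practice = 3L, n_treatment = 28L, n_test = 12L,
                           include_practice_in_history = TRUE,
                           seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(
    is.numeric(assigned_predictivity), length(assigned_predictivity) == 1,
    assigned_predictivity >= 0, assigned_predictivity <= 1,
    payoff_sd >= 0, price_sd >= 0,
    n_practice >= 0, n_treatment >= 0, n_test >= 0
  )
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, seed == round(seed))
    seed <- as.integer(seed)
  }
  structure(
    list(
      condition = condition,
      assigned_predictivity = assigned_predictivity,
      payoff_mean = payoff_mean, payoff_sd = payoff_sd,
      price_mean = price_mean, price_sd = price_sd,
      n_practice = as.integer(n_practice),
      n_treatment = as.integer(n_treatment),
      n_test = as.integer(n_test),
      include_practice_in_history = isTRUE(include_practice_in_history),
      seed = seed
    ),
    class = "session_config"
  )
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  cat("  condition:             ", x$condition, "\n")
  cat("  assigned predictivity: ", x$assigned_predictivity, "\n")
  cat(sprintf("  payoff ~ N(%g, %g), price ~ N(%g, %g), truncated at 1, integer-rounded\n",
              x$payoff_mean, x$payoff_sd, x$price_mean, x$price_sd))
  cat(sprintf("  rounds: %d practice + %d treatment + %d test\n",
              x$n_practice, x$n_treatment, x$n_test))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Read or write a session configuration as YAML
#'
#' Flat key-value YAML mirroring the fields of [session_config()].
#'
#' @param path File path.
#' @param config A `session_config` object.
#' @return `read_config()` returns a `session_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(session_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}
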