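# Truncated-normal sampler via the inverse CDF; exact, vectorised, no
# rejection loop. sd == 0 collapses to the (clamped) mean.
rnorm_trunc <- function(n, mean, sd, lower = 1) {
  if (sd == 0) return(rep(max(mean, lower), n))
  plo <- pnorm(lower, mean, sd)
  if (plo >= 1 - 1e-12) {
    stop("payoff/price distribution has essentially no mass above ", lower)
  }
  qnorm(runif(n, plo, 1), mean, sd)
}

#' Construct a single option
#'
#' One geometric option as shown on a choice screen: a shape of a given
#' area, sold at a price. Its payoff is the area minus the price, exactly.
#'
#' @param area Displayed area, positive (display units).
#' @param price Price in experimental currency units, nonnegative.
#' @param shape One of the six geometric shapes.
#' @param position Screen position: `"left"`, `"middle"` or `"right"`.
#' @param has_decoy,is_decoy,is_default,is_indicator Cue-role flags.
#' @return A one-row tibble with a derived `payoff` column.
#' @export
#' @examples
#' option_spec(area = 183, price = 53)$payoff  # 130
option_spec <- function(area, price, shape = "square", position = "left",
                        has_decoy = FALSE, is_decoy = FALSE,
                        is_default = FALSE, is_indicator = FALSE) {
  stopifnot(area > 0, price >= 0,
            shape %in% OPTION_SHAPES, position %in% OPTION_POSITIONS,
            !(has_decoy && is_decoy))
  tibble(
    shape = shape, area = as.numeric(area), price = as.numeric(price),
    payoff = as.numeric(area) - as.numeric(price),
    position = position,
    has_decoy = has_decoy, is_decoy = is_decoy,
    is_default = is_default, is_indicator = is_indicator
  )
}

#' Draw the three options of one round
#'
#' Three payoffs are drawn from the payoff distribution and ranked; a price
#' is then drawn for each option and the area set to payoff + price, so the
#' payoff identity holds by construction. Values are rounded to whole units
#' before ranking; rounds whose rounded payoffs tie are redrawn so that the
#' superior option is always unique.
#'
#' @param config A [session_config()].
#' @param max_tries Redraw attempts before giving up on breaking payoff
#'   ties (only reachable for degenerate payoff distributions).
#' @return A three-row tibble of options, ranked by payoff (best first),
#'   with a `rank` column and uniformly assigned screen positions.
#' @export
draw_option_set <- function(config, max_tries = 1000L) {
  stopifnot(inherits(config, "session_config"))
  m <- draw_attribute_matrices(config, n = 1L, max_tries = max_tries)
  ord <- order(m$payoff[1, ], decreasing = TRUE)
  tibble(
    rank = 1:3,
    shape = m$shape[1, ord],
    area = m$area[1, ord],
    price = m$price[1, ord],
    payoff = m$payoff[1, ord],
    position = OPTION_POSITIONS[ord],
    has_decoy = FALSE, is_decoy = FALSE,
    is_default = FALSE, is_indicator = FALSE
  )
}

# Vectorised attribute draw for n rounds: payoff, price, area and shape
# matrices with columns = screen positions (left, middle, right). Payoff
# ties within a round are resolved by redrawing that round's payoffs.
draw_attribute_matrices <- function(config, n, max_tries = 1000L) {
  payoff <- matrix(round(rnorm_trunc(n * 3L, config$payoff_mean, config$payoff_sd)),
                   nrow = n)
  tied <- which(payoff[, 1] == payoff[, 2] | payoff[, 1] == payoff[, 3] |
                  payoff[, 2] == payoff[, 3])
  tries <- 0L
  while (length(tied) > 0L) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not draw three distinct payoffs after ", max_tries,
           " attempts; payoff distribution is degenerate")
    }
    payoff[tied, ] <- round(rnorm_trunc(length(tied) * 3L,
                                        config$payoff_mean, config$payoff_sd))
    tied <- tied[payoff[tied, 1] == payoff[tied, 2] |
                   payoff[tied, 1] == payoff[tied, 3] |
                   payoff[tied, 2] == payoff[tied, 3]]
  }
  price <- matrix(round(rnorm_trunc(n * 3L, config$price_mean, config$price_sd)),
                  nrow = n)
  shape <- matrix(sample(OPTION_SHAPES, n * 3L, replace = TRUE), nrow = n)
  list(payoff = payoff, price = price, area = payoff + price, shape = shape)
}

#' Derive a dominated decoy from a target option
#'
#' The decoy keeps the source option's payoff but is dominated by the
#' target in both attributes: a randomised proportion `q` of the payoff
#' difference is added to the target's price to give the decoy's price, and
#' the remaining proportion is subtracted from the target's area to give
#' the decoy's area. The decoy takes the target's shape, which makes the
#' area comparison between the two easy.
#'
#' @param target The option that will have the decoy; must have the larger
#'   payoff.
#' @param source The option whose payoff the decoy inherits.
#' @param q Proportion in \[0, 1\] splitting the payoff difference between
#'   the price increase and the area decrease. Strictly interior `q` gives
#'   strict dominance in both attributes.
#' @return A one-row option tibble with `is_decoy = TRUE`, the source's
#'   position and payoff, and the target's shape.
#' @export
#' @examples
#' t <- option_spec(area = 10, price = 4)
#' s <- option_spec(area = 7, price = 5, position = "middle")
#' make_decoy(t, s, q = 0.5)  # area 8, price 6, payoff 2
make_decoy <- function(target, source, q) {
  stopifnot(is.numeric(q), length(q) == 1, q >= 0, q <= 1)
  if (target$payoff <= source$payoff) {
    stop("target payoff must exceed source payoff; the decoy could not be dominated")
  }
  delta <- target$payoff - source$payoff
  price <- target$price + q * delta
  area <- target$area - (1 - q) * delta
  tibble(
    shape = target$shape, area = area, price = price,
    payoff = area - price,
    position = source$position,
    has_decoy = FALSE, is_decoy = TRUE,
    is_default = FALSE, is_indicator = FALSE
  )
}
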