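#' Midpoint fractional ranks of grouped shares
#'
#' `R_t = sum(f[j < t]) + f[t] / 2`: the midpoint of each group's cumulative
#' population-share interval in the given order. Used by both the grouped
#' Gini and the concentration index.
#'
#' @param f Group shares summing to 1.
#' @return Fractional ranks in (0, 1).
#' @export
fractional_ranks <- function(f) {
  if (abs(sum(f) - 1) > 1e-9) {
    stop("shares must sum to 1, got ", sum(f))
  }
  cumsum(f) - f / 2
}

#' Gini health index of a death distribution
#'
#' Grouped-data Gini of age at death, in Wagstaff's general form
#' `Gini_H = 1 - (v / mu) * sum(f * h * (1 - R)^(v - 1))`
#' with `mu = sum(f * h)` the mean age at death (life expectancy at birth)
#' and `R` the midpoint fractional ranks after ordering the intervals from
#' early to late death. `v > 1` is the inequality-aversion parameter; `v = 2`
#' gives the classical Gini, for which the index equals half the mean
#' pairwise absolute difference in age at death divided by the mean. The
#' index is 0 when everyone dies at the same age.
#'
#' @param dist A [derive_death_distribution()] result, or any list with
#'   fields `f` (shares summing to 1) and `h` (ages at death).
#' @param v Inequality-aversion parameter, > 1 (default 2, the standard
#'   Gini).
#' @return The index, in \[0, 1).
#' @examples
#' gini_h(list(f = c(0.5, 0.5), h = c(40, 60)))  # 0.1
#' @export
gini_h <- function(dist, v = 2) {
  if (v <= 1) stop("inequality aversion v must exceed 1, got ", v)
  f <- dist$f
  h <- dist$h
  if (abs(sum(f) - 1) > 1e-9) stop("death shares must sum to 1")
  if (any(f < 0)) stop("death shares must be non-negative")
  if (is.unsorted(h)) {
    message("gini_h: intervals not ordered from early to late death; sorting")
    o <- order(h)  # stable
    f <- f[o]
    h <- h[o]
  }
  mu <- sum(f * h)
  if (mu <= 0) stop("mean age at death is zero; Gini undefined")
  R <- fractional_ranks(f)
  1 - (v / mu) * sum(f * h * (1 - R)^(v - 1))
}

#' Absolute length-of-life inequality (ALI)
#'
#' `ALI = 2 * LE * Gini_H`, in years: the expected absolute difference in
#' length of life between two randomly picked individuals. For `v = 2` this
#' equals the mean pairwise absolute difference of the death distribution
#' exactly.
#'
#' @param le Life expectancy at birth (years, > 0).
#' @param gini Gini health index in \[0, 1).
#' @return ALI in years.
#' @export
ali <- function(le, gini) {
  if (le <= 0) stop("life expectancy must be positive")
  if (gini < 0 || gini >= 1) stop("gini must lie in [0, 1)")
  2 * le * gini
}

#' Concentration index for socioeconomically ranked groups
#'
#' Grouped-data concentration index
#' `CI = (2 / mu) * sum(f * h * R) - 1`
#' with groups ordered by ascending socioeconomic position (worst-off
#' first), `f` their population shares, `h` the health outcome (here life
#' expectancy), `mu = sum(f * h)` and `R` the midpoint fractional ranks.
#' Equivalently twice the area between the concentration curve and the line
#' of equality; positive when the outcome concentrates among the best-off.
#' The ranking is an explicit input — it encodes socioeconomic position,
#' never the outcome itself.
#'
#' @param h Outcome per group (years).
#' @param f Population shares (default equal); must sum to 1.
#' @param rank Socioeconomic order, 1 = worst-off (default the given order).
#' @return The index, in (-1, 1).
#' @examples
#' concentration_index(c(53.4, 56.2, 60.6, 59.9, 62.5))  # 0.030
#' concentration_index(c(56.7, 59.9))                    # 0.014
#' @export
concentration_index <- function(h, f = rep(1 / length(h), length(h)),
                                rank = seq_along(h)) {
  if (length(h) != length(f) || length(h) != length(rank)) {
    stop("h, f and rank must have equal lengths")
  }
  if (abs(sum(f) - 1) > 1e-9) stop("shares must sum to 1, got ", sum(f))
  o <- order(rank)
  h <- h[o]
  f <- f[o]
  mu <- sum(f * h)
  if (mu <= 0) stop("mean outcome is zero; concentration index undefined")
  R <- fractional_ranks(f)
  (2 / mu) * sum(f * h * R) - 1
}

#' Absolute difference in an outcome between extreme groups
#'
#' Signed difference `h_top - h_bottom` (years); positive when the best-off
#' group lives longer.
#'
#' @param h_top Outcome of the best-off group.
#' @param h_bottom Outcome of the worst-off group.
#' @return Difference in years.
#' @export
absolute_difference <- function(h_top, h_bottom) {
  h_top - h_bottom
}
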