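# Independent oracles and fixture builders, deliberately naive:
# brute-force pairwise sums and trapezoidal areas, no shared code with the
# package's grouped formulas.

# mean pairwise absolute difference of a discrete distribution
brute_mean_abs_diff <- function(f, h) {
  s <- 0
  for (i in seq_along(h)) {
    for (j in seq_along(h)) {
      s <- s + f[i] * f[j] * abs(h[i] - h[j])
    }
  }
  s
}

# classical Gini as half the relative mean absolute difference
brute_gini <- function(f, h) {
  brute_mean_abs_diff(f, h) / (2 * sum(f * h))
}

# concentration index as twice the area between the line of equality and
# the trapezoidal concentration curve (groups already in rank order)
trapezoid_ci <- function(f, h) {
  mu <- sum(f * h)
  x <- c(0, cumsum(f))
  y <- c(0, cumsum(f * h) / mu)
  area <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  1 - 2 * area
}

# random discrete death distribution with k support points
random_death_dist <- function(k = 8, max_age = 100) {
  f <- rexp(k)
  f <- f / sum(f)
  h <- sort(runif(k, 0, max_age))
  list(f = f, h = h)
}

# qx for constant-hazard (exponential) mortality on a grid
exponential_qx <- function(rate, grid) {
  q <- 1 - exp(-rate * grid$width)
  q[!is.finite(grid$width)] <- 1
  q
}

# single-year grid 0..(max-1), open at max
fine_grid <- function(max_age = 110) {
  age_grid(0:max_age)
}
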