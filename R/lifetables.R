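#' Abridged age grid
#'
#' An age grid holds the lower bounds of abridged life-table age intervals
#' (years). All intervals are closed except the last, which is open-ended
#' (85+ by default).
#'
#' @param lower_bounds Strictly increasing interval lower bounds starting at 0.
#' @return An object of class `age_grid` with elements `lower` (bounds),
#'   `width` (interval widths; `Inf` for the open interval) and `k`
#'   (number of intervals).
#' @examples
#' g <- age_grid(c(0, 1, 5, 10))
#' g$width  # 1, 4, 5, Inf
#' @export
age_grid <- function(lower_bounds) {
  lower_bounds <- as.numeric(lower_bounds)
  if (length(lower_bounds) < 2) {
    stop("an age grid needs at least two intervals")
  }
  if (lower_bounds[1] != 0) {
    stop("first lower bound must be 0, got ", lower_bounds[1])
  }
  if (any(diff(lower_bounds) <= 0)) {
    stop("age grid lower bounds must be strictly increasing")
  }
  structure(
    list(
      lower = lower_bounds,
      width = c(diff(lower_bounds), Inf),
      k = length(lower_bounds)
    ),
    class = "age_grid"
  )
}

#' Default abridged age grid: 0, 1-4, then five-year bands to 85+
#'
#' @param max_age Lower bound of the open-ended terminal interval.
#' @return An [age_grid()] with intervals 0, 1-4, 5-9, ..., `max_age`+.
#' @export
default_age_grid <- function(max_age = 85) {
  age_grid(c(0, 1, seq(5, max_age, by = 5)))
}

#' Logit transform of a survivorship probability
#'
#' The Brass logit of survivorship, `Y = 0.5 * log((1 - l) / l)`. `Y` is
#' strictly decreasing in `l`: higher mortality (lower survivorship) maps to
#' larger `Y`.
#'
#' @param l Survivorship probabilities, all strictly inside (0, 1).
#' @return Logit values (real, unbounded).
#' @seealso [inverse_logit_survivorship()]
#' @examples
#' logit_survivorship(0.5)  # 0
#' inverse_logit_survivorship(logit_survivorship(0.73))  # 0.73
#' @export
logit_survivorship <- function(l) {
  bad <- !is.finite(l) | l <= 0 | l >= 1
  if (any(bad)) {
    stop("survivorship must lie strictly in (0, 1); offending value(s): ",
         paste(format(l[bad]), collapse = ", "))
  }
  0.5 * log((1 - l) / l)
}

#' @rdname logit_survivorship
#' @param y Logit values to map back to survivorship.
#' @export
inverse_logit_survivorship <- function(y) {
  1 / (1 + exp(2 * y))
}

#' Separation-factor (ax) rules
#'
#' An ax rule decides the mean years lived within each age interval by those
#' dying in it. Two named rules ship with the package:
#'
#' * `"demographic"` (default): infant interval `a0 = 0.07 + 1.7 * m0`
#'   (iterated, capped to \[0.01, 1\]), `a(1-4) = 1.361` for a 4-year second
#'   interval, `width/2` for the remaining closed intervals, and for the open
#'   interval `1 / m` with `m` extrapolated log-linearly from the last two
#'   closed-interval central death rates.
#' * `"midpoint"`: `width/2` for every closed interval, same open-interval
#'   treatment.
#'
#' A numeric vector of the grid's length can be passed wherever an ax rule is
#' accepted; it is used verbatim (its last entry is the open-interval ax,
#' i.e. remaining life expectancy at the terminal age).
#'
#' @param name `"demographic"` or `"midpoint"`.
#' @return An object of class `ax_rule`.
#' @export
ax_rule <- function(name = c("demographic", "midpoint")) {
  name <- match.arg(name)
  structure(list(name = name), class = "ax_rule")
}

# central death rate implied by (q, n, a): m = d/L with L = n(1-q) + a q
.qx_to_mx <- function(q, n, a) {
  q / (n * (1 - q) + a * q)
}

# open-interval ax = 1/m85 with m85 continued log-linearly from the last two
# closed intervals; keeps Sum(f*h) = e0 exact for any qx input
.open_interval_ax <- function(qx, widths, ax_closed) {
  k <- length(qx)
  iA <- k - 2L
  iB <- k - 1L
  mA <- .qx_to_mx(qx[iA], widths[iA], ax_closed[iA])
  mB <- .qx_to_mx(qx[iB], widths[iB], ax_closed[iB])
  m_open <- if (is.finite(mA) && is.finite(mB) && mA > 0 && mB > mA) {
    mB * (mB / mA)
  } else if (is.finite(mB) && mB > 0) {
    mB
  } else {
    1 # degenerate tail (no survivors reach the open interval)
  }
  min(max(1 / m_open, 0.25), 50)
}

.compute_ax <- function(rule, qx, grid) {
  if (is.numeric(rule)) {
    if (length(rule) != grid$k) {
      stop("numeric ax vector has length ", length(rule),
           " but the grid has ", grid$k, " intervals")
    }
    return(as.numeric(rule))
  }
  if (!inherits(rule, "ax_rule")) {
    stop("ax rule must be an `ax_rule` object or a numeric vector")
  }
  n <- grid$width
  ax <- n / 2
  if (rule$name == "demographic") {
    # infant separation: a0 depends on m0 which depends on a0; iterate
    a0 <- 0.3
    for (i in 1:25) {
      m0 <- .qx_to_mx(qx[1], n[1], a0)
      a0 <- min(max(0.07 + 1.7 * m0, 0.01), 1)
    }
    ax[1] <- a0 * n[1]
    if (grid$k >= 2 && is.finite(n[2]) && n[2] == 4) {
      ax[2] <- 1.361
    }
  }
  ax[grid$k] <- .open_interval_ax(qx, n, ax)
  ax
}

#' Build an abridged life table from conditional death probabilities
#'
#' Standard period life-table bookkeeping on an abridged grid with radix 1:
#' survivorship `lx` by forward recursion, deaths `dx`, person-years `Lx`
#' using the separation factors from `ax_rule`, and remaining life expectancy
#' `ex`. The final `qx` is forced to 1 (the last interval is open-ended), and
#' any interval after survivorship reaches 0 has `qx = 1`.
#'
#' @param qx Conditional death probabilities per interval, in \[0, 1\].
#' @param grid An [age_grid()]; lengths must match.
#' @param ax_rule An [ax_rule()] or a numeric ax vector.
#' @return An object of class `abridged_life_table` with fields `grid`, `qx`,
#'   `lx`, `dx`, `ax`, `Lx`, `Tx`, `ex`.
#' @examples
#' g <- default_age_grid()
#' lt <- build_life_table(rep(0.05, g$k), g)
#' life_expectancy(lt)
#' @export
build_life_table <- function(qx, grid, ax_rule = lifeineq::ax_rule()) {
  qx <- as.numeric(qx)
  if (length(qx) != grid$k) {
    stop("qx has length ", length(qx), " but the grid has ", grid$k,
         " intervals")
  }
  if (any(!is.finite(qx)) || any(qx < 0) || any(qx > 1)) {
    stop("qx values must lie in [0, 1]")
  }
  k <- grid$k
  qx[k] <- 1

  lx <- cumprod(c(1, 1 - qx[-k]))
  # zero-survivor tail: absorbing state, no division by zero
  qx[lx == 0] <- 1
  dx <- lx * qx
  dx[k] <- lx[k]

  ax <- .compute_ax(ax_rule, qx, grid)
  n <- grid$width
  lx_next <- c(lx[-1], 0)
  Lx <- n * lx_next + ax * dx
  Lx[k] <- ax[k] * lx[k]
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)

  structure(
    list(grid = grid, qx = qx, lx = lx, dx = dx, ax = ax,
         Lx = Lx, Tx = Tx, ex = ex),
    class = "abridged_life_table"
  )
}

#' @export
print.abridged_life_table <- function(x, ...) {
  cat("Abridged life table (radix 1):", x$grid$k, "age intervals, e0 =",
      format(round(x$ex[1], 2)), "years\n")
  print(utils::head(as.data.frame(x), 5), row.names = FALSE)
  if (x$grid$k > 5) cat("...", x$grid$k - 5, "more rows\n")
  invisible(x)
}

#' @export
as.data.frame.abridged_life_table <- function(x, ...) {
  data.frame(
    age = x$grid$lower,
    width = x$grid$width,
    qx = x$qx, lx = x$lx, dx = x$dx, ax = x$ax, ex = x$ex
  )
}

#' Life expectancy at birth of an abridged life table
#'
#' @param lt An [build_life_table()] result.
#' @return `e0` in years.
#' @export
life_expectancy <- function(lt) {
  stopifnot(inherits(lt, "abridged_life_table"))
  lt$ex[1]
}

#' Recover conditional death probabilities from a survivorship curve
#'
#' `qx[i] = 1 - lx[i+1] / lx[i]` while survivors remain; once survivorship
#' reaches 0 (and for the open-ended last interval) `qx = 1`.
#'
#' @param lx Non-increasing survivorship with `lx[1] = 1`.
#' @return Death probabilities of the same length.
#' @export
survivorship_to_qx <- function(lx) {
  lx <- as.numeric(lx)
  if (abs(lx[1] - 1) > 1e-12) {
    stop("survivorship must start at radix 1, got l0 = ", lx[1])
  }
  if (any(diff(lx) > 1e-12)) {
    stop("survivorship must be non-increasing")
  }
  if (any(lx < 0)) stop("survivorship cannot be negative")
  k <- length(lx)
  qx <- rep(1, k)
  alive <- lx[-k] > 0
  qx[-k][alive] <- 1 - lx[-1][alive] / lx[-k][alive]
  qx
}

#' Distribution of age at death implied by a life table
#'
#' The death distribution pairs each age interval's share of deaths
#' `f = dx` (radix 1, so `sum(f) = 1`) with its mean age at death
#' `h = lower_bound + ax`. Its mean `sum(f * h)` equals the life table's
#' life expectancy at birth.
#'
#' @param lt An abridged life table.
#' @return An object of class `death_distribution` with fields `h` (years)
#'   and `f` (proportions).
#' @export
derive_death_distribution <- function(lt) {
  stopifnot(inherits(lt, "abridged_life_table"))
  structure(
    list(h = lt$grid$lower + lt$ax, f = lt$dx),
    class = "death_distribution"
  )
}

#' @export
print.death_distribution <- function(x, ...) {
  cat("Death distribution:", length(x$f), "intervals, mean age at death",
      format(round(sum(x$f * x$h), 2)), "years\n")
  invisible(x)
}

#' Adult mortality (45q15) implied by a life table
#'
#' Probability of dying between exact ages 15 and 60 conditional on surviving
#' to 15: `1 - l(60) / l(15)`. Both ages must be interval bounds of the grid.
#'
#' @param lt An abridged life table whose grid contains ages 15 and 60.
#' @return A probability in \[0, 1\].
#' @export
adult_mortality_from_table <- function(lt) {
  stopifnot(inherits(lt, "abridged_life_table"))
  i15 <- match(15, lt$grid$lower)
  i60 <- match(60, lt$grid$lower)
  if (is.na(i15) || is.na(i60)) {
    stop("grid must contain ages 15 and 60 as interval bounds")
  }
  if (lt$lx[i15] <= 0) {
    stop("no survivors at age 15; 45q15 undefined")
  }
  1 - lt$lx[i60] / lt$lx[i15]
}

#' Write / read an abridged life table as CSV
#'
#' Columns `age, width, qx, lx, dx, ax, ex` with a `# radix=1` comment line.
#' The open interval's width is stored as the string `Inf`.
#'
#' @param lt Life table to write.
#' @param path File path.
#' @return `write_life_table` returns `path` invisibly; `read_life_table`
#'   returns an `abridged_life_table` rebuilt from the stored `qx` and `ax`
#'   (and checked against the stored `lx`).
#' @export
write_life_table <- function(lt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# radix=1", con)
  utils::write.csv(as.data.frame(lt), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_life_table
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  needed <- c("age", "qx", "ax")
  if (!all(needed %in% names(df))) {
    stop("life table CSV must have columns ", paste(needed, collapse = ", "))
  }
  lt <- build_life_table(df$qx, age_grid(df$age), ax_rule = df$ax)
  if ("lx" %in% names(df) && max(abs(lt$lx - df$lx)) > 1e-8) {
    stop("stored lx inconsistent with stored qx in ", path)
  }
  lt
}
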