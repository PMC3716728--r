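#' Standard survivorship schedule for the relational model
#'
#' A standard schedule anchors the Brass logit system: every fitted table is
#' a two-parameter transformation of this curve on the logit scale. The
#' optional per-age correction coefficient vectors `gamma` and `theta`
#' activate the modified-logit variant; both are identically zero by default
#' (plain Brass) and must vanish at the anchor ages 5 and 60 so those ages
#' are reproduced exactly.
#'
#' @param grid An [age_grid()].
#' @param ls Standard survivorship at each lower bound; `ls[1] = 1`, strictly
#'   decreasing, in (0, 1) beyond age 0.
#' @param gamma,theta Correction coefficients per age (default all 0).
#' @param label Provenance string.
#' @return An object of class `standard_schedule`.
#' @export
standard_schedule <- function(grid, ls, gamma = NULL, theta = NULL,
                              label = "unlabelled") {
  ls <- as.numeric(ls)
  if (length(ls) != grid$k) {
    stop("ls has length ", length(ls), " but the grid has ", grid$k,
         " intervals")
  }
  if (abs(ls[1] - 1) > 1e-12) stop("standard must have l(0) = 1")
  if (any(diff(ls) >= 0)) stop("standard survivorship must be strictly decreasing")
  if (any(ls[-1] <= 0) || any(ls[-1] >= 1)) {
    stop("standard survivorship must lie in (0, 1) beyond age 0")
  }
  if (is.null(gamma)) gamma <- rep(0, grid$k)
  if (is.null(theta)) theta <- rep(0, grid$k)
  stopifnot(length(gamma) == grid$k, length(theta) == grid$k)
  for (a in c(5, 60)) {
    i <- match(a, grid$lower)
    if (!is.na(i) && (gamma[i] != 0 || theta[i] != 0)) {
      stop("correction coefficients must be 0 at anchor age ", a)
    }
  }
  structure(
    list(grid = grid, ls = ls, gamma = as.numeric(gamma),
         theta = as.numeric(theta), label = label),
    class = "standard_schedule"
  )
}

#' @export
print.standard_schedule <- function(x, ...) {
  corrected <- any(x$gamma != 0) || any(x$theta != 0)
  cat("Standard schedule '", x$label, "': ", x$grid$k, " ages, corrections ",
      if (corrected) "active" else "off (plain Brass)", "\n", sep = "")
  invisible(x)
}

# Siler competing-hazard survival: infant hump a1*exp(-b1 x), background c,
# Gompertz senescence a3*exp(b3 x); cumulative hazard in closed form
siler_survival <- function(x, a1, b1, c, a3, b3) {
  exp(-(a1 / b1 * (1 - exp(-b1 * x)) + c * x + a3 / b3 * (exp(b3 * x) - 1)))
}

#' Built-in synthetic standard schedule
#'
#' A versioned, fully synthetic standard survivorship curve generated from a
#' Siler hazard (exponentially decaying infant mortality, constant background
#' mortality, Gompertz senescence), parameterized to a high-mortality shape
#' typical of low-income, high-fertility settings: substantial under-five
#' mortality, a deep survival plateau over working ages, and steep old-age
#' attrition. Used as the default anchor wherever a standard is needed;
#' any other standard can be supplied via [standard_schedule()] or
#' [read_standard_csv()].
#'
#' @param grid Age grid (default [default_age_grid()]).
#' @return A `standard_schedule` labelled `"siler-synthetic-v1"`.
#' @export
builtin_standard <- function(grid = default_age_grid()) {
  ls <- siler_survival(grid$lower,
                       a1 = 0.12, b1 = 1.2, c = 0.0018,
                       a3 = 5e-5, b3 = 0.105)
  standard_schedule(grid, ls, label = "siler-synthetic-v1")
}

#' Brass relational parameters
#'
#' `alpha` shifts the mortality level on the logit scale; `beta` tilts the
#' balance between child and adult mortality. `(0, 1)` reproduces the
#' standard exactly when corrections are zero.
#'
#' @param alpha Level parameter (real).
#' @param beta Shape parameter (> 0).
#' @return An object of class `brass_params`.
#' @export
brass_params <- function(alpha, beta) {
  if (!is.finite(beta) || beta <= 0) {
    stop("beta must be positive, got ", beta)
  }
  structure(list(alpha = alpha, beta = beta), class = "brass_params")
}

#' @export
print.brass_params <- function(x, ...) {
  cat(sprintf("Brass parameters: alpha = %.6f, beta = %.6f\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Fit targets: under-five and adult mortality
#'
#' @param q5 Under-five mortality 5q0, in (0, 1).
#' @param q45_15 Adult mortality 45q15, in (0, 1).
#' @return An object of class `fit_targets`.
#' @export
fit_targets <- function(q5, q45_15) {
  for (v in c(q5 = q5, q45_15 = q45_15)) {
    if (!is.finite(v) || v <= 0 || v >= 1) {
      stop("fit targets must lie strictly in (0, 1); got q5 = ", q5,
           ", q45_15 = ", q45_15)
    }
  }
  structure(list(q5 = q5, q45_15 = q45_15), class = "fit_targets")
}

#' Apply the relational model to a standard schedule
#'
#' Transforms the standard survivorship on the logit scale:
#' `Y(x) = alpha + beta * Ys(x) + gamma(x) * c5 + theta(x) * c60`,
#' where `Ys(x)` is the standard's logit survivorship and the deviations
#' `c5 = Y0(5) - Ys(5)`, `c60 = Y0(60) - Ys(60)` are computed from the
#' uncorrected relation `Y0 = alpha + beta * Ys`. With zero corrections this
#' is the plain two-parameter Brass system. Age 0 always has survivorship 1.
#'
#' @param params A [brass_params()].
#' @param std A [standard_schedule()].
#' @return The transformed survivorship vector `l(x)` over the grid.
#' @export
apply_relational_model <- function(params, std) {
  stopifnot(inherits(params, "brass_params"),
            inherits(std, "standard_schedule"))
  Ys <- logit_survivorship(std$ls[-1])
  Y0 <- params$alpha + params$beta * Ys

  dev_at <- function(a) {
    i <- match(a, std$grid$lower)
    if (is.na(i)) 0 else Y0[i - 1L] - Ys[i - 1L]
  }
  Y <- Y0 + std$gamma[-1] * dev_at(5) + std$theta[-1] * dev_at(60)
  lx <- c(1, inverse_logit_survivorship(Y))

  bad <- which(lx <= 0 | lx >= 1)
  bad <- bad[bad > 1]
  if (length(bad)) {
    stop("transformed survivorship outside (0, 1) at age ",
         std$grid$lower[bad[1]], ": ", format(lx[bad[1]]))
  }
  if (any(diff(lx) >= 0)) {
    i <- which(diff(lx) >= 0)[1]
    stop("transformed survivorship not decreasing between ages ",
         std$grid$lower[i], " and ", std$grid$lower[i + 1])
  }
  lx
}

#' Fit Brass parameters to (5q0, 45q15) targets
#'
#' For a given `beta`, `alpha` is closed-form from the age-5 anchor
#' (`alpha = logit(1 - q5) - beta * Ys(5)` in the uncorrected relation; the
#' correction coefficients vanish at the anchor ages, so the fitted curve
#' hits 5q0 exactly for any beta). `beta` is then found by a bracketed 1-D
#' root search (`stats::uniroot`) on the 45q15 residual, starting from the
#' bracket \[0.3, 3\] and expanding geometrically to at most \[0.05, 10\].
#'
#' @param targets A [fit_targets()].
#' @param std A [standard_schedule()].
#' @param tol Tolerance on both target probabilities (default 1e-8).
#' @param max_iter Maximum root-search iterations (default 200).
#' @return A [brass_params()] whose implied table reproduces both targets
#'   within `tol`.
#' @export
fit_brass_params <- function(targets, std, tol = 1e-8, max_iter = 200) {
  stopifnot(inherits(targets, "fit_targets"),
            inherits(std, "standard_schedule"))
  if (tol <= 0) stop("tol must be positive")
  i5 <- match(5, std$grid$lower)
  i15 <- match(15, std$grid$lower)
  i60 <- match(60, std$grid$lower)
  if (anyNA(c(i5, i15, i60))) {
    stop("standard grid must contain ages 5, 15 and 60")
  }
  Ys5 <- logit_survivorship(std$ls[i5])
  Y_target5 <- logit_survivorship(1 - targets$q5)

  implied_q45 <- function(beta) {
    alpha <- Y_target5 - beta * Ys5
    lx <- apply_relational_model(brass_params(alpha, beta), std)
    1 - lx[i60] / lx[i15]
  }
  resid <- function(beta) implied_q45(beta) - targets$q45_15
  # extreme betas can push a corrected curve out of its domain while
  # bracketing; treat those endpoints as unusable rather than fatal
  safe_resid <- function(beta) {
    tryCatch(resid(beta), error = function(e) NA_real_)
  }

  lo <- 0.3; hi <- 3
  r_lo <- safe_resid(lo); r_hi <- safe_resid(hi)
  while (is.na(r_lo) && lo < 1) { lo <- lo * 1.3; r_lo <- safe_resid(lo) }
  while (is.na(r_hi) && hi > 1) { hi <- hi / 1.3; r_hi <- safe_resid(hi) }
  if (is.na(r_lo) || is.na(r_hi)) {
    stop("relational model is invalid over the whole beta search range")
  }
  lo_open <- TRUE; hi_open <- TRUE
  while (sign(r_lo) == sign(r_hi) && (lo_open || hi_open)) {
    if (lo_open) {
      lo2 <- max(lo / 1.6, 0.05)
      r_lo2 <- safe_resid(lo2)
      if (!is.na(r_lo2)) { lo <- lo2; r_lo <- r_lo2 }
      lo_open <- !is.na(r_lo2) && lo > 0.05
    }
    if (hi_open) {
      hi2 <- min(hi * 1.6, 10)
      r_hi2 <- safe_resid(hi2)
      if (!is.na(r_hi2)) { hi <- hi2; r_hi <- r_hi2 }
      hi_open <- !is.na(r_hi2) && hi < 10
    }
  }
  if (sign(r_lo) == sign(r_hi)) {
    stop(sprintf(
      "no root for beta in [%.2f, %.2f]: 45q15 residual has sign %d at both ends",
      lo, hi, sign(r_lo)))
  }
  root <- stats::uniroot(resid, c(lo, hi), tol = .Machine$double.eps^0.75,
                         maxiter = max_iter)
  beta <- root$root
  params <- brass_params(Y_target5 - beta * Ys5, beta)

  lx <- apply_relational_model(params, std)
  r5 <- abs((1 - lx[i5]) - targets$q5)
  r45 <- abs((1 - lx[i60] / lx[i15]) - targets$q45_15)
  if (r5 > tol || r45 > tol) {
    stop(sprintf(
      "fit did not converge: |5q0 residual| = %.3g, |45q15 residual| = %.3g",
      r5, r45))
  }
  params
}

#' Model a group's abridged life table from its mortality targets
#'
#' Composition of [fit_brass_params()], [apply_relational_model()],
#' [survivorship_to_qx()] and [build_life_table()]: the resulting table
#' reproduces the group's 5q0 and 45q15 within `tol`.
#'
#' @inheritParams fit_brass_params
#' @param ax_rule Passed to [build_life_table()].
#' @return An `abridged_life_table` with the fitted `brass_params` attached
#'   as attribute `"params"`.
#' @export
model_group_life_table <- function(targets, std, ax_rule = lifeineq::ax_rule(),
                                   tol = 1e-8) {
  params <- fit_brass_params(targets, std, tol = tol)
  lx <- apply_relational_model(params, std)
  lt <- build_life_table(survivorship_to_qx(lx), std$grid, ax_rule = ax_rule)
  attr(lt, "params") <- params
  lt
}

#' Read a standard schedule from CSV
#'
#' Expected columns: `age`, `ls`, and optionally `gamma`, `theta`. The label
#' is taken from a `# label=...` comment line if present, else the file name.
#'
#' @param path CSV file path.
#' @return A [standard_schedule()].
#' @export
read_standard_csv <- function(path) {
  first <- readLines(path, n = 5)
  lab <- grep("^#\\s*label=", first, value = TRUE)
  label <- if (length(lab)) {
    sub("^#\\s*label=\\s*", "", lab[1])
  } else {
    sub("\\.csv$", "", basename(path))
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("age", "ls") %in% names(df))) {
    stop("standard CSV must have columns age, ls")
  }
  standard_schedule(age_grid(df$age), df$ls,
                    gamma = df$gamma, theta = df$theta, label = label)
}

#' Write a standard schedule to CSV
#'
#' @param std A [standard_schedule()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_standard_csv <- function(std, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# label=", std$label), con)
  utils::write.csv(
    data.frame(age = std$grid$lower, ls = std$ls,
               gamma = std$gamma, theta = std$theta),
    con, row.names = FALSE)
  invisible(path)
}
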