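test_that("logit transform evaluates the closed form and round-trips", {
  expect_identical(logit_survivorship(0.5), 0)
  expect_equal(logit_survivorship(0.9), 0.5 * log(1 / 9), tolerance = 1e-12)
  expect_equal(inverse_logit_survivorship(logit_survivorship(0.73)), 0.73,
               tolerance = 1e-12)
  # strictly decreasing in l
  l <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(logit_survivorship(l)) < 0))
  expect_error(logit_survivorship(1), "0, 1")
  expect_error(logit_survivorship(c(0.4, -0.2)), "-0.2")
})

test_that("age grid validates bounds and computes widths", {
  g <- age_grid(c(0, 1, 5, 10))
  expect_equal(g$width, c(1, 4, 5, Inf))
  expect_error(age_grid(c(1, 5)), "must be 0")
  expect_error(age_grid(c(0, 5, 5)), "strictly increasing")
})

test_that("a degenerate table with q0 = 1 puts all deaths in infancy", {
  g <- age_grid(c(0, 1, 5))
  lt <- build_life_table(c(1, 0.5, 1), g, ax_rule = c(0.3, 2, 5))
  expect_equal(lt$dx, c(1, 0, 0))
  expect_equal(life_expectancy(lt), 0.3)
  dd <- derive_death_distribution(lt)
  expect_equal(dd$f[1], 1)
  expect_equal(dd$h[1], 0.3)
})

test_that("exponential mortality recovers e0 = 1/rate on a fine grid", {
  for (rate in c(0.02, 0.05)) {
    g <- fine_grid(round(12 / rate))
    lt <- build_life_table(exponential_qx(rate, g), g,
                           ax_rule = ax_rule("midpoint"))
    expect_equal(life_expectancy(lt), 1 / rate, tolerance = 0.02)
    # 45q15 closed form for constant hazard
    expect_equal(adult_mortality_from_table(lt), 1 - exp(-45 * rate),
                 tolerance = 1e-9)
  }
})

test_that("every constructed table conserves deaths and person-years", {
  set.seed(42)
  g <- default_age_grid()
  for (rep in 1:25) {
    qx <- runif(g$k, 0.005, 0.35)
    lt <- build_life_table(qx, g)
    expect_equal(sum(lt$dx), 1, tolerance = 1e-12)
    dd <- derive_death_distribution(lt)
    expect_equal(sum(dd$f), 1, tolerance = 1e-12)
    expect_true(all(diff(dd$h) > 0))
    # mean age at death equals life expectancy at birth
    expect_equal(sum(dd$f * dd$h), life_expectancy(lt), tolerance = 1e-9)
    # ax within interval bounds for closed intervals
    closed <- is.finite(g$width)
    expect_true(all(lt$ax[closed] >= 0 & lt$ax[closed] <= g$width[closed]))
  }
})

test_that("raising any single qx never increases e0", {
  set.seed(7)
  g <- default_age_grid()
  qx <- runif(g$k, 0.01, 0.2)
  e0 <- life_expectancy(build_life_table(qx, g))
  for (i in seq_len(g$k - 1)) {
    qx2 <- qx
    qx2[i] <- min(qx2[i] + 0.1, 1)
    expect_lte(life_expectancy(build_life_table(qx2, g)), e0 + 1e-12)
  }
})

test_that("abridged e0 agrees with direct numerical integration", {
  # survival curve from a Gompertz-type hazard; integrate l(x) directly
  surv <- function(x) exp(-(0.01 * x + 1e-4 / 0.1 * (exp(0.1 * x) - 1)))
  g <- fine_grid(120)
  lx <- surv(g$lower)
  lt <- build_life_table(survivorship_to_qx(lx), g,
                         ax_rule = ax_rule("midpoint"))
  direct <- stats::integrate(surv, 0, 200, rel.tol = 1e-10)$value
  expect_equal(life_expectancy(lt), direct, tolerance = 0.1 / direct)
})

test_that("survivorship converts to qx and round-trips through the table", {
  expect_equal(survivorship_to_qx(c(1, 0.9, 0.81)), c(0.1, 0.1, 1),
               tolerance = 1e-12)
  # zero tail is absorbed without division by zero
  expect_equal(survivorship_to_qx(c(1, 0.4, 0, 0)), c(0.6, 1, 1, 1))
  expect_error(survivorship_to_qx(c(1, 0.5, 0.6)), "non-increasing")
  expect_error(survivorship_to_qx(c(0.9, 0.5)), "radix")

  set.seed(11)
  g <- default_age_grid()
  qx <- runif(g$k, 0.01, 0.3)
  lt <- build_life_table(qx, g)
  expect_equal(build_life_table(survivorship_to_qx(lt$lx), g)$lx, lt$lx,
               tolerance = 1e-12)
})

test_that("hand-computed two-interval table matches the bookkeeping", {
  g <- age_grid(c(0, 1))
  lt <- build_life_table(c(0.2, 1), g, ax_rule = c(0.5, 10))
  expect_equal(lt$lx, c(1, 0.8))
  expect_equal(lt$dx, c(0.2, 0.8))
  expect_equal(life_expectancy(lt), 0.9 + 8)  # Lx = (0.8 + 0.1, 10 * 0.8)
  dd <- derive_death_distribution(lt)
  expect_equal(dd$h, c(0.5, 11))
  expect_equal(sum(dd$f * dd$h), 8.9)
})

test_that("adult mortality is the survivorship ratio between 15 and 60", {
  g <- default_age_grid()
  lt <- build_life_table(rep(0.04, g$k), g)
  i15 <- match(15, g$lower); i60 <- match(60, g$lower)
  expect_equal(adult_mortality_from_table(lt),
               1 - lt$lx[i60] / lt$lx[i15], tolerance = 1e-12)
  # no adult mortality when lx flat: splice a synthetic lx
  lx <- lt$lx
  lx[i15:i60] <- lx[i15]
  lt2 <- build_life_table(survivorship_to_qx(lx), g)
  expect_equal(adult_mortality_from_table(lt2), 0, tolerance = 1e-12)
  expect_error(adult_mortality_from_table(
    build_life_table(rep(0.1, 4), age_grid(c(0, 1, 5, 10)))), "15 and 60")
})

test_that("life tables round-trip through CSV with the radix comment", {
  g <- default_age_grid()
  lt <- build_life_table(runif(g$k, 0.01, 0.2), g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_life_table(lt, path)
  expect_identical(readLines(path, n = 1), "# radix=1")
  lt2 <- read_life_table(path)
  expect_equal(lt2$lx, lt$lx, tolerance = 1e-9)
  expect_equal(life_expectancy(lt2), life_expectancy(lt), tolerance = 1e-9)
})
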