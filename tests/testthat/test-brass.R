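test_that("(alpha, beta) = (0, 1) reproduces the standard exactly", {
  std <- builtin_standard()
  lx <- apply_relational_model(brass_params(0, 1), std)
  expect_identical(lx[1], 1)
  expect_equal(lx, std$ls, tolerance = 1e-14)
})

test_that("alpha shifts every logit by the same amount", {
  std <- builtin_standard()
  lx <- apply_relational_model(brass_params(-0.2, 1), std)
  shift <- logit_survivorship(lx[-1]) - logit_survivorship(std$ls[-1])
  expect_equal(shift, rep(-0.2, std$grid$k - 1), tolerance = 1e-10)
})

test_that("transformed survivorship is strictly decreasing for any (alpha, beta)", {
  std <- builtin_standard()
  set.seed(3)
  for (i in 1:50) {
    lx <- apply_relational_model(
      brass_params(runif(1, -0.6, 0.6), runif(1, 0.6, 1.4)), std)
    expect_true(all(diff(lx) < 0))
    expect_true(all(lx[-1] > 0 & lx[-1] < 1))
  }
})

test_that("beta must be positive", {
  expect_error(brass_params(0, -1), "positive")
  expect_error(brass_params(0, 0), "positive")
})

test_that("fitting the standard's own targets returns the identity", {
  std <- builtin_standard()
  lt <- build_life_table(survivorship_to_qx(std$ls), std$grid)
  tg <- fit_targets(1 - std$ls[match(5, std$grid$lower)],
                    adult_mortality_from_table(lt))
  p <- fit_brass_params(tg, std)
  expect_equal(p$alpha, 0, tolerance = 1e-7)
  expect_equal(p$beta, 1, tolerance = 1e-7)
  lt2 <- model_group_life_table(tg, std)
  expect_equal(lt2$lx, lt$lx, tolerance = 1e-7)
})

test_that("known (alpha, beta) targets are recovered by refitting", {
  std <- builtin_standard()
  truth <- brass_params(-0.25, 1.15)
  lx <- apply_relational_model(truth, std)
  lt <- build_life_table(survivorship_to_qx(lx), std$grid)
  tg <- fit_targets(1 - lx[match(5, std$grid$lower)],
                    adult_mortality_from_table(lt))
  p <- fit_brass_params(tg, std)
  expect_equal(p$alpha, truth$alpha, tolerance = 1e-6)
  expect_equal(p$beta, truth$beta, tolerance = 1e-6)
  lt2 <- model_group_life_table(tg, std)
  expect_equal(life_expectancy(lt2), life_expectancy(lt), tolerance = 0.01)
})

test_that("the fitted table hits both anchors within tolerance", {
  std <- builtin_standard()
  tg <- fit_targets(0.0829, 0.24)
  lt <- model_group_life_table(tg, std)
  expect_equal(1 - lt$lx[match(5, std$grid$lower)], 0.0829,
               tolerance = 1e-8)
  expect_equal(adult_mortality_from_table(lt), 0.24, tolerance = 1e-8)
})

test_that("e0 responds monotonically to both mortality targets", {
  std <- builtin_standard()
  e0 <- function(q5, q45) {
    life_expectancy(model_group_life_table(fit_targets(q5, q45), std))
  }
  e_q5 <- vapply(seq(0.05, 0.2, length.out = 5), e0, numeric(1), q45 = 0.25)
  expect_true(all(diff(e_q5) < 0))
  e_q45 <- vapply(seq(0.15, 0.4, length.out = 5), function(q) e0(0.09, q),
                  numeric(1))
  expect_true(all(diff(e_q45) < 0))
})

test_that("correction coefficients anchor ages 5 and 60 and are pluggable", {
  g <- default_age_grid()
  base <- builtin_standard(g)
  gamma <- 0.06 * sin(seq(0, pi, length.out = g$k))
  theta <- 0.04 * cos(seq(0, pi, length.out = g$k))
  gamma[match(c(5, 60), g$lower)] <- 0
  theta[match(c(5, 60), g$lower)] <- 0
  std <- standard_schedule(g, base$ls, gamma = gamma, theta = theta,
                           label = "corrected")
  # identity still holds at (0, 1): both deviations vanish
  expect_equal(apply_relational_model(brass_params(0, 1), std), std$ls,
               tolerance = 1e-14)
  # fitted tables still hit both anchors exactly despite the corrections
  tg <- fit_targets(0.11, 0.3)
  lt <- model_group_life_table(tg, std)
  expect_equal(1 - lt$lx[match(5, g$lower)], 0.11, tolerance = 1e-8)
  expect_equal(adult_mortality_from_table(lt), 0.3, tolerance = 1e-8)
  # and the corrected curve differs from the plain-Brass one off-anchor
  p <- attr(lt, "params")
  plain <- apply_relational_model(p, base)
  expect_gt(max(abs(plain - lt$lx)), 1e-6)

  expect_error(
    standard_schedule(g, base$ls, gamma = rep(0.1, g$k)), "anchor age")
})

test_that("standard schedules round-trip through CSV with their label", {
  std <- builtin_standard()
  path <- withr::local_tempfile(fileext = ".csv")
  write_standard_csv(std, path)
  std2 <- read_standard_csv(path)
  expect_equal(std2$ls, std$ls, tolerance = 1e-12)
  expect_identical(std2$label, std$label)
})

test_that("an unreachable beta bracket is reported, not silently clipped", {
  std <- builtin_standard()
  # absurdly low adult mortality given high child mortality: no beta in
  # [0.05, 10] can reconcile the two
  expect_error(fit_brass_params(fit_targets(0.4, 0.001), std), "residual|root")
})
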