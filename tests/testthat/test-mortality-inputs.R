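residence_groups <- function() {
  group_spec(c("rural", "urban"), rank = c(1, 2),
             pop_share = c(0.832, 0.168), u5_ratio = c(1.373, 1))
}

test_that("the correction factor normalizes share-weighted ratios to 1", {
  single <- group_spec("all", rank = 1, pop_share = 1, u5_ratio = 1)
  expect_equal(correction_factor(single), 1)

  expect_equal(round(correction_factor(residence_groups()), 3), 0.763)

  set.seed(5)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    share <- rexp(k); share <- share / sum(share)
    g <- group_spec(paste0("g", 1:k), rank = 1:k, pop_share = share,
                    u5_ratio = runif(k, 0.5, 2))
    x <- correction_factor(g)
    expect_equal(sum(g$pop_share * g$u5_ratio * x), 1, tolerance = 1e-12)
  }
})

test_that("group adult mortality scales the national rate by ratio and x", {
  g <- residence_groups()
  x <- correction_factor(g)
  expect_equal(round(group_adult_mortality(0.2739, g[1, ], x), 3), 0.287)
  # identity when the group is the whole population
  expect_equal(group_adult_mortality(0.2739, 1, 1), 0.2739)
  expect_error(group_adult_mortality(0.9, 1.5, 1), "outside")
  expect_error(group_adult_mortality(-0.1, 1, 1), "positive")
})

test_that("per-group estimates preserve the national rate on average", {
  set.seed(9)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    share <- rexp(k); share <- share / sum(share)
    g <- group_spec(paste0("g", 1:k), rank = 1:k, pop_share = share,
                    q5 = runif(k, 0.03, 0.2))
    national <- runif(1, 0.15, 0.35)
    est <- estimate_group_adult_mortality(g, national)
    expect_equal(sum(est$pop_share * est$q45_15), national,
                 tolerance = 1e-12)
    # best-off (highest rank) group is the ratio reference
    expect_equal(est$u5_ratio[which.max(est$rank)], 1)
  }
})

test_that("under-five ratios are taken relative to the best-off group", {
  g <- group_spec(c("rural", "urban"), rank = c(1, 2),
                  pop_share = c(0.7, 0.3), q5 = c(0.1373, 0.1))
  g <- derive_u5_ratios(g)
  expect_equal(g$u5_ratio, c(1.373, 1), tolerance = 1e-12)
})

test_that("group validation rejects malformed inputs", {
  expect_error(group_spec("a", 1, 0.9), "sum to 1")
  expect_error(group_spec(c("a", "b"), c(1, 1), c(0.5, 0.5)), "distinct")
  expect_error(
    group_spec(c("a", "b"), c(1, 2), c(0.5, 0.5), u5_ratio = c(1, -2)),
    "positive")
})

test_that("sex combination mixes schedules on the central-rate scale", {
  g <- default_age_grid()
  qm <- rep(0.08, g$k)
  qf <- rep(0.05, g$k)
  # identical schedules are invariant to the share
  expect_equal(combine_sexes(qm, qm, 0.3, g), build_life_table(qm, g)$qx,
               tolerance = 1e-12)
  # boundary shares return the single-sex schedule exactly
  expect_identical(combine_sexes(qm, qf, 0, g), qf)
  expect_identical(combine_sexes(qm, qf, 1, g), qm)

  # a 50/50 mix of central rates 0.02 and 0.04 is rate 0.03 at every age
  n <- g$width[is.finite(g$width)]
  q_of_m <- function(m) n * m / (1 + n * m / 2)
  qm2 <- c(q_of_m(0.02), 1)
  qf2 <- c(q_of_m(0.04), 1)
  mixed <- combine_sexes(qm2, qf2, 0.5, g)
  m_back <- mixed[is.finite(g$width)] /
    (n * (1 - mixed[is.finite(g$width)] / 2))
  expect_equal(m_back, rep(0.03, length(n)), tolerance = 1e-12)
  expect_equal(mixed[g$k], 1)

  expect_error(combine_sexes(qm[-1], qf, 0.5, g), "matching lengths")
  expect_error(combine_sexes(qm, qf, 1.2, g), "male_share")
})

test_that("group CSVs are read and validated", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,rank,pop_share,q5",
               "rural,1,0.832,0.1373",
               "urban,2,0.168,0.1"), path)
  g <- read_groups_csv(path)
  expect_equal(nrow(g), 2)
  expect_equal(correction_factor(derive_u5_ratios(g)),
               1 / (1.373 * 0.832 + 0.168), tolerance = 1e-12)
})
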