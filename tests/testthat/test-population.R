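test_that("percentile thresholds follow type-7 interpolation", {
  ctl <- data.frame(mci = 1:100, volume_um3 = 1:100)
  th <- percentile_thresholds(ctl)
  expect_equal(th$q10_mci, 10.9)
  expect_equal(th$q90_mci, 90.1)
  expect_equal(th$q10_vol, 10.9)
  expect_equal(th$q90_vol, 90.1)

  # thresholds do not depend on ordering
  shuf <- ctl[sample(nrow(ctl)), ]
  expect_equal(percentile_thresholds(shuf)$q10_mci, th$q10_mci)

  expect_error(percentile_thresholds(ctl[1:5, ]), "at least")
  const <- data.frame(mci = rep(2, 50), volume_um3 = rep(1, 50))
  expect_error(percentile_thresholds(const), "degenerate")
})

test_that("the control pool classifies exactly 10% simple by construction", {
  set.seed(9)
  n <- 500  # distinct values, multiple of 10
  ctl <- data.frame(mci = rlnorm(n), volume_um3 = rlnorm(n),
                    subject_id = rep(sprintf("s%d", 1:5), each = n / 5),
                    group = "control")
  th <- percentile_thresholds(ctl)
  cl <- classify_population(ctl, th)
  expect_equal(mean(cl$simple), 0.10)
  expect_equal(mean(cl$complex), 0.10)
  expect_equal(mean(cl$small), 0.10)
  expect_equal(mean(cl$large), 0.10)
  # simple and complex are disjoint; per-subject percentages sum sanely
  expect_false(any(cl$simple & cl$complex))
  bs <- attr(cl, "by_subject")
  expect_true(all(bs$pct_simple >= 0 & bs$pct_simple <= 100))

  # a value exactly at the threshold is NOT simple (strict inequality)
  at <- data.frame(mci = th$q10_mci, volume_um3 = th$q10_vol)
  cat_ <- classify_population(at, th)
  expect_false(cat_$simple)
  expect_false(cat_$small)
})

test_that("classification is invariant to joint unit change", {
  set.seed(10)
  ctl <- data.frame(mci = rlnorm(200), volume_um3 = rlnorm(200))
  th <- percentile_thresholds(ctl)
  cl1 <- classify_population(ctl, th)
  scaled <- ctl
  scaled$volume_um3 <- ctl$volume_um3 * 1000  # um^3 -> nm^3 style change
  th2 <- th
  th2$q10_vol <- th$q10_vol * 1000
  th2$q90_vol <- th$q90_vol * 1000
  cl2 <- classify_population(scaled, th2)
  expect_identical(cl1$small, cl2$small)
  expect_identical(cl1$large, cl2$large)
})

test_that("a disease cohort built with 46% sub-q10 mass classifies near 46%", {
  co <- generate_cohort(cohort_spec(seed = 21))
  m <- co$metrics
  th <- percentile_thresholds(m[m$group == "control", ])
  cl <- classify_population(m, th)
  bg <- attr(cl, "by_group")
  simple_dis <- bg$pct_simple[bg$group == "disease"]
  # six subjects' random effects dominate the sampling error
  expect_gt(simple_dis, 30)
  expect_lt(simple_dis, 62)
  expect_equal(bg$pct_simple[bg$group == "control"], 10,
               tolerance = 0.01)
})

test_that("nested CVs follow their definitions and scale invariance", {
  # constant cell: CV 0
  r0 <- suppressWarnings(
    cv_levels(c(10, 10, 10, 1, 3), rep("p1", 5),
              c("a", "a", "a", "b", "b")))
  expect_equal(r0$within_cell$cv[r0$within_cell$cell == "a"], 0)

  # two cells with means 1 and 3: between-cell CV = sd/mean ~ 70.7%
  v <- c(0.5, 1.5, 2.5, 3.5)
  r1 <- cv_levels(v, rep("p1", 4), c("a", "a", "b", "b"))
  expect_equal(r1$between_cell$cv[1], sd(c(1, 3)) / 2,
               tolerance = 1e-12)

  # CV is scale invariant at every level
  set.seed(2)
  vals <- rlnorm(120)
  subj <- rep(c("p1", "p2"), each = 60)
  cell <- rep(rep(c("a", "b", "c"), each = 20), 2)
  a <- cv_levels(vals, subj, cell)
  b <- cv_levels(vals * 37.5, subj, cell)
  expect_equal(a$within_cell$cv, b$within_cell$cv)
  expect_equal(a$between_cell$cv, b$between_cell$cv)
  expect_equal(a$between_person, b$between_person)

  expect_warning(cv_levels(c(1, 2, 3), c("p", "p", "p"),
                           c("a", "a", "b")), "excluded")
})

test_that("hierarchical generator CVs are recovered at study scale", {
  # lognormal hierarchy: within-cell CV 100%, cell 25%, person 40%
  sdw <- sqrt(log(2)); sdc <- sqrt(log(1.0625)); sdp <- sqrt(log(1.16))
  cv_of <- function(s) sqrt(exp(s^2) - 1)
  draws <- function(seed) {
    set.seed(seed)
    subj <- rep(sprintf("p%d", 1:8), each = 150)
    cell <- rep(rep(c("a", "b", "c"), each = 50), 8)
    bp <- rnorm(8, 0, sdp)[rep(1:8, each = 150)]
    bc <- rnorm(24, 0, sdc)[rep(1:24, each = 50)]
    data.frame(v = exp(bp + bc + rnorm(1200, 0, sdw)),
               subj = subj, cell = cell)
  }
  est <- sapply(1:6, function(s) {
    d <- draws(s)
    r <- cv_levels(d$v, d$subj, d$cell)
    c(within = mean(r$within_cell$cv),
      person = r$between_person)
  })
  expect_lt(abs(mean(est["within", ]) - cv_of(sdw)) / cv_of(sdw), 0.20)
  expect_lt(abs(mean(est["person", ]) - cv_of(sdp)) / cv_of(sdp), 0.35)
})

test_that("volume density is a guarded percentage", {
  expect_equal(volume_density(26, 1000), 2.6)
  expect_equal(volume_density(40, 1000), 4.0)
  expect_equal(volume_density(numeric(), 1000), 0)
  expect_error(volume_density(2000, 1000), "exceeds")
  expect_error(volume_density(1, 0), "positive")
})

test_that("distribution moments match known distributions", {
  set.seed(4)
  z <- rnorm(1e5)
  mz <- distribution_moments(z)
  expect_equal(mz$skewness, 0, tolerance = 0.05)
  expect_equal(mz$kurtosis, 3, tolerance = 0.1)
  expect_equal(distribution_moments(z, kurtosis = "excess")$kurtosis,
               mz$kurtosis - 3)

  ex <- rexp(1e5)
  expect_equal(distribution_moments(ex)$skewness, 2, tolerance = 0.1)

  expect_error(distribution_moments(c(1, 2, 3)), "at least 4")
})

test_that("the CDF table enumerates sorted value-fraction pairs", {
  cdf <- cumulative_distribution(c(3, 1, 2))
  expect_equal(cdf$value, c(1, 2, 3))
  expect_equal(cdf$fraction, c(1, 2, 3) / 3)
  # duplicated values collapse to their final fraction
  cdf2 <- cumulative_distribution(c(1, 1, 2))
  expect_equal(cdf2$fraction, c(2 / 3, 1))
})

test_that("cohort summaries assemble the eight signature features", {
  co <- generate_cohort(cohort_spec(seed = 30))
  m <- co$metrics
  th <- percentile_thresholds(m[m$group == "control", ])
  summ <- cohort_summaries(m, th,
                           density = data.frame(
                             subject_id = unique(m$subject_id),
                             volume_density_pct = 2.6),
                           nanotunnel_counts = co$nanotunnel_counts)
  expect_equal(nrow(summ), 14L)
  expect_true(all(c("pct_simple", "nanotunnels_per_100",
                    "volume_density_pct") %in% names(summ)))
  expect_false(anyNA(summ$nanotunnels_per_100))
  # disease subjects carry far more nanotunnels per 100
  agg <- tapply(summ$nanotunnels_per_100, summ$group, mean)
  expect_gt(agg["disease"] / agg["control"], 5)
})
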