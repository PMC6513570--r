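test_that("Mann-Whitney exact p matches enumeration on small samples", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3)
  expect_equal(r$method, "exact")

  # identical samples: p = 1 by symmetry
  expect_equal(mann_whitney(c(5, 6, 7), c(5, 6, 7))$p, 1)

  # against the tie-free reference implementation
  set.seed(8)
  for (i in 1:12) {
    x <- round(rnorm(sample(2:5, 1)), 4)
    y <- round(rnorm(sample(2:5, 1)) + 0.3, 4)
    ours <- mann_whitney(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney handles ties and large samples", {
  # ties: exact enumeration remains valid
  x <- c(1, 2, 2); y <- c(2, 3)
  r <- mann_whitney(x, y)
  expect_equal(r$method, "exact")
  expect_gte(r$p, 0); expect_lte(r$p, 1)

  # large shifted lognormals separate decisively
  set.seed(5)
  a <- rlnorm(150, 0, 0.5); b <- rlnorm(150, 1, 0.5)
  big <- mann_whitney(a, b)
  expect_equal(big$method, "normal")
  expect_lt(big$p, 0.001)
  # tie-corrected normal approximation tracks the reference
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(big$p, ref$p.value, tolerance = 1e-6)

  expect_error(mann_whitney(numeric(), 1), "non-empty")
})

test_that("chi-square on proportions is Pearson's statistic", {
  m <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  r <- chi_square_proportions(m)
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(r$df, 1)

  # observed == expected: statistic 0, p 1
  e <- matrix(c(10, 20, 20, 40), 2)
  r0 <- chi_square_proportions(e)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1)

  # invariant to row/column permutation
  m3 <- matrix(c(40, 51, 9, 55, 30, 15), 2, byrow = TRUE)
  r1 <- chi_square_proportions(m3)
  r2 <- chi_square_proportions(m3[2:1, c(3, 1, 2)])
  expect_equal(r1$statistic, r2$statistic)

  expect_error(chi_square_proportions(matrix(c(0, 0, 5, 5), 2)),
               "pool")
})

test_that("branching class counts separate cohorts at reported mixes", {
  set.seed(14)
  # control vs mouse class mixes from sizable synthetic counts
  ctl <- as.vector(rmultinom(1, 973, c(0.404, 0.506, 0.091)))
  mou <- as.vector(rmultinom(1, 600, c(0.547, 0.302, 0.151)))
  r <- chi_square_proportions(rbind(ctl, mou))
  expect_equal(r$df, 2)
  expect_lt(r$p, 0.001)
})

test_that("variance components degenerate gracefully", {
  # all values identical: every SD is 0 (the optimizer grumbles on the
  # degenerate flat likelihood)
  f <- suppressWarnings(
    nested_variance_components(rep(5, 60),
                               rep(c("a", "b"), each = 30),
                               rep(rep(c("x", "y", "z"), each = 10),
                                   2)))
  expect_equal(f$sd_person, 0, tolerance = 1e-8)
  expect_equal(f$sd_cell, 0, tolerance = 1e-8)
  expect_equal(f$sd_within, 0, tolerance = 1e-8)

  # one cell per subject: the cell component is inestimable
  set.seed(1)
  f1 <- nested_variance_components(rlnorm(40),
                                   rep(c("a", "b"), each = 20),
                                   rep("c1", 40))
  expect_true(is.na(f1$sd_cell))
  expect_match(f1$method, "person-only")
})

test_that("REML matches the balanced-design ANOVA decomposition", {
  set.seed(77)
  ns <- 6; nc <- 4; nr <- 25
  subj <- rep(sprintf("p%d", 1:ns), each = nc * nr)
  cell <- rep(rep(sprintf("c%d", 1:nc), each = nr), ns)
  y <- exp(rnorm(ns, 0, 0.3)[rep(1:ns, each = nc * nr)] +
             rnorm(ns * nc, 0, 0.2)[rep(1:(ns * nc), each = nr)] +
             rnorm(ns * nc * nr, 0, 0.8))
  fit <- nested_variance_components(y, subj, cell)
  # independent oracle: expected-mean-squares estimates for the balanced
  # two-level nested design
  ly <- log(y)
  cellkey <- paste(subj, cell)
  ms <- anova(stats::aov(ly ~ factor(subj) + factor(cellkey)))
  msp <- ms$`Mean Sq`[1]; msc <- ms$`Mean Sq`[2]; mse <- ms$`Mean Sq`[3]
  var_cell <- max((msc - mse) / nr, 0)
  var_person <- max((msp - msc) / (nc * nr), 0)
  expect_equal(fit$sd_within, sqrt(mse), tolerance = 0.02)
  expect_equal(fit$sd_cell, sqrt(var_cell), tolerance = 0.05)
  expect_equal(fit$sd_person, sqrt(var_person), tolerance = 0.05)
})

test_that("doubling within-cell noise doubles the residual SD", {
  gen <- function(sdw, seed) {
    set.seed(seed)
    subj <- rep(sprintf("p%d", 1:8), each = 150)
    cell <- rep(rep(c("a", "b", "c"), each = 50), 8)
    exp(rnorm(8, 0, 0.28)[rep(1:8, each = 150)] +
          rnorm(24, 0, 0.14)[rep(1:24, each = 50)] +
          rnorm(1200, 0, sdw))
  }
  subj <- rep(sprintf("p%d", 1:8), each = 150)
  cell <- rep(rep(c("a", "b", "c"), each = 50), 8)
  f1 <- nested_variance_components(gen(0.4, 2), subj, cell)
  f2 <- nested_variance_components(gen(0.8, 2), subj, cell)
  expect_equal(f2$sd_within / f1$sd_within, 2, tolerance = 0.1)
})

test_that("a group fixed effect is estimated alongside the components", {
  set.seed(6)
  subj <- rep(sprintf("p%d", 1:8), each = 60)
  cell <- rep(rep(c("a", "b"), each = 30), 8)
  grp <- ifelse(as.integer(sub("p", "", subj)) <= 4, "control",
                "disease")
  shift <- ifelse(grp == "disease", -0.5, 0)
  y <- exp(shift + rnorm(8, 0, 0.2)[rep(1:8, each = 60)] +
             rnorm(480, 0, 0.6))
  f <- nested_variance_components(y, subj, cell, group = grp)
  expect_lt(abs(unname(f$fixed_effect) - (-0.5)),
            3 * unname(f$fixed_se) + 0.05)
  expect_gt(unname(f$fixed_se), 0)
})
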