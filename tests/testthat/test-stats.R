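test_that("identical groups give zero between-group F", {
  y <- matrix(rep(c(1, 2, 3), each = 8), 8, 3)
  y <- y + matrix(rnorm(24, sd = 0.5), 8, 3)  # subject noise, same both groups
  y2 <- rbind(y, y)
  des <- rm_design(y2, rep(c("A", "B"), each = 8))
  an <- rm_anova(des)
  expect_equal(an$between$statistic, 0, tolerance = 1e-12)
})

test_that("df structure matches the mixed design: N = 32, d = 3 gives (2, 60)", {
  set.seed(14)
  des <- rm_design(matrix(rnorm(96), 32, 3), rep(c("A", "B"), c(20, 12)))
  an <- rm_anova(des)
  expect_equal(c(an$within$df1, an$within$df2), c(2, 60))
  expect_equal(c(an$between$df1, an$between$df2), c(1, 30))
  expect_equal(c(an$interaction$df1, an$interaction$df2), c(2, 60))
})

test_that("F values match stats::aov Error() strata on random designs", {
  set.seed(20)
  for (rep in 1:10) {
    n1 <- sample(3:9, 1); n2 <- sample(3:9, 1); d <- sample(2:5, 1)
    y <- matrix(rnorm((n1 + n2) * d, sd = runif(1, 0.5, 3)), n1 + n2, d)
    g <- rep(c("A", "B"), c(n1, n2))
    an <- rm_anova(rm_design(y, g))
    long <- data.frame(v = as.vector(y), subj = factor(rep(seq_len(n1 + n2), d)),
                       day = factor(rep(seq_len(d), each = n1 + n2)),
                       g = factor(rep(g, d)))
    av <- summary(stats::aov(v ~ g * day + Error(subj), data = long))
    expect_equal(an$between$statistic, av[[1]][[1]]["g", "F value"],
                 tolerance = 1e-9)
    expect_equal(an$within$statistic, av[[2]][[1]]["day", "F value"],
                 tolerance = 1e-9)
    expect_equal(an$interaction$statistic, av[[2]][[1]]["g:day", "F value"],
                 tolerance = 1e-9)
  }
})

test_that("listwise deletion drops incomplete subjects and enforces group minima", {
  y <- matrix(rnorm(24), 8, 3)
  y[1, 2] <- NA
  des <- rm_design(y, rep(c("A", "B"), each = 4))
  expect_equal(nrow(des$y), 7)
  y[2, 1] <- NA; y[3, 3] <- NA
  expect_error(rm_design(y, rep(c("A", "B"), each = 4)),
               "at least 2 complete subjects")
})

test_that("Mauchly: d = 2 is always spherical; matches stats::mauchly.test", {
  set.seed(8)
  m <- mauchly_test(matrix(rnorm(40), 20, 2))
  expect_equal(m$W, 1)
  expect_equal(m$p, 1)
  Y <- matrix(rnorm(120), 30, 4)
  got <- mauchly_test(Y)
  ref <- stats::mauchly.test(stats::lm(Y ~ 1), X = ~1)
  expect_equal(got$W, unname(ref$statistic), tolerance = 1e-10)
  # stats::mauchly.test adds a higher-order series term to the chi-square
  expect_equal(got$p, ref$p.value, tolerance = 5e-3)
})

test_that("Mauchly type-I error is near nominal under compound symmetry", {
  set.seed(301)
  n <- 30; d <- 4; rho <- 0.4
  S <- matrix(rho, d, d); diag(S) <- 1
  L <- chol(S)
  rej <- mean(vapply(1:600, function(i) {
    y <- matrix(rnorm(n * d), n, d) %*% L
    mauchly_test(y)$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("Mauchly detects strong AR(1) non-sphericity", {
  set.seed(302)
  n <- 30; d <- 4; rho <- 0.9
  S <- rho^abs(outer(1:d, 1:d, "-"))
  L <- chol(S)
  rej <- mean(vapply(1:200, function(i) {
    y <- matrix(rnorm(n * d), n, d) %*% L
    mauchly_test(y)$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.5)
})

test_that("Bonferroni post hocs adjust per-day p-values with a cap, gated on interaction", {
  set.seed(33)
  d <- 3
  y <- matrix(rnorm(48), 16, d)
  y[9:16, 3] <- y[9:16, 3] + 4  # strong group difference on day 3 only
  des <- rm_design(y, rep(c("A", "B"), each = 8))
  an <- rm_anova(des)
  expect_lt(an$interaction$p, 0.05)
  ph <- bonferroni_posthoc(des)
  expect_length(ph, d)
  for (r in ph) {
    expect_equal(r$adjusted_p, min(1, r$p * d))
    expect_gte(r$adjusted_p, r$p)
    expect_lte(r$adjusted_p, 1)
  }
  # gating: without a significant interaction the call must refuse
  y0 <- matrix(rnorm(48), 16, d)
  des0 <- rm_design(y0, rep(c("A", "B"), each = 8))
  p0 <- rm_anova(des0)$interaction$p
  if (p0 >= 0.05) expect_error(bonferroni_posthoc(des0), "significant interaction")
  expect_error(bonferroni_posthoc(des, interaction_p = 0.5),
               "significant interaction")
})

test_that("pooled t from printed summaries reproduces the morphometric tests", {
  r1 <- pooled_t_from_summary(27.14, 0.64, 23, 30.12, 0.92, 21)
  expect_equal(abs(r1$statistic), 2.701, tolerance = 0.01 * 2.701)
  expect_equal(r1$df1, 42)
  expect_lt(r1$p, 0.011)  # printed summaries are rounded
  r2 <- pooled_t_from_summary(28.12, 0.91, 12, 32.79, 1.35, 9)
  expect_equal(abs(r2$statistic), 2.970, tolerance = 0.01 * 2.970)
  expect_equal(r2$df1, 19)
  r0 <- pooled_t_from_summary(5, 0.3, 10, 5, 0.3, 10)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  expect_error(pooled_t_from_summary(1, 0.1, 1, 2, 0.1, 5), "n >= 2")
})

test_that("summary and raw-data t tests agree exactly; permutation p agrees approximately", {
  set.seed(40)
  for (rep in 1:10) {
    x1 <- rnorm(sample(5:15, 1), mean = runif(1, -1, 1))
    x2 <- rnorm(sample(5:15, 1), mean = runif(1, -1, 1))
    a <- pooled_t_from_data(x1, x2)
    b <- pooled_t_from_summary(mean(x1), sd(x1) / sqrt(length(x1)), length(x1),
                               mean(x2), sd(x2) / sqrt(length(x2)), length(x2))
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    # and the classical equal-variance t.test as an independent route
    ref <- stats::t.test(x1, x2, var.equal = TRUE)
    expect_equal(a$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(a$p, ref$p.value, tolerance = 1e-12)
  }
  expect_equal(pooled_t_from_data(c(1, 2, 3), c(1, 2, 3))$statistic, 0)

  # permutation oracle at n = 10 + 10
  set.seed(41)
  x1 <- rnorm(10, 0.8); x2 <- rnorm(10)
  t_obs <- abs(pooled_t_from_data(x1, x2)$statistic)
  pooled <- c(x1, x2)
  perm <- replicate(4000, {
    idx <- sample(20, 10)
    abs(pooled_t_from_data(pooled[idx], pooled[-idx])$statistic)
  })
  p_perm <- mean(perm >= t_obs)
  expect_lt(abs(p_perm - pooled_t_from_data(x1, x2)$p), 0.04)
})

test_that("mean_sem uses the sample sd over sqrt(n)", {
  expect_equal(mean_sem(c(1, 2, 3)), c(mean = 2, sem = sd(1:3) / sqrt(3)))
  expect_equal(unname(mean_sem(c(4, 4, 4, 4))["sem"]), 0)
  expect_equal(unname(mean_sem(3 * c(1, 2, 3))["mean"]), 3 * 2)
  expect_error(mean_sem(c(1)), "at least 2")
})

test_that("significance markers follow the legend thresholds", {
  expect_equal(sig_stars(c(0.2, 0.04, 0.009, 0.0009, 0.00009)),
               c("ns", "*", "**", "***", "****"))
})
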