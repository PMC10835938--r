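test_that("geometric mean and CI follow the log-scale t construction", {
  g <- geometric_mean_ci(c(1, 1, 1))
  expect_equal(g$geometric_mean, 1)
  expect_equal(g$ci_low, 1)
  expect_equal(g$ci_high, 1)

  g2 <- geometric_mean_ci(c(exp(0), exp(2)))
  expect_equal(g2$geometric_mean, exp(1), tolerance = 1e-12)

  set.seed(5)
  x <- exp(rnorm(40, -2.4, 1.2))
  g3 <- geometric_mean_ci(x)
  oracle <- gm_ci_oracle(x)
  expect_equal(g3$geometric_mean, unname(oracle["gm"]), tolerance = 1e-12)
  expect_equal(g3$ci_low, unname(oracle["lo"]), tolerance = 1e-12)
  expect_equal(g3$ci_high, unname(oracle["hi"]), tolerance = 1e-12)
  expect_true(g3$ci_low < g3$geometric_mean && g3$geometric_mean < g3$ci_high)

  expect_error(geometric_mean_ci(c(1, 0)), "positive")
})

test_that("pooled geometric mean is the size-weighted log-scale mean", {
  expect_equal(pooled_geometric_mean(0.7, 12), 0.7)
  expect_equal(pooled_geometric_mean(c(4, 9), c(10, 10)), 6, tolerance = 1e-12)
  expect_error(pooled_geometric_mean(numeric(0), integer(0)), "at least one")
})

test_that("percent change converts ratios to signed percentages", {
  expect_equal(percent_change(1), 0)
  expect_equal(percent_change(2), 100)
  expect_equal(percent_change(0.653), -34.7)
})

test_that("stepwise selection keeps real covariates and drops noise", {
  set.seed(101)
  n <- 120
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 2 * x1 + rnorm(n, sd = 0.3)
  sel <- stepwise_covariates(y, data.frame(x1 = x1, x2 = x2))
  expect_identical(sel$selected, "x1")

  # duplicated candidate columns cannot both enter
  sel_dup <- stepwise_covariates(y, data.frame(x1 = x1, x1_copy = x1))
  expect_length(sel_dup$selected, 1L)

  expect_warning(
    sel_const <- stepwise_covariates(y, data.frame(x1 = x1, cc = rep(1, n))),
    "constant")
  expect_identical(sel_const$selected, "x1")
})

test_that("under the null the selected set is empty at about the nominal rate", {
  set.seed(2024)
  n_rep <- 150
  empty <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    n <- 60
    cand <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    y <- rnorm(n)
    empty[r] <- length(stepwise_covariates(y, cand)$selected) == 0L
  }
  # three independent candidates screened at 0.05 each: P(empty) ~ 0.95^3
  expect_gt(mean(empty), 0.75)
  expect_lt(mean(empty), 0.98)
})

test_that("LSD contrasts back-transform to geometric-mean ratios", {
  d <- data.frame(phenotype = c("gIM", "gIM", "gNM", "gNM"),
                  value = c(2, 2, 1, 1) * exp(c(-0.1, 0.1, -0.1, 0.1)))
  out <- anova_lsd_contrasts(d, "value")
  expect_equal(out$ratio[out$phenotype == "gIM"], 2, tolerance = 1e-12)
  expect_equal(out$ratio[out$phenotype == "gNM"], 1)

  # reference-cohort gUM vs gNM means reproduce the published ratio
  d2 <- two_group_cohort(0.0889, 0.0580, n_a = 20, n_b = 20)
  out2 <- anova_lsd_contrasts(d2, "value")
  expect_equal(out2$ratio[out2$phenotype == "gUM"], 0.653, tolerance = 0.01)
  expect_true(out2$ratio_low[2] < out2$ratio[2],)
  expect_true(out2$ratio_high[2] > out2$ratio[2])
})

test_that("a two-group LSD contrast equals the pooled-variance t-test", {
  set.seed(77)
  d <- data.frame(phenotype = rep(c("gNM", "gIM"), c(15, 12)),
                  value = exp(c(rnorm(15, 0, 0.5), rnorm(12, 0.4, 0.5))))
  out <- anova_lsd_contrasts(d, "value")
  tt <- t.test(log(value) ~ phenotype == "gNM", data = d, var.equal = TRUE)
  expect_equal(out$p_value[out$phenotype == "gIM"], tt$p.value,
               tolerance = 1e-10)
})

test_that("covariate adjustment changes the contrast when a covariate is confounded", {
  set.seed(9)
  n <- 60
  ph <- rep(c("gNM", "gIM"), each = n / 2)
  sexv <- c(rbinom(n / 2, 1, 0.2), rbinom(n / 2, 1, 0.8))
  logy <- 0.5 * (ph == "gIM") + 0.8 * sexv + rnorm(n, sd = 0.3)
  d <- data.frame(phenotype = ph, value = exp(logy), sex = sexv)
  raw <- anova_lsd_contrasts(d, "value")
  adj <- anova_lsd_contrasts(d, "value", covariates = "sex")
  expect_false(isTRUE(all.equal(raw$ratio[raw$phenotype == "gIM"],
                                adj$ratio[adj$phenotype == "gIM"])))
  expect_equal(adj$ratio[adj$phenotype == "gIM"], exp(0.5), tolerance = 0.15)
})

test_that("scaling all values leaves ratios, p-values and percent changes unchanged", {
  set.seed(13)
  d <- data.frame(phenotype = rep(c("gNM", "gIM", "gPM"), c(20, 15, 6)),
                  value = exp(rnorm(41, -2, 1)))
  a <- anova_lsd_contrasts(d, "value")
  d$value <- d$value * 123.4
  b <- anova_lsd_contrasts(d, "value")
  expect_equal(a$ratio, b$ratio, tolerance = 1e-10)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-10)
  expect_equal(b$gm, a$gm * 123.4, tolerance = 1e-10)
  expect_equal(summary(a)$percent_change, summary(b)$percent_change,
               tolerance = 1e-10)
})

test_that("contrasts require the reference class and at least two classes", {
  d <- data.frame(phenotype = rep("gIM", 5), value = exp(rnorm(5)))
  expect_error(anova_lsd_contrasts(d, "value"), "reference")
  d2 <- data.frame(phenotype = rep("gNM", 5), value = exp(rnorm(5)))
  expect_error(anova_lsd_contrasts(d2, "value"), "two phenotype classes")
})
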