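test_that("AUROC equals the tie-aware rank statistic", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.4), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(3, 2, 1), c(1, 0, 1)), 0.5)
  expect_equal(auroc(c(1, 1), c(1, 0)), 0.5)
  expect_error(auroc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUROC matches brute-force pair enumeration on random small sets", {
  set.seed(314)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    labels <- c(0, 1, rbinom(max(n - 2, 0), 1, 0.5))[seq_len(max(n, 2))]
    scores <- sample(seq_len(5), length(labels), replace = TRUE)  # heavy ties
    expect_equal(auroc(scores, labels), auroc_bruteforce(scores, labels))
  }
})

test_that("average precision follows threshold enumeration and its baseline is prevalence", {
  expect_equal(aupr(c(3, 2, 1), c(1, 1, 0))$auprc, 1)
  expect_equal(aupr(c(2, 1), c(0, 1))$auprc, 0.5)
  expect_equal(aupr(c(3, 2, 1), c(1, 0, 1))$auprc, 1 * 0.5 + (2 / 3) * 0.5)
  expect_equal(aupr(rep(1, 205), c(rep(1, 9), rep(0, 196)))$baseline,
               9 / 205)
})

test_that("F1max maximizes the harmonic mean over all thresholds", {
  expect_equal(f1_max(c(3, 2, 1), c(1, 1, 0)), 1)
  expect_equal(f1_max(c(3, 2, 1), c(1, 0, 1)), 0.8)
  # predicting everything positive is always available:
  # F1 at the lowest threshold is 2 prev / (1 + prev)
  set.seed(8)
  labels <- rbinom(40, 1, 0.3)
  labels[1:2] <- c(0, 1)
  scores <- rnorm(40)
  prev <- mean(labels)
  expect_gte(f1_max(scores, labels) + 1e-12, 2 * prev / (1 + prev))
})

test_that("perfect separation yields the full bundle of ones", {
  scores <- c(5, 4.5, 4, 1, 0.9, 0.2)
  labels <- c(1, 1, 1, 0, 0, 0)
  expect_equal(auroc(scores, labels), 1)
  expect_equal(aupr(scores, labels)$auprc, 1)
  expect_equal(f1_max(scores, labels), 1)
})

test_that("metrics are invariant to strictly increasing score transforms", {
  set.seed(21)
  scores <- rnorm(50)
  labels <- rbinom(50, 1, 0.4)
  labels[1:2] <- c(0, 1)
  for (f in list(function(x) 2 * x + 3, function(x) exp(x),
                 function(x) rank(x, ties.method = "average"))) {
    expect_equal(auroc(f(scores), labels), auroc(scores, labels))
    expect_equal(aupr(f(scores), labels)$auprc, aupr(scores, labels)$auprc)
    expect_equal(f1_max(f(scores), labels), f1_max(scores, labels))
  }
})

test_that("orientation flips make low-scoring target classes rank high", {
  scores <- c(0.1, 0.2, 5, 6)
  labels <- c(1, 1, 0, 0)
  expect_equal(auroc(orient_scores(scores, "low"), labels), 1)
  expect_equal(auroc(scores, labels), 0)
})

test_that("stratified bootstrap CIs are reproducible and degenerate when the metric is", {
  scores <- c(5, 4, 3, 1, 0.5)
  labels <- c(1, 1, 1, 0, 0)  # perfectly separated: AUROC constant 1
  ci <- bootstrap_ci(scores, labels, auroc, B = 200, seed = 9)
  expect_equal(ci$ci_low, 1)
  expect_equal(ci$ci_high, 1)

  set.seed(3)
  s <- rnorm(30); l <- rbinom(30, 1, 0.5); l[1:2] <- c(0, 1)
  a <- bootstrap_ci(s, l, auroc, B = 150, seed = 42)
  b <- bootstrap_ci(s, l, auroc, B = 150, seed = 42)
  expect_identical(a$replicates, b$replicates)
  expect_true(a$ci_low <= a$estimate && a$estimate <= a$ci_high)
})

test_that("evaluate_biomarker bundles metrics, baseline, and CIs coherently", {
  set.seed(4)
  scores <- c(rnorm(12, 2), rnorm(30, 0))
  labels <- rep(c(1, 0), c(12, 30))
  perf <- evaluate_biomarker(scores, labels, B = 100, seed = 2)
  expect_equal(perf$baseline_auprc, 12 / 42)
  expect_gte(perf$auprc, perf$baseline_auprc)
  expect_true(perf$ci$auroc$ci_low <= perf$auroc)
  expect_output(print(perf), "baseline AUPRC")
})

test_that("self-comparison gives zero delta, covering CI and p near 1", {
  set.seed(6)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4); labels[1:2] <- c(0, 1)
  cmp <- compare_to_reference(scores, scores, labels, B = 100, seed = 5)
  expect_equal(cmp$delta$auroc, 0)
  expect_equal(cmp$delta$auprc, 0)
  expect_true(cmp$ci$auroc[1] <= 0 && 0 <= cmp$ci$auroc[2])
  expect_equal(cmp$p_value_auroc, 1)
})

test_that("comparison deltas are anti-symmetric", {
  set.seed(10)
  a <- rnorm(36); b <- rnorm(36)
  labels <- rbinom(36, 1, 0.4); labels[1:2] <- c(0, 1)
  ab <- compare_to_reference(a, b, labels, B = 50, seed = 1)
  ba <- compare_to_reference(b, a, labels, B = 50, seed = 1)
  expect_equal(ab$delta$auroc, -ba$delta$auroc)
  expect_equal(ab$delta$auprc, -ba$delta$auprc)
  expect_equal(ab$p_value_auroc, ba$p_value_auroc, tolerance = 1e-12)
})

test_that("the correlated-ROC test agrees with an independent implementation", {
  set.seed(12)
  n <- 80
  labels <- rep(c(1, 0), c(30, 50))
  latent <- labels + rnorm(n)
  cand <- latent + rnorm(n, sd = 0.5)
  ref <- latent + rnorm(n, sd = 1.5)
  cmp <- compare_to_reference(cand, ref, labels, B = 50, seed = 1)
  oracle <- pROC::roc.test(
    pROC::roc(labels, cand, quiet = TRUE, direction = "<"),
    pROC::roc(labels, ref, quiet = TRUE, direction = "<"),
    method = "delong", paired = TRUE)
  expect_equal(cmp$p_value_auroc, oracle$p.value, tolerance = 1e-8)
})
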