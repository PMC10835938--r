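make_dosages <- function(n, m, seed = 1) {
  set.seed(seed)
  maf <- runif(m, 0.1, 0.5)
  G <- vapply(maf, function(p) rbinom(n, 2, p), numeric(n))
  colnames(G) <- paste0("v", seq_len(m))
  G
}

test_that("a noiseless endpoint recovers its variant with beta 1 and vanishing p", {
  G <- make_dosages(100, 5, seed = 2)
  y <- G[, "v3"]
  scan <- association_scan(G, y)
  expect_equal(scan$beta[scan$id == "v3"], 1, tolerance = 1e-10)
  expect_lt(scan$p_value[scan$id == "v3"], 1e-100)
  expect_true(scan$significant[scan$id == "v3"])
})

test_that("the covariate-free scan equals per-variant simple regression", {
  G <- make_dosages(80, 12, seed = 3)
  set.seed(4)
  y <- 0.3 * G[, 1] + rnorm(80)
  scan <- association_scan(G, y)
  for (j in seq_len(ncol(G))) {
    fit <- summary(lm(y ~ G[, j]))$coefficients
    expect_equal(scan$beta[j], fit[2, "Estimate"], tolerance = 1e-10)
    expect_equal(scan$se[j], fit[2, "Std. Error"], tolerance = 1e-10)
    expect_equal(scan$p_value[j], fit[2, "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("the covariate-adjusted scan equals the joint least-squares fit", {
  G <- make_dosages(90, 6, seed = 5)
  set.seed(6)
  covs <- data.frame(sex = rbinom(90, 1, 0.5), logbw = rnorm(90, 4.2, 0.2))
  y <- 0.4 * G[, 2] + 0.5 * covs$sex + rnorm(90)
  scan <- association_scan(G, y, covariates = covs)
  for (j in seq_len(ncol(G))) {
    fit <- summary(lm(y ~ G[, j] + covs$sex + covs$logbw))$coefficients
    expect_equal(scan$beta[j], fit[2, "Estimate"], tolerance = 1e-10)
    expect_equal(scan$se[j], fit[2, "Std. Error"], tolerance = 1e-10)
    expect_equal(scan$p_value[j], fit[2, "Pr(>|t|)"], tolerance = 1e-10)
  }
  expect_error(association_scan(G, y, covariates = cbind(covs, dup = covs$sex)),
               "rank deficient")
})

test_that("monomorphic and missing variants are skipped with reasons, others mean-imputed", {
  G <- make_dosages(60, 4, seed = 7)
  G[, 2] <- 1                 # monomorphic
  G[1:10, 3] <- NA            # partially missing
  G_allna <- cbind(G, v5 = NA_real_)
  set.seed(8)
  y <- rnorm(60)
  scan <- association_scan(G_allna, y)
  expect_true(scan$skipped[scan$id == "v2"])
  expect_identical(scan$reason[scan$id == "v2"], "monomorphic")
  expect_true(scan$skipped[scan$id == "v5"])
  expect_identical(scan$reason[scan$id == "v5"], "all dosages missing")
  expect_false(scan$skipped[scan$id == "v3"])
  # mean imputation oracle
  g3 <- G_allna[, 3]
  g3[is.na(g3)] <- mean(g3, na.rm = TRUE)
  fit <- summary(lm(y ~ g3))$coefficients
  expect_equal(scan$beta[scan$id == "v3"], fit[2, "Estimate"], tolerance = 1e-10)
})

test_that("null p-values are uniform", {
  G <- make_dosages(300, 2000, seed = 9)
  set.seed(10)
  y <- rnorm(300)   # independent of every variant
  scan <- association_scan(G, y)
  ks <- ks.test(scan$p_value[!scan$skipped], "punif")
  expect_gt(ks$p.value, 0.01)
  expect_false(any(scan$significant, na.rm = TRUE))
})

test_that("LD r2 is symmetric, unit on self and allele flips, and near zero for independents", {
  a <- c(0, 1, 2, 1, 0, 2, 1)
  b <- c(2, 1, 0, 1, 2, 0, 1)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(a, b), 1)          # b = 2 - a: sign-free
  expect_equal(ld_r2(a, b), ld_r2(b, a))
  expect_error(ld_r2(a, rep(1, 7)), "monomorphic")

  set.seed(11)
  x <- rbinom(10000, 2, 0.3)
  z <- rbinom(10000, 2, 0.4)
  expect_lt(ld_r2(x, z), 0.01)
})

test_that("conditioning on the causal variant removes the signal; an unrelated one does not", {
  set.seed(12)
  n <- 300
  causal <- rbinom(n, 2, 0.25)
  proxy <- causal
  flip <- sample(n, 25)
  proxy[flip] <- rbinom(25, 2, 0.25)
  G <- cbind(causal = causal, proxy = proxy, make_dosages(n, 50, seed = 13))
  y <- 0.8 * causal + rnorm(n)
  scan <- association_scan(G, y)
  top <- scan$id[which.min(scan$p_value)]
  expect_true(top %in% c("causal", "proxy"))

  cond <- conditional_scan(G, y, adjust_for = "causal")
  expect_false("causal" %in% cond$id)   # the adjusting variant is skipped
  expect_false(any(cond$significant, na.rm = TRUE))

  cond_far <- conditional_scan(G, y, adjust_for = "v37")
  expect_identical(cond_far$id[which.min(cond_far$p_value)], top)

  expect_error(conditional_scan(G, y, adjust_for = "nope"), "not found")
  Gm <- G; Gm[, "v1"] <- 0
  expect_error(conditional_scan(Gm, y, adjust_for = "v1"), "monomorphic")
})

test_that("GT fields in a VCF convert to ALT-allele dosages", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "22\t1000\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "22\t2000\t.\tC\tT\t.\tPASS\t.\tGT\t0|1\t./.\t1|1")
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  out <- read_vcf_dosages(path)
  expect_equal(dim(out$dosages), c(3L, 2L))
  expect_equal(unname(out$dosages[, "rs1"]), c(0, 1, 2))
  expect_equal(unname(out$dosages[, "22:2000"]), c(1, NA, 2))
  expect_equal(out$variant_info$pos, c(1000L, 2000L))
  unlink(path)
})

test_that("manhattan export carries chromosome, position, and -log10 p", {
  G <- make_dosages(50, 3, seed = 14)
  set.seed(15)
  y <- rnorm(50)
  info <- data.frame(id = colnames(G), chr = "22", pos = c(100L, 200L, 300L))
  scan <- association_scan(G, y, variant_info = info)
  md <- manhattan_data(scan)
  expect_identical(names(md), c("chr", "pos", "neg_log10_p"))
  expect_equal(md$neg_log10_p, -log10(scan$p_value[!scan$skipped]))
})
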