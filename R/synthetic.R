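#' Back out a log-scale SD from a geometric mean's confidence interval
#'
#' Published group summaries report only a geometric mean and its 95% CI.
#' On the log scale the CI half-width is z * sigma / sqrt(n), so
#' sigma = sqrt(n) * ln(ci_high / ci_low) / (2 z). The normal quantile
#' (z = 1.96 at 95%) is used rather than a t quantile: the result is a
#' calibration heuristic for the generator, not an estimate with sampling
#' error attached.
#'
#' @param n Group size (>= 2).
#' @param ci_low,ci_high Positive CI bounds, `ci_high >= ci_low`.
#' @param level Confidence level of the interval, default 0.95.
#' @return Log-scale standard deviation (0 for a degenerate interval).
#' @examples
#' backout_log_sd(196, 0.0746, 0.106)  # ~1.255
#' @export
backout_log_sd <- function(n, ci_low, ci_high, level = 0.95) {
  stopifnot(n >= 2, ci_low > 0, ci_high >= ci_low)
  z <- stats::qnorm(1 - (1 - level) / 2)
  sqrt(n) * log(ci_high / ci_low) / (2 * z)
}

#' Generator configuration calibrated to the reference cohort
#'
#' Defaults emulate the study conditions of the reference cohort: four
#' phenotype groups of 9/89/196/20 subjects; per-endpoint, per-group
#' lognormal distributions with geometric means from [reference_summary()]
#' and log-SDs backed out of the printed CIs; solanidine LLOQ 0.01 ng/mL
#' with per-ion metabolite response LLOQs (see [censoring_rules()]); sex
#' Bernoulli(0.5); bodyweight lognormal around 69.7 kg (SD 12.1 kg); study
#' period Bernoulli(0.5); an illustrative diplotype table consistent with
#' each class; NFIB rs28379954 carriage at ~8.7% (17 of 196 gNM in the
#' reference cohort); and a SNP panel with one causal no-function variant
#' plus LD proxies.
#'
#' @param group_sizes Named integer vector of subjects per phenotype class.
#' @param endpoints Data frame like [reference_summary()] giving `endpoint`,
#'   `phenotype`, `n`, `gm`, `ci_low`, `ci_high` (sigma is backed out per
#'   row) - or the same with an explicit `sigma` column.
#' @param rules A [censoring_rules()] object.
#' @param nfib_freq Carrier probability of the NFIB variant.
#' @param n_variants Total SNP-panel size for [simulate_dosages()].
#' @param proxy_r2 Numeric vector of target r-squared values for LD proxies
#'   of the causal variant.
#' @param log_cor Optional log-scale correlation between solanidine and each
#'   metabolite ratio within a subject (default 0: drawn independently; the
#'   joint correlation is not published).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(gPM = 9L, gIM = 89L,
                                          gNM = 196L, gUM = 20L),
                          endpoints = reference_summary(),
                          rules = censoring_rules(),
                          nfib_freq = 17 / 196,
                          n_variants = 2000L,
                          proxy_r2 = c(0.68, 0.84, 0.58),
                          log_cor = 0) {
  stopifnot(all(group_sizes >= 0), all(endpoints$gm > 0),
            log_cor >= -1, log_cor <= 1)
  if (!"sigma" %in% names(endpoints))
    endpoints$sigma <- mapply(backout_log_sd, endpoints$n,
                              endpoints$ci_low, endpoints$ci_high)
  stopifnot(all(endpoints$sigma >= 0))
  diplotypes <- list(
    gPM = c("*4/*4"),
    gIM = c("*1/*4", "*4/*41"),
    gNM = c("*1/*1", "*1/*41"),
    gUM = c("*1x2/*1")
  )
  structure(list(group_sizes = group_sizes, endpoints = endpoints,
                 rules = rules, nfib_freq = nfib_freq,
                 diplotypes = diplotypes,
                 bodyweight = list(mean = 69.7, sd = 12.1),
                 n_variants = as.integer(n_variants),
                 proxy_r2 = proxy_r2, log_cor = log_cor),
            class = "cohort_config")
}

endpoint_param <- function(cfg, endpoint, phenotype, what) {
  e <- cfg$endpoints
  i <- which(e$endpoint == endpoint & e$phenotype == phenotype)
  if (length(i) != 1L)
    stop("no generator calibration for ", endpoint, " in class ", phenotype)
  e[[what]][i]
}

#' Simulate a phenotyped biomarker cohort
#'
#' Draws, per subject: a diplotype consistent with the subject's phenotype
#' class, NFIB carrier status, sex, bodyweight and study period; a
#' phenotype-conditional lognormal solanidine concentration and five
#' metabolite-to-solanidine ratios (optionally log-correlated with
#' solanidine); metabolite responses derived as ratio x solanidine. The
#' censoring rules are then applied exactly as in the quantification module,
#' and both the pre-censoring truth and the post-censoring observed panel
#' are returned.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed; mandatory - the generator is deterministic
#'   given (cfg, seed).
#' @return Object of class `synthetic_cohort`: list with `truth` (data
#'   frame of uncensored values and design columns) and `observed` (the
#'   censored analysis panel with `excluded` and `censored_*` flags and
#'   ratio columns for retained subjects).
#' @export
simulate_cohort <- function(cfg = cohort_config(), seed) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (missing(seed)) stop("a seed is mandatory for the generator")
  set.seed(seed)
  ions <- c("mz414", "mz416", "mz444", "mz430", "mz412")

  groups <- names(cfg$group_sizes)
  infeasible <- setdiff(groups[cfg$group_sizes > 0], names(cfg$diplotypes))
  if (length(infeasible))
    stop("no diplotype configured for class(es): ",
         paste(infeasible, collapse = ", "))

  rows <- lapply(groups, function(ph) {
    n <- cfg$group_sizes[[ph]]
    if (n == 0L) return(NULL)
    dip <- sample(cfg$diplotypes[[ph]], n, replace = TRUE)
    bw <- cfg$bodyweight
    sdlog <- sqrt(log(1 + (bw$sd / bw$mean)^2))
    meanlog <- log(bw$mean) - sdlog^2 / 2

    z_sol <- stats::rnorm(n)
    sol_sigma <- endpoint_param(cfg, "solanidine", ph, "sigma")
    sol_gm <- endpoint_param(cfg, "solanidine", ph, "gm")
    sol <- exp(log(sol_gm) + sol_sigma * z_sol)

    out <- data.frame(
      phenotype = ph,
      diplotype = dip,
      nfib_carrier = stats::runif(n) < cfg$nfib_freq,
      sex = stats::rbinom(n, 1L, 0.5),
      bodyweight = exp(stats::rnorm(n, meanlog, sdlog)),
      period = stats::rbinom(n, 1L, 0.5),
      solanidine = sol,
      stringsAsFactors = FALSE
    )
    for (ion in ions) {
      ep <- paste0("ratio_", ion)
      sg <- endpoint_param(cfg, ep, ph, "sigma")
      gm <- endpoint_param(cfg, ep, ph, "gm")
      z <- cfg$log_cor * z_sol +
        sqrt(1 - cfg$log_cor^2) * stats::rnorm(n)
      ratio <- exp(log(gm) + sg * z)
      out[[ep]] <- ratio
      out[[ion]] <- ratio * sol   # semi-quantitative response units
    }
    out
  })
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  truth$subject_id <- sprintf("S%03d", seq_len(nrow(truth)))

  observed <- apply_censoring(
    truth[c("subject_id", "phenotype", "diplotype", "nfib_carrier",
            "sex", "bodyweight", "period", "solanidine", ions)],
    cfg$rules)
  retained <- !observed$excluded
  observed[paste0("ratio_", ions)] <- NA_real_
  if (any(retained)) {
    rat <- compute_ratios(observed[retained, setdiff(names(observed), "excluded")],
                          ions = ions)
    observed[retained, paste0("ratio_", ions)] <- rat[paste0("ratio_", ions)]
  }
  structure(list(truth = truth, observed = observed, config = cfg, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic biomarker cohort (seed ", x$seed, ")\n", sep = "")
  tab <- table(x$truth$phenotype)[names(x$config$group_sizes)]
  cat("  subjects:", nrow(x$truth),
      paste0("(", paste(names(tab), tab, sep = " ", collapse = ", "), ")"), "\n")
  cat("  excluded below solanidine LLOQ:", sum(x$observed$excluded), "\n")
  invisible(x)
}

no_function_dosage <- function(diplotypes, allele_table = default_allele_table()) {
  vapply(diplotypes, function(s) {
    d <- parse_diplotype(s)
    sum(vapply(list(d$hap1, d$hap2), function(h) {
      i <- match(h$allele, allele_table$allele)
      if (is.na(i)) stop("allele '", h$allele, "' not in table")
      if (allele_table$value[i] == 0) 1L else 0L
    }, integer(1L)))
  }, integer(1L), USE.NAMES = FALSE)
}

#' Simulate a genotype dosage panel with LD structure
#'
#' The causal variant's dosage is derived deterministically from each
#' subject's diplotype as the count of no-function alleles (capped at 2).
#' Each LD proxy starts as a copy of the causal dosage and random entries
#' are re-drawn from the causal variant's marginal distribution until the
#' realized r-squared is within +/- 0.05 of its target. Background variants
#' are independent binomial(2, maf) draws with maf ~ uniform(0.05, 0.5).
#'
#' @param cohort A `synthetic_cohort` (supplies the diplotypes).
#' @param cfg The `cohort_config` (panel size and proxy targets); defaults
#'   to the cohort's own config.
#' @param seed Integer seed.
#' @return List with `dosages` (subjects x variants matrix; columns
#'   `causal`, `proxy_1`..., `bg_...`), `variant_info` (id/chr/pos), and
#'   `achieved_r2` for the proxies.
#' @export
simulate_dosages <- function(cohort, cfg = cohort$config, seed) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (missing(seed)) stop("a seed is mandatory for the generator")
  set.seed(seed)
  n <- nrow(cohort$truth)
  causal <- pmin(no_function_dosage(cohort$truth$diplotype), 2L)
  if (stats::var(causal) == 0)
    stop("causal dosage is monomorphic under this diplotype table")
  marg <- tabulate(causal + 1L, nbins = 3L) / n

  make_proxy <- function(target) {
    g <- causal
    if (target >= 1) return(g)
    # degrade the copy until close to the target r2 (contract: +/- 0.05)
    for (step in seq_len(50L * n)) {
      r2 <- stats::cor(g, causal)^2
      if (r2 <= target + 0.01) {
        if (r2 >= target - 0.05) return(g)
        stop("proxy r2 target ", target, " unattainable: overshot to ",
             round(r2, 3))
      }
      i <- sample.int(n, 1L)
      g[i] <- sample(0:2, 1L, prob = marg)
    }
    stop("proxy r2 target ", target, " not reached")
  }
  proxies <- lapply(cfg$proxy_r2, make_proxy)

  n_bg <- cfg$n_variants - 1L - length(proxies)
  if (n_bg < 0L) stop("n_variants smaller than causal + proxies")
  maf <- stats::runif(n_bg, 0.05, 0.5)
  bg <- vapply(maf, function(p) stats::rbinom(n, 2L, p), numeric(n))

  dos <- cbind(causal, do.call(cbind, proxies), bg)
  colnames(dos) <- c("causal",
                     if (length(proxies)) paste0("proxy_", seq_along(proxies)),
                     if (n_bg > 0L) paste0("bg_", seq_len(n_bg)))
  info <- data.frame(id = colnames(dos), chr = "22",
                     pos = seq_len(ncol(dos)) * 1000L,
                     stringsAsFactors = FALSE)
  list(dosages = dos, variant_info = info,
       achieved_r2 = vapply(proxies, function(g) stats::cor(g, causal)^2,
                            numeric(1L)))
}

#' Simulate a substrate-depletion time course
#'
#' C(t) = C0 exp(-k t) with multiplicative lognormal measurement noise of a
#' given coefficient of variation (mean-one noise, so fitted rate constants
#' are unbiased on the log-linear scale).
#'
#' @param k First-order depletion rate (1/min), >= 0.
#' @param cv Coefficient of variation of the multiplicative noise (0 for a
#'   noiseless curve).
#' @param times Sampling times in minutes, must include 0.
#' @param c0 Initial concentration, default 100.
#' @param seed Integer seed.
#' @return Data frame `time`, `concentration`.
#' @export
simulate_depletion <- function(k, cv = 0, times = c(0, 5, 10, 20, 30),
                               c0 = 100, seed) {
  stopifnot(k >= 0, 0 %in% times, c0 > 0)
  if (cv < 0) stop("cv must be non-negative")
  if (missing(seed)) stop("a seed is mandatory for the generator")
  set.seed(seed)
  mu <- c0 * exp(-k * times)
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    eps <- exp(stats::rnorm(length(times), -sdlog^2 / 2, sdlog))
    mu <- mu * eps
  }
  data.frame(time = times, concentration = mu)
}
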