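#' Geometric mean with a log-scale t confidence interval
#'
#' Biomarker concentrations are analyzed on the natural-log scale; the
#' geometric mean is the back-transformed mean log, and the confidence
#' interval back-transforms mean log +/- t_{1-alpha/2, n-1} * SE(log).
#'
#' @param values Positive numeric vector.
#' @param level Confidence level, default 0.95.
#' @return A list of class `group_summary` with `n`, `geometric_mean`,
#'   `ci_low`, `ci_high`.
#' @examples
#' geometric_mean_ci(c(exp(0), exp(2)))
#' @export
geometric_mean_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no non-missing values")
  if (any(values <= 0)) stop("geometric mean requires strictly positive values")
  lx <- log(values)
  n <- length(lx)
  m <- mean(lx)
  if (n >= 2L) {
    se <- stats::sd(lx) / sqrt(n)
    tq <- stats::qt(1 - (1 - level) / 2, df = n - 1L)
    ci <- exp(m + c(-1, 1) * tq * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(n = n, geometric_mean = exp(m),
                 ci_low = ci[1L], ci_high = ci[2L]),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("n = %d, geometric mean %.4g (95%% CI %.4g, %.4g)\n",
              x$n, x$geometric_mean, x$ci_low, x$ci_high))
  invisible(x)
}

#' Pooled geometric mean across groups
#'
#' Size-weighted combination on the log scale:
#' exp( sum n_g * ln(GM_g) / sum n_g ). This equals the overall geometric
#' mean of the pooled sample when the group GMs come from that sample.
#'
#' @param gm Positive numeric vector of group geometric means.
#' @param n Positive integer vector of group sizes.
#' @return The pooled geometric mean.
#' @examples
#' pooled_geometric_mean(c(1.76, 0.154, 0.0889, 0.0580), c(9, 89, 196, 20))
#' @export
pooled_geometric_mean <- function(gm, n) {
  if (length(gm) == 0L) stop("at least one group is required")
  stopifnot(length(gm) == length(n), all(gm > 0), all(n >= 1))
  exp(sum(n * log(gm)) / sum(n))
}

#' Percent change implied by a geometric-mean ratio
#'
#' `(ratio - 1) * 100`; negative values read as "X% lower than the
#' reference", positive as "X% higher".
#'
#' @param ratio Positive ratio of geometric means.
#' @return Signed percent change.
#' @examples
#' percent_change(0.653)  # -34.7: 34.7% lower
#' @export
percent_change <- function(ratio) {
  stopifnot(all(ratio > 0))
  (ratio - 1) * 100
}

#' Forward stepwise covariate selection
#'
#' Forward entry of candidate covariates into a linear model for the
#' log-transformed endpoint at partial-F p <= `entry_p`, with backward
#' removal at p >= `removal_p`, iterated to convergence. For a single added
#' term the partial F test equals the squared t test on its coefficient.
#' Constant (degenerate) candidates are skipped with a warning; perfectly
#' collinear duplicates can never both enter because the added copy has no
#' partial sum of squares.
#'
#' @param y Numeric response (log endpoint).
#' @param candidates Data frame of candidate covariates (columns are
#'   candidates; typically sex, log bodyweight, study period).
#' @param entry_p Entry threshold, default 0.05.
#' @param removal_p Removal threshold, default 0.10.
#' @return Object of class `covariate_model`: list with `selected` (character
#'   vector of covariate names, possibly empty), `entry_p`, `removal_p`.
#' @export
stepwise_covariates <- function(y, candidates, entry_p = 0.05, removal_p = 0.10) {
  stopifnot(is.data.frame(candidates), length(y) == nrow(candidates))
  if (length(y) <= ncol(candidates) + 2L)
    stop("too few observations for stepwise selection")
  const <- vapply(candidates, function(x) length(unique(x[!is.na(x)])) < 2L,
                  logical(1L))
  if (any(const)) {
    warning("skipping constant candidate(s): ",
            paste(names(candidates)[const], collapse = ", "))
    candidates <- candidates[!const]
  }
  pool <- names(candidates)
  selected <- character(0L)

  partial_p <- function(term, base_terms) {
    # p-value of `term` given base_terms, from the t test in the joint fit
    dat <- cbind(data.frame(.y = y), candidates[c(base_terms, term)])
    fit <- stats::lm(.y ~ ., data = dat)
    tab <- summary(fit)$coefficients
    rn <- rownames(tab)
    i <- which(rn == term | startsWith(rn, term))
    if (length(i) == 0L) return(NA_real_)  # aliased: no partial contribution
    tab[i[1L], "Pr(>|t|)"]
  }

  repeat {
    changed <- FALSE
    # forward step: best remaining candidate
    remaining <- setdiff(pool, selected)
    if (length(remaining)) {
      pvals <- vapply(remaining, partial_p, numeric(1L), base_terms = selected)
      pvals[is.na(pvals)] <- Inf
      if (length(pvals) && min(pvals) <= entry_p) {
        selected <- c(selected, remaining[which.min(pvals)])
        changed <- TRUE
      }
    }
    # backward step: drop worst selected
    if (length(selected) > 0L) {
      pd <- vapply(selected, function(tm)
        partial_p(tm, setdiff(selected, tm)), numeric(1L))
      pd[is.na(pd)] <- Inf
      if (max(pd) >= removal_p) {
        selected <- setdiff(selected, selected[which.max(pd)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(list(selected = selected, entry_p = entry_p, removal_p = removal_p),
            class = "covariate_model")
}

#' @export
print.covariate_model <- function(x, ...) {
  cat("Stepwise covariate model (entry p <=", x$entry_p,
      ", removal p >=", x$removal_p, ")\n")
  cat("  selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' ANOVA with Fisher's LSD contrasts against the normal-metabolizer group
#'
#' Fits a linear model of the log endpoint on phenotype class plus any
#' selected covariates, then reports each non-reference class against the
#' reference (gNM by default) with Fisher's least-significant-difference
#' comparisons: the contrast standard error uses the pooled residual variance
#' from the full model, the CI uses the t quantile at the residual degrees of
#' freedom, and the pairwise p-values are deliberately unadjusted (that is
#' what LSD is). Back-transformed, the contrast is the geometric-mean ratio
#' of each class to the reference.
#'
#' @param data Data frame containing the analysis columns.
#' @param value Name of the column holding the positive endpoint
#'   (concentration or ratio); it is log-transformed internally.
#' @param phenotype Name of the phenotype column. Classes with no subjects
#'   are omitted from the contrast table.
#' @param covariates Character vector of covariate column names to adjust
#'   for (possibly empty).
#' @param reference Reference class, default `"gNM"`.
#' @param level Confidence level, default 0.95.
#' @return Object of class `lsd_contrasts`: a data frame with one row per
#'   non-reference class (`phenotype`, `n`, `gm`, `gm_low`, `gm_high`,
#'   `ratio`, `ratio_low`, `ratio_high`, `p_value`) plus a reference row with
#'   ratio 1; attributes carry the fitted model and settings. The `gm`
#'   columns are the raw per-group geometric means and log-scale t intervals;
#'   the `ratio` columns are covariate-adjusted model contrasts.
#' @export
anova_lsd_contrasts <- function(data, value, phenotype = "phenotype",
                                covariates = character(0L),
                                reference = "gNM", level = 0.95) {
  stopifnot(is.data.frame(data), value %in% names(data),
            phenotype %in% names(data), all(covariates %in% names(data)))
  keep <- !is.na(data[[value]]) & !is.na(data[[phenotype]])
  data <- data[keep, , drop = FALSE]
  if (any(data[[value]] <= 0))
    stop("endpoint must be strictly positive for log-scale analysis")
  classes <- unique(as.character(data[[phenotype]]))
  if (!(reference %in% classes))
    stop("reference class '", reference, "' has no subjects")
  if (length(classes) < 2L)
    stop("at least two phenotype classes are required")

  ph <- stats::relevel(factor(data[[phenotype]]), ref = reference)
  dat <- data.frame(.logy = log(data[[value]]), .ph = ph,
                    data[covariates], check.names = FALSE)
  fit <- stats::lm(.logy ~ ., data = dat)
  tab <- summary(fit)$coefficients
  dfres <- fit$df.residual
  tq <- stats::qt(1 - (1 - level) / 2, df = dfres)

  rows <- lapply(levels(ph), function(cl) {
    vals <- data[[value]][as.character(data[[phenotype]]) == cl]
    gs <- geometric_mean_ci(vals, level = level)
    if (cl == reference) {
      data.frame(phenotype = cl, n = gs$n, gm = gs$geometric_mean,
                 gm_low = gs$ci_low, gm_high = gs$ci_high,
                 ratio = 1, ratio_low = NA_real_, ratio_high = NA_real_,
                 p_value = NA_real_)
    } else {
      rn <- paste0(".ph", cl)
      est <- tab[rn, "Estimate"]
      se <- tab[rn, "Std. Error"]
      data.frame(phenotype = cl, n = gs$n, gm = gs$geometric_mean,
                 gm_low = gs$ci_low, gm_high = gs$ci_high,
                 ratio = exp(est),
                 ratio_low = exp(est - tq * se),
                 ratio_high = exp(est + tq * se),
                 p_value = tab[rn, "Pr(>|t|)"])
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("lsd_contrasts", "data.frame"),
            fit = fit, reference = reference, level = level,
            covariates = covariates, endpoint = value)
}

#' @export
print.lsd_contrasts <- function(x, digits = 3, ...) {
  cat("Log-scale ANOVA with Fisher's LSD contrasts\n")
  cat("  endpoint:", attr(x, "endpoint"),
      " reference:", attr(x, "reference"), "\n")
  cov <- attr(x, "covariates")
  cat("  covariates:", if (length(cov)) paste(cov, collapse = ", ") else "(none)",
      "\n\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, digits = digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.lsd_contrasts <- function(object, ...) {
  df <- as.data.frame(object)
  df$percent_change <- ifelse(df$phenotype == attr(object, "reference"),
                              0, percent_change(df$ratio))
  df
}
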