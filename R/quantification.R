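#' Fit a weighted calibration curve
#'
#' Linear calibration of analyte response against nominal concentration, with
#' the 1/x (inverse-concentration) weighting customary in LC-MS bioanalysis so
#' that low standards are not swamped by the high end of the range. The
#' response is typically a peak-area ratio between analyte and internal
#' standard.
#'
#' @param concentration Numeric vector of standard concentrations (ng/mL),
#'   all positive, at least 3 distinct values.
#' @param response Numeric vector of measured responses, same length.
#' @param weighting `"1/x"` (default) for inverse-concentration weights, or
#'   `"none"` for ordinary least squares.
#' @return An object of class `calibration_curve`: list with `slope`,
#'   `intercept`, `r` (signed correlation of the weighted fit), `weighting`,
#'   `range` (min/max standard concentration) and the underlying `lm` fit.
#' @examples
#' cc <- fit_calibration(c(1, 2, 5), c(2, 4, 10))
#' cc$slope
#' @export
fit_calibration <- function(concentration, response, weighting = c("1/x", "none")) {
  weighting <- match.arg(weighting)
  if (length(concentration) != length(response))
    stop("concentration and response must have equal length")
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("all standard concentrations must be positive and finite")
  if (length(unique(concentration)) < 3L)
    stop("calibration requires at least 3 distinct standard concentrations")
  w <- if (weighting == "1/x") 1 / concentration else rep(1, length(concentration))
  fit <- stats::lm(response ~ concentration, weights = w)
  b <- stats::coef(fit)
  # weighted Pearson correlation, signed like the slope
  mx <- sum(w * concentration) / sum(w)
  my <- sum(w * response) / sum(w)
  sxy <- sum(w * (concentration - mx) * (response - my))
  sxx <- sum(w * (concentration - mx)^2)
  syy <- sum(w * (response - my)^2)
  r <- if (syy > 0) sxy / sqrt(sxx * syy) else NA_real_
  if (is.finite(b[[2L]]) && b[[2L]] <= 0)
    warning("calibration slope is not positive; curve is not invertible")
  structure(list(slope = unname(b[[2L]]), intercept = unname(b[[1L]]),
                 r = r, weighting = weighting,
                 range = range(concentration), fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration curve (weighting: ", x$weighting, ")\n", sep = "")
  cat(sprintf("  response = %.6g + %.6g * concentration   (r = %.5f)\n",
              x$intercept, x$slope, x$r))
  cat(sprintf("  calibrated range: %.4g - %.4g ng/mL\n", x$range[1], x$range[2]))
  invisible(x)
}

#' Back-calculate concentration from a calibration curve
#'
#' Inverts the fitted line: concentration = (response - intercept) / slope.
#' Responses that invert to a negative concentration are non-quantifiable and
#' returned as `NA` (with the pattern available via the
#' `"nonquantifiable"` attribute).
#'
#' @param response Numeric vector of measured responses.
#' @param curve A `calibration_curve`.
#' @return Numeric vector of concentrations (ng/mL); non-quantifiable entries
#'   are `NA` and flagged in `attr(, "nonquantifiable")`.
#' @export
quantify <- function(response, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) || curve$slope <= 0)
    stop("calibration curve has non-positive slope; cannot invert")
  conc <- (response - curve$intercept) / curve$slope
  nonq <- !is.na(conc) & conc < 0
  conc[nonq] <- NA_real_
  attr(conc, "nonquantifiable") <- nonq
  conc
}

#' Default censoring rules
#'
#' Parent solanidine has a validated lower limit of quantification (LLOQ) of
#' 0.01 ng/mL; subjects below it are excluded outright (no recent intake of
#' solanine-containing food can be assumed). Metabolites are semi-quantitative
#' (no reference standards) and their LLOQs are per-ion response levels
#' defined operationally at signal-to-noise 10; values below are imputed at
#' half the LLOQ rather than dropped. Zero or negative responses are treated
#' as below the LLOQ. The default per-ion levels are the synthetic
#' generator's calibration: on the reference-calibrated response scale they
#' reproduce the reference cohort's measurable-subject counts
#' (310/308/299/296/225 of 314 for m/z 414/416/444/430/412).
#'
#' @param solanidine_lloq Parent LLOQ in ng/mL (default 0.01).
#' @param metabolite_lloq Named numeric vector of per-ion response LLOQs; the
#'   names must match the metabolite response columns they censor.
#' @return A list of class `censoring_rules`.
#' @export
censoring_rules <- function(solanidine_lloq = 0.01,
                            metabolite_lloq = c(mz414 = 8.5e-3, mz416 = 8.0e-3,
                                                mz444 = 4.3e-3, mz430 = 5.2e-3,
                                                mz412 = 9.0e-3)) {
  if (!is.numeric(solanidine_lloq) || solanidine_lloq <= 0)
    stop("solanidine_lloq must be a positive number")
  if (is.null(names(metabolite_lloq)) || any(metabolite_lloq <= 0))
    stop("metabolite_lloq must be a named vector of positive response levels")
  structure(list(solanidine_lloq = solanidine_lloq,
                 metabolite_lloq = metabolite_lloq),
            class = "censoring_rules")
}

#' Apply LLOQ censoring to a biomarker panel
#'
#' Subjects whose solanidine concentration is below the parent LLOQ are marked
#' `excluded` (exclusion is a state, not an error). For retained subjects,
#' each metabolite response below its per-ion LLOQ (including zero or negative
#' responses) is replaced by half that LLOQ and flagged in a `censored_<ion>`
#' column. The operation is idempotent: re-censoring an already-censored
#' panel re-imputes the same half-LLOQ values and leaves all flags unchanged.
#'
#' @param panel Data frame with a `solanidine` column (ng/mL) and one response
#'   column per name of `rules$metabolite_lloq`.
#' @param rules A `censoring_rules` object.
#' @return `panel` with logical columns `excluded` and `censored_<ion>`
#'   appended and below-LLOQ metabolite responses imputed at half-LLOQ.
#' @export
apply_censoring <- function(panel, rules = censoring_rules()) {
  stopifnot(is.data.frame(panel), inherits(rules, "censoring_rules"),
            "solanidine" %in% names(panel))
  panel$excluded <- !is.na(panel$solanidine) &
    panel$solanidine < rules$solanidine_lloq
  panel$excluded[is.na(panel$solanidine)] <- TRUE
  for (ion in names(rules$metabolite_lloq)) {
    if (!ion %in% names(panel))
      stop("panel is missing metabolite response column '", ion, "'")
    lloq <- rules$metabolite_lloq[[ion]]
    flag_col <- paste0("censored_", ion)
    prev <- if (flag_col %in% names(panel)) panel[[flag_col]] else
      rep(FALSE, nrow(panel))
    below <- !is.na(panel[[ion]]) & panel[[ion]] < lloq
    panel[[ion]][below] <- lloq / 2
    panel[[flag_col]] <- prev | below
  }
  panel
}

#' Metabolite-to-solanidine ratios
#'
#' The CYP2D6 activity readout: each metabolite response (arbitrary units,
#' peak area / IS area) divided by the parent solanidine concentration
#' (ng/mL). Ratios are defined only for subjects retained after censoring;
#' calling this on excluded subjects is a contract violation.
#'
#' @param panel A censored panel (from [apply_censoring()]), or any data frame
#'   with `solanidine` and the metabolite response columns.
#' @param ions Character vector of response column names to ratio against
#'   solanidine.
#' @return `panel` with `ratio_<ion>` columns appended; excluded rows (if an
#'   `excluded` column is present) must not be passed in.
#' @export
compute_ratios <- function(panel, ions = c("mz414", "mz416", "mz444",
                                           "mz430", "mz412")) {
  stopifnot(is.data.frame(panel), "solanidine" %in% names(panel))
  if ("excluded" %in% names(panel) && any(panel$excluded))
    stop("compute_ratios called on excluded subjects; drop them first")
  for (ion in ions) {
    if (!ion %in% names(panel))
      stop("panel is missing metabolite response column '", ion, "'")
    panel[[paste0("ratio_", ion)]] <- panel[[ion]] / panel$solanidine
  }
  panel
}
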