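#' Published cohort summary used to calibrate the synthetic generator
#'
#' Per-phenotype geometric means and 95% confidence intervals of fasting
#' plasma solanidine (ng/mL) and of the five metabolite-to-solanidine
#' response ratios (arbitrary units / (ng/mL)) in the 314-subject reference
#' cohort (9 gPM, 89 gIM, 196 gNM, 20 gUM). These printed summaries are the
#' only dispersion information available for the cohort and serve as the
#' calibration targets of [cohort_config()]; the raw per-subject data are
#' not public.
#'
#' @return Data frame with columns `endpoint` (`solanidine`, `ratio_mz414`,
#'   ..., `ratio_mz412`), `phenotype`, `n`, `gm`, `ci_low`, `ci_high`.
#' @export
reference_summary <- function() {
  ph <- c("gPM", "gIM", "gNM", "gUM")
  n <- c(9L, 89L, 196L, 20L)
  build <- function(endpoint, gm, lo, hi)
    data.frame(endpoint = endpoint, phenotype = ph, n = n,
               gm = gm, ci_low = lo, ci_high = hi,
               stringsAsFactors = FALSE)
  rbind(
    build("solanidine",
          c(1.76, 0.154, 0.0889, 0.0580),
          c(0.775, 0.119, 0.0746, 0.0333),
          c(4.02, 0.200, 0.106, 0.101)),
    build("ratio_mz414",
          c(0.00649, 5.49, 7.52, 7.20),
          c(0.00441, 4.86, 6.92, 5.55),
          c(0.00954, 6.20, 8.16, 9.34)),
    build("ratio_mz416",
          c(0.00433, 3.08, 5.65, 7.99),
          c(0.00231, 2.53, 4.95, 5.23),
          c(0.00811, 3.76, 6.47, 12.2)),
    build("ratio_mz444",
          c(0.00319, 0.382, 1.14, 2.29),
          c(0.00157, 0.305, 0.979, 1.42),
          c(0.00648, 0.479, 1.33, 3.69)),
    build("ratio_mz430",
          c(0.00420, 0.347, 1.04, 2.15),
          c(0.00217, 0.281, 0.899, 1.38),
          c(0.00816, 0.428, 1.19, 3.37)),
    build("ratio_mz412",
          c(0.00331, 0.152, 0.236, 0.345),
          c(0.00208, 0.131, 0.214, 0.252),
          c(0.00527, 0.177, 0.261, 0.473))
  )
}
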