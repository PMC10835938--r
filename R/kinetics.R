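#' Fit first-order substrate depletion
#'
#' Substrate-depletion experiments follow C(t) = C0 * exp(-k t); the rate
#' constant is estimated as minus the ordinary-least-squares slope of
#' ln(concentration) against time. An increasing (flat-or-rising) profile is
#' clipped to k = 0 with a warning rather than reported as negative
#' elimination.
#'
#' @param time Numeric vector of incubation times (minutes), including 0.
#' @param concentration Positive substrate concentrations (any consistent
#'   unit, or fraction remaining), same length, at least 3 points (2 allowed
#'   for a two-point estimate).
#' @return Object of class `depletion_fit`: list with `k` (1/min),
#'   `half_life` (min), `r_squared`, `n`, and the `lm` fit.
#' @examples
#' fit_depletion(c(0, 5, 10, 30), 100 * exp(-0.1 * c(0, 5, 10, 30)))
#' @export
fit_depletion <- function(time, concentration) {
  stopifnot(length(time) == length(concentration))
  if (length(time) < 2L) stop("at least two time points are required")
  if (!0 %in% time) stop("the time-zero sample must be present")
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("all concentrations must be positive for log-linear fitting")
  fit <- stats::lm(log(concentration) ~ time)
  slope <- unname(stats::coef(fit)[2L])
  k <- -slope
  if (k < -1e-12) {
    warning("increasing concentration profile; depletion rate clipped at 0")
    k <- 0
  } else if (abs(k) < 1e-12) {
    k <- 0  # flat within numerical noise
  }
  r2 <- if (length(time) > 2L)
    suppressWarnings(summary(fit)$r.squared) else 1
  structure(list(k = k, half_life = if (k > 0) log(2) / k else Inf,
                 r_squared = r2, n = length(time), fit = fit),
            class = "depletion_fit")
}

#' @export
print.depletion_fit <- function(x, ...) {
  cat(sprintf("First-order depletion fit (n = %d): k = %.4g /min, t1/2 = %.4g min, R2 = %.4f\n",
              x$n, x$k, x$half_life, x$r_squared))
  invisible(x)
}

#' Intrinsic clearance from a depletion rate constant
#'
#' CLint = k / protein concentration, the in vitro intrinsic clearance per
#' mg of microsomal protein.
#'
#' @param k First-order depletion rate constant (1/min), or a
#'   `depletion_fit`.
#' @param protein Microsomal protein concentration in the incubation
#'   (mg/mL), > 0.
#' @return Intrinsic clearance in mL/min/mg protein.
#' @examples
#' clint(0.1, protein = 0.2)  # 0.5
#' @export
clint <- function(k, protein) {
  if (inherits(k, "depletion_fit")) k <- k$k
  stopifnot(is.numeric(k), k >= 0)
  if (!is.numeric(protein) || protein <= 0)
    stop("protein concentration must be positive (mg/mL)")
  k / protein
}

#' Physiological scaling constants for hepatic clearance
#'
#' Defaults: 40 mg microsomal protein per g liver (MPPGL), 1800 g liver,
#' hepatic blood flow Q = 90 L/h, unbound fraction fu = 1. All configurable;
#' these are generic adult-human values, and predictions shift accordingly
#' if other constants are preferred.
#'
#' @param mppgl mg microsomal protein per g liver.
#' @param liver_mass_g Liver mass in grams.
#' @param q_lh Hepatic blood flow in L/h.
#' @param fu Unbound fraction in blood (0 < fu <= 1).
#' @return List of class `scaling_constants`.
#' @export
scaling_constants <- function(mppgl = 40, liver_mass_g = 1800,
                              q_lh = 90, fu = 1) {
  stopifnot(mppgl > 0, liver_mass_g > 0, q_lh > 0, fu > 0, fu <= 1)
  structure(list(mppgl = mppgl, liver_mass_g = liver_mass_g,
                 q_lh = q_lh, fu = fu),
            class = "scaling_constants")
}

#' Well-stirred scaling of intrinsic clearance to hepatic clearance
#'
#' The microsomal CLint (mL/min/mg) is scaled to whole-liver intrinsic
#' clearance via MPPGL and liver mass (converted to L/h), then fed into the
#' well-stirred liver model CL_h = Q fu CLint,liver / (Q + fu CLint,liver),
#' which is bounded above by hepatic blood flow Q.
#'
#' @param clint_ml_min_mg Intrinsic clearance in mL/min/mg protein.
#' @param constants A [scaling_constants()] object.
#' @return List with `clint_liver_lh` (whole-liver intrinsic clearance,
#'   L/h), `cl_h_lh` (well-stirred hepatic clearance, L/h), and
#'   `percent_of_q`.
#' @examples
#' scale_hepatic(0.25, scaling_constants())
#' @export
scale_hepatic <- function(clint_ml_min_mg, constants = scaling_constants()) {
  stopifnot(inherits(constants, "scaling_constants"), clint_ml_min_mg >= 0)
  clint_liver <- clint_ml_min_mg * constants$mppgl * constants$liver_mass_g *
    60 / 1000  # mL/min -> L/h
  num <- constants$q_lh * constants$fu * clint_liver
  cl_h <- if (clint_liver == 0) 0 else
    num / (constants$q_lh + constants$fu * clint_liver)
  list(clint_liver_lh = clint_liver, cl_h_lh = cl_h,
       percent_of_q = 100 * cl_h / constants$q_lh)
}

#' Percent inhibition of intrinsic clearance
#'
#' @param control_clint CLint without inhibitor (> 0).
#' @param inhibited_clint CLint with inhibitor.
#' @return Percent reduction, (1 - inhibited/control) * 100.
#' @examples
#' percent_inhibition(1.0, 0.05)  # 95
#' @export
percent_inhibition <- function(control_clint, inhibited_clint) {
  if (control_clint <= 0) stop("control CLint must be positive")
  (1 - inhibited_clint / control_clint) * 100
}

#' Fraction metabolized from phenotype geometric means
#'
#' Assuming that steady-state concentration differences between poor and
#' normal metabolizers reflect inverse clearance differences, the fraction
#' of clearance mediated by the enzyme in normal metabolizers is
#' fm = 1 - GM_gNM / GM_gPM. A gPM mean at or below the gNM mean yields a
#' non-positive fm and a warning (no meaningful enzyme contribution can be
#' inferred).
#'
#' @param gm_pm Geometric-mean concentration in poor metabolizers (ng/mL).
#' @param gm_nm Geometric-mean concentration in normal metabolizers (ng/mL).
#' @return Fraction metabolized (unitless).
#' @examples
#' fraction_metabolized(1.76, 0.0889)  # ~0.95
#' @export
fraction_metabolized <- function(gm_pm, gm_nm) {
  stopifnot(gm_pm > 0, gm_nm > 0)
  fm <- 1 - gm_nm / gm_pm
  if (fm <= 0)
    warning("gPM mean does not exceed gNM mean; fm <= 0 is not meaningful")
  fm
}
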