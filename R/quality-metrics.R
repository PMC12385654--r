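#' Initial-maturity index from a quality indicator
#'
#' Expresses an indicator reading as a percentage of its span between the
#' initial (unripe) and final (fully ripe) values:
#' `M = (y - y1) / (y2 - y1) * 100`.
#'
#' @param y Indicator value(s).
#' @param y_initial,y_final Calibration endpoints `y1`, `y2` (must differ).
#' @return Maturity in percent (0 at `y1`, 100 at `y2`).
#' @export
#' @examples
#' maturity_index(14.455, y_initial = 5.37, y_final = 23.54) # 50
maturity_index <- function(y, y_initial, y_final) {
  if (y_initial == y_final) {
    abort("degenerate calibration: `y_initial` and `y_final` must differ.")
  }
  (y - y_initial) / (y_final - y_initial) * 100
}

#' Calibrated maturity from soluble solids content
#'
#' Site-specific linear calibration for wolfberry maturity from SSC:
#' `M = 3.958 - 0.258 * y_ssc`, applied exactly as calibrated (the output is
#' not clipped to `[0, 100]`; see the methods vignette for the unit caveat).
#'
#' @param y_ssc SSC in percent.
#' @return Calibrated maturity value.
#' @export
maturity_from_ssc <- function(y_ssc) {
  3.958 - 0.258 * y_ssc
}

#' Calibrated maturity from vitamin C content
#'
#' Companion calibration to [maturity_from_ssc()] using vitamin C:
#' `M = 0.237 * y_vc - 0.434` (not clipped; see vignette).
#'
#' @param y_vc Vitamin C in mg per 100 g.
#' @return Calibrated maturity value.
#' @export
maturity_from_vc <- function(y_vc) {
  0.237 * y_vc - 0.434
}

#' Titratable acidity from an NaOH titration record
#'
#' `TA = V * c * (V1 - V0) * f / (Vs * m) * 100`, in percent malic acid:
#' total extract volume `V` (mL), titrant molarity `c` (mol/L), sample and
#' blank titre volumes `V1`, `V0` (mL), aliquot volume `Vs` (mL), sample mass
#' `m` (g) and the malic-acid conversion factor `f` (g/mol).
#'
#' @param extract_volume_mL,naoh_molarity,titre_sample_mL,titre_blank_mL
#'   Titration quantities as above.
#' @param aliquot_mL,sample_mass_g Denominator quantities, both positive.
#' @param acid_factor Malic-acid conversion factor (0.067 g/mmol by default).
#' @return Titratable acidity in percent.
#' @export
#' @examples
#' titratable_acidity(200, 0.1, 2.5, 0.5, aliquot_mL = 10, sample_mass_g = 20)
titratable_acidity <- function(extract_volume_mL, naoh_molarity,
                               titre_sample_mL, titre_blank_mL,
                               aliquot_mL, sample_mass_g,
                               acid_factor = 0.067) {
  vols <- c(extract_volume_mL, titre_sample_mL, titre_blank_mL)
  if (any(vols < 0)) abort("volumes must be non-negative.")
  if (aliquot_mL <= 0 || sample_mass_g <= 0) {
    abort("`aliquot_mL` and `sample_mass_g` must be positive.")
  }
  extract_volume_mL * naoh_molarity * (titre_sample_mL - titre_blank_mL) *
    acid_factor / (aliquot_mL * sample_mass_g) * 100
}

check_paired <- function(observed, predicted, min_n = 1) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have the same length.")
  }
  if (length(observed) < min_n) {
    abort(sprintf("need at least %d observations.", min_n))
  }
}

#' Root mean square error
#' @param observed,predicted Numeric vectors of equal length.
#' @return `sqrt(mean((predicted - observed)^2))`, in response units.
#' @export
rmse <- function(observed, predicted) {
  check_paired(observed, predicted)
  sqrt(mean((predicted - observed)^2))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((M - P)^2) / (sum(M^2) - sum(M)^2 / n)`, with observed `M`
#' and predicted `P`. The denominator is algebraically the centered total sum
#' of squares, so this is the classical `1 - SSE/SST`.
#'
#' @param observed,predicted Numeric vectors of equal length, n >= 2;
#'   `observed` must not be constant.
#' @return R-squared (at most 1; can be negative for poor fits).
#' @export
r_squared <- function(observed, predicted) {
  check_paired(observed, predicted, min_n = 2)
  n <- length(observed)
  denom <- sum(observed^2) - sum(observed)^2 / n
  if (denom <= 0) abort("degenerate data: observed values are constant.")
  1 - sum((observed - predicted)^2) / denom
}

#' Mean absolute percentage error
#' @param observed,predicted Numeric vectors; `observed` must be nonzero.
#' @return `mean(|P - M| / |M|) * 100`, in percent.
#' @export
mape <- function(observed, predicted) {
  check_paired(observed, predicted)
  if (any(observed == 0)) abort("MAPE is undefined for zero observed values.")
  mean(abs(predicted - observed) / abs(observed)) * 100
}

#' Range-normalized RMSE
#' @param observed,predicted Numeric vectors, n >= 2; `observed` must not be
#'   constant.
#' @return `rmse / (max(observed) - min(observed))`, dimensionless.
#' @export
nrmse <- function(observed, predicted) {
  check_paired(observed, predicted, min_n = 2)
  rng <- max(observed) - min(observed)
  if (rng == 0) abort("NRMSE is undefined for constant observed values.")
  rmse(observed, predicted) / rng
}

#' All fit metrics for one response
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return One-row tibble with `r2`, `rmse`, `mape` (percent) and `nrmse`.
#' @export
fit_metrics <- function(observed, predicted) {
  tibble(
    r2 = r_squared(observed, predicted),
    rmse = rmse(observed, predicted),
    mape = mape(observed, predicted),
    nrmse = nrmse(observed, predicted)
  )
}
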