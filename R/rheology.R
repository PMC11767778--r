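#' Shear rate from wall shear stress
#'
#' Newtonian conversion \eqn{\dot\gamma = \tau / \mu} with the unit bookkeeping
#' of the instrument conventions: stress in dyn/cm^2 (1 dyn/cm^2 = 0.1 Pa),
#' viscosity in mPa.s (1 mPa.s = 1e-3 Pa.s), shear rate in 1/s. For the
#' suspension viscosity of 1.12 mPa.s this maps the working stresses of
#' 5 and 0.1 dyn/cm^2 to shear rates of 446 and 8.9 1/s.
#'
#' @param shear_stress wall shear stress in dyn/cm^2 (vectorized).
#' @param viscosity dynamic viscosity in mPa.s (default 1.12).
#' @return shear rate in 1/s.
#' @export
shear_rate_from_stress <- function(shear_stress, viscosity = 1.12) {
  if (any(!is.finite(viscosity)) || any(viscosity <= 0))
    stop("'viscosity' must be positive")
  if (any(shear_stress < 0)) stop("'shear_stress' must be non-negative")
  (shear_stress * 0.1) / (viscosity * 1e-3)
}

#' Wall shear stress from shear rate
#'
#' Inverse of \code{\link{shear_rate_from_stress}}.
#'
#' @param shear_rate shear rate in 1/s.
#' @param viscosity dynamic viscosity in mPa.s.
#' @return shear stress in dyn/cm^2.
#' @export
stress_from_shear_rate <- function(shear_rate, viscosity = 1.12) {
  if (any(!is.finite(viscosity)) || any(viscosity <= 0))
    stop("'viscosity' must be positive")
  shear_rate * viscosity * 1e-3 / 0.1
}

#' Display rounding for shear rates
#'
#' Shear rates at or above 100 1/s are displayed as integers, smaller rates
#' with one decimal, matching hemorheology reporting practice.
#'
#' @param rate shear rate(s) in 1/s.
#' @return numeric vector rounded for display.
#' @export
format_shear_rate <- function(rate) {
  ifelse(rate >= 100, round(rate), round(rate, 1))
}

#' Final hematocrit after dilution
#'
#' Volume-balance hematocrit of a diluted suspension:
#' \code{Hct * V_sample / (V_sample + V_diluent)}. The study protocol —
#' 10 uL of a 40\% hematocrit suspension into 200 uL of Dextran 70 —
#' gives 1.9\%, i.e. 2\% to the nearest percent.
#'
#' @param sample_volume sample volume in uL (> 0).
#' @param sample_hematocrit hematocrit fraction of the sample in \[0, 1\].
#' @param diluent_volume diluent volume in uL (>= 0).
#' @return final hematocrit fraction.
#' @export
final_hematocrit <- function(sample_volume, sample_hematocrit,
                             diluent_volume) {
  if (any(sample_volume <= 0) || any(diluent_volume < 0))
    stop("volumes must be positive (diluent may be zero)")
  if (any(sample_hematocrit < 0 | sample_hematocrit > 1))
    stop("'sample_hematocrit' must be a fraction in [0, 1]")
  if (any(sample_volume + diluent_volume <= 0))
    stop("total volume must be positive")
  sample_hematocrit * sample_volume / (sample_volume + diluent_volume)
}
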