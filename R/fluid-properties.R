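#' @title Oxygen physics of water and aCSF
#' @description
#' Temperature- and composition-dependent oxygen diffusivity, solubility and
#' Krogh coefficient (`Kf = D * S`) of the perfusion fluid. Diffusivity uses
#' the Han-Bartels interpolation; solubility uses the Green-Carritt Bunsen
#' coefficient with explicit chlorinity (salting-out) dependence, with the
#' NASA-JPL and Sander Henry's-law forms as cross-checks. Dissolved glucose
#' (20 mM) depresses diffusivity by 1% and solubility by 0.5%; applied
#' cumulatively this lowers `Kf` by 1.5%.
#' @name fluid_properties
NULL

T_RANGE <- c(273.15, 323.15)

check_temperature <- function(t) {
  if (any(t < T_RANGE[1] | t > T_RANGE[2]))
    warning("temperature outside the validated 0-50 degC interpolation range")
  invisible(t)
}

#' Oxygen diffusivity in pure water
#'
#' Interpolation `log10 D = -8.410 + 773.8/T - (506.4/T)^2` (T in kelvin,
#' D in m^2/s). The final term is the squared ratio; see the methods vignette
#' for why the alternative typographic reading is rejected.
#'
#' @param t temperature, kelvin.
#' @return Diffusivity in m^2/s; about 2.0e-9 at 25 degC.
#' @export
oxygen_diffusivity_water <- function(t) {
  check_temperature(t)
  10^(-8.410 + 773.8 / t - (506.4 / t)^2)
}

#' Bunsen absorption coefficient of oxygen
#'
#' Green-Carritt interpolation: volume of gas (at 0 degC, 1 atm) dissolved
#' per unit volume of solvent at 1 atm oxygen partial pressure, with a
#' chlorinity term capturing the salting-out reduction in saline solutions.
#'
#' @param t temperature, kelvin.
#' @param mcl chlorinity, grams of chloride per kg of solution (>= 0).
#' @return Dimensionless Bunsen coefficient.
#' @export
bunsen_coefficient <- function(t, mcl = 0) {
  check_temperature(t)
  if (any(mcl < 0)) stop("chlorinity must be non-negative")
  1e-3 * exp((-7.424 + 4417 / t - 2.927 * log(t) + 0.04238 * t) -
             mcl * (-0.1288 + 53.44 / t - 0.04442 * log(t) + 7.145e-4 * t))
}

#' Oxygen solubility (Green-Carritt, with chlorinity)
#'
#' Converts the Bunsen coefficient to SI solubility using the non-ideal O2
#' molar volume 22.392 L/mol at 0 degC, 1 atm:
#' `S = alpha * 1000 / (101325 * 22.392) = 4.4075e-4 * alpha`.
#'
#' @inheritParams bunsen_coefficient
#' @return Solubility in mol/(m^3 Pa).
#' @export
solubility_green_carritt <- function(t, mcl = 0) {
  GC_PREFACTOR * bunsen_coefficient(t, mcl)
}

#' Solubility prefactor 1000/(101325 x 22.392) = 4.4075e-4
#' @keywords internal
GC_PREFACTOR <- 1000 / (101325 * 22.392)

#' Oxygen solubility (NASA-JPL Henry's-law tabulation)
#'
#' `S = 9.8692e-3 exp(-161.6 + 8160/T + 22.39 ln T)`, pure water.
#'
#' @param t temperature, kelvin.
#' @return Solubility in mol/(m^3 Pa).
#' @export
solubility_nasa_jpl <- function(t) {
  check_temperature(t)
  9.8692e-3 * exp(-161.6 + 8160 / t + 22.39 * log(t))
}

#' Oxygen solubility (Sander two-parameter form)
#'
#' `S = 1.3e-5 exp(1500 (1/T - 1/298.15))`, pure water.
#'
#' @param t temperature, kelvin.
#' @return Solubility in mol/(m^3 Pa); exactly 1.3e-5 at 25 degC.
#' @export
solubility_sander <- function(t) {
  check_temperature(t)
  1.3e-5 * exp(1500 * (1 / t - 1 / 298.15))
}

#' Krogh coefficient of the perfusion fluid
#'
#' `Kf = D(T) * S(T, mcl)`, optionally depressed by 1.5% for dissolved
#' glucose (1% on diffusivity, 0.5% on solubility, cumulative). For no-Mg
#' aCSF (chlorinity 4.904 g/kg, glucose on) this gives 2.262e-14 at 20 degC
#' and 2.348e-14 mol/(m s Pa) at 25 degC.
#'
#' @inheritParams bunsen_coefficient
#' @param glucose logical; apply the 1.5% glucose depression.
#' @return Krogh coefficient in mol/(m s Pa).
#' @export
krogh_fluid <- function(t, mcl = 0, glucose = FALSE) {
  kf <- oxygen_diffusivity_water(t) * solubility_green_carritt(t, mcl)
  if (glucose) kf <- kf * (1 - 0.015)
  kf
}

#' RMS relative difference between two solubility curves
#'
#' Evaluates both functions on an inclusive temperature grid and reports
#' `100 * sqrt(mean(((f - g)/g)^2))` with `g` as the reference.
#'
#' @param f,g functions of temperature (kelvin).
#' @param t_lo,t_hi grid endpoints, kelvin.
#' @param step grid step, kelvin (default 1).
#' @return RMS relative difference, percent.
#' @export
rms_relative_difference <- function(f, g, t_lo, t_hi, step = 1) {
  if (!(t_lo < t_hi)) stop("empty temperature grid")
  grid <- seq(t_lo, t_hi, by = step)
  fv <- f(grid); gv <- g(grid)
  100 * sqrt(mean(((fv - gv) / gv)^2))
}
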