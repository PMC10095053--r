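#' @title Krogh-coefficient unit systems
#' @description
#' The physiology literature quotes the Krogh coefficient in at least seven
#' compound unit systems mixing amount units (mol, mmol, mL, cm^3, nM mm^3),
#' lengths (m, cm, mm), times (s, min) and pressures (Pa, atm, mmHg, torr).
#' Length/time/pressure conversions are exact (1 atm = 101325 Pa = 760 mmHg
#' = 760 torr); converting between molar and volumetric gas amounts requires
#' a gas molar volume, which depends on the (often unstated) temperature and
#' pressure convention - so those conversions demand an explicit `molar_volume`.
#' @name krogh_units
NULL

R_GAS <- 8.314462        # J/(mol K)
PA_PER_ATM <- 101325
PA_PER_MMHG <- 101325 / 760

#' Molar volume of an ideal gas
#'
#' `Vm = R T / p`, returned in L/mol. 22.414 at 0 degC / 1 atm (pre-1982
#' STP), 22.711 at 0 degC / 100 kPa, 24.055 at 20 degC / 1 atm (NTP). The
#' measured (non-ideal) O2 molar volume at 0 degC / 1 atm is 22.392 L/mol,
#' the package default for gas-amount conversions.
#'
#' @param t temperature, kelvin (> 0).
#' @param p pressure, Pa (> 0).
#' @return Molar volume in L/mol.
#' @export
molar_volume_ideal <- function(t, p = PA_PER_ATM) {
  if (any(t <= 0) || any(p <= 0)) stop("temperature and pressure must be positive")
  R_GAS * t / p * 1000
}

#' Non-ideal O2 molar volume at 0 degC, 1 atm (L/mol)
#' @export
VM_O2_DEFAULT <- 22.392

.amount_units <- c("mol", "mmol", "mL", "cm3", "nM.mm3")
.length_m <- c(m = 1, cm = 0.01, mm = 0.001)
.time_s <- c(s = 1, min = 60)
.press_pa <- c(Pa = 1, atm = PA_PER_ATM, mmHg = PA_PER_MMHG, torr = PA_PER_MMHG)

#' Define a Krogh-coefficient unit system
#'
#' @param gas_amount_unit one of `"mol"`, `"mmol"`, `"mL"`, `"cm3"`,
#'   `"nM.mm3"` (the van der Laarse amount unit, treated as 1e-9 mol with
#'   mm^3 volume bookkeeping; see Details).
#' @param length_unit `"m"`, `"cm"` or `"mm"`.
#' @param time_unit `"s"` or `"min"`.
#' @param pressure_unit `"Pa"`, `"atm"`, `"mmHg"` or `"torr"`.
#' @param molar_volume gas molar volume in L/mol; required when converting
#'   between molar and volumetric amount units. Default `NA` (unset).
#' @details The `nM.mm3` amount unit has internally unusual dimensioning in
#'   the source literature; it is implemented provisionally as nmol
#'   (1e-9 mol), the only reading with coherent dimensions.
#' @return An object of class `krogh_unit_system`.
#' @export
krogh_unit_system <- function(gas_amount_unit = "mol", length_unit = "m",
                              time_unit = "s", pressure_unit = "Pa",
                              molar_volume = NA_real_) {
  gas_amount_unit <- match.arg(gas_amount_unit, .amount_units)
  length_unit <- match.arg(length_unit, names(.length_m))
  time_unit <- match.arg(time_unit, names(.time_s))
  pressure_unit <- match.arg(pressure_unit, names(.press_pa))
  structure(list(gas_amount_unit = gas_amount_unit, length_unit = length_unit,
                 time_unit = time_unit, pressure_unit = pressure_unit,
                 molar_volume = molar_volume),
            class = "krogh_unit_system")
}

#' Named unit systems from the literature survey
#'
#' `si`, `mmol_cm_min_mmHg`, `mmol_cm_min_torr`, `nM_mm3_mm_s_mmHg`,
#' `mL_cm_min_atm`, `cm3_cm_min_atm`, `mL_cm_s_mmHg`.
#'
#' @param name system name (see Description).
#' @param molar_volume molar volume in L/mol attached to the system
#'   (default the non-ideal O2 value 22.392).
#' @return A [krogh_unit_system()].
#' @export
krogh_system <- function(name, molar_volume = VM_O2_DEFAULT) {
  switch(name,
    si = krogh_unit_system("mol", "m", "s", "Pa", molar_volume),
    mmol_cm_min_mmHg = krogh_unit_system("mmol", "cm", "min", "mmHg", molar_volume),
    mmol_cm_min_torr = krogh_unit_system("mmol", "cm", "min", "torr", molar_volume),
    nM_mm3_mm_s_mmHg = krogh_unit_system("nM.mm3", "mm", "s", "mmHg", molar_volume),
    mL_cm_min_atm = krogh_unit_system("mL", "cm", "min", "atm", molar_volume),
    cm3_cm_min_atm = krogh_unit_system("cm3", "cm", "min", "atm", molar_volume),
    mL_cm_s_mmHg = krogh_unit_system("mL", "cm", "s", "mmHg", molar_volume),
    stop("unknown Krogh unit system: ", name))
}

#' A Krogh coefficient with its unit system
#'
#' @param magnitude numeric magnitude (> 0 for physical coefficients).
#' @param system a [krogh_unit_system()] or a name accepted by
#'   [krogh_system()].
#' @return An object of class `krogh_value`.
#' @export
krogh_value <- function(magnitude, system = "si") {
  if (is.character(system)) system <- krogh_system(system)
  stopifnot(inherits(system, "krogh_unit_system"), is.numeric(magnitude))
  structure(list(magnitude = magnitude, system = system), class = "krogh_value")
}

#' @export
print.krogh_value <- function(x, ...) {
  s <- x$system
  cat(sprintf("%.6g %s/(%s.%s.%s)\n", x$magnitude, s$gas_amount_unit,
              s$length_unit, s$time_unit, s$pressure_unit))
  invisible(x)
}

amount_factor_mol <- function(unit, vm) {
  switch(unit,
    mol = 1,
    mmol = 1e-3,
    nM.mm3 = 1e-9,
    mL = , cm3 = {
      if (is.na(vm)) stop("molar volume required to convert volumetric gas amounts")
      1e-3 / vm   # mL gas -> mol, via Vm [L/mol]
    })
}

#' Convert a Krogh coefficient between unit systems
#'
#' Exact multiplicative conversion through SI. When either the source or
#' target amount unit is volumetric, a molar volume must be set on at least
#' one system (and must agree if set on both).
#'
#' @param v a [krogh_value()].
#' @param target a [krogh_unit_system()] or a name for [krogh_system()].
#' @return A [krogh_value()] in the target system.
#' @examples
#' kt <- krogh_value(1.29e-14, "si")
#' convert_krogh(kt, "mL_cm_min_atm")     # ~1.76e-5
#' convert_krogh(kt, "mmol_cm_min_mmHg")  # ~1.03e-9
#' @export
convert_krogh <- function(v, target) {
  stopifnot(inherits(v, "krogh_value"))
  if (is.character(target)) target <- krogh_system(target)
  stopifnot(inherits(target, "krogh_unit_system"))
  src <- v$system
  vm <- c(src$molar_volume, target$molar_volume)
  vm <- vm[!is.na(vm)]
  if (length(vm) == 2 && abs(vm[1] - vm[2]) > 1e-9 * vm[1])
    stop("source and target molar volumes disagree")
  vm <- if (length(vm)) vm[1] else NA_real_
  needs_vm <- function(s) s$gas_amount_unit %in% c("mL", "cm3")
  sys_factor <- function(s) {
    amount_factor_mol(s$gas_amount_unit, vm) /
      (.length_m[[s$length_unit]] * .time_s[[s$time_unit]] *
         .press_pa[[s$pressure_unit]])
  }
  if ((needs_vm(src) || needs_vm(target)) && is.na(vm))
    stop("molar volume required: mol <-> volumetric gas-amount conversion is ",
         "ambiguous without a stated temperature/pressure convention")
  si <- v$magnitude * sys_factor(src)
  krogh_value(si / sys_factor(target), target)
}
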