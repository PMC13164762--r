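#' Degree of protein binding from equilibrium dialysis
#'
#' `% bound = 100 (C_donor - C_receiver) / C_donor`, where the donor chamber
#' holds spiked matrix (plasma or brain homogenate) and the receiver holds
#' buffer after equilibration.
#'
#' @param donor,receiver chamber concentrations in the same units.
#' @return percent bound.
#' @export
percent_bound <- function(donor, receiver) {
  if (any(donor <= 0)) stop("donor concentration must be positive")
  100 * (donor - receiver) / donor
}

#' Fraction unbound from equilibrium dialysis
#'
#' At equilibrium the receiver (buffer) concentration equals the unbound
#' concentration in the donor, so `fu = C_receiver / C_donor`.
#'
#' @inheritParams percent_bound
#' @return fraction unbound.
#' @export
dialysis_fu <- function(donor, receiver) {
  if (any(donor <= 0)) stop("donor concentration must be positive")
  receiver / donor
}

#' Blood-to-plasma concentration ratio
#'
#' `R_b/p = C_blood / C_plasma`; values below 1 indicate the compound does
#' not partition into red blood cells.
#'
#' @param c_blood,c_plasma matched concentrations.
#' @return R_b/p.
#' @export
blood_plasma_ratio <- function(c_blood, c_plasma) {
  if (any(c_plasma <= 0)) stop("plasma concentration must be positive")
  c_blood / c_plasma
}

#' Kinetic solubility from a spiked dilution series
#'
#' Each nominal spiking level is classified as saturated when the measured
#' concentration falls below `threshold x nominal` (default 0.8). The
#' solubility estimate is the plateau: the mean measured concentration over
#' the saturated levels. When no level saturates, the highest measured
#' concentration is returned with `saturated_any = FALSE` (the true
#' solubility exceeds the tested range).
#'
#' @param nominal spiked nominal concentrations (ug/mL), >= 3 levels.
#' @param measured measured concentrations after equilibration (ug/mL).
#' @param threshold saturation cutoff as a fraction of nominal.
#' @return list with `solubility` (ug/mL), `saturated` (logical per level),
#'   `saturated_any`.
#' @export
kinetic_solubility <- function(nominal, measured, threshold = 0.8) {
  if (length(nominal) != length(measured)) stop("paired vectors required")
  if (length(nominal) < 1) stop("need at least one level")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  sat <- measured < threshold * nominal
  if (!any(sat)) {
    return(list(solubility = max(measured), saturated = sat,
                saturated_any = FALSE))
  }
  list(solubility = mean(measured[sat]), saturated = sat,
       saturated_any = TRUE)
}

#' Convert between molar and mass concentration
#'
#' `ng/mL = uM x M` for molar mass `M` in g/mol (equivalently ng/nmol).
#'
#' @param value concentration value(s).
#' @param direction `"uM_to_ng_ml"` or `"ng_ml_to_uM"`.
#' @param molar_mass g/mol; the default 483 corresponds to a protonated
#'   precursor at m/z 484.
#' @return converted concentration.
#' @examples
#' molar_convert(1.7, "uM_to_ng_ml")  # 821.1 ng/mL
#' @export
molar_convert <- function(value, direction = c("uM_to_ng_ml", "ng_ml_to_uM"),
                          molar_mass = 483) {
  direction <- match.arg(direction)
  if (molar_mass <= 0) stop("molar mass must be positive")
  switch(direction,
    uM_to_ng_ml = value * molar_mass,
    ng_ml_to_uM = value / molar_mass
  )
}
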