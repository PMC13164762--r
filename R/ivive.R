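#' Fit a mono-exponential decay to a microsomal time course
#'
#' Substrate-depletion kinetics: the analyte/IS area ratio is assumed to
#' decay as `ratio(t) = ratio(0) * exp(-k t)`. The elimination rate constant
#' `k` is minus the slope of the ordinary least-squares fit of `ln(ratio)`
#' against time, and `t1/2 = 0.693 / k`.
#'
#' @param time_min sampling times in minutes, strictly increasing from 0.
#' @param ratio analyte/IS area ratios, all > 0.
#' @return list with `k` (1/min), `t_half` (min, `Inf` when no decay),
#'   `r_squared`, `stable` (TRUE when the fitted k <= 0, i.e. no measurable
#'   depletion), and the underlying `lm` fit.
#' @export
fit_monoexponential_decay <- function(time_min, ratio) {
  if (length(time_min) < 3) stop("need >= 3 time points")
  if (any(diff(time_min) <= 0)) stop("times must be strictly increasing")
  if (any(ratio <= 0)) stop("log-domain error: all ratios must be positive")
  fit <- stats::lm(log(ratio) ~ time_min)
  k <- -unname(stats::coef(fit)["time_min"])
  stable <- k <= 0
  list(
    k = k,
    t_half = if (stable) Inf else 0.693 / k,
    r_squared = suppressWarnings(summary(fit)$r.squared),  # exact fits warn
    stable = stable,
    fit = fit
  )
}

#' Intrinsic clearance from a microsomal half-life
#'
#' `CL_int = (0.693 / t1/2) * V / m_protein`, in mL/min per mg microsomal
#' protein. For a typical incubation at 0.5 mg/mL protein in 0.5 mL,
#' `protein_mg = 0.25`.
#'
#' @param t_half depletion half-life, minutes.
#' @param incubation_volume_ml incubation volume, mL.
#' @param protein_mg microsomal protein in the incubation, mg
#'   (protein concentration x volume).
#' @return CL_int in mL/min/mg protein.
#' @export
clint_from_halflife <- function(t_half, incubation_volume_ml = 0.5,
                                protein_mg = 0.25) {
  if (any(c(t_half, incubation_volume_ml, protein_mg) <= 0)) {
    stop("all inputs must be positive")
  }
  (0.693 / t_half) * incubation_volume_ml / protein_mg
}

#' Physiological scaling constants for liver clearance
#'
#' Microsomal protein yield per gram of liver and liver weight per kg body
#' weight (mouse 45 mg/g and 60 g/kg; human 32 mg/g and 25 g/kg), plus
#' hepatic blood flow where the species value is established (mouse
#' 90 mL/min/kg). `fu_plasma` is compound-specific and left for the caller.
#'
#' @param species `"mouse"` or `"human"`.
#' @param fu_plasma optional fraction unbound in plasma for the compound.
#' @return list with `species`, `mg_protein_per_g_liver`,
#'   `g_liver_per_kg_bw`, `hepatic_blood_flow` (mL/min/kg, NA for human),
#'   `fu_plasma`.
#' @export
species_scaling <- function(species = c("mouse", "human"), fu_plasma = NULL) {
  species <- match.arg(species)
  p <- switch(species,
    mouse = list(mg_protein_per_g_liver = 45, g_liver_per_kg_bw = 60,
                 hepatic_blood_flow = 90),
    human = list(mg_protein_per_g_liver = 32, g_liver_per_kg_bw = 25,
                 hepatic_blood_flow = NA_real_)
  )
  c(list(species = species), p, list(fu_plasma = fu_plasma))
}

#' Scale microsomal intrinsic clearance to the whole liver
#'
#' `CL_H,int = CL_int x (mg protein / g liver) x (g liver / kg body weight)`,
#' giving mL/min/kg body weight.
#'
#' @param clint CL_int in mL/min/mg protein.
#' @param scaling a [species_scaling()] list (or any list with
#'   `mg_protein_per_g_liver` and `g_liver_per_kg_bw`).
#' @return CL_H,int in mL/min/kg.
#' @export
scale_clint_to_liver <- function(clint, scaling = species_scaling("mouse")) {
  if (clint < 0) stop("CL_int must be non-negative")
  stopifnot(scaling$mg_protein_per_g_liver > 0, scaling$g_liver_per_kg_bw > 0)
  clint * scaling$mg_protein_per_g_liver * scaling$g_liver_per_kg_bw
}

#' Fraction unbound in the microsomal incubation from logP
#'
#' Lipophilicity-based estimate of nonspecific microsomal binding:
#' `fu_inc = 1 / (1 + 10^(0.53 logP - 1.42))`, strictly decreasing in logP
#' and mapping onto (0, 1).
#'
#' @param logp octanol-water partition coefficient (log10).
#' @return fraction unbound in the incubation.
#' @export
fraction_unbound_microsomes <- function(logp) {
  if (any(!is.finite(logp))) stop("logP must be finite")
  1 / (1 + 10^(0.53 * logp - 1.42))
}

#' Well-stirred hepatic clearance
#'
#' The well-stirred (venous-equilibrium) liver model, with the intrinsic
#' clearance corrected for nonspecific microsomal binding:
#' `CL_H = Q * fu_p * (CL_H,int / fu_inc) / (Q + fu_p * (CL_H,int / fu_inc))`.
#' The prediction is bounded above by hepatic blood flow `Q` (flow-limited
#' extraction).
#'
#' @param clh_int scaled hepatic intrinsic clearance, mL/min/kg.
#' @param fu_plasma fraction unbound in plasma, in (0, 1].
#' @param fu_inc fraction unbound in the microsomal incubation, in (0, 1].
#' @param q hepatic blood flow, mL/min/kg (90 in mouse).
#' @return predicted hepatic clearance, mL/min/kg.
#' @export
well_stirred_clearance <- function(clh_int, fu_plasma, fu_inc, q) {
  if (q <= 0) stop("hepatic blood flow must be positive")
  if (fu_plasma <= 0 || fu_plasma > 1 || fu_inc <= 0 || fu_inc > 1) {
    stop("unbound fractions must lie in (0, 1]")
  }
  if (clh_int < 0) stop("CL_H,int must be non-negative")
  x <- fu_plasma * clh_int / fu_inc
  q * x / (q + x)
}

#' In vitro-in vivo extrapolation chain
#'
#' Runs the full microsomal-stability-to-hepatic-clearance chain: half-life
#' (or a precomputed CL_int / CL_H,int) -> intrinsic clearance -> liver
#' scaling -> microsomal-binding correction from logP -> well-stirred model.
#' Supply exactly one of `t_half`, `clint`, `clh_int`; downstream quantities
#' are computed from it. The whole-body prediction `clh_predict` is only
#' computed when both `fu_plasma` and a hepatic blood flow are available
#' (human Q is deliberately not defaulted).
#'
#' @param t_half microsomal depletion half-life, min.
#' @param clint intrinsic clearance, mL/min/mg protein.
#' @param clh_int scaled hepatic intrinsic clearance, mL/min/kg.
#' @param scaling a [species_scaling()] list.
#' @param logp compound logP for the microsomal-binding correction.
#' @param fu_plasma fraction unbound in plasma; defaults to
#'   `scaling$fu_plasma`.
#' @param q hepatic blood flow mL/min/kg; defaults to
#'   `scaling$hepatic_blood_flow`.
#' @param incubation_volume_ml,protein_mg incubation geometry for
#'   [clint_from_halflife()].
#' @return object of class `ivive_result`: list with `t_half`, `clint`,
#'   `clh_int`, `fu_inc`, `clh_predict` (NA when Q or fu_plasma missing),
#'   `species`.
#' @examples
#' ivive_chain(clh_int = 41, logp = 2.3, fu_plasma = 0.025, q = 90)
#' @export
ivive_chain <- function(t_half = NULL, clint = NULL, clh_int = NULL,
                        scaling = species_scaling("mouse"), logp,
                        fu_plasma = scaling$fu_plasma,
                        q = scaling$hepatic_blood_flow,
                        incubation_volume_ml = 0.5, protein_mg = 0.25) {
  given <- !c(is.null(t_half), is.null(clint), is.null(clh_int))
  if (sum(given) != 1) {
    stop("supply exactly one of t_half, clint, clh_int")
  }
  if (!is.null(t_half)) {
    clint <- clint_from_halflife(t_half, incubation_volume_ml, protein_mg)
  }
  if (!is.null(clint) && is.null(clh_int)) {
    clh_int <- scale_clint_to_liver(clint, scaling)
  }
  fu_inc <- fraction_unbound_microsomes(logp)
  clh_predict <- if (!is.null(fu_plasma) && !is.null(q) &&
                     is.finite(q) && !is.na(fu_plasma)) {
    well_stirred_clearance(clh_int, fu_plasma, fu_inc, q)
  } else {
    NA_real_
  }
  structure(
    list(
      t_half = if (is.null(t_half)) NA_real_ else t_half,
      clint = if (is.null(clint)) NA_real_ else clint,
      clh_int = clh_int, fu_inc = fu_inc, clh_predict = clh_predict,
      species = scaling$species
    ),
    class = "ivive_result"
  )
}

#' @export
print.ivive_result <- function(x, ...) {
  cat("IVIVE chain", if (!is.null(x$species)) paste0("(", x$species, ")"), "\n")
  cat(sprintf("  t1/2      : %s min\n", format(x$t_half, digits = 3)))
  cat(sprintf("  CL_int    : %s mL/min/mg\n", format(x$clint, digits = 3)))
  cat(sprintf("  CL_H,int  : %s mL/min/kg\n", format(x$clh_int, digits = 3)))
  cat(sprintf("  fu,inc    : %s\n", format(x$fu_inc, digits = 3)))
  cat(sprintf("  CL_H,pred : %s mL/min/kg\n", format(x$clh_predict, digits = 3)))
  invisible(x)
}
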