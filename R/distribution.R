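#' Unbound concentration or tissue content
#'
#' Scales a total concentration (ng/mL) or tissue content (ng/g) by the
#' fraction unbound in that matrix.
#'
#' @param value total concentration/content.
#' @param fu fraction unbound, in (0, 1].
#' @return unbound value in the same units.
#' @export
unbound <- function(value, fu) {
  if (any(fu <= 0) || any(fu > 1)) stop("fu must be in (0, 1]")
  value * fu
}

#' Reporting-style rounding for disposition tables
#'
#' Rounds a value the way compact disposition tables print them:
#' concentrations/contents to two significant figures below 10 and to the
#' nearest integer at 10 or above; ratios (Kp, Kp,uu) to two decimals. Mode
#' `"none"` returns full precision; full precision is the computational
#' default everywhere, the policy only exists so printed cells can be
#' reproduced and checked.
#'
#' @param x numeric value(s).
#' @param kind `"conc"` (concentration/content) or `"ratio"`.
#' @param policy `"none"` or `"table"`.
#' @return rounded (or untouched) values.
#' @export
round_report <- function(x, kind = c("conc", "ratio"),
                         policy = c("none", "table")) {
  kind <- match.arg(kind)
  policy <- match.arg(policy)
  if (policy == "none") return(x)
  if (kind == "ratio") return(round(x, 2))
  ifelse(abs(x) >= 10, round(x), signif(x, 2))
}

#' Unbound brain-to-plasma partition coefficient
#'
#' `Kp,uu,brain = (C_brain * fu_brain) / (C_plasma * fu_plasma)`: the ratio
#' of unbound brain content to unbound plasma concentration, the exposure
#' metric for CNS penetration (tissue density ~1 g/mL, so ng/g and ng/mL are
#' treated as commensurate). Under the `"table"` policy the unbound values
#' are rounded to reporting precision before the ratio, and the ratio to two
#' decimals, mirroring how a printed table chains its cells.
#'
#' @param brain_content total brain content, ng/g.
#' @param plasma_conc total plasma concentration, ng/mL, > 0.
#' @param fu_brain,fu_plasma fractions unbound (defaults 0.057 and 0.025).
#' @param policy rounding policy, see [round_report()].
#' @return Kp,uu,brain (dimensionless).
#' @export
kpuu_brain <- function(brain_content, plasma_conc, fu_brain = 0.057,
                       fu_plasma = 0.025, policy = c("none", "table")) {
  policy <- match.arg(policy)
  if (any(plasma_conc <= 0)) stop("plasma concentration must be positive")
  ub <- round_report(unbound(brain_content, fu_brain), "conc", policy)
  up <- round_report(unbound(plasma_conc, fu_plasma), "conc", policy)
  round_report(ub / up, "ratio", policy)
}

#' Total tissue-to-plasma partition ratio
#'
#' `Kp = C_tissue / C_plasma` at a matched sampling time.
#'
#' @param tissue_content ng/g.
#' @param plasma_conc ng/mL, > 0.
#' @return Kp (dimensionless).
#' @export
tissue_kp <- function(tissue_content, plasma_conc) {
  if (any(plasma_conc <= 0)) stop("plasma concentration must be positive")
  tissue_content / plasma_conc
}

#' Exposure relative to a potency reference
#'
#' Ratio of an observed concentration to an in vitro IC50 (same units), with
#' a flag for exposures at or above the reference.
#'
#' @param conc concentration, ng/mL.
#' @param ic50 reference IC50, ng/mL, > 0.
#' @return list with `ratio` and `above` (ratio >= 1).
#' @export
exposure_vs_ic50 <- function(conc, ic50) {
  if (any(ic50 <= 0)) stop("IC50 must be positive")
  ratio <- conc / ic50
  list(ratio = ratio, above = ratio >= 1)
}

#' Brain-penetration table
#'
#' Builds the per-time-point brain disposition summary: total and unbound
#' brain content, total and unbound plasma concentration, Kp,uu,brain, and
#' the exposure ratio of unbound brain content to the IC50. When reference
#' Kp,uu values are supplied (e.g. previously reported cells), the computed
#' values are compared against them and disagreement beyond the rounding
#' grain is flagged in `kpuu_discrepant` — reported, never silently matched.
#'
#' @param time_h sampling times, h.
#' @param brain_content total brain content, ng/g.
#' @param plasma_conc total plasma concentration, ng/mL.
#' @param fu_brain,fu_plasma fractions unbound.
#' @param ic50 reference IC50, ng/mL (optional).
#' @param policy rounding policy, see [round_report()].
#' @param reference_kpuu optional vector of reported Kp,uu values to audit.
#' @return data.frame, one row per time point, class `brain_penetration`.
#' @export
brain_penetration <- function(time_h, brain_content, plasma_conc,
                              fu_brain = 0.057, fu_plasma = 0.025,
                              ic50 = NULL, policy = c("none", "table"),
                              reference_kpuu = NULL) {
  policy <- match.arg(policy)
  n <- length(time_h)
  stopifnot(length(brain_content) == n, length(plasma_conc) == n)
  ub <- round_report(unbound(brain_content, fu_brain), "conc", policy)
  up <- round_report(unbound(plasma_conc, fu_plasma), "conc", policy)
  kpuu <- kpuu_brain(brain_content, plasma_conc, fu_brain, fu_plasma, policy)
  out <- data.frame(
    time_h = time_h,
    brain_content = brain_content,
    unbound_brain = ub,
    plasma_conc = plasma_conc,
    unbound_plasma = up,
    kpuu = kpuu
  )
  if (!is.null(ic50)) {
    out$unbound_brain_vs_ic50 <- ub / ic50
  }
  if (!is.null(reference_kpuu)) {
    stopifnot(length(reference_kpuu) == n)
    out$kpuu_reference <- reference_kpuu
    # discrepant when the reference cell cannot be obtained from the data at
    # its own precision (half a unit in its last reported decimal)
    frac_digits <- vapply(reference_kpuu, function(v) {
      s <- sub("0+$", "", format(v, scientific = FALSE))
      if (!grepl("\\.", s)) 0L else nchar(sub(".*\\.", "", s))
    }, integer(1))
    out$kpuu_discrepant <- abs(kpuu - reference_kpuu) >
      0.5 * 10^(-frac_digits)
  }
  class(out) <- c("brain_penetration", "data.frame")
  out
}
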