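#' ICH M10 batch-acceptance thresholds
#'
#' Default acceptance limits for a chromatographic bioanalytical assay:
#' accuracy (% bias) within +/-20% at the LLOQ and +/-15% elsewhere,
#' precision (% RSD) at most 20% at the LLOQ and 15% elsewhere, carryover in
#' a blank after the high QC at most 20% of the analyte LLOQ response and 5%
#' of the internal-standard response (the same limits apply per source in
#' selectivity), and storage-stability recovery within 85-115% of fresh QCs.
#'
#' @param bias_lloq,bias_other accuracy limits, percent.
#' @param rsd_lloq,rsd_other precision limits, percent.
#' @param carryover_analyte,carryover_is blank response ceilings as fractions
#'   of the LLOQ analyte / IS response.
#' @param stability_low,stability_high stability recovery window, percent.
#' @return named list of limits, class `threshold_set`.
#' @export
ich_m10_thresholds <- function(bias_lloq = 20, bias_other = 15,
                               rsd_lloq = 20, rsd_other = 15,
                               carryover_analyte = 0.20, carryover_is = 0.05,
                               stability_low = 85, stability_high = 115) {
  out <- list(
    bias_lloq = bias_lloq, bias_other = bias_other,
    rsd_lloq = rsd_lloq, rsd_other = rsd_other,
    carryover_analyte = carryover_analyte, carryover_is = carryover_is,
    stability_low = stability_low, stability_high = stability_high
  )
  if (any(unlist(out) <= 0)) stop("all threshold limits must be positive")
  structure(out, class = "threshold_set")
}

qc_is_lloq <- function(level) toupper(as.character(level)) == "LLOQ"

#' Accuracy and precision of quality-control replicates
#'
#' Per-level accuracy (% bias of the replicate mean from nominal) and
#' precision (% RSD, sample standard deviation over mean). Intra-day
#' statistics are computed within each run; inter-day statistics pool every
#' replicate across runs.
#'
#' @param qc data.frame with columns `level` (e.g. LLOQ/LQC/MQC/HQC),
#'   `nominal` (ng/mL), `run_id`, and `value` (back-calculated ng/mL).
#' @param grouping `"intra_day"` (per run) or `"inter_day"` (pooled).
#' @param thresholds a [ich_m10_thresholds()] set.
#' @return data.frame with one row per level (and per run for intra-day):
#'   `level`, `run_id` (NA when pooled), `nominal`, `n`, `mean`, `bias_pct`,
#'   `rsd_pct`, `bias_pass`, `rsd_pass`.
#' @export
accuracy_precision <- function(qc, grouping = c("intra_day", "inter_day"),
                               thresholds = ich_m10_thresholds()) {
  grouping <- match.arg(grouping)
  stopifnot(all(c("level", "nominal", "value") %in% names(qc)))
  if (grouping == "intra_day" && !"run_id" %in% names(qc)) {
    stop("intra_day grouping needs a run_id column")
  }
  key <- if (grouping == "intra_day") {
    interaction(qc$level, qc$run_id, drop = TRUE)
  } else {
    factor(qc$level)
  }
  rows <- lapply(split(qc, key), function(g) {
    if (nrow(g) < 2) stop("need >= 2 replicates per group for statistics")
    nominal <- unique(g$nominal)
    if (length(nominal) != 1) stop("mixed nominal within one QC level group")
    m <- mean(g$value)
    if (m == 0) stop("undefined RSD: replicate mean is zero")
    lloq <- qc_is_lloq(g$level[1])
    bias <- 100 * (m - nominal) / nominal
    rsd <- 100 * stats::sd(g$value) / m
    data.frame(
      level = as.character(g$level[1]),
      run_id = if (grouping == "intra_day") as.character(g$run_id[1]) else NA_character_,
      nominal = nominal, n = nrow(g), mean = m,
      bias_pct = bias, rsd_pct = rsd,
      bias_pass = abs(bias) <= if (lloq) thresholds$bias_lloq else thresholds$bias_other,
      rsd_pass = rsd <= if (lloq) thresholds$rsd_lloq else thresholds$rsd_other
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extraction recovery
#'
#' Mean peak area of extracted samples relative to samples spiked into
#' post-extraction matrix, as a percentage.
#'
#' @param extracted_areas,postspiked_areas peak areas at one QC level.
#' @return recovery in percent.
#' @export
recovery <- function(extracted_areas, postspiked_areas) {
  if (!length(extracted_areas) || !length(postspiked_areas)) {
    stop("both area sets must be non-empty")
  }
  mp <- mean(postspiked_areas)
  if (mp <= 0) stop("post-extracted mean must be positive")
  100 * mean(extracted_areas) / mp
}

#' Matrix effect
#'
#' Ion suppression/enhancement: percent deviation of post-extraction spiked
#' areas from neat (mobile-phase) reference areas. Positive values indicate
#' enhancement; the usual acceptance compares `abs()` to a 15% ceiling.
#'
#' @param postspiked_areas,neat_areas peak areas at one QC level.
#' @return matrix effect in percent (signed).
#' @export
matrix_effect <- function(postspiked_areas, neat_areas) {
  mn <- mean(neat_areas)
  if (mn <= 0) stop("neat reference mean must be positive")
  100 * (mean(postspiked_areas) / mn - 1)
}

#' Carryover check after a high-concentration injection
#'
#' A blank injected after the high QC must show at most 20% of the analyte
#' response at the LLOQ and at most 5% of the internal-standard response.
#'
#' @param blank_analyte,lloq_analyte analyte responses in the blank and at
#'   the LLOQ.
#' @param blank_is,lloq_is internal-standard responses.
#' @param thresholds a [ich_m10_thresholds()] set.
#' @return list with `analyte_fraction`, `is_fraction`, `pass`.
#' @export
carryover_check <- function(blank_analyte, lloq_analyte, blank_is, lloq_is,
                            thresholds = ich_m10_thresholds()) {
  if (lloq_analyte <= 0 || lloq_is <= 0) {
    stop("invalid reference: LLOQ responses must be positive")
  }
  fa <- blank_analyte / lloq_analyte
  fi <- blank_is / lloq_is
  list(
    analyte_fraction = fa, is_fraction = fi,
    pass = fa <= thresholds$carryover_analyte && fi <= thresholds$carryover_is
  )
}

#' Selectivity across independent blank-matrix sources
#'
#' Applies the carryover response limits to blanks from multiple matrix lots
#' (six in a typical validation): each source passes when its blank analyte
#' response is at most 20% of the LLOQ response and its blank IS response at
#' most 5% of the IS response.
#'
#' @param blank_analyte,blank_is vectors of blank responses, one per source.
#' @param lloq_analyte,is_response reference responses.
#' @param thresholds a [ich_m10_thresholds()] set.
#' @return data.frame per source (`source`, `analyte_fraction`,
#'   `is_fraction`, `pass`) with an `overall_pass` attribute.
#' @export
selectivity_check <- function(blank_analyte, blank_is, lloq_analyte,
                              is_response,
                              thresholds = ich_m10_thresholds()) {
  if (!length(blank_analyte)) stop("need at least one blank source")
  if (length(blank_is) != length(blank_analyte)) {
    stop("blank_analyte and blank_is must have one entry per source")
  }
  if (lloq_analyte <= 0 || is_response <= 0) {
    stop("invalid reference: LLOQ/IS responses must be positive")
  }
  fa <- blank_analyte / lloq_analyte
  fi <- blank_is / is_response
  out <- data.frame(
    source = seq_along(fa),
    analyte_fraction = fa, is_fraction = fi,
    pass = fa <= thresholds$carryover_analyte & fi <= thresholds$carryover_is
  )
  attr(out, "overall_pass") <- all(out$pass)
  out
}

#' Storage-stability recovery
#'
#' Mean stored-sample concentration relative to freshly prepared QCs;
#' acceptable when within 85-115%.
#'
#' @param stored_values,fresh_values back-calculated concentrations.
#' @param thresholds a [ich_m10_thresholds()] set.
#' @return list with `recovery_pct` and `pass`.
#' @export
storage_stability <- function(stored_values, fresh_values,
                              thresholds = ich_m10_thresholds()) {
  mf <- mean(fresh_values)
  if (mf <= 0) stop("fresh mean must be positive")
  rec <- 100 * mean(stored_values) / mf
  list(
    recovery_pct = rec,
    pass = rec >= thresholds$stability_low & rec <= thresholds$stability_high
  )
}

#' Percent remaining after matrix incubation
#'
#' Enzymatic-degradation check: concentration after incubation (typically
#' 5 h at 37 C in plasma or brain homogenate) as a percentage of time zero.
#'
#' @param conc_t concentration after incubation.
#' @param conc_0 concentration at time zero (> 0).
#' @return percent remaining.
#' @export
matrix_incubation_remaining <- function(conc_t, conc_0) {
  if (conc_0 <= 0) stop("time-zero concentration must be positive")
  100 * conc_t / conc_0
}
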