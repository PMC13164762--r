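#' Construct a concentration-time profile
#'
#' One subject's dosed route, dose and timed plasma concentrations, with the
#' assay LLOQ attached so below-quantitation handling is explicit.
#'
#' @param time sampling times, hours, strictly increasing.
#' @param conc concentrations, ng/mL, non-negative (0 marks a BLQ sample).
#' @param dose dose in mg/kg, > 0.
#' @param route `"IV"` (bolus) or `"PO"`.
#' @param subject_id optional label.
#' @param lloq lower limit of quantitation, ng/mL (default 0.2).
#' @return object of class `pk_profile`.
#' @export
pk_profile <- function(time, conc, dose, route = c("IV", "PO"),
                       subject_id = NA_character_, lloq = 0.2) {
  route <- match.arg(route)
  if (length(time) != length(conc)) stop("time and conc lengths differ")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (dose <= 0) stop("dose must be positive")
  structure(
    list(time = time, conc = conc, dose = dose, route = route,
         subject_id = subject_id, lloq = lloq),
    class = "pk_profile"
  )
}

#' @export
print.pk_profile <- function(x, ...) {
  cat(sprintf("PK profile %s: %s %.3g mg/kg, %d samples (LLOQ %.3g ng/mL)\n",
              x$subject_id, x$route, x$dose, length(x$time), x$lloq))
  invisible(x)
}

# BLQ convention: below-LLOQ values before Tmax are treated as true zeros
# (absorption has not started); embedded and trailing BLQ samples are
# excluded from all calculations.
quantifiable_profile <- function(profile) {
  blq <- profile$conc < profile$lloq
  if (all(blq)) stop("no quantifiable samples in profile")
  i_max <- which.max(profile$conc)
  keep_zero <- blq & seq_along(blq) < i_max
  drop <- blq & !keep_zero
  time <- profile$time[!drop]
  conc <- profile$conc[!drop]
  conc[time < profile$time[i_max] & conc < profile$lloq] <- 0
  list(time = time, conc = conc)
}

#' Observed Cmax and Tmax
#'
#' Maximum observed concentration and its time; ties are broken by the
#' earliest occurrence.
#'
#' @param profile a [pk_profile()].
#' @return list with `cmax` (ng/mL) and `tmax` (h).
#' @export
cmax_tmax <- function(profile) {
  q <- quantifiable_profile(profile)
  i <- which.max(q$conc)  # which.max returns the first maximum
  list(cmax = q$conc[i], tmax = q$time[i])
}

# trapezoidal AUC on cleaned vectors
auc_segments <- function(time, conc, method) {
  dt <- diff(time)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  seg <- dt * (c1 + c2) / 2
  if (method == "linear_up_log_down") {
    logdown <- c2 < c1 & c2 > 0 & c1 > 0
    seg[logdown] <- dt[logdown] * (c1[logdown] - c2[logdown]) /
      log(c1[logdown] / c2[logdown])
  }
  seg
}

#' Trapezoidal AUC to the last quantifiable concentration
#'
#' Linear trapezoidal rule by default; `"linear_up_log_down"` switches to
#' the logarithmic trapezoid on strictly decreasing positive segments, which
#' is exact for mono-exponential decline.
#'
#' @param profile a [pk_profile()].
#' @param method `"linear"` or `"linear_up_log_down"`.
#' @return AUC_last in ng·h/mL.
#' @export
auc_trapezoid <- function(profile, method = c("linear", "linear_up_log_down")) {
  method <- match.arg(method)
  q <- quantifiable_profile(profile)
  if (length(q$time) < 2) stop("need >= 2 quantifiable samples")
  sum(auc_segments(q$time, q$conc, method))
}

#' Terminal elimination rate constant by best-fit window search
#'
#' Log-linear regression over candidate terminal windows: every run of at
#' least `min_points` consecutive samples ending at the last quantifiable
#' point and excluding Cmax. The window maximizing adjusted r-squared wins;
#' ties go to the window with fewer points. A non-positive slope (no
#' terminal decline) yields `lambda_z = NA` and a flag.
#'
#' @param profile a [pk_profile()].
#' @param min_points minimum points in the regression (default 3).
#' @return list with `lambda_z` (1/h, NA when absent), `n_points`, `adj_r2`,
#'   `t_half` (h), `no_terminal_phase`.
#' @export
select_lambda_z <- function(profile, min_points = 3) {
  q <- quantifiable_profile(profile)
  pos <- q$conc > 0
  time <- q$time[pos]
  conc <- q$conc[pos]
  i_cmax <- which.max(conc)
  # candidate points: strictly after Cmax
  idx <- which(seq_along(time) > i_cmax)
  n <- length(idx)
  if (n < min_points) {
    # too few declining points to define a terminal phase (e.g. a rising
    # profile whose maximum is the last sample)
    return(list(lambda_z = NA_real_, n_points = 0L, adj_r2 = NA_real_,
                t_half = NA_real_, no_terminal_phase = TRUE))
  }
  best <- NULL
  for (start in 1:(n - min_points + 1)) {
    sel <- idx[start:n]
    fit <- stats::lm(log(conc[sel]) ~ time[sel])
    slope <- unname(stats::coef(fit)[2])
    adj <- suppressWarnings(summary(fit))$adj.r.squared  # exact fits warn
    if (slope >= 0) next
    # prefer higher adjusted r2; on (near-)ties prefer fewer points
    if (is.null(best) || adj > best$adj_r2 + 1e-10 ||
        (abs(adj - best$adj_r2) <= 1e-10 && length(sel) < best$n_points)) {
      best <- list(lambda_z = -slope, n_points = length(sel), adj_r2 = adj)
    }
  }
  if (is.null(best)) {
    return(list(lambda_z = NA_real_, n_points = 0L, adj_r2 = NA_real_,
                t_half = NA_real_, no_terminal_phase = TRUE))
  }
  best$t_half <- log(2) / best$lambda_z
  best$no_terminal_phase <- FALSE
  best
}

#' Non-compartmental analysis of a single profile
#'
#' Computes the standard NCA parameter set: Cmax/Tmax, AUC to the last
#' quantifiable point, terminal slope and half-life, AUC extrapolated to
#' infinity (`AUC_last + C_last / lambda_z`), clearance `dose / AUC_inf` and
#' terminal volume `CL / lambda_z`. After oral dosing, clearance and volume
#' are apparent (CL/F, Vz/F); the `route` field records which.
#'
#' Units: dose mg/kg and AUC ng·h/mL give CL in L/h/kg via
#' `CL = 1000 * dose / AUC_inf`.
#'
#' @param profile a [pk_profile()].
#' @param auc_method integration rule, see [auc_trapezoid()].
#' @param min_points minimum terminal points, see [select_lambda_z()].
#' @return object of class `nca_result`: list with `cmax`, `tmax`,
#'   `auc_last`, `auc_inf`, `lambda_z`, `lambda_z_n`, `lambda_z_adj_r2`,
#'   `t_half`, `cl` (L/h/kg; CL/F for PO), `vz` (L/kg; Vz/F for PO),
#'   `pct_extrapolated`, `dose`, `route`, `subject_id`, `auc_method`.
#' @export
nca <- function(profile, auc_method = c("linear", "linear_up_log_down"),
                min_points = 3) {
  auc_method <- match.arg(auc_method)
  cm <- cmax_tmax(profile)
  auc_last <- auc_trapezoid(profile, auc_method)
  lz <- select_lambda_z(profile, min_points)
  q <- quantifiable_profile(profile)
  c_last <- q$conc[max(which(q$conc > 0))]
  if (!lz$no_terminal_phase) {
    auc_inf <- auc_last + c_last / lz$lambda_z
    cl <- 1000 * profile$dose / auc_inf
    vz <- cl / lz$lambda_z
  } else {
    auc_inf <- cl <- vz <- NA_real_
  }
  structure(
    list(
      cmax = cm$cmax, tmax = cm$tmax,
      auc_last = auc_last, auc_inf = auc_inf,
      lambda_z = lz$lambda_z, lambda_z_n = lz$n_points,
      lambda_z_adj_r2 = lz$adj_r2, t_half = lz$t_half,
      cl = cl, vz = vz,
      pct_extrapolated = if (is.na(auc_inf)) NA_real_ else
        100 * (auc_inf - auc_last) / auc_inf,
      dose = profile$dose, route = profile$route,
      subject_id = profile$subject_id, auc_method = auc_method
    ),
    class = "nca_result"
  )
}

#' @export
print.nca_result <- function(x, ...) {
  suffix <- if (x$route == "PO") "/F" else ""
  cat(sprintf("NCA (%s, %.3g mg/kg)%s\n", x$route, x$dose,
              if (is.na(x$subject_id)) "" else paste0(" subject ", x$subject_id)))
  cat(sprintf("  Cmax %.4g ng/mL at Tmax %.3g h\n", x$cmax, x$tmax))
  cat(sprintf("  AUC_last %.5g, AUC_inf %.5g ng.h/mL (%.1f%% extrapolated)\n",
              x$auc_last, x$auc_inf, x$pct_extrapolated))
  cat(sprintf("  lambda_z %.4g 1/h (n=%d, adj r2 %.4f), t1/2 %.3g h\n",
              x$lambda_z, x$lambda_z_n, x$lambda_z_adj_r2, x$t_half))
  cat(sprintf("  CL%s %.4g L/h/kg, Vz%s %.4g L/kg\n",
              suffix, x$cl, suffix, x$vz))
  invisible(x)
}

#' Absolute oral bioavailability
#'
#' Dose-normalized exposure ratio
#' `F = 100 (AUC_po / dose_po) / (AUC_iv / dose_iv)`, in percent. Arguments
#' may be [nca()] results (AUC_inf and dose are taken from them) or raw
#' numbers.
#'
#' @param auc_po,auc_iv AUCs (ng·h/mL) or `nca_result` objects.
#' @param dose_po,dose_iv doses (mg/kg); ignored when results are passed.
#' @return F in percent.
#' @examples
#' bioavailability(6803, 11608, dose_po = 10, dose_iv = 2.5)  # 14.65
#' @export
bioavailability <- function(auc_po, auc_iv, dose_po = NULL, dose_iv = NULL) {
  if (inherits(auc_po, "nca_result")) {
    dose_po <- auc_po$dose
    auc_po <- auc_po$auc_inf
  }
  if (inherits(auc_iv, "nca_result")) {
    dose_iv <- auc_iv$dose
    auc_iv <- auc_iv$auc_inf
  }
  if (is.null(dose_po) || is.null(dose_iv)) stop("doses are required")
  if (auc_po <= 0 || auc_iv <= 0) stop("AUCs must be positive")
  100 * (auc_po / dose_po) / (auc_iv / dose_iv)
}

#' Convert apparent oral parameters to absolute ones
#'
#' Multiplies an apparent oral parameter (CL/F or Vz/F) by the
#' bioavailability fraction, recovering CL or Vz.
#'
#' @param value apparent parameter (CL/F in L/h/kg or Vz/F in L/kg).
#' @param f_fraction bioavailability as a fraction in (0, 1].
#' @return the bioavailability-normalized parameter.
#' @export
normalize_oral_by_f <- function(value, f_fraction) {
  if (any(f_fraction <= 0) || any(f_fraction > 1)) {
    stop("bioavailability fraction must be in (0, 1]")
  }
  value * f_fraction
}

#' Clearance as a fraction of hepatic blood flow
#'
#' `100 * CL / Q_blood`; low percentages indicate a low-extraction compound.
#'
#' @param cl plasma clearance, L/h/kg.
#' @param q_blood hepatic blood flow, L/h/kg (3.6 in mouse).
#' @return percent of hepatic blood flow.
#' @export
fraction_of_hepatic_flow <- function(cl, q_blood = 3.6) {
  if (q_blood <= 0) stop("hepatic blood flow must be positive")
  100 * cl / q_blood
}

#' Group summary of NCA results
#'
#' Arithmetic mean and sample standard deviation of each NCA parameter
#' across subjects (per-subject analysis first, then summary).
#'
#' @param results list of [nca()] results.
#' @return data.frame with `parameter`, `mean`, `sd` (NA when n < 2), `n`.
#' @export
summarize_nca <- function(results) {
  if (!length(results)) stop("no results to summarize")
  params <- c("cmax", "tmax", "auc_last", "auc_inf", "lambda_z", "t_half",
              "cl", "vz", "pct_extrapolated")
  rows <- lapply(params, function(p) {
    v <- vapply(results, function(r) r[[p]], numeric(1))
    v <- v[!is.na(v)]
    data.frame(
      parameter = p,
      mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
      n = length(v)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
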