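#' Simulate plasma concentration-time profiles
#'
#' One-compartment closed forms with lognormal inter-subject variability and
#' proportional residual error, emulating a small-rodent PK study. IV bolus:
#' `C(t) = (dose/V) exp(-(CL/V) t)`; first-order-absorption oral:
#' `C(t) = F dose ka / (V (ka - ke)) (exp(-ke t) - exp(-ka t))` with
#' `ke = CL/V` (`ka` is nudged when it collides with `ke`). Concentrations
#' below the LLOQ are censored to 0 (the BLQ marker). Each profile carries
#' the simulation truth in `attr(, "truth")`.
#'
#' Defaults are the study conditions the generators emulate: IV 2.5 and oral
#' 10 mg/kg, CL 0.23 L/h/kg, V 1.2 L/kg, oral F 0.15, ka 8 1/h (giving a
#' noiseless Tmax near 0.5 h), the 5/15/30 min then 1/2/4/8/24 h sampling
#' schedule, LLOQ 0.2 ng/mL, 30/25/30% inter-subject CVs on CL/V/ka and 10%
#' residual CV.
#'
#' @param n_subjects number of subjects.
#' @param route `"IV"` or `"PO"`.
#' @param dose mg/kg; defaults to 2.5 (IV) or 10 (PO).
#' @param cl,v,ka,f typical clearance (L/h/kg), volume (L/kg), absorption
#'   rate (1/h) and bioavailability fraction.
#' @param times sampling times, h.
#' @param cv_cl,cv_v,cv_ka lognormal inter-subject CVs (fractions).
#' @param residual_cv proportional assay/residual CV (fraction).
#' @param lloq censoring limit, ng/mL.
#' @param seed RNG seed (set when non-NULL).
#' @return list of [pk_profile()] objects; each has a `truth` attribute with
#'   the subject's parameters, and the list itself carries the typical
#'   values.
#' @export
sim_plasma_profiles <- function(n_subjects = 4,
                                route = c("PO", "IV"),
                                dose = NULL,
                                cl = 0.23, v = 1.2, ka = 8, f = 0.15,
                                times = c(5 / 60, 15 / 60, 0.5, 1, 2, 4, 8, 24),
                                cv_cl = 0.30, cv_v = 0.25, cv_ka = 0.30,
                                residual_cv = 0.10,
                                lloq = 0.2, seed = NULL) {
  route <- match.arg(route)
  if (is.null(dose)) dose <- if (route == "IV") 2.5 else 10
  if (any(c(cl, v, ka, dose) <= 0) || f <= 0 || f > 1) {
    stop("config error: rates, volumes, dose positive and F in (0, 1]")
  }
  if (any(c(cv_cl, cv_v, cv_ka, residual_cv) < 0)) {
    stop("config error: CVs must be non-negative")
  }
  if (!is.null(seed)) set.seed(seed)
  # lognormal draws centered so the arithmetic mean equals the typical
  # value: group summaries are reported as mean +/- SD, so the group mean of
  # simulated subjects should sit at the nominal parameter
  draw <- function(typical, cv, n) {
    if (cv == 0) return(rep(typical, n))
    sigma2 <- log(1 + cv^2)
    typical * exp(stats::rnorm(n, 0, sqrt(sigma2)) - sigma2 / 2)
  }
  cl_i <- draw(cl, cv_cl, n_subjects)
  v_i <- draw(v, cv_v, n_subjects)
  ka_i <- draw(ka, cv_ka, n_subjects)
  profiles <- lapply(seq_len(n_subjects), function(i) {
    ke <- cl_i[i] / v_i[i]
    kai <- ka_i[i]
    if (route == "PO" && abs(kai - ke) < 1e-8) kai <- kai * (1 + 1e-6)
    conc_mg_l <- if (route == "IV") {
      (dose / v_i[i]) * exp(-ke * times)
    } else {
      f * dose * kai / (v_i[i] * (kai - ke)) *
        (exp(-ke * times) - exp(-kai * times))
    }
    conc <- conc_mg_l * 1000  # mg/L -> ng/mL
    if (residual_cv > 0) {
      conc <- conc * (1 + stats::rnorm(length(conc), 0, residual_cv))
      conc[conc < 0] <- 0
    }
    conc[conc < lloq] <- 0
    p <- pk_profile(times, conc, dose = dose, route = route,
                    subject_id = sprintf("S%03d", i), lloq = lloq)
    attr(p, "truth") <- list(cl = cl_i[i], v = v_i[i],
                             ka = if (route == "PO") kai else NA_real_,
                             f = if (route == "PO") f else 1,
                             ke = ke)
    p
  })
  attr(profiles, "truth") <- list(cl = cl, v = v, ka = ka, f = f,
                                  route = route, dose = dose)
  profiles
}

#' Simulate a microsomal depletion time course
#'
#' `ratio(t) = exp(-k t) (1 + e)`, with proportional noise `e ~ N(0, cv)`.
#' NADPH-free negative controls (`nadph = FALSE`) are generated flat at 1.
#'
#' @param k depletion rate constant, 1/min (>= 0).
#' @param times sampling times, min.
#' @param cv proportional noise CV (fraction).
#' @param nadph cofactor present? `FALSE` yields the flat control.
#' @param seed RNG seed.
#' @return data.frame with `time_min`, `ratio`, `nadph`; truth parameters in
#'   `attr(, "truth")`.
#' @export
sim_microsomal_decay <- function(k = 0.00468,
                                 times = c(0, 5, 10, 20, 30, 45, 60),
                                 cv = 0, nadph = TRUE, seed = NULL) {
  if (k < 0 || cv < 0) stop("config error: k and cv must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  ratio <- if (nadph) exp(-k * times) else rep(1, length(times))
  if (cv > 0) {
    ratio <- ratio * (1 + stats::rnorm(length(times), 0, cv))
    ratio <- pmax(ratio, 1e-6)
  }
  out <- data.frame(time_min = times, ratio = ratio, nadph = nadph)
  attr(out, "truth") <- list(k = if (nadph) k else 0,
                             t_half = if (nadph && k > 0) 0.693 / k else Inf)
  out
}

#' Simulate an equilibrium-dialysis measurement
#'
#' At equilibrium the receiver (buffer) concentration equals the unbound
#' donor concentration: `receiver = fu * donor`, with optional proportional
#' noise on both chambers.
#'
#' @param fu fraction unbound, in (0, 1].
#' @param donor donor-chamber concentration.
#' @param cv proportional noise CV (fraction).
#' @param seed RNG seed.
#' @return list with `donor`, `receiver`; truth in `attr(, "truth")`.
#' @export
sim_dialysis <- function(fu = 0.025, donor = 100, cv = 0, seed = NULL) {
  if (fu <= 0 || fu > 1) stop("config error: fu must be in (0, 1]")
  if (donor <= 0) stop("config error: donor must be positive")
  if (!is.null(seed)) set.seed(seed)
  d <- donor
  r <- fu * donor
  if (cv > 0) {
    d <- d * (1 + stats::rnorm(1, 0, cv))
    r <- r * (1 + stats::rnorm(1, 0, cv))
  }
  out <- list(donor = d, receiver = min(r, d))
  attr(out, "truth") <- list(fu = fu, percent_bound = 100 * (1 - fu))
  out
}

#' Simulate a PAMPA two-chamber assay end point
#'
#' Exact two-chamber passive-diffusion solution: the acceptor approaches the
#' mass-balance equilibrium concentration as
#' `Ca(t) = Ceq (1 - exp(-Papp A (1/Vd + 1/Va) t))` with
#' `Ceq = C0 Vd / (Vd + Va)`; the donor follows by mass balance.
#'
#' @param papp true permeability, cm/s.
#' @param c0 initial donor concentration (any unit).
#' @param vd,va donor/acceptor volumes, mL.
#' @param area filter area, cm^2.
#' @param t read-out time, s.
#' @return list with `cd_t`, `ca_t` plus geometry; truth in
#'   `attr(, "truth")`.
#' @export
sim_pampa <- function(papp = 7e-6, c0 = 5, vd = 0.3, va = 0.2,
                      area = 0.3, t = 18000) {
  if (papp < 0 || c0 <= 0) stop("config error")
  ceq <- c0 * vd / (vd + va)
  ca <- ceq * (1 - exp(-papp * area * (1 / vd + 1 / va) * t))
  cd <- (c0 * vd - ca * va) / vd  # mass balance
  out <- list(cd_t = cd, ca_t = ca, vd = vd, va = va, area = area, t = t)
  attr(out, "truth") <- list(papp = papp)
  out
}

#' Simulate a Caco-2 receiver time course with sampling withdrawals
#'
#' Sink-condition linear-phase flux: the cumulative transported amount is
#' `Papp A C0 t`. At each sampling time `withdrawal_volume` is removed from
#' the receiver (taking analyte with it) and replaced by blank buffer, so
#' measured receiver concentrations under-represent cumulative transport
#' unless the analysis adds the withdrawn amounts back.
#'
#' @param papp true permeability, cm/s.
#' @param c0 apical donor concentration (e.g. nmol/mL).
#' @param times_min receiver sampling times, minutes.
#' @param receiver_volume receiver volume, mL.
#' @param withdrawal_volume per-sample withdrawal, mL.
#' @param area monolayer area, cm^2.
#' @return data.frame with `time_s` and `conc` (measured, post-withdrawal
#'   bookkeeping); truth in `attr(, "truth")`.
#' @export
sim_caco2 <- function(papp = 3e-6, c0 = 10,
                      times_min = c(0, 30, 60, 90, 120),
                      receiver_volume = 1.5, withdrawal_volume = 0.1,
                      area = 1.12) {
  if (papp < 0 || c0 <= 0) stop("config error")
  time_s <- times_min * 60
  n <- length(time_s)
  conc <- numeric(n)
  amount <- 0  # analyte amount currently in the receiver
  prev_t <- 0
  for (i in seq_len(n)) {
    amount <- amount + papp * area * c0 * (time_s[i] - prev_t)
    conc[i] <- amount / receiver_volume
    amount <- amount - conc[i] * withdrawal_volume  # sampling removes analyte
    prev_t <- time_s[i]
  }
  out <- data.frame(time_s = time_s, conc = conc)
  attr(out, "truth") <- list(papp = papp, c0 = c0, area = area,
                             receiver_volume = receiver_volume,
                             withdrawal_volume = withdrawal_volume)
  out
}

#' Simulate a calibration and QC batch
#'
#' Area-ratio responses generated around a known line
#' `response = slope x + intercept` with proportional noise, at the standard
#' nine-level curve (0.2-500 ng/mL) plus LLOQ/LQC/MQC/HQC quality controls
#' replicated within each run. A per-level systematic bias can be injected
#' into the QCs to exercise the accuracy statistics.
#'
#' @param slope,intercept generating line (defaults 0.023 and 0.006).
#' @param levels standard nominal concentrations, ng/mL.
#' @param qc_levels named QC nominals, ng/mL.
#' @param n_qc_rep QC replicates per level per run.
#' @param n_runs number of runs (days).
#' @param cv proportional response CV (fraction).
#' @param qc_bias named vector of fractional biases per QC level
#'   (e.g. `c(HQC = 0.05)` spikes HQC responses 5% high).
#' @param is_area internal-standard area used to decompose the response.
#' @param seed RNG seed.
#' @return data.frame with `sample_type` (standard/qc), `level`, `run_id`,
#'   `nominal`, `analyte_area`, `is_area`, `response`; truth in
#'   `attr(, "truth")`.
#' @export
sim_calibration_batch <- function(slope = 0.023, intercept = 0.006,
                                  levels = c(0.2, 0.5, 1, 2, 5, 20, 50, 200, 500),
                                  qc_levels = c(LLOQ = 0.2, LQC = 0.5,
                                                MQC = 100, HQC = 375),
                                  n_qc_rep = 3, n_runs = 1, cv = 0,
                                  qc_bias = NULL, is_area = 1e5,
                                  seed = NULL) {
  if (slope <= 0) stop("config error: slope must be positive")
  if (!is.null(seed)) set.seed(seed)
  noisy <- function(x) {
    if (cv == 0) x else pmax(x * (1 + stats::rnorm(length(x), 0, cv)), 0)
  }
  rows <- list()
  for (run in seq_len(n_runs)) {
    resp <- noisy(slope * levels + intercept)
    rows[[length(rows) + 1]] <- data.frame(
      sample_type = "standard", level = as.character(levels),
      run_id = sprintf("run%d", run), nominal = levels,
      analyte_area = resp * is_area, is_area = is_area, response = resp
    )
    for (lv in names(qc_levels)) {
      nominal <- qc_levels[[lv]]
      bias <- if (!is.null(qc_bias) && lv %in% names(qc_bias)) qc_bias[[lv]] else 0
      resp <- noisy(rep((slope * nominal + intercept) * (1 + bias), n_qc_rep))
      rows[[length(rows) + 1]] <- data.frame(
        sample_type = "qc", level = lv, run_id = sprintf("run%d", run),
        nominal = nominal, analyte_area = resp * is_area,
        is_area = is_area, response = resp
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(slope = slope, intercept = intercept, cv = cv,
                             qc_bias = qc_bias)
  out
}

#' Simulate a matched tissue-distribution table
#'
#' Tissue contents generated as `Kp x plasma concentration` at each sampling
#' time, with optional proportional noise — the ground-truth complement of
#' the tissue-to-plasma ratio estimators.
#'
#' @param plasma data.frame with `time_h` and `conc` (ng/mL).
#' @param kp named vector of tissue-to-plasma ratios.
#' @param cv proportional noise CV.
#' @param seed RNG seed.
#' @return data.frame with `tissue`, `time_h`, `content`; truth in
#'   `attr(, "truth")`.
#' @export
sim_tissue_profile <- function(plasma, kp = c(liver = 4.1, kidney = 2.0,
                                              spleen = 1.3, lung = 1.75,
                                              brain = 0.037),
                               cv = 0, seed = NULL) {
  stopifnot(all(c("time_h", "conc") %in% names(plasma)))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(kp), function(ts) {
    content <- kp[[ts]] * plasma$conc
    if (cv > 0) {
      content <- pmax(content * (1 + stats::rnorm(length(content), 0, cv)), 0)
    }
    data.frame(tissue = ts, time_h = plasma$time_h, content = content)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(kp = kp)
  out
}
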