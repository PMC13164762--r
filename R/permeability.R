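#' PAMPA apparent permeability
#'
#' Mass-balance estimate for a two-chamber artificial-membrane assay read at
#' a single end point:
#' `Papp = -ln(1 - Ca(t)/Ceq) / (A (1/Vd + 1/Va) t)`, with the equilibrium
#' concentration from mass balance `Ceq = (Cd(t) Vd + Ca(t) Va) / (Vd + Va)`.
#' Concentration units cancel, so any consistent unit may be used.
#'
#' @param cd_t donor concentration at read-out time.
#' @param ca_t acceptor concentration at read-out time.
#' @param vd,va donor and acceptor volumes, mL (defaults 0.3 and 0.2).
#' @param area filter area, cm^2 (default 0.3).
#' @param t incubation time, seconds (default 18000 = 5 h).
#' @return Papp in cm/s.
#' @export
pampa_papp <- function(cd_t, ca_t, vd = 0.3, va = 0.2, area = 0.3,
                       t = 18000) {
  if (any(c(vd, va, area, t) <= 0)) stop("geometry and time must be positive")
  if (ca_t < 0 || cd_t < 0) stop("concentrations must be non-negative")
  ceq <- (cd_t * vd + ca_t * va) / (vd + va)
  if (ca_t == 0) return(0)
  if (ca_t >= ceq) {
    stop("saturated assay: acceptor concentration has reached equilibrium")
  }
  -log(1 - ca_t / ceq) / (area * (1 / vd + 1 / va) * t)
}

#' Caco-2 apparent permeability with withdrawal correction
#'
#' Apical-to-basolateral permeability from a receiver-chamber time course:
#' `Papp = (dQ/dt) / (A C0)` where `dQ/dt` is the slope of the cumulative
#' transported amount versus time. Because each sampling withdraws
#' `withdrawal_volume` from the receiver and replaces it with blank buffer,
#' the cumulative amount at time `t_n` must add back the analyte removed at
#' earlier samplings: `Q(t_n) = C_n V_receiver + sum_{i<n} C_i V_withdrawn`.
#' Skipping that correction biases Papp low.
#'
#' @param time_s receiver sampling times in seconds, increasing, >= 3 points.
#' @param receiver_conc receiver concentrations at each time (e.g. nmol/mL).
#' @param c0 initial donor (apical) concentration, same concentration units.
#' @param area monolayer area, cm^2 (default 1.12).
#' @param receiver_volume receiver chamber volume, mL (default 1.5).
#' @param withdrawal_volume volume removed per sample, mL (default 0.1).
#' @param correct_withdrawal apply the withdrawal correction (default TRUE).
#' @param teer optional transepithelial electrical resistance (ohm cm^2) for
#'   the insert; values below `teer_min` set `integrity_warning` and raise an
#'   R warning (such inserts are normally rejected).
#' @param teer_min monolayer-integrity threshold (default 400).
#' @param window optional c(min, max) time window (s) restricting the slope
#'   fit to the linear phase; default uses all sampled points.
#' @return list with `papp` (cm/s), `dq_dt` (amount/s), `cumulative_amount`
#'   (per time point), `integrity_warning`.
#' @export
caco2_papp <- function(time_s, receiver_conc, c0, area = 1.12,
                       receiver_volume = 1.5, withdrawal_volume = 0.1,
                       correct_withdrawal = TRUE, teer = NULL,
                       teer_min = 400, window = NULL) {
  if (length(time_s) < 3) stop("need >= 3 receiver time points")
  if (any(diff(time_s) <= 0)) stop("times must be strictly increasing")
  if (c0 <= 0) stop("initial donor concentration must be positive")
  if (any(receiver_conc < 0)) stop("receiver concentrations must be >= 0")
  integrity_warning <- FALSE
  if (!is.null(teer) && any(teer < teer_min)) {
    integrity_warning <- TRUE
    warning("monolayer integrity: TEER below ", teer_min, " ohm cm^2")
  }
  removed <- if (correct_withdrawal) {
    c(0, cumsum(receiver_conc * withdrawal_volume)[-length(receiver_conc)])
  } else {
    rep(0, length(receiver_conc))
  }
  q <- receiver_conc * receiver_volume + removed
  keep <- if (is.null(window)) {
    rep(TRUE, length(time_s))
  } else {
    time_s >= window[1] & time_s <= window[2]
  }
  if (sum(keep) < 2) stop("fewer than 2 points in the fitting window")
  if (all(receiver_conc == 0)) {
    return(list(papp = 0, dq_dt = 0, cumulative_amount = q,
                integrity_warning = integrity_warning))
  }
  fit <- stats::lm(q[keep] ~ time_s[keep])
  dq_dt <- unname(stats::coef(fit)[2])
  list(
    papp = dq_dt / (area * c0),
    dq_dt = dq_dt,
    cumulative_amount = q,
    integrity_warning = integrity_warning
  )
}
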