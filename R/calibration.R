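#' Fit a weighted linear calibration curve
#'
#' Fits the analyte-to-internal-standard response ratio against nominal
#' concentration by least squares, optionally weighted by `1/x` or `1/x^2`
#' (the usual choices for heteroscedastic LC-MS/MS responses, where variance
#' grows with concentration). The fitted line is the quantitation model used
#' for back-calculating unknowns.
#'
#' @param standards data.frame of calibration standards with a `nominal`
#'   column (ng/mL, all > 0) and either a `response` column (area ratio) or
#'   both `analyte_area` and `is_area`, from which the response is computed
#'   as `analyte_area / is_area`.
#' @param weighting one of `"1/x^2"` (default, the standard bioanalytical
#'   choice), `"1/x"`, or `"none"`.
#' @return object of class `cal_fit`: list with `slope`, `intercept`,
#'   `weighting`, `r_squared` (weighted coefficient of determination about
#'   the weighted mean), `range` (c(lloq, uloq) = min/max nominal),
#'   `n_levels`, and the underlying `lm` fit.
#' @details Blanks and zero-concentration samples are not valid standards
#'   under reciprocal-concentration weighting and are rejected. A calibration
#'   needs at least two distinct levels to define a line; fewer than six
#'   distinct levels triggers a warning because regulatory acceptance
#'   expects six or more.
#' @examples
#' std <- data.frame(nominal = c(0.2, 0.5, 1, 2, 5, 20, 50, 200, 500))
#' std$response <- 0.023 * std$nominal + 0.006
#' fit <- fit_calibration(std)
#' fit$slope
#' @export
fit_calibration <- function(standards, weighting = c("1/x^2", "1/x", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(standards), "nominal" %in% names(standards))
  nominal <- standards$nominal
  if ("response" %in% names(standards)) {
    response <- standards$response
  } else if (all(c("analyte_area", "is_area") %in% names(standards))) {
    if (any(standards$is_area <= 0)) {
      stop("internal-standard areas must be positive")
    }
    response <- standards$analyte_area / standards$is_area
  } else {
    stop("standards must carry 'response' or 'analyte_area' + 'is_area'")
  }
  if (any(!is.finite(nominal)) || any(!is.finite(response))) {
    stop("non-finite nominal concentration or response")
  }
  if (any(response < 0)) stop("responses must be non-negative")
  if (weighting != "none" && any(nominal <= 0)) {
    stop("invalid weighting: nominal concentrations must be > 0 under ",
         weighting, " weighting")
  }
  if (any(nominal <= 0)) stop("standards must have nominal > 0")
  n_levels <- length(unique(nominal))
  if (n_levels < 2) stop("degenerate design: need >= 2 distinct levels")
  if (n_levels < 6) {
    warning("fewer than 6 distinct calibration levels (", n_levels, ")")
  }

  w <- switch(weighting,
    "none"  = rep(1, length(nominal)),
    "1/x"   = 1 / nominal,
    "1/x^2" = 1 / nominal^2
  )
  fit <- stats::lm(response ~ nominal, weights = w)
  cf <- stats::coef(fit)
  structure(
    list(
      slope = unname(cf["nominal"]),
      intercept = unname(cf["(Intercept)"]),
      weighting = weighting,
      r_squared = suppressWarnings(summary(fit)$r.squared),  # exact fits warn
      range = c(lloq = min(nominal), uloq = max(nominal)),
      n_levels = n_levels,
      fit = fit
    ),
    class = "cal_fit"
  )
}

#' Predicted response at given nominal concentrations
#'
#' @param object a [fit_calibration()] model.
#' @param nominal concentrations (ng/mL).
#' @param ... ignored.
#' @return predicted area-ratio responses.
#' @export
predict.cal_fit <- function(object, nominal, ...) {
  object$intercept + object$slope * nominal
}

#' @export
print.cal_fit <- function(x, ...) {
  cat(sprintf(
    "Calibration: Y = %.4gX + %.4g  (weighting %s, r^2 = %.4f)\n",
    x$slope, x$intercept, x$weighting, x$r_squared
  ))
  cat(sprintf("Range: %.4g - %.4g ng/mL (%d levels)\n",
              x$range[["lloq"]], x$range[["uloq"]], x$n_levels))
  invisible(x)
}

#' Back-calculate concentration from an instrument response
#'
#' Inverts the calibration line: `(response - intercept) / slope`. Results
#' outside the calibrated range are flagged but never clamped, so that
#' dilution-and-reassay decisions stay with the analyst.
#'
#' @param model a [fit_calibration()] model.
#' @param response area-ratio response(s).
#' @return data.frame with columns `response`, `conc` (ng/mL) and `flag`
#'   (`"ok"`, `"below_lloq"` or `"above_uloq"`).
#' @export
back_calculate <- function(model, response) {
  stopifnot(inherits(model, "cal_fit"))
  if (model$slope == 0) stop("non-invertible model: slope is zero")
  conc <- (response - model$intercept) / model$slope
  flag <- rep("ok", length(conc))
  flag[conc < model$range[["lloq"]]] <- "below_lloq"
  flag[conc > model$range[["uloq"]]] <- "above_uloq"
  data.frame(response = response, conc = conc, flag = flag)
}
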