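# Independent oracles used across the suite.

# Brute-force weighted least squares via the normal equations:
# minimize sum w_i (y_i - (a + b x_i))^2.
wls_normal_equations <- function(x, y, w) {
  X <- cbind(1, x)
  A <- t(X) %*% (w * X)
  b <- t(X) %*% (w * y)
  beta <- solve(A, b)
  list(intercept = beta[1], slope = beta[2])
}

# Weighted R^2 about the weighted mean.
wls_r_squared <- function(x, y, w, intercept, slope) {
  fitted <- intercept + slope * x
  ybar <- sum(w * y) / sum(w)
  1 - sum(w * (y - fitted)^2) / sum(w * (y - ybar)^2)
}

# One-compartment closed forms (truth for NCA recovery checks).
one_cpt_iv <- function(t, dose_mg_kg, cl, v) {
  1000 * (dose_mg_kg / v) * exp(-(cl / v) * t)  # ng/mL
}
one_cpt_oral <- function(t, dose_mg_kg, cl, v, ka, f) {
  ke <- cl / v
  1000 * f * dose_mg_kg * ka / (v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}
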