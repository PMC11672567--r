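# Assay analytics: 4PL dose-response with log-ratio relative potency,
# AC-SINS quadratic plasmon-peak extraction, SEC molecular-weight
# calibration.

#' Fit a four-parameter logistic dose-response curve
#'
#' Model: `response = bottom + (top - bottom) / (1 + (ec50/conc)^hill)`.
#' Least squares via Levenberg-Marquardt with a deterministic
#' initialization: bottom/top from the response extremes, EC50 from
#' mid-response log interpolation, hill +1 or -1 by response direction.
#'
#' @param concentration Concentrations (pM), all > 0, >= 5 distinct values.
#' @param response Measured responses (e.g. absorbance, AU).
#' @return List of class `fourpl_fit`: `bottom`, `top`, `ec50`, `hill`,
#'   `residual_sse`, `converged`. Non-convergence (including degenerate
#'   flat data) is flagged, never silent.
#' @export
fit_4pl <- function(concentration, response) {
  x <- as.numeric(concentration); y <- as.numeric(response)
  if (length(x) != length(y)) stop("concentration/response length mismatch")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("concentrations must be positive and finite")
  if (length(unique(x)) < 5) stop("need >= 5 distinct concentrations")
  out <- list(bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
              hill = NA_real_, residual_sse = NA_real_, converged = FALSE)
  class(out) <- "fourpl_fit"
  rng <- diff(range(y))
  if (rng <= max(1e-12, 1e-9 * max(abs(y)))) return(out)  # flat data
  # direction: does response rise with concentration?
  rising <- coef(lm(y ~ log10(x)))[2] > 0
  b0 <- min(y); t0 <- max(y)
  mid <- (b0 + t0) / 2
  ord <- order(x)
  e0 <- 10^stats::approx(y[ord], log10(x[ord]), xout = mid, ties = mean,
                         rule = 2)$y
  if (!is.finite(e0) || e0 <= 0) e0 <- exp(mean(log(x)))
  start <- list(bottom = b0, top = t0, log_ec50 = log10(e0),
                hill = if (rising) 1 else -1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + (10^log_ec50 / x)^hill),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  cf <- coef(fit)
  conv <- isTRUE(fit$convInfo$isConv)
  out$bottom <- unname(cf["bottom"]); out$top <- unname(cf["top"])
  out$ec50 <- unname(10^cf["log_ec50"]); out$hill <- unname(cf["hill"])
  out$residual_sse <- sum(residuals(fit)^2)
  # canonical form: bottom = lower asymptote, top = upper; a descending
  # curve keeps a negative hill. An inverted pair is equivalent to the
  # swapped pair with negated hill.
  if (out$bottom > out$top) {
    tmp <- out$bottom; out$bottom <- out$top; out$top <- tmp
    out$hill <- -out$hill
  }
  # honest convergence: solver converged and the asymptotes separate
  out$converged <- conv && out$top > out$bottom
  out
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (!x$converged) cat("<fourpl_fit> NOT CONVERGED\n")
  cat(sprintf("<fourpl_fit> bottom %.4g, top %.4g, EC50 %.4g pM, hill %.3g, SSE %.3g\n",
              x$bottom, x$top, x$ec50, x$hill, x$residual_sse))
  invisible(x)
}

#' Relative potency from two EC50 values
#'
#' `potency% = log10(EC50_ref) / log10(EC50_sample) * 100`, the convention
#' in which the reference antibody is 100% and a larger sample EC50 (weaker
#' binding) gives a potency below 100%. The formula is unit-dependent:
#' logs of values at or below 1 change sign, so EC50s must be expressed in
#' units where both values exceed 1 (pM here).
#'
#' @param ec50_ref,ec50_sample EC50 values in pM, both > 1.
#' @return Potency in percent.
#' @export
relative_potency <- function(ec50_ref, ec50_sample) {
  if (any(c(ec50_ref, ec50_sample) <= 1))
    stop("EC50 <= 1 pM: log-ratio potency is unit-ambiguous (log sign ",
         "flip); express EC50s in pM with values > 1")
  log10(ec50_ref) / log10(ec50_sample) * 100
}

#' AC-SINS plasmon-peak wavelength by quadratic fit
#'
#' Ordinary least-squares second-order polynomial over the spectrum points
#' inside the fit window (endpoints inclusive); the peak is the vertex
#' `lambda_max = -b / (2a)`. A non-concave fit (a >= 0) is returned flagged
#' as invalid rather than producing a spurious peak.
#'
#' @param wavelength Wavelengths in nm, strictly increasing.
#' @param absorbance Absorbance values (AU).
#' @param window Fit window in nm, default `c(500, 560)`.
#' @return List of class `acsins_fit`: `a`, `b`, `c`, `lambda_max` (nm; NA
#'   when invalid), `valid`, `fit_window`, `n_points`.
#' @export
acsins_lambda_max <- function(wavelength, absorbance,
                              window = c(500, 560)) {
  x <- as.numeric(wavelength); y <- as.numeric(absorbance)
  if (length(x) != length(y)) stop("wavelength/absorbance length mismatch")
  if (any(diff(x) <= 0)) stop("wavelengths must be strictly increasing")
  keep <- x >= window[1] & x <= window[2]
  if (sum(keep) < 5) stop("need >= 5 points inside the fit window")
  xf <- x[keep]; yf <- y[keep]
  cf <- coef(lm(yf ~ xf + I(xf^2)))
  a <- unname(cf[3]); b <- unname(cf[2]); cc <- unname(cf[1])
  valid <- is.finite(a) && a < 0
  lam <- if (valid) -b / (2 * a) else NA_real_
  if (valid && (lam < window[1] || lam > window[2])) valid <- FALSE
  structure(list(a = a, b = b, c = cc, lambda_max = lam, valid = valid,
                 fit_window = window, n_points = sum(keep)),
            class = "acsins_fit")
}

#' AC-SINS plasmon shift
#'
#' Difference of sample and control peak wavelengths; a red shift
#' (positive delta) indicates self-interaction.
#'
#' @param sample_fit,control_fit `acsins_fit` objects.
#' @return Delta lambda_max in nm.
#' @export
acsins_shift <- function(sample_fit, control_fit) {
  if (!isTRUE(sample_fit$valid) || !isTRUE(control_fit$valid))
    stop("cannot compute shift from an invalid peak fit")
  sample_fit$lambda_max - control_fit$lambda_max
}

#' Fit a SEC molecular-weight calibration line
#'
#' Linear fit of `log10(MW)` on retention volume over the calibration
#' standards; larger proteins elute earlier, so the slope must be negative.
#'
#' @param mw_kda Standard molecular weights (kDa), >= 2 values.
#' @param retention_ml Their retention volumes (mL).
#' @return List of class `sec_calibration`: `slope`, `intercept`,
#'   `standards` (data frame), `range_ml`.
#' @export
sec_calibration <- function(mw_kda, retention_ml) {
  if (length(mw_kda) < 2 || length(retention_ml) != length(mw_kda))
    stop("need >= 2 standards with matching retention volumes")
  cf <- coef(lm(log10(mw_kda) ~ retention_ml))
  if (!(cf[2] < 0))
    stop("calibration slope must be negative (larger MW elutes earlier)")
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 standards = data.frame(mw_kda = mw_kda,
                                        retention_ml = retention_ml),
                 range_ml = range(retention_ml)),
            class = "sec_calibration")
}

#' Estimate molecular weight from SEC retention volume
#'
#' `MW = 10^(slope * V + intercept)`. Retention volumes outside the
#' standard range by more than `guard` mL trigger an extrapolation warning.
#'
#' @param retention_ml Query retention volume (mL).
#' @param calibration A `sec_calibration`.
#' @param guard Extrapolation guard band in mL (default 1).
#' @return Estimated MW in kDa.
#' @export
sec_mw_estimate <- function(retention_ml, calibration, guard = 1) {
  lo <- calibration$range_ml[1] - guard
  hi <- calibration$range_ml[2] + guard
  if (any(retention_ml < lo | retention_ml > hi))
    warning("retention volume outside calibration range; extrapolating")
  10^(calibration$slope * retention_ml + calibration$intercept)
}
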