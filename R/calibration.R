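#' Calibration sweep record
#'
#' Raw record of one gravimetric rotation calibration: the sensor, loaded
#' with a steel ball of known mass, is rotated through one revolution and
#' its ADC output is sampled at each angular position.
#'
#' @param angles Stage angles in degrees, strictly increasing within one
#'   revolution; at least 4.
#' @param adc_values Sensor ADC output at each angle (ADU).
#' @param ball_mass Ball mass in grams, > 0.
#' @param gravity Gravitational acceleration used when converting the
#'   ball's weight to force (m/s^2).
#' @return An object of class `calibration_sweep`.
#' @export
calibration_sweep <- function(angles, adc_values, ball_mass = 3.27e-5,
                              gravity = STANDARD_GRAVITY) {
  stopifnot(is.numeric(angles), is.numeric(adc_values))
  if (length(angles) != length(adc_values))
    stopf("`angles` and `adc_values` must have equal length")
  if (length(angles) < 4) stopf("a sweep needs at least 4 angular positions")
  if (any(diff(angles) <= 0))
    stopf("`angles` must be strictly increasing")
  if (max(angles) - min(angles) >= 360)
    stopf("`angles` must span less than one full revolution")
  check_scalar(ball_mass, "ball_mass", positive = TRUE)
  check_scalar(gravity, "gravity", positive = TRUE)
  structure(list(angles = as.numeric(angles),
                 adc_values = as.numeric(adc_values),
                 ball_mass = ball_mass, gravity = gravity),
            class = "calibration_sweep")
}

#' @export
print.calibration_sweep <- function(x, ...) {
  cat(sprintf("Calibration sweep: %d positions, %.2f-%.2f deg, ball %.3g g\n",
              length(x$angles), min(x$angles), max(x$angles), x$ball_mass))
  invisible(x)
}

#' Gravity component along the sensor axis
#'
#' Force (nN) exerted by a ball of mass `ball_mass` grams along the
#' sensitive axis when the stage is at `angle`:
#' \eqn{F = m g \cos(\theta - \phi)}. Mass is converted g -> kg and the
#' result N -> nN.
#'
#' @param ball_mass Ball mass in grams, > 0.
#' @param angle Stage angle(s), degrees.
#' @param phase Angular offset of the sensitive axis, degrees.
#' @param gravity Gravitational acceleration (m/s^2).
#' @return Force(s) in nN (vectorized over `angle`).
#' @examples
#' expected_axis_force(3.27e-5, angle = 0)   # ~320.7 nN ball weight
#' expected_axis_force(3.27e-5, angle = 90)  # 0: axis horizontal
#' @export
expected_axis_force <- function(ball_mass, angle, phase = 0,
                                gravity = STANDARD_GRAVITY) {
  check_scalar(ball_mass, "ball_mass", positive = TRUE)
  stopifnot(is.numeric(angle))
  check_scalar(phase, "phase")
  check_scalar(gravity, "gravity", positive = TRUE)
  ball_mass * gravity * NN_PER_GRAM_MS2 * cos(deg2rad(angle - phase))
}

#' Fit the force-to-signal conversion coefficient
#'
#' Recovers the sensor's conversion coefficient from a rotation sweep by
#' linear least squares of the ADC values on \eqn{\{\cos\theta,
#' \sin\theta, 1\}}. With fitted amplitudes \eqn{(A, B)} and offset
#' \eqn{C}: amplitude \eqn{R = \sqrt{A^2+B^2}}, phase
#' \eqn{= \mathrm{atan2}(-B, A)}, baseline \eqn{= C}, and the
#' coefficient is \eqn{mg/R} in nN/ADU. Error metrics (RMSE and maximum
#' absolute error of predicted vs measured force) are reported in nN
#' after converting residuals with the fitted coefficient.
#'
#' @param sweep A [calibration_sweep()].
#' @return An object of class `calibration_result` with fields
#'   `coefficient` (nN/ADU), `phase` (degrees), `baseline` (ADU), `rmse`
#'   (nN), `max_error` (nN), `resolution` (nN, see
#'   [estimate_resolution()]), `n`, and `residual_force_nN`.
#' @examples
#' sw <- simulate_calibration_sweep(sensor_params(adc_noise_sd = 0), seed = 1)
#' fit_calibration(sw)
#' @export
fit_calibration <- function(sweep) {
  stopifnot(inherits(sweep, "calibration_sweep"))
  th <- deg2rad(sweep$angles)
  X <- cbind(cos = cos(th), sin = sin(th), one = 1)
  if (qr(X)$rank < 3)
    stopf("degenerate sweep design: angles do not identify the sinusoid")
  beta <- stats::lm.fit(X, sweep$adc_values)$coefficients
  A <- beta[["cos"]]; B <- beta[["sin"]]; C <- beta[["one"]]
  R <- sqrt(A^2 + B^2)
  if (R <= .Machine$double.eps)
    stopf("sweep has no angular modulation; cannot calibrate")
  # R cos(theta - phi) = R cos(phi) cos(theta) + R sin(phi) sin(theta),
  # so A = R cos(phi), B = R sin(phi)
  phase <- rad2deg(atan2(B, A))
  mg <- sweep$ball_mass * sweep$gravity * NN_PER_GRAM_MS2   # nN
  coefficient <- mg / R

  adc_pred <- C + R * cos(th - deg2rad(phase))
  resid_force <- (sweep$adc_values - adc_pred) * coefficient
  res <- structure(list(
    coefficient = coefficient,
    phase = phase,
    baseline = C,
    rmse = sqrt(mean(resid_force^2)),
    max_error = max(abs(resid_force)),
    resolution = NA_real_,
    n = length(th),
    residual_force_nN = as.numeric(resid_force)
  ), class = "calibration_result")
  res$resolution <- tryCatch(estimate_resolution(sweep, res),
                             error = function(e) NA_real_)
  res
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    paste0("Sensor calibration (n = %d)\n",
           "  coefficient: %.6g nN/ADU\n  phase: %.4g deg",
           "  baseline: %.6g ADU\n  rmse: %.4g nN",
           "  max error: %.4g nN\n  resolution: %.4g nN\n"),
    x$n, x$coefficient, x$phase, x$baseline, x$rmse, x$max_error,
    x$resolution))
  invisible(x)
}

#' Operational force resolution of a calibrated sensor
#'
#' Resolution is defined here operationally as the standard deviation of
#' the force-converted fit residuals (ADC residual times the fitted
#' coefficient): the smallest force step distinguishable from the
#' sensor's own scatter about the calibration model. This is this
#' package's proxy definition; instrument datasheets may define
#' resolution differently.
#'
#' @param sweep A [calibration_sweep()].
#' @param result A [fit_calibration()] result for that sweep.
#' @return Resolution in nN.
#' @export
estimate_resolution <- function(sweep, result) {
  stopifnot(inherits(sweep, "calibration_sweep"),
            inherits(result, "calibration_result"))
  r <- result$residual_force_nN
  if (length(r) < 5)
    stopf("need at least 5 residuals to estimate resolution (got %d)",
          length(r))
  stats::sd(r)
}

#' Convert an ADC trace to force
#'
#' Applies a calibration: `force = (adc - baseline) * coefficient`.
#'
#' @param adc_values Numeric ADC series (ADU).
#' @param result A [fit_calibration()] result.
#' @return Force series in nN, same length.
#' @export
convert_trace <- function(adc_values, result) {
  stopifnot(is.numeric(adc_values), inherits(result, "calibration_result"))
  (adc_values - result$baseline) * result$coefficient
}

#' Read / write calibration files
#'
#' `read_sweep_csv()` reads a sweep CSV with columns `angle_deg`,
#' `adc_value` plus a JSON sidecar holding `ball_mass_g` and `gravity`;
#' `write_sweep_csv()` writes the pair; `write_calibration_json()`
#' serializes a [fit_calibration()] result.
#'
#' @param path CSV path.
#' @param meta_path JSON sidecar path; defaults to `path` with a `.json`
#'   extension.
#' @return `read_sweep_csv()` returns a [calibration_sweep()].
#' @export
read_sweep_csv <- function(path, meta_path = NULL) {
  meta_path <- meta_path %||% sub("\\.csv$", ".json", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("angle_deg", "adc_value") %in% names(df)))
    stopf("sweep CSV needs columns angle_deg, adc_value")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  calibration_sweep(df$angle_deg, df$adc_value,
                    ball_mass = meta$ball_mass_g %||% 3.27e-5,
                    gravity = meta$gravity %||% STANDARD_GRAVITY)
}

#' @rdname read_sweep_csv
#' @param sweep A [calibration_sweep()] to write.
#' @param header Optional comment lines (e.g. a config hash) written at
#'   the top of the CSV, prefixed with `#`.
#' @export
write_sweep_csv <- function(sweep, path, meta_path = NULL, header = NULL) {
  stopifnot(inherits(sweep, "calibration_sweep"))
  meta_path <- meta_path %||% sub("\\.csv$", ".json", path)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(data.frame(angle_deg = sweep$angles,
                              adc_value = sweep$adc_values),
                   con, row.names = FALSE)
  jsonlite::write_json(list(ball_mass_g = sweep$ball_mass,
                            gravity = sweep$gravity),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_sweep_csv
#' @param result A [fit_calibration()] result to write.
#' @export
write_calibration_json <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  jsonlite::write_json(
    list(coefficient_nN_per_ADU = result$coefficient,
         phase_deg = result$phase, baseline_ADU = result$baseline,
         rmse_nN = result$rmse, max_error_nN = result$max_error,
         resolution_nN = result$resolution, n = result$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
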