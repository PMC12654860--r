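#' Apparent modulus at a strain checkpoint
#'
#' Reduces one compression run to a single viscoelastic sample: the
#' secant apparent modulus \eqn{E = \sigma(\epsilon^*)/\epsilon^*} at a
#' fixed strain checkpoint, paired with the indentation time elapsed
#' from contact onset to that strain. Stress and time are linearly
#' interpolated between the loading points bracketing the checkpoint;
#' contact onset is the (extrapolated) time of zero strain. Varying the
#' plate speed then varies the indentation time at a fixed checkpoint,
#' which is what the power-law fit needs.
#'
#' Checkpoints below the nucleus-contact strain probe mostly the
#' cytoplasm (`regime = "low_compression"`); checkpoints beyond it also
#' load the nucleus (`"high_compression"`).
#'
#' @param curve A [build_curve()] result.
#' @param record The originating [compression_record()] (supplies the
#'   plate speed).
#' @param strain_checkpoint Engineering strain at which to sample, in
#'   (0, max achieved strain].
#' @param nucleus_contact_strain Strain at which the plates reach the
#'   nucleus; used only to tag the regime.
#' @return A one-row data.frame of class `rheology_sample` with columns
#'   `t_s`, `apparent_E_kPa`, `speed_um_s`, `regime`, `checkpoint`.
#' @export
apparent_modulus_at_checkpoint <- function(curve, record, strain_checkpoint,
                                           nucleus_contact_strain = 0.3) {
  stopifnot(inherits(curve, "stress_strain_curve"),
            inherits(record, "compression_record"))
  check_scalar(strain_checkpoint, "strain_checkpoint", positive = TRUE)
  load <- curve[curve$branch == "loading", , drop = FALSE]
  load <- load[order(load$strain), , drop = FALSE]
  if (max(load$strain) < strain_checkpoint)
    stopf("insufficient compression: run reaches strain %.3f < checkpoint %.3f",
          max(load$strain), strain_checkpoint)
  sig <- stats::approx(load$strain, load$stress_kPa,
                       xout = strain_checkpoint, ties = "ordered")$y
  t_at <- stats::approx(load$strain, load$time_s,
                        xout = strain_checkpoint, ties = "ordered")$y
  # contact onset: extrapolate the first two loading points to zero strain
  t0 <- if (load$strain[1] <= 0) load$time_s[1] else {
    s1 <- load$strain[1]; s2 <- load$strain[2]
    load$time_s[1] - s1 * (load$time_s[2] - load$time_s[1]) / (s2 - s1)
  }
  out <- data.frame(
    t_s = t_at - t0,
    apparent_E_kPa = sig / strain_checkpoint,
    speed_um_s = record$speed,
    regime = if (strain_checkpoint < nucleus_contact_strain)
      "low_compression" else "high_compression",
    checkpoint = strain_checkpoint
  )
  class(out) <- c("rheology_sample", "data.frame")
  out
}

#' Fit the power-law rheology model
#'
#' Fits \eqn{E(t) = E_0 (t/t_{ref})^{-\beta}} to apparent-modulus
#' samples. \eqn{\beta = 0} is a purely elastic solid with modulus
#' \eqn{E_0}; \eqn{\beta = 1} a Newtonian viscous liquid. The default
#' fit is ordinary least squares in log-log space, where the model is
#' exactly linear: \eqn{\ln E = \ln E_0 - \beta \ln(t/t_{ref})}.
#' `method = "nls"` refits by nonlinear least squares on the original
#' scale (started from the log fit) as a cross-check.
#'
#' @param samples A data.frame with columns `t_s` and `apparent_E_kPa`
#'   (e.g. stacked [apparent_modulus_at_checkpoint()] rows), >= 3 rows
#'   with distinct times.
#' @param tref Reference time in seconds (1 s by convention).
#' @param method `"ols"` (log-log least squares) or `"nls"`.
#' @return An object of class `rheology_fit`: list with `E0_kPa`,
#'   `beta`, `tref_s`, `r_squared`, `n_samples`, `method`.
#' @examples
#' t <- c(0.2, 0.5, 1, 2)
#' fit_power_law(data.frame(t_s = t, apparent_E_kPa = 5 * t^-0.3))
#' @export
fit_power_law <- function(samples, tref = 1, method = c("ols", "nls")) {
  stopifnot(is.data.frame(samples),
            all(c("t_s", "apparent_E_kPa") %in% names(samples)))
  method <- match.arg(method)
  check_scalar(tref, "tref", positive = TRUE)
  t <- samples$t_s
  E <- samples$apparent_E_kPa
  if (any(!is.finite(t)) || any(t <= 0)) stopf("indentation times must be > 0")
  if (any(!is.finite(E)) || any(E <= 0))
    stopf("invalid sample: apparent moduli must be > 0")
  if (length(t) < 3) stopf("need at least 3 samples")
  if (length(unique(t)) < 2)
    stopf("singular fit: all indentation times are equal")

  x <- log(t / tref)
  y <- log(E)
  fit <- stats::lm(y ~ x)
  beta <- -unname(stats::coef(fit)[["x"]])
  E0 <- exp(unname(stats::coef(fit)[[1]]))
  r2 <- r_squared_of(fit, y)

  if (method == "nls") {
    # started from the log-space solution; on exact data nls has nothing
    # to improve and warns about iterations, which is not a failure
    nfit <- suppressWarnings(
      stats::nls(E ~ E0 * (t / tref)^(-beta),
                 start = list(E0 = E0, beta = beta),
                 control = stats::nls.control(warnOnly = TRUE)))
    cf <- stats::coef(nfit)
    E0 <- unname(cf[["E0"]]); beta <- unname(cf[["beta"]])
    r2 <- 1 - sum(stats::resid(nfit)^2) / sum((E - mean(E))^2)
  }

  structure(list(E0_kPa = E0, beta = beta, tref_s = tref,
                 r_squared = r2, n_samples = length(t), method = method),
            class = "rheology_fit")
}

#' @export
print.rheology_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law rheology fit (%s, n = %d): E0 = %.4g kPa, beta = %.4g (r^2 = %.4f, tref = %g s)\n",
    x$method, x$n_samples, x$E0_kPa, x$beta, x$r_squared, x$tref_s))
  invisible(x)
}

#' Compare low- and high-compression rheology fits
#'
#' Contrasts the cytoplasm-dominated (low compression) and
#' nucleus-engaging (high compression) regimes. For cells whose nucleus
#' is stiffer and more solid-like than the cytoplasm, the expected
#' ordering is a higher \eqn{E_0} and a lower \eqn{\beta} at high
#' compression; the report flags whether each holds for the given fits
#' (it is a description of the fits, not an invariant of arbitrary
#' input).
#'
#' @param fit_low,fit_high [fit_power_law()] results for the
#'   low-/high-compression regimes.
#' @return A list with `E0_ratio` (high/low), `beta_difference`
#'   (low - high), and logical flags `stiffer_at_depth`,
#'   `more_solid_at_depth`, `consistent_ordering`.
#' @export
compare_regimes <- function(fit_low, fit_high) {
  if (!inherits(fit_low, "rheology_fit") || !inherits(fit_high, "rheology_fit"))
    stopf("both regimes must be rheology_fit objects")
  ratio <- fit_high$E0_kPa / fit_low$E0_kPa
  dbeta <- fit_low$beta - fit_high$beta
  list(E0_low = fit_low$E0_kPa, E0_high = fit_high$E0_kPa,
       beta_low = fit_low$beta, beta_high = fit_high$beta,
       E0_ratio = ratio, beta_difference = dbeta,
       stiffer_at_depth = ratio > 1,
       more_solid_at_depth = dbeta > 0,
       consistent_ordering = ratio > 1 && dbeta > 0)
}
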