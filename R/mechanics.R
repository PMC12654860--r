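#' Synchronized compression record
#'
#' One cell's compression experiment: a force trace synchronized with
#' per-frame geometry (contact length `Dt`, cell width `Lt`). `L0`, the
#' initial cell width, defaults to `Lt` at the first frame with plate
#' contact (`Dt > 0`), which is where engineering strain is zero.
#'
#' @param time_s Time in seconds, strictly increasing.
#' @param force_nN Force in nN.
#' @param Dt_um Contact length per frame (um).
#' @param Lt_um Cell width per frame (um).
#' @param L0 Initial cell width (um); inferred when `NULL`.
#' @param branch Optional per-point branch labels
#'   (`"loading"`/`"unloading"`); recomputed by [build_curve()].
#' @param speed Plate speed (um/s), informational.
#' @return An object of class `compression_record` with a `data` frame
#'   and fields `L0`, `speed`.
#' @export
compression_record <- function(time_s, force_nN, Dt_um, Lt_um, L0 = NULL,
                               branch = NULL, speed = NA_real_) {
  n <- length(time_s)
  if (!all(lengths(list(force_nN, Dt_um, Lt_um)) == n))
    stopf("time, force and geometry series must have equal length")
  if (n < 1) stopf("empty record")
  if (any(diff(time_s) <= 0)) stopf("`time_s` must be strictly increasing")
  if (any(Dt_um < 0) || any(Lt_um <= 0))
    stopf("geometry must satisfy Dt >= 0, Lt > 0")
  if (is.null(L0)) {
    i0 <- which(Dt_um > 0)[1]
    if (is.na(i0)) stopf("no contact frames; cannot infer L0")
    L0 <- Lt_um[i0]
  }
  check_scalar(L0, "L0", positive = TRUE)
  structure(list(
    data = data.frame(time_s = time_s, force_nN = force_nN,
                      Dt_um = Dt_um, Lt_um = Lt_um,
                      branch = branch %||% rep(NA_character_, n)),
    L0 = L0, speed = speed
  ), class = "compression_record")
}

#' @export
print.compression_record <- function(x, ...) {
  cat(sprintf("Compression record: %d samples over %.3g s, L0 = %.3g um\n",
              nrow(x$data), max(x$data$time_s), x$L0))
  invisible(x)
}

#' Engineering stress
#'
#' \eqn{\sigma_t = F_t / S_t}. With force in nN and area in um^2 the
#' result is directly in kPa (1 nN/um^2 = 1 kPa).
#'
#' @param Ft Force(s) in nN.
#' @param St Contact area(s) in um^2, > 0.
#' @return Stress in kPa.
#' @export
compute_stress <- function(Ft, St) {
  stopifnot(is.numeric(Ft), is.numeric(St))
  if (any(St <= 0))
    stopf("no-contact point: St must be > 0 (exclude St = 0 upstream)")
  Ft / St
}

#' Engineering strain
#'
#' \eqn{\epsilon_t = (L_0 - L_t) / L_0}, the fractional reduction of
#' cell width along the compression axis.
#'
#' @param Lt Cell width(s) in um, > 0.
#' @param L0 Initial width in um, > 0.
#' @return Strain (dimensionless). Points with `Lt > L0` yield negative
#'   strain and raise a warning; flag or drop them upstream.
#' @export
compute_strain <- function(Lt, L0) {
  stopifnot(is.numeric(Lt))
  check_scalar(L0, "L0", positive = TRUE)
  if (any(Lt <= 0)) stopf("`Lt` must be > 0")
  eps <- (L0 - Lt) / L0
  if (any(eps < 0))
    warning(sprintf("%d point(s) with Lt > L0 give negative strain",
                    sum(eps < 0)), call. = FALSE)
  eps
}

#' Build a stress-strain curve from a compression record
#'
#' Computes per-point stress and strain, drops points without plate
#' contact (`Dt = 0`, where stress is undefined), and labels the
#' loading/unloading branches by splitting at the point of maximum
#' strain.
#'
#' @param record A [compression_record()].
#' @return An object of class `stress_strain_curve`: a data frame with
#'   columns `time_s`, `strain`, `stress_kPa`, `branch`, plus attributes
#'   `L0` and `n_dropped` (no-contact points removed).
#' @export
build_curve <- function(record) {
  stopifnot(inherits(record, "compression_record"))
  d <- record$data
  keep <- d$Dt_um > 0
  n_dropped <- sum(!keep)
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 3)
    stopf("fewer than 3 contact points (%d); cannot build a curve", nrow(d))
  strain <- compute_strain(d$Lt_um, record$L0)
  stress <- compute_stress(d$force_nN, contact_area(d$Dt_um))
  i_max <- which.max(strain)
  branch <- rep("unloading", nrow(d))
  branch[seq_len(i_max)] <- "loading"
  out <- data.frame(time_s = d$time_s, strain = strain,
                    stress_kPa = stress, branch = branch)
  structure(out, L0 = record$L0, n_dropped = n_dropped,
            class = c("stress_strain_curve", "data.frame"))
}

#' Elastic modulus from the high-strain region
#'
#' Ordinary least-squares regression of stress on strain over the
#' high-strain part of the loading branch, where the stress-strain plot
#' of a compressed cell is linear. The window is the loading points with
#' \eqn{\epsilon \ge (1 - f)\,\epsilon_{max}} for window fraction
#' `f = high_strain_fraction`; the modulus is the slope. The regression
#' includes an intercept, so a contact-onset stress offset does not bias
#' the slope.
#'
#' @param curve A [build_curve()] result.
#' @param high_strain_fraction Fraction of the achieved strain range
#'   kept in the fit window (default 0.3, i.e. the top 30%).
#' @return An object of class `modulus_estimate`: list with `E_kPa`,
#'   `r_squared`, `n_points`, `fit_strain_range`, `intercept_kPa`.
#' @export
fit_elastic_modulus <- function(curve, high_strain_fraction = 0.3) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  check_scalar(high_strain_fraction, "high_strain_fraction",
               lower = 1e-6, upper = 1)
  load <- curve[curve$branch == "loading", , drop = FALSE]
  eps_max <- max(load$strain)
  lo <- (1 - high_strain_fraction) * eps_max
  win <- load[load$strain >= lo, , drop = FALSE]
  if (nrow(win) < 3)
    stopf("fewer than 3 loading points in the high-strain window")
  fit <- stats::lm(stress_kPa ~ strain, data = win)
  structure(list(
    E_kPa = unname(stats::coef(fit)[["strain"]]),
    intercept_kPa = unname(stats::coef(fit)[[1]]),
    r_squared = r_squared_of(fit, win$stress_kPa),
    n_points = nrow(win),
    fit_strain_range = c(lo = min(win$strain), hi = max(win$strain))
  ), class = "modulus_estimate")
}

#' @export
print.modulus_estimate <- function(x, ...) {
  cat(sprintf(
    "Elastic modulus: %.4g kPa (r^2 = %.4f, n = %d, strain %.3f-%.3f)\n",
    x$E_kPa, x$r_squared, x$n_points,
    x$fit_strain_range[["lo"]], x$fit_strain_range[["hi"]]))
  invisible(x)
}

#' Maximum recorded force
#'
#' @param record A [compression_record()].
#' @return Maximum of the force series (nN).
#' @export
max_force <- function(record) {
  stopifnot(inherits(record, "compression_record"))
  if (nrow(record$data) == 0) stopf("empty force series")
  max(record$data$force_nN)
}

#' Read / write compression records as CSV
#'
#' The CSV has columns `time_s`, `force_nN`, `Dt_um`, `Lt_um` (and
#' optionally `branch`); comment lines start with `#`.
#'
#' @param path CSV path.
#' @param L0 Initial width (um); inferred from first contact when `NULL`.
#' @export
read_compression_csv <- function(path, L0 = NULL) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time_s", "force_nN", "Dt_um", "Lt_um")
  if (!all(need %in% names(df)))
    stopf("compression CSV needs columns %s", paste(need, collapse = ", "))
  if (is.null(L0)) {
    # the writer stores L0 in a comment; fall back to first-contact Lt
    head_lines <- grep("^#", readLines(path, n = 10), value = TRUE)
    l0_line <- grep("L0_um", head_lines, value = TRUE)
    if (length(l0_line))
      L0 <- as.numeric(sub(".*L0_um[ =]+", "", l0_line[1]))
  }
  compression_record(df$time_s, df$force_nN, df$Dt_um, df$Lt_um, L0 = L0)
}

#' @rdname read_compression_csv
#' @param record A [compression_record()] to write.
#' @param header Optional `#`-prefixed comment line(s).
#' @export
write_compression_csv <- function(record, path, header = NULL) {
  stopifnot(inherits(record, "compression_record"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(sprintf("# L0_um = %.17g", record$L0), con)
  utils::write.csv(record$data, con, row.names = FALSE)
  invisible(path)
}
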