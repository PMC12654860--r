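#' Condition-labelled stiffness population
#'
#' @param moduli Elastic moduli in kPa, all > 0, length >= 1.
#' @param condition Condition label.
#' @return An object of class `cell_population`.
#' @export
cell_population <- function(moduli, condition = "unlabelled") {
  stopifnot(is.numeric(moduli))
  if (length(moduli) < 1) stopf("a population needs at least one cell")
  if (any(!is.finite(moduli)) || any(moduli <= 0))
    stopf("all moduli must be finite and > 0")
  structure(list(condition = condition, moduli = as.numeric(moduli),
                 n = length(moduli)),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  s <- summarize_population(x)
  cat(sprintf("%s: %.3g +/- %.3g kPa (n = %d)\n",
              x$condition, s$mean_kPa, s$sd_kPa, s$n))
  invisible(x)
}

#' Mean, SD, and SEM of a stiffness population
#'
#' Results are reported as mean +/- sample standard deviation (n-1
#' denominator), with the standard error of the mean alongside.
#'
#' @param pop A [cell_population()] (or bare numeric vector).
#' @return A one-row data.frame with `condition`, `mean_kPa`, `sd_kPa`,
#'   `n`, `sem_kPa`.
#' @export
summarize_population <- function(pop) {
  if (is.numeric(pop)) pop <- cell_population(pop)
  stopifnot(inherits(pop, "cell_population"))
  x <- pop$moduli
  s <- if (length(x) >= 2) stats::sd(x) else 0
  data.frame(condition = pop$condition, mean_kPa = mean(x), sd_kPa = s,
             n = length(x), sem_kPa = s / sqrt(length(x)))
}

#' Two-sample Student's t-test between conditions
#'
#' Classic pooled-variance two-sample t-test, two-tailed, with
#' `n_a + n_b - 2` degrees of freedom; set `welch = TRUE` for the
#' unequal-variance (Welch) form. Two identical degenerate samples
#' (zero pooled variance, equal means) return `p = 1` by convention.
#'
#' @param a,b [cell_population()] objects (or numeric vectors).
#' @param welch Use Welch's correction instead of pooled variance.
#' @param alpha Significance level for the `significant` flag.
#' @return A list with `t`, `p`, `df`, `significant`, `mean_a`,
#'   `mean_b`.
#' @examples
#' students_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
students_t_test <- function(a, b, welch = FALSE, alpha = 0.05) {
  # accepts bare numeric vectors too: the test itself is generic and does
  # not require the positivity constraint of a stiffness population
  xa <- if (inherits(a, "cell_population")) a$moduli else as.numeric(a)
  xb <- if (inherits(b, "cell_population")) b$moduli else as.numeric(b)
  if (any(!is.finite(xa)) || any(!is.finite(xb)))
    stopf("samples must be finite")
  if (length(xa) < 2 || length(xb) < 2) stopf("both groups need n >= 2")
  if (stats::var(xa) == 0 && stats::var(xb) == 0) {
    if (mean(xa) == mean(xb))
      return(list(t = 0, p = 1, df = length(xa) + length(xb) - 2,
                  significant = FALSE,
                  mean_a = mean(xa), mean_b = mean(xb)))
    stopf("degenerate variance: both groups constant with unequal means")
  }
  ht <- stats::t.test(xa, xb, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       significant = ht$p.value < alpha,
       mean_a = mean(xa), mean_b = mean(xb))
}

#' Binned stiffness density histogram
#'
#' Histogram of the fraction of cells per `bin_width`-kPa interval,
#' normalized as a density: bins are `[k w, (k+1) w)` and each bin's
#' density is `count / (n * w)`, so density times `w` sums to 1.
#'
#' @param pop A [cell_population()] (or numeric vector).
#' @param bin_width Bin width in kPa (default 1).
#' @return A data.frame with `bin_lo_kPa`, `bin_hi_kPa`, `count`,
#'   `density`.
#' @export
histogram_density <- function(pop, bin_width = 1) {
  if (is.numeric(pop)) pop <- cell_population(pop)
  stopifnot(inherits(pop, "cell_population"))
  check_scalar(bin_width, "bin_width", positive = TRUE)
  x <- pop$moduli
  k <- floor(x / bin_width)
  ks <- seq(min(k), max(k))
  counts <- vapply(ks, function(ki) sum(k == ki), integer(1))
  data.frame(bin_lo_kPa = ks * bin_width, bin_hi_kPa = (ks + 1) * bin_width,
             count = counts, density = counts / (pop$n * bin_width))
}

#' Detect stiffness modes (peaks) in a population
#'
#' Gaussian kernel density estimate (Silverman's bandwidth) followed by
#' local-maximum detection. A local maximum counts as a mode when (a)
#' its height is at least 10% of the global peak and (b) it is
#' separated from the global peak by a genuine valley: the density
#' between them must dip below `valley_ratio` times the candidate's
#' height. The valley condition suppresses sampling ripple in the tail
#' of a unimodal distribution, which would otherwise be counted as a
#' mode in a few percent of 100-cell samples. The population is flagged
#' bimodal when at least two retained modes are more than
#' `separation_kPa` apart — wide enough to distinguish genuinely
#' distinct stiffness subpopulations (e.g. 2-4 kPa vs 6-8 kPa bands).
#'
#' @param pop A [cell_population()] (or numeric vector), n >= 20.
#' @param separation_kPa Minimum mode separation for the bimodal flag.
#' @param valley_ratio Maximum valley-to-peak density ratio for a
#'   candidate mode to count as separate.
#' @return A list with `modes_kPa` (sorted), `n_modes`, `bimodal`,
#'   and the `bandwidth` used.
#' @export
detect_modes <- function(pop, separation_kPa = 2, valley_ratio = 0.75) {
  if (is.numeric(pop)) pop <- cell_population(pop)
  stopifnot(inherits(pop, "cell_population"))
  if (pop$n < 20)
    stopf("mode detection needs n >= 20 (got %d)", pop$n)
  x <- pop$moduli
  bw <- stats::bw.nrd0(x)                    # Silverman's rule
  den <- stats::density(x, bw = bw, n = 512, from = 0,
                        to = max(x) + 3 * bw)
  y <- den$y
  pk <- which(diff(sign(diff(y))) == -2) + 1
  pk <- pk[y[pk] >= 0.1 * max(y)]
  if (length(pk) > 1) {
    gm <- pk[which.max(y[pk])]
    keep <- vapply(pk, function(i) {
      if (i == gm) return(TRUE)
      min(y[if (i < gm) i:gm else gm:i]) <= valley_ratio * y[i]
    }, logical(1))
    pk <- pk[keep]
  }
  modes <- sort(den$x[pk])
  bimodal <- length(modes) >= 2 &&
    (max(modes) - min(modes)) > separation_kPa
  list(modes_kPa = modes, n_modes = length(modes), bimodal = bimodal,
       bandwidth = bw)
}

#' Dose-response monotonicity check
#'
#' Given per-condition summaries ordered by increasing dose, reports
#' whether the mean stiffness is non-increasing with dose and the total
#' relative decrease from the first to the last condition.
#'
#' @param summaries A data.frame of stacked [summarize_population()]
#'   rows in dose order (>= 2 rows), or a list of them.
#' @return A list with `monotone_decreasing`, `total_relative_decrease`,
#'   and the `means_kPa` in order.
#' @export
dose_response_check <- function(summaries) {
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- do.call(rbind, summaries)
  stopifnot(is.data.frame(summaries), "mean_kPa" %in% names(summaries))
  if (nrow(summaries) < 2) stopf("need at least 2 conditions in dose order")
  m <- summaries$mean_kPa
  list(monotone_decreasing = all(diff(m) <= 0),
       total_relative_decrease = (m[1] - m[length(m)]) / m[1],
       means_kPa = m)
}

#' Read / write condition-labelled modulus tables
#'
#' CSV format: columns `condition`, `modulus_kPa`; comment lines start
#' with `#`.
#'
#' @param path CSV path.
#' @return A named list of [cell_population()] objects, one per
#'   condition (in file order).
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("condition", "modulus_kPa") %in% names(df)))
    stopf("population CSV needs columns condition, modulus_kPa")
  conds <- unique(df$condition)
  out <- lapply(conds, function(cn) {
    cell_population(df$modulus_kPa[df$condition == cn], cn)
  })
  names(out) <- conds
  out
}

#' @rdname read_population_csv
#' @param pops A list of [cell_population()] objects (or one).
#' @param header Optional `#`-prefixed comment line(s).
#' @export
write_population_csv <- function(pops, path, header = NULL) {
  if (inherits(pops, "cell_population")) pops <- list(pops)
  df <- do.call(rbind, lapply(pops, function(p) {
    data.frame(condition = p$condition, modulus_kPa = p$moduli)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
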