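# Internal helpers: units, argument checks, seeded evaluation.

# Standard gravity (m/s^2). Used everywhere a weight is converted to force.
STANDARD_GRAVITY <- 9.80665

# 1 g mass under 1 m/s^2 = 1e-3 kg m/s^2 = 1e-3 N = 1e6 nN.
NN_PER_GRAM_MS2 <- 1e6

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (positive && x <= 0) stopf("`%s` must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stopf("`%s` must be >= 0 (got %g)", name, x)
  if (x < lower || x > upper)
    stopf("`%s` must lie in [%g, %g] (got %g)", name, lower, upper, x)
  if (integer && x != round(x)) stopf("`%s` must be an integer", name)
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package route through this,
# so no function leaves a footprint on .Random.seed.
with_seed <- function(seed, expr) {
  check_scalar(seed, "seed", integer = TRUE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit hash of a character scalar, reported as 8 hex digits.
# Used to stamp output files with a configuration fingerprint.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # XOR with a byte only touches the low 8 bits; keeps h in double range
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    # 32-bit modular multiply by the FNV prime 16777619, done in doubles
    h <- (h * 16777619) %% 4294967296
  }
  # format as 8 hex digits (h may exceed .Machine$integer.max, so by halves)
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coefficient of determination without summary.lm's perfect-fit warning;
# a zero-variance response fitted exactly counts as r^2 = 1.
r_squared_of <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  ssr <- sum(stats::resid(fit)^2)
  if (sst <= .Machine$double.eps) return(if (ssr <= 1e-12) 1 else 0)
  1 - ssr / sst
}
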