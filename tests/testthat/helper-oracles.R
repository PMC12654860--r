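# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Classic pooled-variance two-sample t-test from the textbook formula.
t_test_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

# Direct weight of the calibration ball in nN: m[g] -> kg, N -> nN.
mg_oracle <- function(mass_g, g = 9.80665) mass_g * 1e-3 * g * 1e9

# An elastic test cell: both compartments equal and time-invariant, so the
# whole-cell modulus is E by construction.
elastic_cell <- function(E, L0 = 15) {
  virtual_cell_params(L0 = L0, E0_cyto = E, E0_nuc = E,
                      beta_cyto = 0, beta_nuc = 0)
}

quiet_run <- function(run = NULL, ...) {
  compression_run_spec(force_noise_sd = 0, ...)
}
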