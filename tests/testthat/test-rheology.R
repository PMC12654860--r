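test_that("log-log fitting is exact on noise-free power-law samples", {
  t <- c(0.2, 0.5, 1, 2)
  # beta = 0: purely elastic solid
  f0 <- fit_power_law(data.frame(t_s = t, apparent_E_kPa = rep(4.2, 4)))
  expect_lt(abs(f0$beta), 1e-9)
  expect_equal(f0$E0_kPa, 4.2, tolerance = 1e-9)
  # beta = 1: Newtonian viscous liquid
  f1 <- fit_power_law(data.frame(t_s = t, apparent_E_kPa = 3 / t))
  expect_lt(abs(f1$beta - 1), 1e-9)
  expect_equal(f1$E0_kPa, 3, tolerance = 1e-9)
  # intermediate exponent
  fm <- fit_power_law(data.frame(t_s = t, apparent_E_kPa = 5 * t^-0.3))
  expect_lt(abs(fm$beta - 0.3), 1e-9)
  expect_lt(abs(fm$E0_kPa - 5), 1e-9)
  expect_equal(fm$r_squared, 1, tolerance = 1e-9)
  # nonlinear refit agrees on exact data
  fn <- fit_power_law(data.frame(t_s = t, apparent_E_kPa = 5 * t^-0.3),
                      method = "nls")
  expect_equal(fn$beta, 0.3, tolerance = 1e-6)
  expect_equal(fn$E0_kPa, 5, tolerance = 1e-6)
})

test_that("parameter recovery holds over the (E0, beta) grid", {
  speeds <- c(2.5, 5, 10, 15)
  L0 <- 15
  checkpoint <- 0.15
  t <- checkpoint * L0 / speeds      # >= 6x range in indentation time
  expect_gte(max(t) / min(t), 6)
  for (E0 in c(1, 3, 5, 10)) {
    for (beta in c(0, 0.1, 0.3, 0.5, 1.0)) {
      fit <- fit_power_law(data.frame(t_s = t,
                                      apparent_E_kPa = E0 * t^-beta))
      expect_lt(abs(fit$E0_kPa - E0) / E0, 1e-6)
      expect_lt(abs(fit$beta - beta), 1e-6)
    }
  }
})

test_that("noisy samples still localize beta (median error <= 0.05)", {
  speeds <- c(2.5, 5, 10, 15)
  t <- 0.15 * 15 / speeds
  err <- with(list(), {
    set.seed(77)
    vapply(1:100, function(i) {
      E <- 3 * t^-0.3 * exp(rnorm(length(t), 0, 0.05))
      abs(fit_power_law(data.frame(t_s = t, apparent_E_kPa = E))$beta - 0.3)
    }, numeric(1))
  })
  expect_lte(median(err), 0.05)
})

test_that("changing tref rescales E0 analytically and leaves beta alone", {
  t <- c(0.2, 0.5, 1, 2, 4)
  samples <- data.frame(t_s = t, apparent_E_kPa = 6 * t^-0.45)
  f1 <- fit_power_law(samples, tref = 1)
  f2 <- fit_power_law(samples, tref = 2)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-9)
  expect_equal(f2$E0_kPa, f1$E0_kPa * (2 / 1)^(-f1$beta), tolerance = 1e-9)
})

test_that("fitter rejects degenerate sample sets", {
  expect_error(fit_power_law(data.frame(t_s = c(1, 2),
                                        apparent_E_kPa = c(1, 2))),
               "at least 3")
  expect_error(fit_power_law(data.frame(t_s = rep(1, 4),
                                        apparent_E_kPa = 1:4)),
               "singular")
  expect_error(fit_power_law(data.frame(t_s = 1:4,
                                        apparent_E_kPa = c(1, -1, 2, 3))),
               "invalid sample")
})

test_that("checkpoint sampling returns the secant modulus and elapsed time", {
  # elastic cell: apparent modulus equals E at every checkpoint
  cell <- elastic_cell(4, L0 = 10)
  run <- compression_run_spec(speed = 2.5, max_strain = 0.5,
                              force_noise_sd = 0)
  rec <- simulate_compression(cell, run)
  cv <- build_curve(rec)
  for (cp in c(0.1, 0.2, 0.45)) {
    s <- apparent_modulus_at_checkpoint(cv, rec, cp)
    expect_equal(s$apparent_E_kPa, 4, tolerance = 1e-6)
  }
  # t = eps * L0 / speed: 0.2 * 10 / 2.5 = 0.8 s
  s <- apparent_modulus_at_checkpoint(cv, rec, 0.2)
  expect_equal(s$t_s, 0.8, tolerance = 1e-9)
  expect_equal(s$regime, "low_compression")
  expect_equal(apparent_modulus_at_checkpoint(cv, rec, 0.45)$regime,
               "high_compression")
  expect_error(apparent_modulus_at_checkpoint(cv, rec, 0.6),
               "insufficient compression")
})

test_that("coarse-grid interpolation matches a dense-grid oracle", {
  cell <- virtual_cell_params(E0_cyto = 3, beta_cyto = 0.4)
  mk <- function(rate) {
    run <- compression_run_spec(speed = 7.5, max_strain = 0.4,
                                sample_rate = rate, force_noise_sd = 0)
    rec <- simulate_compression(cell, run)
    apparent_modulus_at_checkpoint(build_curve(rec), rec, 0.17)
  }
  coarse <- mk(15)
  dense <- mk(2000)
  expect_lt(abs(coarse$apparent_E_kPa - dense$apparent_E_kPa) /
              dense$apparent_E_kPa, 0.005)
  expect_lt(abs(coarse$t_s - dense$t_s) / dense$t_s, 0.005)
})

test_that("full-pipeline speed sweep recovers compartment rheology", {
  # both compartments share beta: each regime is an exact power law
  cell <- virtual_cell_params(E0_cyto = 2, E0_nuc = 8,
                              beta_cyto = 0.35, beta_nuc = 0.35)
  samples <- lapply(c(low = 0.15, high = 0.45), function(cp) {
    do.call(rbind, lapply(c(2.5, 5, 10, 15), function(v) {
      run <- compression_run_spec(speed = v, max_strain = 0.55,
                                  sample_rate = 500, force_noise_sd = 0)
      rec <- simulate_compression(cell, run)
      apparent_modulus_at_checkpoint(build_curve(rec), rec, cp,
                                     nucleus_contact_strain = 0.3)
    }))
  })
  fit_low <- fit_power_law(samples$low)
  fit_high <- fit_power_law(samples$high)
  expect_equal(fit_low$beta, 0.35, tolerance = 1e-3)
  expect_equal(fit_low$E0_kPa, 2, tolerance = 1e-3)
  expect_equal(fit_high$beta, 0.35, tolerance = 1e-3)
  expect_gt(fit_high$E0_kPa, fit_low$E0_kPa)  # nucleus stiffens the stack
})

test_that("regime comparison flags the expected orderings", {
  mkfit <- function(E0, beta) {
    t <- c(0.25, 0.5, 1, 2)
    fit_power_law(data.frame(t_s = t, apparent_E_kPa = E0 * t^-beta))
  }
  # nucleus stiffer and more solid-like than cytoplasm
  rep1 <- compare_regimes(mkfit(2, 0.4), mkfit(6, 0.1))
  expect_true(rep1$consistent_ordering)
  expect_equal(rep1$E0_ratio, 3, tolerance = 1e-6)
  expect_equal(rep1$beta_difference, 0.3, tolerance = 1e-6)
  # identical regimes
  rep2 <- compare_regimes(mkfit(3, 0.2), mkfit(3, 0.2))
  expect_equal(rep2$E0_ratio, 1, tolerance = 1e-9)
  expect_equal(rep2$beta_difference, 0, tolerance = 1e-9)
  expect_false(rep2$consistent_ordering)
  # swapped parameters invert the flags
  rep3 <- compare_regimes(mkfit(6, 0.1), mkfit(2, 0.4))
  expect_false(rep3$stiffer_at_depth)
  expect_false(rep3$more_solid_at_depth)
})
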