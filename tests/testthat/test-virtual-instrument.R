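test_that("truncated-sphere contact geometry has the closed form", {
  rec <- simulate_compression(elastic_cell(3, L0 = 10),
                              compression_run_spec(max_strain = 0.5,
                                                   force_noise_sd = 0))
  last <- nrow(rec$data)
  expect_equal(rec$data$Lt_um[last], 5)
  expect_equal(rec$data$Dt_um[last], 10 * sqrt(2 * 0.5 - 0.25))  # 8.660 um
  # D(0) = 0, strictly increasing in strain, bounded by L0
  eps <- seq(0, 0.99, by = 0.01)
  D <- micropress:::truncated_sphere_contact(eps, 10)
  expect_equal(D[1], 0)
  expect_true(all(diff(D) > 0))
  expect_true(all(D <= 10 + 1e-12))
})

test_that("a purely elastic cell gives constant stress/strain ratio", {
  rec <- simulate_compression(elastic_cell(4), quiet_run())
  St <- contact_area(rec$data$Dt_um)
  eps <- (rec$L0 - rec$data$Lt_um) / rec$L0
  ratio <- (rec$data$force_nN / St) / eps
  expect_equal(ratio, rep(4, length(ratio)), tolerance = 1e-10)
})

test_that("loading force is monotone increasing without noise", {
  for (beta in c(0, 0.3, 1)) {
    cell <- virtual_cell_params(E0_cyto = 2, E0_nuc = 8,
                                beta_cyto = beta, beta_nuc = beta / 2)
    rec <- simulate_compression(cell,
             compression_run_spec(sample_rate = 500, force_noise_sd = 0))
    f <- rec$data$force_nN[rec$data$branch == "loading"]
    expect_true(all(diff(f) > 0))
  }
})

test_that("unloading branch mirrors loading scaled by the retention factor", {
  cell <- elastic_cell(5)
  rec <- simulate_compression(cell,
           compression_run_spec(include_unloading = TRUE, force_noise_sd = 0))
  cv <- build_curve(rec)
  up <- cv[cv$branch == "loading", ]
  dn <- cv[cv$branch == "unloading", ]
  m <- match(round(dn$strain, 9), round(up$strain, 9))
  matched <- !is.na(m)
  expect_gt(sum(matched), 10)
  expect_equal(dn$stress_kPa[matched], 0.7 * up$stress_kPa[m[matched]],
               tolerance = 1e-9)
})

test_that("identical seeds reproduce sweeps, records, frames and samples", {
  s <- sensor_params()
  expect_identical(simulate_calibration_sweep(s, seed = 5),
                   simulate_calibration_sweep(s, seed = 5))
  cell <- virtual_cell_params()
  run <- compression_run_spec()
  expect_identical(simulate_compression(cell, run, seed = 9),
                   simulate_compression(cell, run, seed = 9))
  expect_false(identical(simulate_compression(cell, run, seed = 9),
                         simulate_compression(cell, run, seed = 10)))
  expect_identical(sample_moduli("HEK293A", 20, seed = 3),
                   sample_moduli("HEK293A", 20, seed = 3))
  f1 <- render_frame(8, 4)
  f2 <- render_frame(8, 4)
  expect_identical(f1$intensities, f2$intensities)
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(simulate_compression(virtual_cell_params(),
                                 compression_run_spec(), seed = 4))
  invisible(sample_moduli("HEK293A", 10, seed = 2))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("preset sampling matches its distribution", {
  # degenerate sd: all draws equal the mean
  p0 <- population_preset("const", data.frame(weight = 1, mean_kPa = 4,
                                              sd_kPa = 0))
  expect_equal(sample_moduli(p0, 10, seed = 1), rep(4, 10))
  # two well-separated components appear as two density peaks
  p2 <- population_preset("mix", data.frame(weight = c(0.5, 0.5),
                                            mean_kPa = c(3, 7),
                                            sd_kPa = c(0.5, 0.5)))
  x <- sample_moduli(p2, 500, seed = 11)
  md <- detect_modes(cell_population(x))
  expect_true(md$bimodal)
  expect_equal(length(md$modes_kPa), 2)
  expect_lt(abs(md$modes_kPa[1] - 3), 0.5)
  expect_lt(abs(md$modes_kPa[2] - 7), 0.5)
  # truncation: no draws at or below the bound
  pt <- population_preset("soft", data.frame(weight = 1, mean_kPa = 0.5,
                                             sd_kPa = 1))
  expect_true(all(sample_moduli(pt, 500, seed = 2) > 0.1))
  expect_error(preset_registry("NOPE"), "unknown preset")
})

test_that("population grand mean converges to the preset mean", {
  # asymptotic unbiasedness: 50 seeds at n = 500
  for (cond in c("HEK293A", "C2C12")) {
    p <- preset_registry(cond)
    grand <- mean(vapply(1:50, function(s) {
      mean(sample_moduli(p, 500, seed = s))
    }, numeric(1)))
    expect_lt(abs(grand - micropress:::preset_mean(p)) /
                micropress:::preset_mean(p), 0.01)
  }
})

test_that("needle end-effector max forces vary more than plate ones", {
  moduli <- sample_moduli("HEK293A", 50, seed = 21)
  panel <- simulate_end_effector_panel(moduli, compression_run_spec(),
                                       seed = 21)
  v <- tapply(panel$max_force_nN, panel$scenario, var)
  expect_gt(v[["needle"]], v[["plate"]])
})

test_that("rendered frames match the requested geometry", {
  f <- render_frame(Lt = 10, Dt = 6, pixel_size = 0.1)
  pl <- locate_plates(f)
  expect_equal(pl$right_px - pl$left_px, 100)    # 10 um at 0.1 um/px
  # no-contact frame: plate-adjacent band stays empty
  f0 <- render_frame(Lt = 8, Dt = 0, pixel_size = 0.1)
  m0 <- measure_contact_length(f0)
  expect_lte(m0$Dt_um, 2 * 0.1)
  expect_false(m0$contact)
  expect_error(render_frame(Lt = 50, Dt = 0, pixel_size = 0.1,
                            image_shape = c(60, 60)),
               "does not fit")
})
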