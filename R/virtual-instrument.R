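#' Virtual force-sensor parameters
#'
#' Ground-truth description of a semiconductor strain-gauge microforce
#' sensor as seen through its analog-to-digital converter. The sensor is
#' linear: one ADC unit (ADU) above baseline corresponds to
#' `true_coefficient` nanonewtons along the sensitive axis.
#'
#' @param true_coefficient Force per ADC unit (nN/ADU), > 0.
#' @param phase_offset Angular offset (degrees) between the rotary stage
#'   zero and the sensor's sensitive axis.
#' @param adc_baseline ADC output at zero force (ADU).
#' @param adc_noise_sd Standard deviation of additive Gaussian ADC noise
#'   (ADU), >= 0.
#' @return An object of class `sensor_params`.
#' @examples
#' sensor_params(true_coefficient = 1.9, phase_offset = 30)
#' @export
sensor_params <- function(true_coefficient = 1.9, phase_offset = 0,
                          adc_baseline = 512, adc_noise_sd = 1.0) {
  check_scalar(true_coefficient, "true_coefficient", positive = TRUE)
  check_scalar(phase_offset, "phase_offset")
  check_scalar(adc_baseline, "adc_baseline")
  check_scalar(adc_noise_sd, "adc_noise_sd", nonneg = TRUE)
  structure(list(true_coefficient = true_coefficient,
                 phase_offset = phase_offset,
                 adc_baseline = adc_baseline,
                 adc_noise_sd = adc_noise_sd),
            class = "sensor_params")
}

#' Simulate a gravimetric calibration sweep
#'
#' Emulates the automated rotation calibration: a steel ball of known mass
#' rests on the sensor tip while a motorized stage rotates the assembly
#' through one full revolution in `n_steps` equal increments (50 steps of
#' 7.2 degrees by default). At stage angle \eqn{\theta} the gravity
#' component along the sensitive axis is \eqn{m g \cos(\theta - \phi)},
#' so the noise-free ADC output is
#' \deqn{ADC(\theta) = baseline + m g \cos(\theta - \phi) / k}
#' with \eqn{k} the true conversion coefficient (nN/ADU). Gaussian ADC
#' noise is added when `adc_noise_sd > 0`.
#'
#' @param sensor A [sensor_params()] object (ground truth).
#' @param ball_mass Mass of the calibration ball in grams, > 0.
#' @param n_steps Number of angular positions over 360 degrees, >= 4.
#' @param seed Integer seed for the ADC noise.
#' @param gravity Gravitational acceleration (m/s^2).
#' @return A [calibration_sweep()] object with `n_steps` (angle, ADC)
#'   pairs; angles are `i * 360 / n_steps` degrees for `i = 0..n_steps-1`.
#' @examples
#' sw <- simulate_calibration_sweep(sensor_params(), seed = 1)
#' diff(sw$angles)[1]  # 7.2 degrees per step
#' @export
simulate_calibration_sweep <- function(sensor, ball_mass = 3.27e-5,
                                       n_steps = 50, seed = 1,
                                       gravity = STANDARD_GRAVITY) {
  if (!inherits(sensor, "sensor_params"))
    stopf("`sensor` must be a sensor_params object")
  check_scalar(ball_mass, "ball_mass", positive = TRUE)
  check_scalar(n_steps, "n_steps", integer = TRUE, lower = 4)
  check_scalar(gravity, "gravity", positive = TRUE)

  angles <- (seq_len(n_steps) - 1) * 360 / n_steps
  force_nN <- expected_axis_force(ball_mass, angles, sensor$phase_offset,
                                  gravity)
  adc <- sensor$adc_baseline + force_nN / sensor$true_coefficient
  if (sensor$adc_noise_sd > 0)
    adc <- adc + with_seed(seed, stats::rnorm(n_steps, 0, sensor$adc_noise_sd))
  calibration_sweep(angles, adc, ball_mass = ball_mass, gravity = gravity)
}

#' Virtual cell parameters
#'
#' Two-compartment (cytoplasm around nucleus) power-law viscoelastic cell
#' used by the compression simulator. Each compartment follows
#' \eqn{E(t) = E_0 (t/t_{ref})^{-\beta}} with \eqn{t_{ref} = 1} s:
#' \eqn{\beta = 0} is a purely elastic solid, \eqn{\beta = 1} a Newtonian
#' liquid. The nucleus engages once the plates have closed past the
#' cytoplasmic shell, i.e. at engineering strain
#' \eqn{\epsilon^* = 1 - } `nucleus_fraction`.
#'
#' @param L0 Initial cell diameter (um), > 0.
#' @param nucleus_fraction Nucleus diameter as a fraction of `L0`, in (0,1).
#' @param E0_cyto,E0_nuc Initial elastic moduli of cytoplasm and nucleus
#'   (kPa), > 0.
#' @param beta_cyto,beta_nuc Power-law exponents in [0, 1].
#' @param unload_retention Hysteresis factor in (0, 1]: unloading stress
#'   at a given strain equals `unload_retention` times the loading stress.
#' @return An object of class `virtual_cell_params`.
#' @export
virtual_cell_params <- function(L0 = 15, nucleus_fraction = 0.7,
                                E0_cyto = 2, E0_nuc = 8,
                                beta_cyto = 0.4, beta_nuc = 0.1,
                                unload_retention = 0.7) {
  check_scalar(L0, "L0", positive = TRUE)
  check_scalar(nucleus_fraction, "nucleus_fraction")
  if (nucleus_fraction <= 0 || nucleus_fraction >= 1)
    stopf("`nucleus_fraction` must lie in (0, 1)")
  check_scalar(E0_cyto, "E0_cyto", positive = TRUE)
  check_scalar(E0_nuc, "E0_nuc", positive = TRUE)
  check_scalar(beta_cyto, "beta_cyto", lower = 0, upper = 1)
  check_scalar(beta_nuc, "beta_nuc", lower = 0, upper = 1)
  check_scalar(unload_retention, "unload_retention", upper = 1)
  if (unload_retention <= 0) stopf("`unload_retention` must lie in (0, 1]")
  structure(list(L0 = L0, nucleus_fraction = nucleus_fraction,
                 E0_cyto = E0_cyto, E0_nuc = E0_nuc,
                 beta_cyto = beta_cyto, beta_nuc = beta_nuc,
                 unload_retention = unload_retention),
            class = "virtual_cell_params")
}

#' Compression run settings
#'
#' @param speed Plate closing (indentation) speed in um/s; the instrument
#'   operates between 2.5 and 15 um/s.
#' @param max_strain Target engineering strain, in (0, 1).
#' @param sample_rate Sampling rate of the synchronized force/video
#'   stream (Hz).
#' @param include_unloading If `TRUE`, the run retracts at the same speed
#'   after reaching `max_strain`.
#' @param force_noise_sd Additive Gaussian force noise (nN); the default
#'   matches the ~2 nN resolution of the physical sensor class emulated.
#' @return An object of class `compression_run_spec`.
#' @export
compression_run_spec <- function(speed = 7.5, max_strain = 0.5,
                                 sample_rate = 100,
                                 include_unloading = FALSE,
                                 force_noise_sd = 2) {
  check_scalar(speed, "speed", positive = TRUE)
  check_scalar(max_strain, "max_strain")
  if (max_strain <= 0 || max_strain >= 1)
    stopf("`max_strain` must lie in (0, 1)")
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  check_scalar(force_noise_sd, "force_noise_sd", nonneg = TRUE)
  structure(list(speed = speed, max_strain = max_strain,
                 sample_rate = sample_rate,
                 include_unloading = isTRUE(include_unloading),
                 force_noise_sd = force_noise_sd),
            class = "compression_run_spec")
}

# Contact patch diameter of a rigidly truncated sphere of diameter L0
# compressed to engineering strain eps: the chord at the cut plane,
# D = L0 * sqrt(2 eps - eps^2). D(0) = 0, D is increasing, D <= L0.
truncated_sphere_contact <- function(eps, L0) {
  L0 * sqrt(pmax(0, 2 * eps - eps^2))
}

# Effective modulus of the stacked cytoplasm/nucleus column at strain eps
# and elapsed indentation time t (s). Below the nucleus-contact strain
# eps* = 1 - nucleus_fraction only the cytoplasm deforms; past it the two
# compartments act in series along the compression axis, so the combined
# modulus is the strain-weighted harmonic mean.
effective_modulus <- function(cell, eps, t) {
  tt <- pmax(t, .Machine$double.eps)
  E_c <- cell$E0_cyto * tt^(-cell$beta_cyto)
  eps_star <- 1 - cell$nucleus_fraction
  out <- E_c
  hi <- eps >= eps_star & eps > 0
  if (any(hi)) {
    E_n <- cell$E0_nuc * tt^(-cell$beta_nuc)
    w_c <- eps_star / eps[hi]        # strain share carried by cytoplasm
    w_n <- 1 - w_c
    out[hi] <- 1 / (w_c / E_c[hi] + w_n / E_n[hi])
  }
  out
}

#' Simulate constant-speed compression of a virtual cell
#'
#' Generates one synchronized force/geometry record for a cell squeezed
#' between two rigid plates closing at constant speed. At each timestep
#' the engineering strain is \eqn{\epsilon(t) = \min(vt/L_0,
#' \epsilon_{max})}; the stress is \eqn{\sigma = E_{eff}(\epsilon, t)
#' \epsilon} with the two-compartment effective modulus of
#' [virtual_cell_params()]; the contact diameter follows the
#' truncated-sphere chord \eqn{D = L_0\sqrt{2\epsilon - \epsilon^2}}; and
#' the recorded force is \eqn{F = \sigma \pi D^2 / 4} plus Gaussian
#' noise. The unloading branch (optional) mirrors the loading strain ramp
#' with stress scaled by `unload_retention`. Ground-truth geometry
#' (`Dt_um`, `Lt_um`) is stored alongside the force trace, emulating
#' per-frame image measurements.
#'
#' @param cell A [virtual_cell_params()] object.
#' @param run A [compression_run_spec()] object.
#' @param seed Integer seed for the force noise.
#' @return A [compression_record()] whose `data` has columns `time_s`,
#'   `force_nN`, `Dt_um`, `Lt_um`, `branch`.
#' @examples
#' cell <- virtual_cell_params(E0_cyto = 3, E0_nuc = 3,
#'                             beta_cyto = 0, beta_nuc = 0)
#' rec <- simulate_compression(cell, compression_run_spec(force_noise_sd = 0))
#' @export
simulate_compression <- function(cell, run = compression_run_spec(),
                                 seed = 1) {
  if (!inherits(cell, "virtual_cell_params"))
    stopf("`cell` must be a virtual_cell_params object")
  if (!inherits(run, "compression_run_spec"))
    stopf("`run` must be a compression_run_spec object")
  if (run$max_strain >= 1) stopf("`max_strain` must be < 1")

  dt <- 1 / run$sample_rate
  t_load <- run$max_strain * cell$L0 / run$speed
  t_up <- seq(dt, t_load, by = dt)
  if (length(t_up) == 0 || t_up[length(t_up)] < t_load)
    t_up <- c(t_up, t_load)          # always sample the strain peak
  eps_up <- pmin(run$speed * t_up / cell$L0, run$max_strain)
  sig_up <- effective_modulus(cell, eps_up, t_up) * eps_up
  branch <- rep("loading", length(t_up))
  time <- t_up
  eps <- eps_up
  sigma <- sig_up

  if (run$include_unloading) {
    t_dn <- seq(t_load + dt, 2 * t_load, by = dt)
    eps_dn <- pmax(run$max_strain - run$speed * (t_dn - t_load) / cell$L0, 0)
    # hysteresis: unloading stress is a fixed fraction of the loading
    # stress at equal strain (time frozen at the peak for the modulus)
    sig_dn <- cell$unload_retention *
      effective_modulus(cell, eps_dn, rep(t_load, length(t_dn))) * eps_dn
    time <- c(time, t_dn)
    eps <- c(eps, eps_dn)
    sigma <- c(sigma, sig_dn)
    branch <- c(branch, rep("unloading", length(t_dn)))
  }

  Dt <- truncated_sphere_contact(eps, cell$L0)
  St <- pi * Dt^2 / 4
  force <- sigma * St                 # kPa * um^2 = nN
  if (run$force_noise_sd > 0)
    force <- force + with_seed(seed,
      stats::rnorm(length(force), 0, run$force_noise_sd))

  compression_record(time_s = time, force_nN = force,
                     Dt_um = Dt, Lt_um = cell$L0 * (1 - eps),
                     L0 = cell$L0, branch = branch,
                     speed = run$speed)
}

#' Render a bright-field-like frame of a compressed cell
#'
#' Draws a synthetic micrograph: two dark plate bands perpendicular to
#' the (horizontal) compression axis with inner edges `Lt` apart, and a
#' darker cell between them. The cell is drawn as a flat contact collar
#' of transverse extent `Dt` at each plate joined to an elliptical
#' mid-body bulge, the silhouette of a strongly squashed sphere. When
#' `Dt = 0` the cell is an ellipse tangent to both plates.
#'
#' @param Lt Cell width along the compression axis (um), > 0.
#' @param Dt Contact length at the plates (um), >= 0.
#' @param pixel_size Pixel pitch (um/px).
#' @param image_shape Integer (rows, cols) of the frame; chosen
#'   automatically when `NULL`.
#' @param cell_center (row, col) pixel position of the cell center;
#'   defaults to the frame center.
#' @param lateral_extent Transverse cell diameter (um); defaults to
#'   `max(Lt, 1.2 * Dt)` so the mid-body always bulges past the contact.
#' @return A [micrograph()] with attributes `truth` (list with `Dt`,
#'   `Lt`) attached.
#' @export
render_frame <- function(Lt, Dt, pixel_size = 0.1, image_shape = NULL,
                         cell_center = NULL, lateral_extent = NULL) {
  check_scalar(Lt, "Lt", positive = TRUE)
  check_scalar(Dt, "Dt", nonneg = TRUE)
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  W <- lateral_extent %||% max(Lt, 1.2 * Dt)
  if (W < Dt) stopf("`lateral_extent` must be >= Dt")

  if (is.null(image_shape)) {
    n_col <- ceiling((Lt + 10) / pixel_size)      # plates + margin
    n_row <- ceiling((W + 6) / pixel_size)
    image_shape <- c(n_row, n_col)
  }
  n_row <- image_shape[1]; n_col <- image_shape[2]
  cc <- cell_center %||% c(n_row / 2, n_col / 2)
  # pixel centers in um (0-based indices, centers at i + 0.5)
  x <- ((seq_len(n_col) - 0.5) - cc[2]) * pixel_size   # along axis
  y <- ((seq_len(n_row) - 0.5) - cc[1]) * pixel_size   # transverse

  if (Lt + 2 * pixel_size > n_col * pixel_size ||
      W + 2 * pixel_size > n_row * pixel_size)
    stopf("cell geometry (Lt=%g, width=%g um) does not fit a %dx%d frame at %g um/px",
          Lt, W, n_row, n_col, pixel_size)

  img <- matrix(0.95, n_row, n_col)               # bright background
  plate <- abs(x) >= Lt / 2
  img[, plate] <- 0.15                            # dark plates

  X <- matrix(abs(x), n_row, n_col, byrow = TRUE)
  Y <- matrix(abs(y), n_row, n_col)
  # mid-body ellipse, inset axially by a collar so that the silhouette
  # right at the plates is set by the flat contact, not the bulge
  collar <- if (Dt > 0) max(3 * pixel_size, 0.04 * Lt) else 0
  a <- Lt / 2 - collar
  mask <- (X / a)^2 + (Y / (W / 2))^2 <= 1
  if (Dt > 0)
    mask <- mask | (X <= Lt / 2 & Y <= Dt / 2)    # contact collar
  mask <- mask & !matrix(plate, n_row, n_col, byrow = TRUE)
  img[mask] <- 0.45                               # cell darker than bg

  out <- micrograph(img, pixel_size = pixel_size,
                    compression_axis = "horizontal")
  attr(out, "truth") <- list(Dt = Dt, Lt = Lt, lateral_extent = W)
  out
}

#' Render a full compression image stack from a record
#'
#' Convenience wrapper that renders one [render_frame()] per timepoint of
#' a [compression_record()], using its stored ground-truth geometry.
#'
#' @param record A [compression_record()].
#' @param pixel_size Pixel pitch (um/px).
#' @param every Keep every `every`-th frame (thins dense force sampling
#'   to a video-like rate).
#' @return A list of [micrograph()] frames (a constant frame size is
#'   used across the stack).
#' @export
render_stack <- function(record, pixel_size = 0.1, every = 5) {
  stopifnot(inherits(record, "compression_record"))
  idx <- seq(1, nrow(record$data), by = every)
  W_max <- max(record$L0, 1.2 * max(record$data$Dt_um))
  shape <- c(ceiling((W_max + 6) / pixel_size),
             ceiling((record$L0 + 10) / pixel_size))
  lapply(idx, function(i) {
    render_frame(Lt = record$data$Lt_um[i], Dt = record$data$Dt_um[i],
                 pixel_size = pixel_size, image_shape = shape)
  })
}

#' Simulate maximum-force panels for needle vs plate end-effectors
#'
#' Scenario used to compare end-effector designs. The plate scenario
#' compresses each cell with the standard parallel-plate simulator and
#' records the maximum force. The needle scenario models the unstable
#' contact of a narrow tip on a rounded cell: with probability
#' `p_engage` the needle stays centered and loads the whole cell
#' (plate-like peak force, jittered by a multiplicative lognormal slip
#' factor); otherwise it slides off-axis and only pokes the cell
#' shallowly over its fixed small tip area (diameter `needle_tip_um`),
#' producing a far smaller force. With equal cell populations the
#' needle max-force distribution is therefore substantially broader
#' than the plate one.
#'
#' @param moduli Vector of whole-cell elastic moduli (kPa).
#' @param run A [compression_run_spec()].
#' @param needle_tip_um Needle tip diameter (um).
#' @param p_engage Probability that a needle attempt loads the whole
#'   cell instead of slipping off.
#' @param slip_sd SD of the lognormal slip factor (log scale).
#' @param seed Integer seed.
#' @return A data.frame with columns `scenario` ("plate"/"needle") and
#'   `max_force_nN`.
#' @export
simulate_end_effector_panel <- function(moduli, run = compression_run_spec(),
                                        needle_tip_um = 2, p_engage = 0.3,
                                        slip_sd = 0.3, seed = 1) {
  stopifnot(is.numeric(moduli), length(moduli) >= 2, all(moduli > 0))
  check_scalar(p_engage, "p_engage", lower = 0, upper = 1)
  plate <- vapply(seq_along(moduli), function(i) {
    cell <- virtual_cell_params(E0_cyto = moduli[i], E0_nuc = moduli[i],
                                beta_cyto = 0, beta_nuc = 0)
    max_force(simulate_compression(cell, run, seed = seed + i))
  }, numeric(1))
  needle <- with_seed(seed, {
    engaged <- stats::runif(length(moduli)) < p_engage
    slip <- stats::rlnorm(length(moduli), 0, slip_sd)
    tip_area <- pi * needle_tip_um^2 / 4
    shallow <- moduli * run$max_strain * tip_area   # sigma * tip area
    ifelse(engaged, plate, shallow) * slip
  })
  data.frame(
    scenario = rep(c("plate", "needle"), each = length(moduli)),
    max_force_nN = c(plate, needle)
  )
}
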