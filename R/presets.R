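#' Define a population stiffness preset
#'
#' A preset describes the distribution of whole-cell elastic moduli for
#' one experimental condition as a mixture of normal components truncated
#' below at `truncation` kPa (moduli are positive). Most conditions are a
#' single component parameterized by the condition's reported mean and
#' SD; the progerin-overexpression condition is a two-component mixture
#' reflecting its two stiffness peaks.
#'
#' @param name Condition label.
#' @param components A data.frame with columns `weight`, `mean_kPa`,
#'   `sd_kPa`; weights must sum to 1.
#' @param truncation Lower truncation bound in kPa, > 0.
#' @param n_reported Sample size reported for this condition (informational).
#' @return An object of class `population_preset`.
#' @examples
#' population_preset("HEK293A",
#'   data.frame(weight = 1, mean_kPa = 2.85, sd_kPa = 1.15), n_reported = 57)
#' @export
population_preset <- function(name, components, truncation = 0.1,
                              n_reported = NA_integer_) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(is.data.frame(components),
            all(c("weight", "mean_kPa", "sd_kPa") %in% names(components)))
  if (abs(sum(components$weight) - 1) > 1e-8)
    stopf("component weights must sum to 1")
  if (any(components$sd_kPa < 0)) stopf("component sds must be >= 0")
  check_scalar(truncation, "truncation", positive = TRUE)
  structure(list(name = name, components = components,
                 truncation = truncation, n_reported = n_reported),
            class = "population_preset")
}

#' Registry of built-in condition presets
#'
#' Returns the built-in registry of stiffness presets, one per
#' experimental condition: a cell-line panel (HEK293A, C2C12, HeLa,
#' 10T1/2, UE7T-13), the Cytochalasin D and Trichostatin A dose series,
#' the trypsinized/non-trypsinized comparison, and the lamin
#' A/progerin overexpression panel. Single-component presets carry each
#' condition's mean +/- SD; the progerin-overexpression preset is a
#' two-component mixture with peaks in the 2-4 and 6-8 kPa bands, and
#' the lamin A preset is a right-skewed (close, merging) mixture.
#'
#' @param name Optional condition name; if given, that single preset is
#'   returned (unknown names are an error).
#' @return A named list of [population_preset()] objects, or one preset.
#' @examples
#' names(preset_registry())
#' preset_registry("HEK293A")
#' @export
preset_registry <- function(name = NULL) {
  comp1 <- function(m, s) data.frame(weight = 1, mean_kPa = m, sd_kPa = s)
  reg <- list(
    # cell-line panel
    population_preset("HEK293A",  comp1(2.85, 1.15), n_reported = 57L),
    population_preset("C2C12",    comp1(6.55, 2.46), n_reported = 23L),
    population_preset("HeLa",     comp1(5.08, 1.47), n_reported = 16L),
    population_preset("10T1/2",   comp1(6.36, 1.96), n_reported = 31L),
    population_preset("UE7T-13",  comp1(5.90, 1.60), n_reported = 31L),
    # Cytochalasin D dose series (actin depolymerization)
    population_preset("CD_untreated", comp1(3.05, 0.99), n_reported = 26L),
    population_preset("CD_1uM",       comp1(2.81, 1.16), n_reported = 17L),
    population_preset("CD_2uM",       comp1(2.39, 1.10), n_reported = 29L),
    # Trichostatin A dose series (chromatin relaxation)
    population_preset("TSA_control", comp1(2.70, 0.86), n_reported = 30L),
    population_preset("TSA_250nM",   comp1(2.64, 0.92), n_reported = 31L),
    population_preset("TSA_500nM",   comp1(2.42, 0.76), n_reported = 26L),
    # harvesting comparison
    population_preset("trypsinized",     comp1(2.84, 1.15), n_reported = 57L),
    population_preset("non_trypsinized", comp1(3.21, 1.09), n_reported = 36L),
    # lamin A / progerin overexpression panel
    population_preset("WT", comp1(3.0, 1.0)),
    population_preset("LaminA_OX", data.frame(
      weight = c(0.7, 0.3), mean_kPa = c(3.0, 4.4), sd_kPa = c(1.0, 1.3))),
    population_preset("Progerin_OX", data.frame(
      weight = c(0.55, 0.45), mean_kPa = c(3.0, 7.0), sd_kPa = c(0.7, 0.8)))
  )
  names(reg) <- vapply(reg, `[[`, character(1), "name")
  if (is.null(name)) return(reg)
  if (!name %in% names(reg))
    stopf("unknown preset '%s'; known: %s", name,
          paste(names(reg), collapse = ", "))
  reg[[name]]
}

# Mean of the preset mixture after truncation (used as the generator's
# ground-truth population mean in recovery checks).
preset_mean <- function(preset) {
  stopifnot(inherits(preset, "population_preset"))
  co <- preset$components
  a <- preset$truncation
  m <- vapply(seq_len(nrow(co)), function(i) {
    mu <- co$mean_kPa[i]; s <- co$sd_kPa[i]
    if (s == 0) return(max(mu, a))
    z <- (a - mu) / s
    mu + s * stats::dnorm(z) / (1 - stats::pnorm(z))  # truncated-normal mean
  }, numeric(1))
  sum(co$weight * m)
}

#' Draw whole-cell moduli from a preset
#'
#' Samples `n` elastic moduli from the preset's truncated normal mixture
#' (rejection sampling below the truncation bound). Deterministic under a
#' fixed seed.
#'
#' @param preset A [population_preset()] or a registry condition name.
#' @param n Number of cells, >= 1.
#' @param seed Integer seed.
#' @return Numeric vector of `n` moduli (kPa), all `> truncation`.
#' @export
sample_moduli <- function(preset, n, seed = 1) {
  if (is.character(preset)) preset <- preset_registry(preset)
  stopifnot(inherits(preset, "population_preset"))
  check_scalar(n, "n", integer = TRUE, lower = 1)
  co <- preset$components
  with_seed(seed, {
    comp <- sample.int(nrow(co), n, replace = TRUE, prob = co$weight)
    x <- stats::rnorm(n, co$mean_kPa[comp], co$sd_kPa[comp])
    bad <- which(x < preset$truncation)
    while (length(bad) > 0) {
      x[bad] <- stats::rnorm(length(bad), co$mean_kPa[comp[bad]],
                             co$sd_kPa[comp[bad]])
      bad <- bad[x[bad] < preset$truncation]
    }
    x
  })
}

#' Sample a virtual cell population from a preset
#'
#' Draws `n` whole-cell moduli with [sample_moduli()] and converts each
#' to a [virtual_cell_params()] with matched effective modulus: both
#' compartments are set to the drawn modulus with zero power-law
#' exponent, so the cell's quasi-static stiffness equals the draw
#' exactly and population recovery is attributable to the measurement
#' pipeline, not to compartment bookkeeping.
#'
#' @inheritParams sample_moduli
#' @param L0 Initial cell diameter (um) given to every cell.
#' @return A list of [virtual_cell_params()]; the drawn moduli are
#'   attached as attribute `"moduli"` and the condition as `"condition"`.
#' @examples
#' cells <- sample_population("HEK293A", n = 5, seed = 1)
#' attr(cells, "moduli")
#' @export
sample_population <- function(preset, n, seed = 1, L0 = 15) {
  if (is.character(preset)) preset <- preset_registry(preset)
  moduli <- sample_moduli(preset, n, seed)
  cells <- lapply(moduli, function(E) {
    virtual_cell_params(L0 = L0, E0_cyto = E, E0_nuc = E,
                        beta_cyto = 0, beta_nuc = 0)
  })
  structure(cells, moduli = moduli, condition = preset$name)
}
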