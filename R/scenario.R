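# Bundled case study: a material changeover between two grades of anhydrous
# dicalcium phosphate (DCPA), DI-CAFOS A150 (coarse, x50 = 167 um) and
# DI-CAFOS A60 (fine, x50 = 64 um), on a four-station pilot-scale rotary
# press.  The press starts on A150; after 1 min the hopper feed switches to
# A60 for 12 min, then back to A150.

#' Case-study material definitions
#'
#' The two DCPA grades with their measured densities and fitted Kawakita
#' coefficients.  The elastic-recovery triplets are synthetic: the in-die
#' densities at the 30/400 MPa calibration stresses come from the fitted
#' Kawakita curves, and the recovery magnitudes (instantaneous
#' 1e-4 g/cm^3 per MPa, slow 0.005 g/cm^3, identical for both grades) are
#' representative of a brittle, low-recovery filler; they are configurable
#' through [material_spec()].
#'
#' @param recovery_k instantaneous recovery slope, g/cm^3 per MPa.
#' @param recovery_slow slow recovery, g/cm^3.
#' @return named list of two [material_spec()] objects (`A150`, `A60`).
#' @examples
#' case_study_materials()$A150
#' @export
case_study_materials <- function(recovery_k = 1e-4, recovery_slow = 0.005) {
  strength <- case_study_strength()
  synth_recovery <- function(kw) {
    P <- c(30, 400)
    rmax <- vapply(P, function(p)
      kw$rho0 * (1 + kw$b * p) / (1 + (1 - kw$a) * kw$b * p), numeric(1))
    r0 <- rmax - recovery_k * P
    recovery_calibration(P[1], P[2], rmax, r0, r0 - recovery_slow)
  }
  kw150 <- kawakita_coefficients(1.22954, 0.4981, 0.0072, solid_density = 2.842)
  kw60 <- suppressWarnings(  # asymptote of the fine grade sits above the
    # solid density; the fit range ends at 350 MPa and the press never
    # reaches the asymptote, but the constructor flags the extrapolation
    kawakita_coefficients(1.62302, 0.4891, 0.0041, solid_density = 2.849))
  list(
    A150 = material_spec(
      name = "A150", solid_density = 2.842, bulk_density = 0.68,
      tapped_density = 0.75, consolidated_bulk_density = 0.73,
      kawakita = kw150, recovery = synth_recovery(kw150),
      sigma0_pure = sigma0_of_x(1, strength), kb_pure = kb_of_x(1, strength)),
    A60 = material_spec(
      name = "A60", solid_density = 2.849, bulk_density = 1.33,
      tapped_density = 1.51, consolidated_bulk_density = 1.41,
      kawakita = kw60, recovery = synth_recovery(kw60),
      sigma0_pure = sigma0_of_x(0, strength), kb_pure = kb_of_x(0, strength))
  )
}

#' Case-study strength mixing coefficients
#'
#' Ryshkewitch-Duckworth mixing-rule coefficients for the DCPA A150/A60
#' system, expressed in the A150 mass fraction.
#'
#' @return a [strength_mix_coefficients()].
#' @export
case_study_strength <- function() {
  strength_mix_coefficients(c1 = 19.99, c2 = 5.56, c3 = 28.32,
                            m = 3.80, n = 15.09)
}

#' Build the material-changeover case study
#'
#' Assembles the full scenario: the two DCPA grades, the press configuration
#' (11.28 mm punches, 7 mm dosing, 3.2 mm minimal punch distance, 20 rpm
#' turret, 60 rpm paddle, 33 mm midstream, 40/35/25 fill ratios), the hopper
#' schedule (A150 on [0,1) min, A60 on [1,13) min, A150 again from 13 min;
#' the two A150 intervals carry distinct lot labels for tracing), and the
#' tablet sampling times (every minute, except every two minutes between
#' minutes 8 and 18).
#'
#' The press deformation (affine punch-distance model) is calibrated from
#' two steady operating points — about 60 MPa for pure A150 and about
#' 200 MPa at 75 wt% A60 — via [calibrate_punch_affine()]; without it a pure
#' fine-grade fill would imply an in-die density above the solid density at
#' the set punch distance.
#'
#' @param sim_duration simulated minutes (default 25).
#' @param changeover_start feed switch to the fine grade, min (default 1).
#' @param changeover_end switch back to the coarse grade, min (default 13).
#' @param midstream_diameter midstream diameter, mm.
#' @param fill_ratios die-filling ratios.
#' @param pipe_height filling pipe height, mm.
#' @param calibrate_press calibrate the affine punch-distance model (default
#'   TRUE); if FALSE the press is perfectly stiff.
#' @return An object of class `press_scenario`: list with `materials`,
#'   `config`, `schedule`, `strength`, `strength_reference` and
#'   `sampling_times` (min).
#' @examples
#' scn <- build_case_study(sim_duration = 2)
#' scn$config
#' @export
build_case_study <- function(sim_duration = 25, changeover_start = 1,
                             changeover_end = 13, midstream_diameter = 33,
                             fill_ratios = c(0.40, 0.35, 0.25),
                             pipe_height = 200, calibrate_press = TRUE) {
  stopifnot(changeover_start > 0, changeover_end > changeover_start)
  materials <- case_study_materials()
  config <- press_config(midstream_diameter = midstream_diameter,
                         fill_ratios = fill_ratios,
                         pipe_height = pipe_height,
                         sim_duration = sim_duration)
  if (calibrate_press) {
    pts <- list(
      list(composition = blend_composition("A150", fraction = 1),
           stress_MPa = 60),
      list(composition = blend_composition(c("A60", "A150"),
                                           fraction = c(0.75, 0.25)),
           stress_MPa = 200))
    cal <- calibrate_punch_affine(pts, config, materials)
    config$punch_offset <- cal$punch_offset
    config$machine_compliance <- cal$machine_compliance
  }
  schedule <- hopper_schedule(
    start_min = c(0, changeover_start, changeover_end),
    material = c("A150", "A60", "A150"),
    lot = c("A150-lot-1", "A60-lot-1", "A150-lot-2"))
  times <- c(1:8, seq(10, 18, by = 2), 19:25)
  structure(list(
    materials = materials, config = config, schedule = schedule,
    strength = case_study_strength(), strength_reference = "A150",
    sampling_times = times[times <= sim_duration]
  ), class = "press_scenario")
}

#' @export
print.press_scenario <- function(x, ...) {
  cat("Press scenario:", paste(names(x$materials), collapse = ", "),
      "| schedule:\n")
  print.data.frame(x$schedule)
  invisible(x)
}

#' Run a scenario
#'
#' Convenience wrapper around [run_simulation()].
#'
#' @param scenario a [build_case_study()]-style scenario.
#' @return a `press_run`.
#' @export
run_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "press_scenario"))
  run_simulation(scenario$config, scenario$materials, scenario$schedule,
                 scenario$strength, scenario$strength_reference)
}

#' Generate a synthetic compressibility dataset
#'
#' Densities from the Kawakita model at the given stresses, optionally with
#' multiplicative Gaussian noise, emulating a compaction-simulator
#' compressibility measurement.
#'
#' @param coeffs a [kawakita_coefficients()] object.
#' @param stresses stress grid, MPa (default the six standard levels
#'   30/50/100/200/300/400).
#' @param noise_sd multiplicative noise standard deviation (e.g. 0.01 = 1%).
#' @param seed RNG seed (required when `noise_sd > 0` for reproducibility).
#' @param material material label attached to the dataset.
#' @return data.frame with columns `stress_MPa`, `density_g_cm3` and
#'   attribute `material`.
#' @export
generate_compressibility_data <- function(coeffs,
                                          stresses = c(30, 50, 100, 200, 300, 400),
                                          noise_sd = 0, seed = NULL,
                                          material = "synthetic") {
  stopifnot(inherits(coeffs, "kawakita_coefficients"))
  rho <- coeffs$rho0 * (1 + coeffs$b * stresses) /
    (1 + (1 - coeffs$a) * coeffs$b * stresses)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    rho <- rho * (1 + stats::rnorm(length(rho), 0, noise_sd))
  }
  out <- data.frame(stress_MPa = stresses, density_g_cm3 = rho)
  attr(out, "material") <- material
  out
}

#' Generate a synthetic compactability dataset
#'
#' Tensile strengths from the Ryshkewitch-Duckworth model with the
#' composition-dependent coefficients, optionally with multiplicative
#' lognormal noise, emulating diametral-compression strength measurements.
#'
#' @param strength a [strength_mix_coefficients()] object.
#' @param x mass fraction of the coarse component.
#' @param porosities porosity grid.
#' @param noise_sdlog lognormal noise sigma (e.g. 0.05 = ~5%).
#' @param seed RNG seed.
#' @return data.frame with columns `porosity`, `tensile_strength_MPa` and
#'   attribute `x`.
#' @export
generate_compactability_data <- function(strength, x,
                                         porosities = seq(0.15, 0.5, by = 0.05),
                                         noise_sdlog = 0, seed = NULL) {
  sigma <- tensile_strength(porosities, x, strength)
  if (noise_sdlog > 0) {
    if (!is.null(seed)) set.seed(seed)
    sigma <- sigma * exp(stats::rnorm(length(sigma), 0, noise_sdlog))
  }
  out <- data.frame(porosity = porosities, tensile_strength_MPa = sigma)
  attr(out, "x") <- x
  out
}

#' Generate a reference time series from a scenario run
#'
#' Runs the scenario and samples a tablet quantity at the scenario's sampling
#' times, optionally perturbed with multiplicative measurement noise — a
#' synthetic stand-in for an experimentally sampled series (tablet weights
#' show coefficients of variation below 1.5% on a well-running press).
#'
#' @param scenario a `press_scenario`.
#' @param column tablet record column (default `"mass"`).
#' @param noise_cv multiplicative noise coefficient of variation (default 0).
#' @param seed RNG seed.
#' @return data.frame with columns `time_min`, `value`.
#' @export
generate_reference_series <- function(scenario, column = "mass",
                                      noise_cv = 0, seed = NULL) {
  run <- run_scenario(scenario)
  ref <- sample_tablet_series(run, scenario$sampling_times, column)
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    ref$value <- ref$value * (1 + stats::rnorm(nrow(ref), 0, noise_cv))
  }
  ref
}
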