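#' Sensitivity sweep over the midstream diameter
#'
#' Reruns the scenario for each candidate midstream diameter and scores the
#' sampled tablet-weight series against a reference series with the mean
#' absolute relative error [error_metric_f()].  This mirrors the structural
#' calibration of the flow model: the diameter minimizing `f` best reproduces
#' the observed changeover dynamics.
#'
#' @param scenario a `press_scenario` (the changeover scenario to rerun).
#' @param diameters candidate midstream diameters, mm (all below the pipe
#'   inner diameter).
#' @param reference data.frame with columns `time_min`, `value` (e.g. from
#'   [generate_reference_series()]).
#' @param column tablet record column to score (default `"mass"`).
#' @return data.frame with columns `midstream_diameter` and `f`.
#' @export
sweep_midstream_diameter <- function(scenario,
                                     diameters = c(6, 12, 18, 24, 30, 33, 36, 42),
                                     reference, column = "mass") {
  stopifnot(inherits(scenario, "press_scenario"),
            all(c("time_min", "value") %in% names(reference)))
  if (any(diameters >= scenario$config$pipe_inner_diameter))
    stop("sweep_midstream_diameter: diameters must be below the pipe ",
         "inner diameter", call. = FALSE)
  f <- vapply(diameters, function(d) {
    scn <- scenario
    scn$config$midstream_diameter <- d
    run <- run_scenario(scn)
    sim <- sample_tablet_series(run, reference$time_min, column)
    error_metric_f(reference$value, sim$value)
  }, numeric(1))
  data.frame(midstream_diameter = diameters, f = f)
}

#' Standard die-filling ratio candidates
#'
#' The descending three-compartment filling patterns scanned when calibrating
#' the die-filling distribution (first-compartment share reduced in steps,
#' remainder distributed with declining ratio).
#'
#' @return list of length-3 numeric vectors, each summing to 1.
#' @export
default_fill_ratio_sets <- function() {
  list(c(1.00, 0.00, 0.00), c(0.90, 0.05, 0.05), c(0.80, 0.15, 0.05),
       c(0.70, 0.25, 0.05), c(0.60, 0.35, 0.05), c(0.50, 0.40, 0.10),
       c(0.40, 0.35, 0.25), c(0.34, 0.33, 0.33))
}

#' Sensitivity sweep over the die-filling ratios
#'
#' As [sweep_midstream_diameter()], varying the fractions of the dosing
#' volume donated by successive feed-frame compartments.
#'
#' @param scenario a `press_scenario`.
#' @param ratio_sets list of fill-ratio vectors, each summing to 1.
#' @param reference data.frame with columns `time_min`, `value`.
#' @param column tablet record column to score.
#' @return data.frame with columns `ratios` (label) and `f`.
#' @export
sweep_fill_ratios <- function(scenario, ratio_sets = default_fill_ratio_sets(),
                              reference, column = "mass") {
  stopifnot(inherits(scenario, "press_scenario"),
            all(c("time_min", "value") %in% names(reference)))
  bad <- vapply(ratio_sets, function(r) abs(sum(r) - 1) > 1e-9, logical(1))
  if (any(bad))
    stop("sweep_fill_ratios: every ratio set must sum to 1", call. = FALSE)
  f <- vapply(ratio_sets, function(r) {
    scn <- scenario
    scn$config$fill_ratios <- r
    run <- run_scenario(scn)
    sim <- sample_tablet_series(run, reference$time_min, column)
    error_metric_f(reference$value, sim$value)
  }, numeric(1))
  data.frame(
    ratios = vapply(ratio_sets, function(r)
      paste(format(100 * r, trim = TRUE, digits = 3), collapse = "/"),
      character(1)),
    f = f)
}
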