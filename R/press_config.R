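#' Rotary press configuration
#'
#' Geometry and kinematics of the rotary press plus the two calibrated
#' structural parameters of the flow model (midstream diameter of the filling
#' pipe, die-filling ratios).  Defaults correspond to a pilot-scale press with
#' four stations, a twelve-blade paddle wheel, 11.28 mm flat-faced punches,
#' 10 mm fill depth, 7 mm dosing depth and a 3.2 mm minimal punch distance,
#' running at 20 rpm turret and 60 rpm paddle speed.
#'
#' The punch distance during compression is modeled affine in the compression
#' force, `h = h_min + punch_offset + machine_compliance * F`, to account for
#' the elastic deformation of the press; both coefficients default to 0
#' (perfectly stiff press).
#'
#' @param die_diameter die diameter, mm.
#' @param fill_depth fill cam depth, mm (metadata; dosing governs the fill).
#' @param dosing_height dosing depth `h_dos`, mm.
#' @param min_punch_distance minimal punch distance `h_min`, mm.
#' @param n_stations number of punch stations.
#' @param turret_rpm turret speed, 1/min.
#' @param paddle_rpm paddle wheel speed, 1/min.
#' @param n_compartments number of feed-frame compartments (paddle
#'   interspaces).
#' @param fill_ratios fractions of the dosing volume donated by successive
#'   compartments crossing the die (must sum to 1).
#' @param pipe_inner_diameter filling pipe inner diameter, mm (must exceed
#'   `midstream_diameter`).
#' @param midstream_diameter diameter of the fast central stream, mm.
#' @param velocity_ratio midstream-to-outer-ring velocity ratio (>= 1).
#' @param pipe_height filling pipe height, mm.
#' @param compartment_capacity compartment volume, cm^3; defaults to three
#'   dosing volumes so that a worst-case drain is always covered at refill.
#' @param machine_compliance punch-distance compliance, mm/kN.
#' @param punch_offset constant punch-distance offset, mm.
#' @param sim_duration simulated time, min.
#' @param use_consolidated_density use the apparent consolidated bulk density
#'   after filling (default) rather than the cylinder bulk density for all
#'   fill computations.
#' @return An object of class `press_config`.
#' @examples
#' cfg <- press_config()
#' dosing_volume(cfg)
#' @export
press_config <- function(die_diameter = 11.28,
                         fill_depth = 10,
                         dosing_height = 7,
                         min_punch_distance = 3.2,
                         n_stations = 4,
                         turret_rpm = 20,
                         paddle_rpm = 60,
                         n_compartments = 12,
                         fill_ratios = c(0.40, 0.35, 0.25),
                         pipe_inner_diameter = 45,
                         midstream_diameter = 33,
                         velocity_ratio = 2,
                         pipe_height = 200,
                         compartment_capacity = NULL,
                         machine_compliance = 0,
                         punch_offset = 0,
                         sim_duration = 25,
                         use_consolidated_density = TRUE) {
  if (abs(sum(fill_ratios) - 1) > 1e-9)
    stop("press_config: fill_ratios must sum to 1", call. = FALSE)
  if (any(fill_ratios < 0))
    stop("press_config: fill_ratios must be >= 0", call. = FALSE)
  if (length(fill_ratios) > n_compartments)
    stop("press_config: more fill ratios than compartments", call. = FALSE)
  if (!(midstream_diameter < pipe_inner_diameter))
    stop("press_config: midstream_diameter must be below pipe_inner_diameter",
         call. = FALSE)
  if (velocity_ratio < 1)
    stop("press_config: velocity_ratio must be >= 1", call. = FALSE)
  if (machine_compliance < 0 || punch_offset < 0)
    stop("press_config: compliance and punch offset must be >= 0", call. = FALSE)
  cfg <- structure(list(
    die_diameter = die_diameter, fill_depth = fill_depth,
    dosing_height = dosing_height, min_punch_distance = min_punch_distance,
    n_stations = n_stations, turret_rpm = turret_rpm, paddle_rpm = paddle_rpm,
    n_compartments = n_compartments, fill_ratios = fill_ratios,
    pipe_inner_diameter = pipe_inner_diameter,
    midstream_diameter = midstream_diameter, velocity_ratio = velocity_ratio,
    pipe_height = pipe_height,
    compartment_capacity = compartment_capacity,
    machine_compliance = machine_compliance, punch_offset = punch_offset,
    sim_duration = sim_duration,
    use_consolidated_density = use_consolidated_density
  ), class = "press_config")
  if (is.null(cfg$compartment_capacity))
    cfg$compartment_capacity <- 3 * dosing_volume(cfg)
  if (cfg$compartment_capacity < dosing_volume(cfg) * max(fill_ratios))
    stop("press_config: compartment_capacity below worst-case single drain",
         call. = FALSE)
  cfg
}

#' @export
print.press_config <- function(x, ...) {
  cat(sprintf("Rotary press: D = %.2f mm, h_dos = %.1f mm, h_min = %.1f mm, %d stations\n",
              x$die_diameter, x$dosing_height, x$min_punch_distance, x$n_stations))
  cat(sprintf("  turret %.0f rpm, paddle %.0f rpm, %d compartments, fill ratios %s\n",
              x$turret_rpm, x$paddle_rpm, x$n_compartments,
              paste(format(x$fill_ratios), collapse = "/")))
  cat(sprintf("  pipe %.0f mm (midstream %.0f mm, velocity ratio %.1f), height %.0f mm\n",
              x$pipe_inner_diameter, x$midstream_diameter, x$velocity_ratio,
              x$pipe_height))
  cat(sprintf("  punch distance: h_min + %.4f mm + %.4f mm/kN * F\n",
              x$punch_offset, x$machine_compliance))
  invisible(x)
}

#' Dosing volume of the die
#'
#' \deqn{V_{dos} = \pi (D/2)^2 h_{dos}} in cm^3; the volume metered into the
#' die at each fill event, and the volume extracted from the filling pipe per
#' event in equilibrium.
#'
#' @param config a [press_config()].
#' @return dosing volume, cm^3.
#' @export
dosing_volume <- function(config) {
  stopifnot(inherits(config, "press_config"))
  if (!(config$dosing_height > 0 && config$die_diameter > 0))
    stop("dosing_volume: non-positive die geometry", call. = FALSE)
  pi * (config$die_diameter / 20)^2 * (config$dosing_height / 10)
}

#' Die-fill events per minute
#'
#' One die-fill (and one tablet) occurs every
#' `60 / (turret_rpm * n_stations)` seconds.
#'
#' @param config a [press_config()].
#' @return events per minute.
#' @export
fills_per_minute <- function(config) {
  stopifnot(inherits(config, "press_config"))
  config$turret_rpm * config$n_stations
}

#' Compartment positions advanced per die-fill event
#'
#' The paddle wheel sweeps `paddle_rpm * n_compartments` interspaces past a
#' fixed location per minute, while `turret_rpm * n_stations` die fills occur
#' per minute; the rotation per fill event is the (rounded) ratio, modulo the
#' number of compartments.
#'
#' @param config a [press_config()].
#' @return integer number of positions advanced per fill event.
#' @export
rotation_per_fill <- function(config) {
  stopifnot(inherits(config, "press_config"))
  k <- round(config$paddle_rpm * config$n_compartments /
               (config$turret_rpm * config$n_stations))
  ((k - 1) %% config$n_compartments) + 1
}

#' Hopper feed schedule
#'
#' A timeline of contiguous, non-overlapping intervals, each feeding one
#' `(material, lot)` into the top of the filling pipe.  Intervals run from
#' each `start_min` to the next one (the last interval is open-ended).
#'
#' @param start_min numeric vector of interval start times, min; must start
#'   at 0 and be strictly increasing.
#' @param material character vector of material names.
#' @param lot character vector of lot labels; defaults to `"lot-<i>"`.
#' @return An object of class `hopper_schedule`.
#' @examples
#' hopper_schedule(c(0, 1, 13), c("A150", "A60", "A150"))
#' @export
hopper_schedule <- function(start_min, material,
                            lot = paste0("lot-", seq_along(start_min))) {
  stopifnot(length(start_min) == length(material),
            length(start_min) == length(lot))
  if (length(start_min) == 0L)
    stop("hopper_schedule: empty schedule", call. = FALSE)
  if (start_min[1] != 0)
    stop("hopper_schedule: first interval must start at 0", call. = FALSE)
  if (is.unsorted(start_min, strictly = TRUE))
    stop("hopper_schedule: start times must be strictly increasing", call. = FALSE)
  structure(
    data.frame(start_min = start_min, material = as.character(material),
               lot = as.character(lot), stringsAsFactors = FALSE),
    class = c("hopper_schedule", "data.frame"))
}

#' Feed active at a given time
#'
#' @param schedule a [hopper_schedule()].
#' @param t_min time, min.
#' @return list with `material` and `lot` of the active interval.
#' @export
schedule_at <- function(schedule, t_min) {
  stopifnot(inherits(schedule, "hopper_schedule"))
  i <- findInterval(t_min, schedule$start_min)
  if (i < 1L) i <- 1L
  list(material = schedule$material[i], lot = schedule$lot[i])
}
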