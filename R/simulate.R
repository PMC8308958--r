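#' Run the rotary press simulation
#'
#' Executes the event loop of the press at one die-fill event per
#' `60 / (turret_rpm * n_stations)` seconds: fill the die from the feed-frame
#' compartments crossing it, rotate the paddle wheel, top up the compartments
#' that swept past the filling-pipe outlet (drawing hopper material through
#' the pipe's plug-flow streams), compress, and eject one tablet.  The run is
#' fully deterministic and a mass-conservation ledger is checked at every
#' event: initial pipe and feed-frame inventory plus cumulative hopper feed
#' must equal current pipe plus feed-frame inventory plus cumulative tablet
#' mass, to a relative tolerance of 1e-9.
#'
#' @param config a [press_config()].
#' @param materials named list of [material_spec()] objects.
#' @param schedule a [hopper_schedule()]; the first interval's material also
#'   pre-fills pipe and feed frame.
#' @param strength a [strength_mix_coefficients()] object.
#' @param strength_reference material name whose mass fraction enters the
#'   strength mixing rule.
#' @param ledger_tol relative mass-conservation tolerance checked per event.
#' @return An object of class `press_run`: list with `tablets` (data.frame,
#'   one row per tablet with CQAs and per-lot mass-fraction columns
#'   `frac_<material>.<lot>`), `ledger` (per-event relative conservation
#'   error), `config`, `schedule`, and the final `pipe` and `frame` states.
#' @examples
#' \donttest{
#' scn <- build_case_study(sim_duration = 2)
#' run <- run_simulation(scn$config, scn$materials, scn$schedule, scn$strength)
#' head(run$tablets)
#' }
#' @export
run_simulation <- function(config, materials, schedule, strength,
                           strength_reference = "A150", ledger_tol = 1e-9) {
  stopifnot(inherits(config, "press_config"),
            inherits(schedule, "hopper_schedule"),
            inherits(strength, "strength_mix_coefficients"))
  miss <- setdiff(unique(schedule$material), names(materials))
  if (length(miss))
    stop("run_simulation: schedule references unknown material(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  fpm <- fills_per_minute(config)
  n_ev <- floor(config$sim_duration * fpm)
  dt_s <- 60 / fpm
  if (n_ev < 1L)
    return(structure(list(
      tablets = data.frame(), ledger = numeric(0), config = config,
      schedule = schedule, pipe = NULL, frame = NULL), class = "press_run"))

  kw <- lapply(materials, `[[`, "kawakita")
  first <- schedule_at(schedule, 0)
  pipe <- build_pipe(config, first$material, materials,
                     initial_lot = first$lot)
  frame <- feed_frame(config, first$material, materials,
                      initial_lot = first$lot)
  keys <- unique(.key(schedule$material, schedule$lot))
  dens <- pipe$fill_density

  initial_mass <- pipe_contents(pipe)$mass + feed_frame_mass(frame)
  hopper_in <- 0
  tablets_out <- 0

  col <- function() numeric(n_ev)
  rec <- list(index = seq_len(n_ev), ejection_time = col(), mass = col(),
              fill_density = col(), in_die_density = col(),
              out_die_density = col(), compression_stress = col(),
              compression_force = col(), punch_distance_actual = col(),
              out_die_porosity = col(), tensile_strength = col())
  colmap <- make.names(paste0("frac_", gsub("\\|", ".", keys)), unique = TRUE)
  names(colmap) <- keys
  fracs <- matrix(0, n_ev, length(keys), dimnames = list(NULL, colmap))
  ledger <- col()

  for (ev in seq_len(n_ev)) {
    t_min <- ev * dt_s / 60

    fd <- fill_die(frame, config)
    frame <- fd$frame

    rot <- rotate_feed_frame(frame, config)
    frame <- rot$frame
    for (idx in rot$passed) {
      deficit <- frame$capacity - .mass_volume(frame$mass[[idx]], dens)
      if (deficit > 1e-12) {
        drawn <- .pipe_draw(pipe, schedule, t_min, deficit)
        pipe <- drawn$pipe
        hopper_in <- hopper_in + drawn$mass_in
        frame <- refill_compartment(frame, idx, drawn$mass)
      }
    }

    cmp <- compress(fd$tablet_mass, fd$composition, config, kw)
    tab <- eject(cmp, fd$tablet_mass, fd$fill_density, fd$composition,
                 materials, strength, strength_reference,
                 ejection_time = ev * dt_s, index = ev)

    rec$ejection_time[ev] <- tab$ejection_time
    rec$mass[ev] <- tab$mass
    rec$fill_density[ev] <- tab$fill_density
    rec$in_die_density[ev] <- tab$in_die_density
    rec$out_die_density[ev] <- tab$out_die_density
    rec$compression_stress[ev] <- tab$compression_stress
    rec$compression_force[ev] <- tab$compression_force
    rec$punch_distance_actual[ev] <- tab$punch_distance_actual
    rec$out_die_porosity[ev] <- tab$out_die_porosity
    rec$tensile_strength[ev] <- tab$tensile_strength
    fk <- fd$mass / sum(fd$mass)
    fracs[ev, colmap[names(fk)]] <- fk

    tablets_out <- tablets_out + fd$tablet_mass
    acc <- pipe_contents(pipe)$mass + feed_frame_mass(frame) + tablets_out
    rel <- abs(acc - (initial_mass + hopper_in)) / (initial_mass + hopper_in)
    ledger[ev] <- rel
    if (rel > ledger_tol)
      stop(sprintf(
        "mass conservation violated at event %d (t = %.3f min): relative error %.3e",
        ev, t_min, rel), call. = FALSE)
  }

  tablets <- cbind(as.data.frame(rec), as.data.frame(fracs))
  structure(list(tablets = tablets, ledger = ledger, config = config,
                 schedule = schedule, pipe = pipe, frame = frame),
            class = "press_run")
}

#' @export
print.press_run <- function(x, ...) {
  n <- nrow(x$tablets)
  cat(sprintf("Press run: %d tablets over %.2f min\n", n,
              if (n) max(x$tablets$ejection_time) / 60 else 0))
  if (n) {
    cat(sprintf("  mass %.4f-%.4f g, stress %.1f-%.1f MPa, max ledger error %.2e\n",
                min(x$tablets$mass), max(x$tablets$mass),
                min(x$tablets$compression_stress),
                max(x$tablets$compression_stress), max(x$ledger)))
  }
  invisible(x)
}

#' Sample a tablet series at given times
#'
#' Picks, for each requested time, the tablet whose ejection time is nearest
#' (ties resolved toward the earlier tablet).  This emulates taking tablets
#' off the press at scheduled sampling times.
#'
#' @param run a [run_simulation()] result.
#' @param times_min sampling times, min.
#' @param column tablet record column to extract (default `"mass"`).
#' @return data.frame with `time_min` and `value`.
#' @export
sample_tablet_series <- function(run, times_min, column = "mass") {
  stopifnot(inherits(run, "press_run"))
  if (!column %in% names(run$tablets))
    stop("sample_tablet_series: no column '", column, "'", call. = FALSE)
  et <- run$tablets$ejection_time / 60
  idx <- vapply(times_min, function(t) which.min(abs(et - t)), integer(1))
  data.frame(time_min = times_min, value = run$tablets[[column]][idx])
}
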