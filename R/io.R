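# Configuration and tabular I/O.  Scenarios round-trip through a single YAML
# file with sections press / materials / schedule / strength; tablet records
# and calibration datasets use plain comma-separated CSV with a header row,
# '.' decimal and UTF-8.

#' Write a scenario to a YAML configuration file
#'
#' @param scenario a `press_scenario`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "press_scenario"))
  mat_list <- lapply(scenario$materials, function(m) {
    list(solid_density = m$solid_density, bulk_density = m$bulk_density,
         tapped_density = m$tapped_density,
         consolidated_bulk_density = m$consolidated_bulk_density,
         kawakita = list(rho0 = m$kawakita$rho0, a = m$kawakita$a,
                         b = m$kawakita$b),
         recovery = list(P_low = m$recovery$P_low, P_high = m$recovery$P_high,
                         rho_P_max = as.numeric(m$recovery$rho_P_max),
                         rho_P_0 = as.numeric(m$recovery$rho_P_0),
                         rho_out_die = as.numeric(m$recovery$rho_out_die),
                         correction_offset = m$recovery$correction_offset),
         sigma0_pure = m$sigma0_pure, kb_pure = m$kb_pure)
  })
  press <- unclass(scenario$config)
  obj <- list(
    press = press,
    materials = mat_list,
    schedule = lapply(seq_len(nrow(scenario$schedule)), function(i)
      as.list(scenario$schedule[i, ])),
    strength = c(scenario$strength[c("c1", "c2", "c3", "m", "n")],
                 list(reference = scenario$strength_reference)),
    sampling_times = as.numeric(scenario$sampling_times))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a scenario from a YAML configuration file
#'
#' @param path configuration file written by [write_scenario()] (or edited by
#'   hand with the same sections).
#' @return a `press_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path))
    stop("read_scenario: no such file: ", path, call. = FALSE)
  obj <- yaml::read_yaml(path)
  for (section in c("press", "materials", "schedule", "strength"))
    if (is.null(obj[[section]]))
      stop("read_scenario: missing section '", section, "' in ", path,
           call. = FALSE)
  press_args <- obj$press
  press_args$fill_ratios <- as.numeric(unlist(press_args$fill_ratios))
  config <- do.call(press_config, press_args)
  materials <- lapply(names(obj$materials), function(nm) {
    m <- obj$materials[[nm]]
    need <- c("solid_density", "bulk_density", "tapped_density",
              "consolidated_bulk_density", "kawakita", "recovery",
              "sigma0_pure", "kb_pure")
    miss <- setdiff(need, names(m))
    if (length(miss))
      stop("read_scenario: material '", nm, "' misses field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    material_spec(
      name = nm, solid_density = m$solid_density,
      bulk_density = m$bulk_density, tapped_density = m$tapped_density,
      consolidated_bulk_density = m$consolidated_bulk_density,
      kawakita = suppressWarnings(kawakita_coefficients(
        m$kawakita$rho0, m$kawakita$a, m$kawakita$b,
        solid_density = m$solid_density)),
      recovery = recovery_calibration(
        m$recovery$P_low, m$recovery$P_high,
        as.numeric(m$recovery$rho_P_max), as.numeric(m$recovery$rho_P_0),
        as.numeric(m$recovery$rho_out_die),
        correction_offset = m$recovery$correction_offset %||% 0),
      sigma0_pure = m$sigma0_pure, kb_pure = m$kb_pure)
  })
  names(materials) <- names(obj$materials)
  sched <- do.call(rbind, lapply(obj$schedule, as.data.frame))
  structure(list(
    materials = materials, config = config,
    schedule = hopper_schedule(sched$start_min, sched$material, sched$lot),
    strength = strength_mix_coefficients(
      obj$strength$c1, obj$strength$c2, obj$strength$c3,
      obj$strength$m, obj$strength$n),
    strength_reference = obj$strength$reference %||% "A150",
    sampling_times = as.numeric(obj$sampling_times)
  ), class = "press_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write tablet records to CSV
#'
#' @param run a `press_run`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tablets_csv <- function(run, path) {
  stopifnot(inherits(run, "press_run"))
  utils::write.csv(run$tablets, path, row.names = FALSE)
  invisible(path)
}

# run manifest: one per simulation/calibration run, making runs auditable
.write_manifest <- function(path, inputs, outputs, seed = NA,
                            started, finished) {
  manifest <- list(
    tool = "rotapress",
    version = as.character(utils::packageVersion("rotapress")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = lapply(inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    outputs = lapply(outputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Simulate from a configuration file
#'
#' Reads a scenario configuration, runs the simulation, and writes the tablet
#' CSV, a per-minute run log and a run manifest into the output directory.
#' Reruns with identical inputs reproduce byte-identical tablet CSVs.
#'
#' @param config_path scenario YAML path.
#' @param out_dir output directory (created if missing).
#' @param log_level `"summary"` (per-minute lines) or `"debug"` (per-event
#'   lines).
#' @return the `press_run`, invisibly.
#' @export
cmd_simulate <- function(config_path, out_dir, log_level = c("summary", "debug")) {
  log_level <- match.arg(log_level)
  started <- Sys.time()
  scenario <- read_scenario(config_path)
  run <- run_scenario(scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "tablets.csv")
  write_tablets_csv(run, csv)
  logf <- file.path(out_dir, "run.log")
  tb <- run$tablets
  if (log_level == "debug") {
    lines <- sprintf(
      "event %d t=%.2fs mass=%.5fg stress=%.2fMPa porosity=%.4f strength=%.4fMPa",
      tb$index, tb$ejection_time, tb$mass, tb$compression_stress,
      tb$out_die_porosity, tb$tensile_strength)
  } else {
    minute <- ceiling(tb$ejection_time / 60)
    lines <- vapply(sort(unique(minute)), function(m) {
      i <- minute == m
      sprintf("minute %d: %d tablets, mean mass %.5f g, mean stress %.2f MPa",
              m, sum(i), mean(tb$mass[i]), mean(tb$compression_stress[i]))
    }, character(1))
  }
  writeLines(lines, logf)
  .write_manifest(file.path(out_dir, "manifest.json"),
                  inputs = config_path, outputs = c(csv, logf),
                  started = started, finished = Sys.time())
  invisible(run)
}

#' Calibrate a sub-model from a CSV dataset
#'
#' @param data_path CSV path.  Expected columns: `stress_MPa`,
#'   `density_g_cm3` for `model = "kawakita"`; `porosity`,
#'   `tensile_strength_MPa` for `"rd"`; `stress_MPa`, `rho_P_max`,
#'   `rho_P_0`, `rho_out_die` for `"recovery"`.
#' @param model which sub-model to fit.
#' @param out_path YAML file to write the fitted coefficients to.
#' @return the fit result, invisibly.
#' @export
cmd_calibrate <- function(data_path, model = c("kawakita", "rd", "recovery"),
                          out_path) {
  model <- match.arg(model)
  started <- Sys.time()
  if (!file.exists(data_path))
    stop("cmd_calibrate: no such file: ", data_path, call. = FALSE)
  data <- utils::read.csv(data_path)
  if (nrow(data) == 0L)
    stop("cmd_calibrate: empty dataset: ", data_path, call. = FALSE)
  fit <- switch(model,
    kawakita = {
      f <- fit_kawakita(data)
      list(model = "kawakita", rho0 = f$coefficients$rho0,
           a = f$coefficients$a, b = f$coefficients$b,
           r_squared = f$r_squared, n = f$n)
    },
    rd = {
      f <- fit_rd(data)
      list(model = "ryshkewitch_duckworth", sigma0 = f$sigma0, kb = f$kb,
           r_squared = f$r_squared, n = f$n)
    },
    recovery = {
      rc <- fit_recovery(data)
      list(model = "elastic_recovery", P_low = rc$P_low, P_high = rc$P_high,
           rho_P_max = as.numeric(rc$rho_P_max),
           rho_P_0 = as.numeric(rc$rho_P_0),
           rho_out_die = as.numeric(rc$rho_out_die),
           k_instant = rc$k_instant, l_instant = rc$l_instant,
           delta_rho_slow_avg = rc$delta_rho_slow_avg,
           correction_offset = rc$correction_offset)
    })
  yaml::write_yaml(fit, out_path, precision = 15)
  .write_manifest(paste0(out_path, ".manifest.json"),
                  inputs = data_path, outputs = out_path,
                  started = started, finished = Sys.time())
  invisible(fit)
}

#' Run a structural-parameter sweep from files
#'
#' @param config_path scenario YAML path.
#' @param sweep_path sweep specification YAML: either
#'   `parameter: midstream_diameter` with a `values:` list (mm), or
#'   `parameter: fill_ratios` with a list of ratio vectors under `values:`.
#' @param reference_path reference series CSV (`time_min`, `value`).
#' @param out_path output CSV for the sweep results.
#' @return the sweep result data.frame, invisibly.
#' @export
cmd_sweep <- function(config_path, sweep_path, reference_path, out_path) {
  started <- Sys.time()
  scenario <- read_scenario(config_path)
  spec <- yaml::read_yaml(sweep_path)
  reference <- utils::read.csv(reference_path)
  res <- switch(as.character(spec$parameter),
    midstream_diameter = sweep_midstream_diameter(
      scenario, diameters = as.numeric(unlist(spec$values)),
      reference = reference),
    fill_ratios = sweep_fill_ratios(
      scenario, ratio_sets = lapply(spec$values, as.numeric),
      reference = reference),
    stop("cmd_sweep: unknown sweep parameter '", spec$parameter, "'",
         call. = FALSE))
  utils::write.csv(res, out_path, row.names = FALSE)
  .write_manifest(paste0(out_path, ".manifest.json"),
                  inputs = c(config_path, sweep_path, reference_path),
                  outputs = out_path, started = started, finished = Sys.time())
  invisible(res)
}

#' Regenerate the bundled fixtures
#'
#' Writes the case-study scenario YAML, noiseless and noisy synthetic
#' compressibility/compactability CSVs and a reference tablet-weight series
#' into a directory, with one manifest.
#'
#' @param out_dir output directory.
#' @param seed RNG seed for the noisy fixtures.
#' @return character vector of written paths, invisibly.
#' @export
cmd_make_fixtures <- function(out_dir, seed = 1L) {
  started <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  scn <- build_case_study()
  p <- file.path(out_dir, "case_study.yaml")
  write_scenario(scn, p); paths <- c(paths, p)
  for (nm in names(scn$materials)) {
    d <- generate_compressibility_data(scn$materials[[nm]]$kawakita,
                                       noise_sd = 0.01, seed = seed,
                                       material = nm)
    p <- file.path(out_dir, paste0("compressibility_", nm, ".csv"))
    utils::write.csv(d, p, row.names = FALSE); paths <- c(paths, p)
  }
  for (x in c(0, 0.5, 1)) {
    d <- generate_compactability_data(scn$strength, x, noise_sdlog = 0.05,
                                      seed = seed + round(100 * x))
    p <- file.path(out_dir, sprintf("compactability_x%03.0f.csv", 100 * x))
    utils::write.csv(d, p, row.names = FALSE); paths <- c(paths, p)
  }
  ref <- generate_reference_series(scn, noise_cv = 0.015, seed = seed)
  p <- file.path(out_dir, "reference_weight.csv")
  utils::write.csv(ref, p, row.names = FALSE); paths <- c(paths, p)
  .write_manifest(file.path(out_dir, "manifest.json"), inputs = character(0),
                  outputs = paths, seed = seed,
                  started = started, finished = Sys.time())
  invisible(paths)
}
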