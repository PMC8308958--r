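# Shared oracles and fixtures, built in code.

# independent bisection inversion of the forward Kawakita mixture model
bisect_invert <- function(target, composition, coeffs, lo = 0, hi = 1e4,
                          iter = 80L) {
  f <- function(p) kawakita_mixture_density(p, composition, coeffs,
                                            low_pressure_warning = FALSE)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# blend of the two case-study grades at a given A60 mass fraction
a60_blend <- function(x_a60) {
  if (x_a60 <= 0) return(blend_composition("A150", fraction = 1))
  if (x_a60 >= 1) return(blend_composition("A60", fraction = 1))
  blend_composition(c("A60", "A150"), fraction = c(x_a60, 1 - x_a60))
}

# reduced changeover scenario for fast dynamic tests: short pipe, short run
small_scenario <- function(sim_duration = 6, changeover_start = 0.5,
                           changeover_end = 3, pipe_height = 50) {
  scn <- build_case_study(sim_duration = sim_duration,
                          changeover_start = changeover_start,
                          changeover_end = changeover_end,
                          pipe_height = pipe_height)
  scn$sampling_times <- seq(0.5, sim_duration, by = 0.5)
  scn
}

# the full 25-minute case-study run, computed once and cached for the suite
.case_run_cache <- new.env(parent = emptyenv())
case_study_run <- function() {
  if (is.null(.case_run_cache$run)) {
    .case_run_cache$scenario <- build_case_study()
    .case_run_cache$elapsed <- system.time(
      .case_run_cache$run <- run_scenario(.case_run_cache$scenario))[["elapsed"]]
  }
  list(run = .case_run_cache$run, scenario = .case_run_cache$scenario,
       elapsed = .case_run_cache$elapsed)
}
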