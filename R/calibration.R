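#' Fit the Kawakita model to a compressibility dataset
#'
#' Nonlinear least squares on the pure-substance density form
#' \deqn{\rho(P) = \rho_0 \frac{1 + bP}{1 + (1-a)bP}} over the stated stress
#' range (default 20-350 MPa, since the model is not suited to very low
#' pressures).  Start values are taken from the data: `rho0` from the density
#' at the lowest stress, `a` from a 5%-inflated asymptote guess, `b` =
#' 0.01/MPa.
#'
#' @param data data.frame with columns `stress_MPa` (strictly increasing) and
#'   `density_g_cm3` (positive).
#' @param stress_range length-2 numeric, MPa; rows outside are dropped.
#' @return list with `coefficients` (a [kawakita_coefficients()]), `r_squared`
#'   (on density) and `n` (rows used).
#' @examples
#' kw <- kawakita_coefficients(1.22954, 0.4981, 0.0072)
#' d <- generate_compressibility_data(kw, noise_sd = 0)
#' fit_kawakita(d)$coefficients
#' @export
fit_kawakita <- function(data, stress_range = c(20, 350)) {
  stopifnot(is.data.frame(data),
            all(c("stress_MPa", "density_g_cm3") %in% names(data)))
  d <- data[data$stress_MPa >= stress_range[1] &
              data$stress_MPa <= stress_range[2], , drop = FALSE]
  d <- d[order(d$stress_MPa), , drop = FALSE]
  if (nrow(d) < 4L)
    stop("fit_kawakita: need at least 4 points inside the stress range",
         call. = FALSE)
  if (any(diff(unique(d$stress_MPa)) <= 0) || any(d$density_g_cm3 <= 0))
    stop("fit_kawakita: stresses must be increasing and densities positive",
         call. = FALSE)
  rho0_0 <- d$density_g_cm3[1]
  a_0 <- max(min(1 - rho0_0 / (1.05 * max(d$density_g_cm3)), 0.95), 0.05)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      density_g_cm3 ~ rho0 * (1 + b * stress_MPa) /
        (1 + (1 - a) * b * stress_MPa),
      data = d, start = list(rho0 = rho0_0, a = a_0, b = 0.01),
      lower = c(1e-6, 1e-6, 1e-8), upper = c(Inf, 1 - 1e-9, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) stop(sprintf(
      "fit_kawakita did not converge (start rho0=%.4f, a=%.3f, b=0.01): %s",
      rho0_0, a_0, conditionMessage(e)), call. = FALSE))
  cf <- stats::coef(fit)
  pred <- stats::predict(fit)
  r2 <- 1 - sum((d$density_g_cm3 - pred)^2) /
    sum((d$density_g_cm3 - mean(d$density_g_cm3))^2)
  list(coefficients = kawakita_coefficients(cf[["rho0"]], cf[["a"]], cf[["b"]]),
       r_squared = r2, n = nrow(d))
}

#' Fit the two-point elastic recovery calibration
#'
#' Aggregates replicate tablets per calibration stress (means of the three
#' state densities) and draws the exact instantaneous-recovery line through
#' the two stresses; the slow recovery is averaged and the correction offset
#' is the mean measured-minus-predicted out-die residual.
#'
#' @param data data.frame with columns `stress_MPa`, `rho_P_max`, `rho_P_0`,
#'   `rho_out_die` (one row per calibration tablet); exactly two distinct
#'   stress levels are required.
#' @return a [recovery_calibration()].
#' @export
fit_recovery <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("stress_MPa", "rho_P_max", "rho_P_0", "rho_out_die") %in%
                  names(data)))
  lev <- sort(unique(data$stress_MPa))
  if (length(lev) != 2L)
    stop("fit_recovery: need exactly two distinct calibration stresses, got ",
         length(lev), call. = FALSE)
  agg <- function(col) vapply(lev, function(p)
    mean(data[[col]][data$stress_MPa == p]), numeric(1))
  rmax <- agg("rho_P_max"); r0 <- agg("rho_P_0"); rout <- agg("rho_out_die")
  rc <- recovery_calibration(lev[1], lev[2], rmax, r0, rout)
  predicted <- rmax - (rc$k_instant * lev + rc$l_instant) - rc$delta_rho_slow_avg
  rc$correction_offset <- mean(rout - predicted)
  rc
}

#' Fit the Ryshkewitch-Duckworth compactability model
#'
#' Linear least squares of `ln sigma` on porosity: `kb` is minus the slope,
#' `sigma0` the exponential of the intercept.
#'
#' @param data data.frame with columns `porosity` (in (0,1)) and
#'   `tensile_strength_MPa` (positive).
#' @return list with `sigma0` (MPa), `kb`, `r_squared` (on `ln sigma`) and `n`.
#' @export
fit_rd <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("porosity", "tensile_strength_MPa") %in% names(data)))
  if (nrow(data) < 3L)
    stop("fit_rd: need at least 3 points", call. = FALSE)
  if (any(data$tensile_strength_MPa <= 0))
    stop("fit_rd: tensile strengths must be positive", call. = FALSE)
  if (any(data$porosity <= 0 | data$porosity >= 1))
    stop("fit_rd: porosities must lie in (0, 1)", call. = FALSE)
  if (stats::sd(data$porosity) < 1e-12)
    stop("fit_rd: ill-conditioned, porosities are (nearly) identical",
         call. = FALSE)
  fit <- stats::lm(log(tensile_strength_MPa) ~ porosity, data = data)
  cf <- stats::coef(fit)
  ls <- log(data$tensile_strength_MPa)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ls - mean(ls))^2)
  list(sigma0 = unname(exp(cf[1])), kb = unname(-cf[2]), r_squared = r2,
       n = nrow(data))
}

#' Derive the strength mixing rule from three support compositions
#'
#' From fitted `(sigma0, kb)` pairs of the two pure substances and one blend,
#' solves the three-point exponential system
#' \eqn{\sigma_0(x) = c_1 e^{x c_2} + c_3} exactly (one-dimensional root
#' search in `c2` followed by a linear solve) and fits the `kb` line by least
#' squares.  The `sigma0` support must be strictly monotone in `x`, else the
#' exponential form cannot interpolate it.
#'
#' @param support data.frame with columns `x` (mass fraction of the coarse
#'   component; three distinct values, typically 0, 0.5, 1), `sigma0` (MPa)
#'   and `kb`.
#' @return a [strength_mix_coefficients()].
#' @examples
#' sup <- data.frame(x = c(0, 0.5, 1),
#'                   sigma0 = c(48.31, 350.545, 5222.19),
#'                   kb = c(15.09, 16.99, 18.89))
#' derive_strength_mixing(sup)
#' @export
derive_strength_mixing <- function(support) {
  stopifnot(is.data.frame(support),
            all(c("x", "sigma0", "kb") %in% names(support)))
  if (nrow(support) != 3L)
    stop("derive_strength_mixing: exactly three support compositions required",
         call. = FALSE)
  s <- support[order(support$x), ]
  if (any(diff(s$x) <= 0))
    stop("derive_strength_mixing: support compositions must be distinct",
         call. = FALSE)
  if (any(diff(s$sigma0) <= 0))
    stop("derive_strength_mixing: sigma0 support must be strictly increasing ",
         "in x; the exponential form cannot represent it", call. = FALSE)
  x1 <- s$x[1]; x2 <- s$x[2]; x3 <- s$x[3]
  g <- function(c2) {
    # c1 implied by the first two points; residual on the third
    c1 <- (s$sigma0[2] - s$sigma0[1]) / (exp(c2 * x2) - exp(c2 * x1))
    c1 * (exp(c2 * x3) - exp(c2 * x1)) - (s$sigma0[3] - s$sigma0[1])
  }
  c2 <- stats::uniroot(g, c(1e-8, 100), tol = 1e-12)$root
  c1 <- (s$sigma0[2] - s$sigma0[1]) / (exp(c2 * x2) - exp(c2 * x1))
  c3 <- s$sigma0[1] - c1 * exp(c2 * x1)
  kb_fit <- stats::lm(kb ~ x, data = s)
  strength_mix_coefficients(c1, c2, c3,
                            m = unname(stats::coef(kb_fit)[2]),
                            n = unname(stats::coef(kb_fit)[1]))
}

#' Mean absolute relative error between two matched series
#'
#' \deqn{f = \frac{1}{n} \sum_k \left| \frac{exp_k - sim_k}{sim_k} \right|}
#' with the simulated value in the denominator.  Invariant under a common
#' rescaling of both series; zero iff the series are identical.
#'
#' @param reference observed (experimental) values.
#' @param simulated simulated values at the matched time points (nonzero).
#' @return dimensionless error `f` (multiply by 100 for percent).
#' @examples
#' error_metric_f(c(1, 2), c(1, 2.5))  # 0.10
#' @export
error_metric_f <- function(reference, simulated) {
  if (length(reference) != length(simulated))
    stop("error_metric_f: series lengths differ", call. = FALSE)
  if (!length(reference))
    stop("error_metric_f: empty series", call. = FALSE)
  if (any(simulated == 0))
    stop("error_metric_f: simulated values must be nonzero", call. = FALSE)
  mean(abs((reference - simulated) / simulated))
}

#' Calibrate the affine punch-distance model from operating points
#'
#' The punch distance during compression is
#' `h = h_min + punch_offset + machine_compliance * F`.  Given one or two
#' observed steady operating points (blend composition and measured
#' compression stress), this solves for the affine coefficients: the
#' required punch distance at each point follows from the tablet mass (die
#' fill at the blend density) and the Kawakita density at the observed
#' stress.  With one point the offset is fixed at 0 and only the compliance
#' is fitted.
#'
#' @param points list of lists, each with `composition` (a
#'   [blend_composition()]) and `stress_MPa` (observed steady stress).
#' @param config a [press_config()].
#' @param materials named list of [material_spec()] objects.
#' @return list with `punch_offset` (mm) and `machine_compliance` (mm/kN).
#' @export
calibrate_punch_affine <- function(points, config, materials) {
  stopifnot(length(points) %in% 1:2, inherits(config, "press_config"))
  kw <- lapply(materials, `[[`, "kawakita")
  dens <- .fill_density_table(materials, config$use_consolidated_density)
  A_cm2 <- pi * (config$die_diameter / 20)^2
  h_F <- vapply(points, function(pt) {
    rho_fill <- mix_bulk_density(pt$composition, dens)
    m <- dosing_volume(config) * rho_fill
    rho_c <- kawakita_mixture_density(pt$stress_MPa, pt$composition, kw)
    h_mm <- 10 * m / (A_cm2 * rho_c)
    c(h = h_mm, F = 0.1 * A_cm2 * pt$stress_MPa)
  }, numeric(2))
  if (length(points) == 1L) {
    cc <- (h_F["h", 1] - config$min_punch_distance) / h_F["F", 1]
    off <- 0
  } else {
    cc <- (h_F["h", 2] - h_F["h", 1]) / (h_F["F", 2] - h_F["F", 1])
    off <- h_F["h", 1] - config$min_punch_distance - cc * h_F["F", 1]
  }
  if (cc < 0 || off < -1e-9)
    stop("calibrate_punch_affine: operating points imply negative press ",
         "deformation; check the stresses", call. = FALSE)
  list(punch_offset = max(unname(off), 0), machine_compliance = unname(cc))
}
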