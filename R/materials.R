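#' Kawakita compressibility coefficients
#'
#' Coefficients of the volume-additive Kawakita density model
#' \deqn{1/\rho(P) = (1/\rho_0)\,\frac{1 + (1-a)\,b\,P}{1 + b\,P}}
#' where `rho0` is the density at the low-pressure end of the fitted range
#' (20 MPa for the bundled materials), `a` is the dimensionless compressibility
#' parameter and `b` carries units of 1/MPa.  The asymptotic density for
#' \eqn{P \to \infty} is `rho0 / (1 - a)`.
#'
#' @param rho0 density at low pressure, g/cm^3 (> 0).
#' @param a dimensionless Kawakita parameter, in (0, 1).
#' @param b stress scale parameter, 1/MPa (> 0).
#' @param solid_density optional solid (pycnometric) density, g/cm^3.  When
#'   given, the asymptote is checked against it and a warning is issued if the
#'   asymptote exceeds it (the model is then extrapolating into unphysical
#'   densities at very high stress).
#' @return An object of class `kawakita_coefficients`.
#' @examples
#' kw <- kawakita_coefficients(1.22954, 0.4981, 0.0072)
#' kawakita_asymptote(kw)
#' @export
kawakita_coefficients <- function(rho0, a, b, solid_density = NULL) {
  stopifnot(is.numeric(rho0), is.numeric(a), is.numeric(b),
            length(rho0) == 1L, length(a) == 1L, length(b) == 1L)
  if (!(rho0 > 0)) stop("kawakita: rho0 must be > 0", call. = FALSE)
  if (!(a > 0 && a < 1)) stop("kawakita: a must lie in (0, 1)", call. = FALSE)
  if (!(b > 0)) stop("kawakita: b must be > 0", call. = FALSE)
  obj <- structure(list(rho0 = rho0, a = a, b = b),
                   class = "kawakita_coefficients")
  if (!is.null(solid_density)) {
    if (rho0 >= solid_density)
      stop("kawakita: rho0 must be below the solid density", call. = FALSE)
    if (kawakita_asymptote(obj) > solid_density)
      warning(sprintf(
        "kawakita asymptote %.4f g/cm^3 exceeds solid density %.4f g/cm^3; ",
        kawakita_asymptote(obj), solid_density),
        "the model extrapolates beyond the physical density at high stress",
        call. = FALSE)
  }
  obj
}

#' @rdname kawakita_coefficients
#' @param x a `kawakita_coefficients` object.
#' @export
kawakita_asymptote <- function(x) {
  stopifnot(inherits(x, "kawakita_coefficients"))
  x$rho0 / (1 - x$a)
}

#' @export
print.kawakita_coefficients <- function(x, ...) {
  cat(sprintf("Kawakita coefficients: rho0 = %.5f g/cm^3, a = %.4f, b = %.4f 1/MPa\n",
              x$rho0, x$a, x$b))
  cat(sprintf("  asymptotic density: %.5f g/cm^3\n", kawakita_asymptote(x)))
  invisible(x)
}

#' Two-point elastic recovery calibration
#'
#' Calibration of the out-die density model from tablets compressed at a low
#' and a high stress.  At each calibration stress the density at maximum
#' stress `rho_P_max`, at zero axial stress `rho_P_0`, and out of the die
#' `rho_out_die` must be supplied (units g/cm^3).  The instantaneous (in-die)
#' recovery \eqn{\Delta\rho_{in\mbox{-}die} = \rho_{P,max} - \rho_{P,0}} is
#' modeled linear in stress; the slow (post-ejection) recovery
#' \eqn{\Delta\rho_{slow} = \rho_{P,0} - \rho_{out\mbox{-}die}} is taken as the
#' arithmetic mean of its two calibration values.  Derived fields:
#' `k_instant` (g/cm^3 per MPa), `l_instant` (g/cm^3), `delta_rho_slow_avg`
#' (g/cm^3).
#'
#' @param P_low,P_high calibration stresses, MPa (`P_low < P_high`).
#' @param rho_P_max,rho_P_0,rho_out_die length-2 numeric vectors giving the
#'   density in the respective state at `c(P_low, P_high)`.
#' @param correction_offset scalar measured-minus-predicted out-die density
#'   correction, g/cm^3 (default 0).
#' @return An object of class `recovery_calibration`.
#' @examples
#' recovery_calibration(30, 400,
#'   rho_P_max   = c(1.45, 2.20),
#'   rho_P_0     = c(1.447, 2.16),
#'   rho_out_die = c(1.442, 2.155))
#' @export
recovery_calibration <- function(P_low, P_high, rho_P_max, rho_P_0,
                                 rho_out_die, correction_offset = 0) {
  stopifnot(length(rho_P_max) == 2L, length(rho_P_0) == 2L,
            length(rho_out_die) == 2L, length(correction_offset) == 1L)
  if (!(P_low > 0 && P_high > P_low))
    stop("recovery: need 0 < P_low < P_high", call. = FALSE)
  if (any(rho_P_max < rho_P_0 - 1e-12) || any(rho_P_0 < rho_out_die - 1e-12))
    stop("recovery: need rho_P_max >= rho_P_0 >= rho_out_die at each stress",
         call. = FALSE)
  d_in <- rho_P_max - rho_P_0
  d_slow <- rho_P_0 - rho_out_die
  k <- (d_in[2] - d_in[1]) / (P_high - P_low)
  l <- d_in[1] - k * P_low
  structure(list(
    P_low = P_low, P_high = P_high,
    rho_P_max = rho_P_max, rho_P_0 = rho_P_0, rho_out_die = rho_out_die,
    k_instant = k, l_instant = l,
    delta_rho_slow_avg = mean(d_slow),
    correction_offset = correction_offset
  ), class = "recovery_calibration")
}

#' @export
print.recovery_calibration <- function(x, ...) {
  cat(sprintf("Elastic recovery calibration at %.0f / %.0f MPa\n", x$P_low, x$P_high))
  cat(sprintf("  instantaneous: k = %.3e g/cm^3/MPa, l = %.3e g/cm^3\n",
              x$k_instant, x$l_instant))
  cat(sprintf("  slow (mean):   %.4f g/cm^3; correction offset %.4f g/cm^3\n",
              x$delta_rho_slow_avg, x$correction_offset))
  invisible(x)
}

#' Strength mixing-rule coefficients
#'
#' Coefficients of the composition dependence of the Ryshkewitch-Duckworth
#' parameters for a two-component blend, expressed in the mass fraction `x` of
#' the coarse component (here DCPA A150):
#' \deqn{\sigma_0(x) = c_1 e^{x c_2} + c_3, \qquad k_b(x) = m\,x + n.}
#'
#' @param c1,c3 MPa; `c2`, `m`, `n` dimensionless.
#' @return An object of class `strength_mix_coefficients`.
#' @examples
#' strength_mix_coefficients(19.99, 5.56, 28.32, 3.80, 15.09)
#' @export
strength_mix_coefficients <- function(c1, c2, c3, m, n) {
  obj <- structure(list(c1 = c1, c2 = c2, c3 = c3, m = m, n = n),
                   class = "strength_mix_coefficients")
  xg <- seq(0, 1, by = 0.05)
  if (any(c1 * exp(xg * c2) + c3 <= 0) || any(m * xg + n <= 0))
    stop("strength coefficients give non-positive sigma0 or kb on [0,1]",
         call. = FALSE)
  obj
}

#' @export
print.strength_mix_coefficients <- function(x, ...) {
  cat(sprintf("sigma0(x) = %.4g * exp(%.4g x) + %.4g MPa;  kb(x) = %.4g x + %.4g\n",
              x$c1, x$c2, x$c3, x$m, x$n))
  invisible(x)
}

#' Powder grade definition
#'
#' Complete description of one powder grade: densities, Kawakita
#' compressibility coefficients, elastic-recovery calibration and
#' pure-substance Ryshkewitch-Duckworth parameters.  Densities in g/cm^3.
#' `consolidated_bulk_density` is the apparent density of the powder bed after
#' die filling (forced feeding consolidates free-flowing powders above the
#' cylinder bulk density); it is the density used for all fill computations.
#'
#' @param name grade label.
#' @param solid_density pycnometric density (> all bulk densities).
#' @param bulk_density cylinder bulk density.
#' @param tapped_density tapped density (informational).
#' @param consolidated_bulk_density apparent density after die filling.
#' @param kawakita a [kawakita_coefficients()] object.
#' @param recovery a [recovery_calibration()] object.
#' @param sigma0_pure zero-porosity tensile strength of the pure substance, MPa.
#' @param kb_pure porosity sensitivity of the pure substance, dimensionless.
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(name, solid_density, bulk_density, tapped_density,
                          consolidated_bulk_density, kawakita, recovery,
                          sigma0_pure, kb_pure) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(kawakita, "kawakita_coefficients"),
            inherits(recovery, "recovery_calibration"))
  if (!(bulk_density > 0 && bulk_density <= consolidated_bulk_density &&
        consolidated_bulk_density < solid_density))
    stop("material '", name,
         "': need 0 < bulk <= consolidated bulk < solid density", call. = FALSE)
  if (!(bulk_density <= tapped_density && tapped_density < solid_density))
    stop("material '", name, "': need bulk <= tapped < solid density",
         call. = FALSE)
  if (kawakita$rho0 >= solid_density)
    stop("material '", name, "': Kawakita rho0 must be below solid density",
         call. = FALSE)
  if (!(sigma0_pure > 0 && kb_pure > 0))
    stop("material '", name, "': sigma0_pure and kb_pure must be > 0",
         call. = FALSE)
  structure(list(
    name = name, solid_density = solid_density, bulk_density = bulk_density,
    tapped_density = tapped_density,
    consolidated_bulk_density = consolidated_bulk_density,
    kawakita = kawakita, recovery = recovery,
    sigma0_pure = sigma0_pure, kb_pure = kb_pure
  ), class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("Material %s: solid %.3f, bulk %.3f, tapped %.3f, consolidated %.3f g/cm^3\n",
              x$name, x$solid_density, x$bulk_density, x$tapped_density,
              x$consolidated_bulk_density))
  print(x$kawakita)
  invisible(x)
}

#' Blend composition with lot provenance
#'
#' A blend is a set of `(material, lot, mass fraction)` entries.  Mass
#' fractions must be non-negative and sum to 1 (within 1e-12).  Lot labels are
#' preserved through every mixing operation, which is the basis of tracking
#' and tracing input material through to individual tablets.
#'
#' @param material character vector of material names.
#' @param lot character vector of lot labels (default one lot per material).
#' @param fraction numeric vector of mass fractions.
#' @return An object of class `blend_composition` (a data.frame with columns
#'   `material`, `lot`, `fraction`).
#' @examples
#' blend_composition(c("A150", "A60"), fraction = c(0.5, 0.5))
#' @export
blend_composition <- function(material, lot = rep("lot-1", length(material)),
                              fraction) {
  stopifnot(length(material) == length(lot),
            length(material) == length(fraction))
  if (any(fraction < 0))
    stop("blend: mass fractions must be >= 0", call. = FALSE)
  if (abs(sum(fraction) - 1) > 1e-12)
    stop(sprintf("blend: mass fractions sum to %.15g, not 1", sum(fraction)),
         call. = FALSE)
  key <- paste(material, lot, sep = "|")
  if (anyDuplicated(key))
    stop("blend: duplicated (material, lot) entry", call. = FALSE)
  structure(
    data.frame(material = as.character(material), lot = as.character(lot),
               fraction = as.numeric(fraction), stringsAsFactors = FALSE),
    class = c("blend_composition", "data.frame"))
}

#' Mass fractions aggregated over lots
#'
#' @param composition a [blend_composition()].
#' @return named numeric vector of per-material mass fractions.
#' @export
material_fractions <- function(composition) {
  stopifnot(inherits(composition, "blend_composition"))
  out <- tapply(composition$fraction, composition$material, sum)
  v <- as.numeric(out)
  names(v) <- names(out)
  v
}

# internal: look up a per-material quantity for each entry of a composition,
# with a diagnostic when a material is missing from the table
.lookup_by_material <- function(composition, table, what) {
  mats <- unique(composition$material)
  missing <- setdiff(mats, names(table))
  if (length(missing))
    stop("unknown material(s) in composition: ", paste(missing, collapse = ", "),
         " (no ", what, " supplied)", call. = FALSE)
  table[composition$material]
}
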