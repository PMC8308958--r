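#' Compress the die content
#'
#' Solves the coupled compression problem: the punch distance is affine in
#' the compression force, `h = h_min + punch_offset + compliance * F`, the
#' in-die density follows from the tablet mass at that distance, the stress
#' follows from the Kawakita mixture model, and the force is stress times die
#' area.  With a perfectly stiff press (`compliance = 0`) this reduces to the
#' direct closed-form stress inversion at the set punch distance.  Otherwise
#' the self-consistency equation in `P` (strictly monotone residual) is
#' solved to 1e-10 MPa.
#'
#' @param tablet_mass die fill mass, g (> 0).
#' @param composition a [blend_composition()] of the die content.
#' @param config a [press_config()].
#' @param coeffs named list of [kawakita_coefficients()] per material.
#' @return list with `stress` (MPa), `force` (kN), `punch_distance` (mm),
#'   `in_die_density` (g/cm^3) and `residual` (self-consistency residual in
#'   mm, zero for the stiff press).
#' @examples
#' kw <- list(A150 = kawakita_coefficients(1.22954, 0.4981, 0.0072))
#' b <- blend_composition("A150", fraction = 1)
#' compress(0.51065, b, press_config(), kw)
#' @export
compress <- function(tablet_mass, composition, config, coeffs) {
  stopifnot(inherits(composition, "blend_composition"),
            inherits(config, "press_config"))
  if (!(tablet_mass > 0)) stop("compress: tablet mass must be > 0", call. = FALSE)
  A_cm2 <- pi * (config$die_diameter / 20)^2
  h0 <- config$min_punch_distance + config$punch_offset  # mm
  cc <- config$machine_compliance                        # mm/kN
  force_of <- function(P) 0.1 * A_cm2 * P                # kN

  if (cc == 0) {
    rho <- tablet_mass / (A_cm2 * h0 / 10)
    P <- invert_compression_stress(rho, composition, coeffs)
    return(list(stress = P, force = force_of(P), punch_distance = h0,
                in_die_density = rho, residual = 0))
  }

  kw <- .lookup_by_material(composition, coeffs, "Kawakita coefficients")
  keep <- composition$fraction > 0
  x <- composition$fraction[keep]
  kw <- kw[keep]
  w <- vapply(seq_along(x), function(i) x[i] / kw[[i]]$rho0, numeric(1))
  a <- vapply(kw, `[[`, numeric(1), "a")
  b <- vapply(kw, `[[`, numeric(1), "b")
  fwd <- function(P) 1 / sum(w * (1 + (1 - a) * b * P) / (1 + b * P))
  target <- function(P) tablet_mass / (A_cm2 * (h0 + cc * force_of(P)) / 10)
  g <- function(P) target(P) - fwd(P)
  if (g(0) <= 0)
    stop("compress: die fill is not consolidated at the set punch distance ",
         "(target density below the low-pressure blend density)", call. = FALSE)
  upper <- 512
  it <- 0L
  while (g(upper) > 0 && it < 30L) {
    upper <- upper * 2
    it <- it + 1L
  }
  if (g(upper) > 0)
    stop("compress: no finite stress satisfies the compliance equation",
         call. = FALSE)
  P <- stats::uniroot(g, c(0, upper), tol = 1e-10)$root
  FkN <- force_of(P)
  h <- h0 + cc * FkN
  rho <- tablet_mass / (A_cm2 * h / 10)
  list(stress = P, force = FkN, punch_distance = h, in_die_density = rho,
       residual = h - h0 - cc * FkN)
}

#' Eject the tablet and record its quality attributes
#'
#' Applies the elastic-recovery chain (out-die density, out-die porosity) and
#' the Ryshkewitch-Duckworth strength model to a compression result, creating
#' one tablet record.  Ejection also releases the die for the next fill; in
#' the event loop this ordering is implicit.
#'
#' @param compression result of [compress()].
#' @param tablet_mass tablet mass, g.
#' @param fill_density blend fill density of the die content, g/cm^3.
#' @param composition a [blend_composition()] of the tablet.
#' @param materials named list of [material_spec()] objects.
#' @param strength a [strength_mix_coefficients()] object.
#' @param strength_reference material whose mass fraction is the `x` of the
#'   strength mixing rule (the coarse grade for the bundled coefficients).
#' @param ejection_time ejection time stamp, s.
#' @param index tablet index.
#' @return one-row list of tablet record fields: `index`, `ejection_time` (s),
#'   `mass` (g), `fill_density`, `in_die_density`, `out_die_density` (g/cm^3),
#'   `compression_stress` (MPa), `compression_force` (kN),
#'   `punch_distance_actual` (mm), `out_die_porosity`,
#'   `tensile_strength` (MPa) and `composition`.
#' @export
eject <- function(compression, tablet_mass, fill_density, composition,
                  materials, strength, strength_reference = "A150",
                  ejection_time = NA_real_, index = NA_integer_) {
  stopifnot(inherits(composition, "blend_composition"))
  recov <- lapply(materials, `[[`, "recovery")
  solids <- vapply(materials, `[[`, numeric(1), "solid_density")
  rho_out <- out_die_density(compression$stress, compression$in_die_density,
                             composition, recov)
  if (rho_out > compression$in_die_density + 1e-12)
    stop("eject: out-die density exceeds in-die density; ",
         "check recovery correction offsets", call. = FALSE)
  eps <- out_die_porosity(rho_out, composition, solids)
  xf <- material_fractions(composition)
  xref <- if (strength_reference %in% names(xf)) xf[[strength_reference]] else 0
  sigma <- tensile_strength(eps, xref, strength)
  list(index = index, ejection_time = ejection_time, mass = tablet_mass,
       fill_density = fill_density,
       in_die_density = compression$in_die_density,
       out_die_density = rho_out,
       compression_stress = compression$stress,
       compression_force = compression$force,
       punch_distance_actual = compression$punch_distance,
       out_die_porosity = eps, tensile_strength = sigma,
       composition = composition)
}
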