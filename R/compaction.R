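#' Volume-additive bulk density of a blend
#'
#' Mass-weighted harmonic mean of the component bulk densities,
#' \deqn{1/\rho_{fill,mix} = \sum_i x_i / \rho_{bulk,i},}
#' i.e. component volumes are additive.  This is the blend density governing
#' die filling.
#'
#' @param composition a [blend_composition()].
#' @param densities named numeric vector of bulk densities per material,
#'   g/cm^3 (all > 0).
#' @return blend bulk density, g/cm^3; always between the smallest and largest
#'   input density.
#' @examples
#' b <- blend_composition(c("A150", "A60"), fraction = c(0.5, 0.5))
#' mix_bulk_density(b, c(A150 = 0.73, A60 = 1.41))
#' @export
mix_bulk_density <- function(composition, densities) {
  stopifnot(inherits(composition, "blend_composition"))
  rho <- .lookup_by_material(composition, densities, "density")
  if (any(!is.finite(rho)) || any(rho <= 0))
    stop("mix_bulk_density: all densities must be finite and > 0", call. = FALSE)
  1 / sum(composition$fraction / rho)
}

#' Tablet weight from the dosing geometry
#'
#' \deqn{m_T = \pi (D/2)^2 \, h_{dos} \, \rho_{fill,mix}.}
#' Inputs are in press units (mm); the result is in grams (internal cm).
#'
#' @param die_diameter die diameter, mm.
#' @param dosing_height dosing height, mm.
#' @param fill_density blend fill density, g/cm^3.
#' @return tablet mass, g.
#' @examples
#' tablet_weight(11.28, 7, 0.73)  # about 0.51 g
#' @export
tablet_weight <- function(die_diameter, dosing_height, fill_density) {
  if (!(die_diameter > 0 && dosing_height > 0 && fill_density > 0))
    stop("tablet_weight: die_diameter, dosing_height and fill_density must be > 0",
         call. = FALSE)
  area_cm2 <- pi * (die_diameter / 20)^2
  area_cm2 * (dosing_height / 10) * fill_density
}

#' In-die density at a given punch distance
#'
#' \deqn{\rho = m_T / (\pi (D/2)^2 h).}
#'
#' @param tablet_mass tablet mass, g.
#' @param die_diameter die diameter, mm.
#' @param punch_distance punch face distance, mm.
#' @return in-die density, g/cm^3.
#' @export
in_die_density <- function(tablet_mass, die_diameter, punch_distance) {
  if (!(tablet_mass > 0 && die_diameter > 0 && punch_distance > 0))
    stop("in_die_density: all arguments must be > 0", call. = FALSE)
  area_cm2 <- pi * (die_diameter / 20)^2
  tablet_mass / (area_cm2 * punch_distance / 10)
}

#' Kawakita density of a blend under stress
#'
#' Volume-additive mixture form of the Kawakita model,
#' \deqn{1/\rho_{P,mix} = \sum_i \frac{x_i}{\rho_{0,i}}
#'       \frac{1 + (1-a_i) b_i P}{1 + b_i P}.}
#' Strictly increasing in `P`; at `P = 0` it reduces to the harmonic blend of
#' the `rho0` values.  The model is calibrated from 20 MPa upward; evaluation
#' below 20 MPa is permitted but warned about, since the Kawakita model is not
#' suited to very low pressures.
#'
#' @param P compression stress, MPa (>= 0); may be a vector.
#' @param composition a [blend_composition()].
#' @param coeffs named list of [kawakita_coefficients()] per material.
#' @param low_pressure_warning warn when any `P` is below 20 MPa (default TRUE).
#' @return blend density, g/cm^3 (same length as `P`).
#' @examples
#' kw <- list(A150 = kawakita_coefficients(1.22954, 0.4981, 0.0072))
#' b <- blend_composition("A150", fraction = 1)
#' kawakita_mixture_density(100, b, kw)
#' @export
kawakita_mixture_density <- function(P, composition, coeffs,
                                     low_pressure_warning = TRUE) {
  stopifnot(inherits(composition, "blend_composition"))
  if (any(P < 0)) stop("kawakita_mixture_density: P must be >= 0", call. = FALSE)
  if (low_pressure_warning && any(P < 20 & P > 0))
    warning("Kawakita model evaluated below 20 MPa; ",
            "it is not calibrated for very low pressures", call. = FALSE)
  kw <- .lookup_by_material(composition, coeffs, "Kawakita coefficients")
  x <- composition$fraction
  inv <- vapply(P, function(p) {
    sum(vapply(seq_along(x), function(i) {
      k <- kw[[i]]
      x[i] / k$rho0 * (1 + (1 - k$a) * k$b * p) / (1 + k$b * p)
    }, numeric(1)))
  }, numeric(1))
  1 / inv
}

#' Compression stress that yields a target blend density
#'
#' Inverts the volume-additive Kawakita mixture model for the stress `P`.  For
#' one component the inversion is linear; for two components clearing the
#' denominators gives a quadratic in `P` that is solved exactly (pq formula),
#' keeping the positive root at which the forward model reproduces the target
#' density.  For more than two components a bracketed bisection/uniroot search
#' on the strictly monotone forward model is used (bracket `[0, 1e4]` MPa,
#' tolerance 1e-9 MPa).
#'
#' @inheritParams kawakita_mixture_density
#' @param target_density desired in-die density, g/cm^3.  Must exceed the
#'   blend density at `P = 0` and stay below the blend asymptote.
#' @return stress, MPa.
#' @examples
#' kw <- list(A150 = kawakita_coefficients(1.22954, 0.4981, 0.0072))
#' b <- blend_composition("A150", fraction = 1)
#' P <- invert_compression_stress(1.598, b, kw)
#' kawakita_mixture_density(P, b, kw)  # 1.598
#' @export
invert_compression_stress <- function(target_density, composition, coeffs) {
  stopifnot(inherits(composition, "blend_composition"),
            length(target_density) == 1L, target_density > 0)
  kw <- .lookup_by_material(composition, coeffs, "Kawakita coefficients")
  x <- composition$fraction
  keep <- x > 0
  kw <- kw[keep]; x <- x[keep]

  rho_zero <- 1 / sum(vapply(seq_along(x), function(i) x[i] / kw[[i]]$rho0,
                             numeric(1)))
  rho_inf <- 1 / sum(vapply(seq_along(x), function(i)
    x[i] * (1 - kw[[i]]$a) / kw[[i]]$rho0, numeric(1)))
  if (target_density <= rho_zero || target_density >= rho_inf)
    stop(sprintf(
      "unreachable density: target %.5f g/cm^3 outside attainable range (%.5f, %.5f)",
      target_density, rho_zero, rho_inf), call. = FALSE)

  V <- 1 / target_density
  w <- vapply(seq_along(x), function(i) x[i] / kw[[i]]$rho0, numeric(1))
  a <- vapply(kw, `[[`, numeric(1), "a")
  b <- vapply(kw, `[[`, numeric(1), "b")

  if (length(x) == 1L) {
    # V (1 + bP) = w (1 + (1-a) b P)
    P <- (V - w) / (w * (1 - a) * b - V * b)
  } else if (length(x) == 2L) {
    # multiply by (1+b1 P)(1+b2 P): quadratic A P^2 + B P + C = 0
    A <- V * b[1] * b[2] -
      w[1] * (1 - a[1]) * b[1] * b[2] - w[2] * (1 - a[2]) * b[1] * b[2]
    B <- V * (b[1] + b[2]) -
      w[1] * ((1 - a[1]) * b[1] + b[2]) - w[2] * ((1 - a[2]) * b[2] + b[1])
    C <- V - w[1] - w[2]
    # pq formula on P^2 + pP + q = 0
    p <- B / A; q <- C / A
    disc <- p^2 / 4 - q
    if (disc < 0)
      stop("unreachable density: no real stress solves the blend quadratic",
           call. = FALSE)
    roots <- c(-p / 2 + sqrt(disc), -p / 2 - sqrt(disc))
    pos <- roots[roots > 0]
    if (!length(pos))
      stop("unreachable density: no positive stress root", call. = FALSE)
    # keep the root at which the forward model reproduces the target
    resid <- vapply(pos, function(r)
      abs(1 / sum(w * (1 + (1 - a) * b * r) / (1 + b * r)) - target_density),
      numeric(1))
    P <- pos[which.min(resid)]
  } else {
    fwd <- function(p) 1 / sum(w * (1 + (1 - a) * b * p) / (1 + b * p))
    P <- stats::uniroot(function(p) fwd(p) - target_density,
                        interval = c(0, 1e4), tol = 1e-9)$root
  }
  unname(P)
}

# internal: harmonic (volume-additive) mix of a per-material density vector
.harmonic_mix <- function(x, rho) 1 / sum(x / rho)

#' Out-die density after elastic recovery
#'
#' Predicts the tablet density after ejection from the in-die density at
#' maximum stress.  Per-material recovery calibrations are blended to the
#' mixture level by applying the volume-additive rule to the calibration-state
#' densities at the low and high calibration stress; the blend's instantaneous
#' recovery line (slope `k`, intercept `l`) is then drawn through the two
#' resulting in-die recovery values, and the slow recovery is the mean of the
#' blend values at the two stresses:
#' \deqn{\rho_{out\mbox{-}die} = \rho_{P,max} - (kP + l) -
#'       \bar{\Delta\rho}_{slow} + \delta_{corr}.}
#' The correction offset `delta_corr` is blended linearly by mass fraction.
#'
#' @param P compression stress the tablet experienced, MPa (> 0).
#' @param rho_P_max in-die density at maximum stress, g/cm^3.
#' @param composition a [blend_composition()].
#' @param recovery named list of [recovery_calibration()] per material; all
#'   entries must share the same calibration stresses.
#' @return out-die density, g/cm^3 (never above `rho_P_max` for non-negative
#'   recovery and zero correction).
#' @export
out_die_density <- function(P, rho_P_max, composition, recovery) {
  stopifnot(inherits(composition, "blend_composition"), P > 0, rho_P_max > 0)
  rc <- .lookup_by_material(composition, recovery, "recovery calibration")
  P_low <- vapply(rc, `[[`, numeric(1), "P_low")
  P_high <- vapply(rc, `[[`, numeric(1), "P_high")
  if (length(unique(P_low)) != 1L || length(unique(P_high)) != 1L)
    stop("out_die_density: recovery calibrations use different stresses",
         call. = FALSE)
  x <- composition$fraction
  mix_state <- function(field, j)
    .harmonic_mix(x, vapply(rc, function(r) r[[field]][j], numeric(1)))
  d_in <- d_slow <- numeric(2)
  for (j in 1:2) {
    rmax <- mix_state("rho_P_max", j)
    r0 <- mix_state("rho_P_0", j)
    rout <- mix_state("rho_out_die", j)
    d_in[j] <- rmax - r0
    d_slow[j] <- r0 - rout
  }
  Pc <- c(P_low[1], P_high[1])
  k <- (d_in[2] - d_in[1]) / (Pc[2] - Pc[1])
  l <- d_in[1] - k * Pc[1]
  offset <- sum(x * vapply(rc, `[[`, numeric(1), "correction_offset"))
  out <- unname(rho_P_max - (k * P + l) - mean(d_slow) + offset)
  if (out <= 0)
    stop("out_die_density: predicted density is not positive; ",
         "implausible recovery calibration", call. = FALSE)
  out
}

#' Out-die porosity of a blend tablet
#'
#' \deqn{\varepsilon = 1 - \rho_{out\mbox{-}die} / \rho_{s,mix}} with the
#' mixture solid density from the same volume-additive rule as the fill
#' density, \eqn{1/\rho_{s,mix} = \sum_i x_i / \rho_{s,i}}.
#'
#' @param rho_out_die out-die density, g/cm^3.
#' @param composition a [blend_composition()].
#' @param solid_densities named numeric vector of solid densities per
#'   material, g/cm^3.
#' @return porosity in (0, 1); zero-or-negative porosity is an error.
#' @export
out_die_porosity <- function(rho_out_die, composition, solid_densities) {
  stopifnot(inherits(composition, "blend_composition"), rho_out_die > 0)
  rho_s <- .lookup_by_material(composition, solid_densities, "solid density")
  rho_s_mix <- .harmonic_mix(composition$fraction, rho_s)
  eps <- unname(1 - rho_out_die / rho_s_mix)
  if (eps < 0)
    stop(sprintf(
      "out_die_porosity: density %.5f exceeds mixture solid density %.5f",
      rho_out_die, rho_s_mix), call. = FALSE)
  eps
}

#' Composition dependence of the Ryshkewitch-Duckworth parameters
#'
#' `sigma0_of_x()` evaluates \eqn{\sigma_0(x) = c_1 e^{x c_2} + c_3} and
#' `kb_of_x()` evaluates \eqn{k_b(x) = m x + n}, where `x` is the mass
#' fraction of the coarse component (DCPA A150 for the bundled coefficients).
#'
#' @param x mass fraction in `[0, 1]` (vectorized).
#' @param coeffs a [strength_mix_coefficients()] object.
#' @return `sigma0_of_x()`: MPa; `kb_of_x()`: dimensionless.
#' @export
sigma0_of_x <- function(x, coeffs) {
  stopifnot(inherits(coeffs, "strength_mix_coefficients"))
  if (any(x < 0 | x > 1))
    stop("sigma0_of_x: x must lie in [0, 1]", call. = FALSE)
  coeffs$c1 * exp(x * coeffs$c2) + coeffs$c3
}

#' @rdname sigma0_of_x
#' @export
kb_of_x <- function(x, coeffs) {
  stopifnot(inherits(coeffs, "strength_mix_coefficients"))
  if (any(x < 0 | x > 1))
    stop("kb_of_x: x must lie in [0, 1]", call. = FALSE)
  coeffs$m * x + coeffs$n
}

#' Tensile strength from out-die porosity
#'
#' Ryshkewitch-Duckworth relation with composition-dependent coefficients:
#' \deqn{\sigma = \sigma_0(x)\, e^{-k_b(x)\,\varepsilon}.}
#' Strictly decreasing in porosity; at zero porosity it equals
#' \eqn{\sigma_0(x)}.
#'
#' @param eps_out_die out-die porosity in `[0, 1)` (vectorized).
#' @param x mass fraction of the coarse component in `[0, 1]`.
#' @param coeffs a [strength_mix_coefficients()] object.
#' @return tensile strength, MPa.
#' @export
tensile_strength <- function(eps_out_die, x, coeffs) {
  if (any(eps_out_die < 0 | eps_out_die >= 1))
    stop("tensile_strength: porosity must lie in [0, 1)", call. = FALSE)
  sigma0_of_x(x, coeffs) * exp(-kb_of_x(x, coeffs) * eps_out_die)
}
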