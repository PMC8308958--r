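# Feed frame: the paddle-wheel interspaces are modeled as n_compartments
# ideal mixers (CSTRs) attached to rotating positions.  Position 1 is under
# the filling pipe (refill), the output position is over the die.  Each
# compartment holds a named mass vector over "material|lot" keys; its volume
# follows from the per-key fill densities (volume additivity), so mass and
# volume can never drift apart.

# volume of a named mass vector given the per-material fill-density table
.mass_volume <- function(mass, dens) {
  if (!length(mass)) return(0)
  sum(mass / dens[.key_material(names(mass))])
}

#' Build the feed frame
#'
#' All compartments start filled to capacity with the initial material.
#'
#' @param config a [press_config()].
#' @param initial_material material name of the initial charge.
#' @param materials named list of [material_spec()] objects.
#' @param initial_lot lot label of the initial charge.
#' @param output_position position index over the die (default 5; position 1
#'   is under the filling pipe).
#' @return An object of class `feed_frame`.
#' @export
feed_frame <- function(config, initial_material, materials,
                       initial_lot = "lot-1", output_position = 5) {
  stopifnot(inherits(config, "press_config"))
  n <- config$n_compartments
  dens <- .fill_density_table(materials, config$use_consolidated_density)
  if (!initial_material %in% names(dens))
    stop("feed_frame: unknown initial material", call. = FALSE)
  key <- .key(initial_material, initial_lot)
  m0 <- config$compartment_capacity * dens[[initial_material]]
  names(m0) <- key
  structure(list(
    mass = rep(list(m0), n),
    position = seq_len(n),
    capacity = config$compartment_capacity,
    fill_density = dens,
    n = n,
    output_position = output_position
  ), class = "feed_frame")
}

#' Compartment state
#'
#' @param frame a [feed_frame()].
#' @param index compartment index.
#' @return list with `index`, `position`, `composition` (a
#'   [blend_composition()]), `fill_volume` (cm^3) and `bulk_density` (g/cm^3).
#' @export
compartment_state <- function(frame, index) {
  stopifnot(inherits(frame, "feed_frame"))
  mass <- frame$mass[[index]]
  vol <- .mass_volume(mass, frame$fill_density)
  list(index = index, position = frame$position[index],
       composition = .mass_to_blend(mass),
       fill_volume = vol,
       bulk_density = if (vol > 0) sum(mass) / vol else NA_real_)
}

#' Refill a compartment with incoming material
#'
#' The incoming material (from the filling pipe) is mixed instantaneously and
#' ideally with the residual compartment content; the compartment is a CSTR.
#' The compartment must sit at (or be passing) the input position.
#'
#' @param frame a [feed_frame()].
#' @param index compartment index to refill.
#' @param mass named mass vector of the incoming material, g.
#' @return updated `feed_frame`.
#' @export
refill_compartment <- function(frame, index, mass) {
  stopifnot(inherits(frame, "feed_frame"))
  new_mass <- .madd(frame$mass[[index]], mass)
  vol <- .mass_volume(new_mass, frame$fill_density)
  if (vol > frame$capacity * (1 + 1e-9))
    stop(sprintf(
      "refill_compartment: overfill (%.5f cm^3 into capacity %.5f cm^3)",
      vol, frame$capacity), call. = FALSE)
  frame$mass[[index]] <- new_mass
  frame
}

#' Fill the die from the feed frame
#'
#' The compartment at the output position donates the first fill ratio of the
#' dosing volume; the following ratios are donated by the compartments that
#' sweep across the die opening next (positions `output_position - 1`,
#' `output_position - 2`, ..., since positions advance with the paddle
#' rotation).  Each donation removes a homogeneous volume fraction of the
#' compartment.  The mixed fill density follows the volume-additive rule; the
#' tablet mass is the donated mass.
#'
#' @param frame a [feed_frame()].
#' @param config a [press_config()].
#' @return list with `frame` (updated), `mass` (named mass vector of the die
#'   content, g), `tablet_mass` (g), `fill_density` (g/cm^3) and
#'   `composition` (a [blend_composition()]).
#' @export
fill_die <- function(frame, config) {
  stopifnot(inherits(frame, "feed_frame"), inherits(config, "press_config"))
  v_dos <- dosing_volume(config)
  ratios <- config$fill_ratios
  n <- frame$n
  die_mass <- numeric(0)
  for (j in seq_along(ratios)) {
    if (ratios[j] <= 0) next
    pos <- ((frame$output_position - j) %% n) + 1L
    idx <- which(frame$position == pos)
    need <- ratios[j] * v_dos
    mass <- frame$mass[[idx]]
    vol <- .mass_volume(mass, frame$fill_density)
    if (vol < need * (1 - 1e-9))
      stop(sprintf(
        "fill_die: compartment %d at position %d holds %.5f cm^3 but %.5f cm^3 needed (underfill)",
        idx, pos, vol, need), call. = FALSE)
    frac <- need / vol
    die_mass <- .madd(die_mass, mass * frac)
    frame$mass[[idx]] <- mass * (1 - frac)
  }
  m_t <- sum(die_mass)
  list(frame = frame, mass = die_mass, tablet_mass = m_t,
       fill_density = m_t / v_dos,
       composition = .mass_to_blend(die_mass))
}

#' Rotate the feed frame
#'
#' Advances every compartment by `k` positions (from [rotation_per_fill()]).
#' Compartments that pass or land on the input position (1) during the sweep
#' are reported in passing order so they can be refilled from the pipe.
#'
#' @param frame a [feed_frame()].
#' @param config a [press_config()]; alternatively pass `k` directly.
#' @param k positions to advance (default from the paddle/turret rates).
#' @return list with `frame` (updated) and `passed` (compartment indices that
#'   swept over the input position, in passing order).
#' @export
rotate_feed_frame <- function(frame, config, k = rotation_per_fill(config)) {
  stopifnot(inherits(frame, "feed_frame"))
  n <- frame$n
  old <- frame$position
  frame$position <- ((old - 1L + k) %% n) + 1L
  # steps until a compartment reaches position 1 from its old position
  d <- (1L - old) %% n
  d[d == 0L] <- n
  passed <- order(d)[sort(d) <= k]
  list(frame = frame, passed = passed)
}

#' Total mass held in the feed frame
#'
#' @param frame a [feed_frame()].
#' @return total mass, g.
#' @export
feed_frame_mass <- function(frame) {
  stopifnot(inherits(frame, "feed_frame"))
  sum(vapply(frame$mass, sum, numeric(1)))
}
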