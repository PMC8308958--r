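# Filling pipe: two concentric plug-flow streams (fast midstream, slow outer
# ring) represented as bottom-to-top queues of material parcels.  A parcel is
# list(vol = cm^3, mass = named mass vector over "material|lot" keys).
# Volumes are additive (each key has a fixed fill density), so parcel mass and
# volume stay mutually consistent under any split or merge.

.key <- function(material, lot) paste(material, lot, sep = "|")

.key_material <- function(keys) vapply(strsplit(keys, "|", fixed = TRUE),
                                       `[[`, character(1), 1L)

# merge-add two named mass vectors
.madd <- function(a, b) {
  if (!length(a)) return(b)
  if (!length(b)) return(a)
  keys <- union(names(a), names(b))
  out <- numeric(length(keys))
  names(out) <- keys
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + b
  out
}

# named mass vector -> blend_composition
.mass_to_blend <- function(mass) {
  mass <- mass[mass > 0]
  keys <- names(mass)
  parts <- strsplit(keys, "|", fixed = TRUE)
  blend_composition(material = vapply(parts, `[[`, character(1), 1L),
                    lot = vapply(parts, `[[`, character(1), 2L),
                    fraction = as.numeric(mass / sum(mass)))
}

# per-material fill density table from a list of material_spec
.fill_density_table <- function(materials, use_consolidated = TRUE) {
  vapply(materials, function(m)
    if (use_consolidated) m$consolidated_bulk_density else m$bulk_density,
    numeric(1))
}

# extract `vol` from the bottom of a parcel queue; returns remaining queue and
# the extracted named mass vector
.queue_take <- function(parcels, vol) {
  taken <- numeric(0)
  remaining <- vol
  while (remaining > 1e-15 && length(parcels)) {
    p <- parcels[[1]]
    if (p$vol <= remaining + 1e-15) {
      taken <- .madd(taken, p$mass)
      remaining <- remaining - p$vol
      parcels[[1]] <- NULL
    } else {
      frac <- remaining / p$vol
      taken <- .madd(taken, p$mass * frac)
      parcels[[1]]$mass <- p$mass * (1 - frac)
      parcels[[1]]$vol <- p$vol - remaining
      remaining <- 0
    }
  }
  if (remaining > 1e-12)
    stop("filling pipe ran empty during extraction", call. = FALSE)
  list(parcels = parcels, mass = taken)
}

# append a pure parcel at the top, coalescing with a same-key top parcel
.queue_put <- function(parcels, vol, mass) {
  n <- length(parcels)
  if (n > 0L) {
    top <- parcels[[n]]
    if (length(top$mass) == length(mass) &&
        identical(names(top$mass), names(mass))) {
      parcels[[n]]$vol <- top$vol + vol
      parcels[[n]]$mass <- top$mass + mass
      return(parcels)
    }
  }
  parcels[[n + 1L]] <- list(vol = vol, mass = mass)
  parcels
}

#' Build the filling pipe
#'
#' Constructs the two plug-flow streams of the filling pipe, initially
#' homogeneous in the given material.  The conceptual layer height is chosen
#' so that one fill event's extraction (the bottom outer-ring layer plus
#' `velocity_ratio` bottom midstream layers) totals exactly the dosing volume:
#' \deqn{h_{layer} = V_{dos} / (A_{outer} + r\,A_{mid}).}
#' Any extracted volume is split between the streams in the fixed ratio
#' `A_outer : r * A_mid`, which realizes the `r : 1` velocity difference.
#'
#' @param config a [press_config()].
#' @param initial_material material name filling the pipe at start.
#' @param materials named list of [material_spec()] objects.
#' @param initial_lot lot label of the initial charge.
#' @return An object of class `filling_pipe`.
#' @examples
#' mats <- case_study_materials()
#' pipe <- build_pipe(press_config(), "A150", mats)
#' pipe$layer_height
#' @export
build_pipe <- function(config, initial_material, materials,
                       initial_lot = "lot-1") {
  stopifnot(inherits(config, "press_config"))
  r_pipe <- config$pipe_inner_diameter / 20   # cm
  r_mid <- config$midstream_diameter / 20
  if (r_mid >= r_pipe)
    stop("build_pipe: midstream does not fit inside the pipe", call. = FALSE)
  A_mid <- pi * r_mid^2
  A_outer <- pi * (r_pipe^2 - r_mid^2)
  r <- config$velocity_ratio
  v_dos <- dosing_volume(config)
  h_layer <- v_dos / (A_outer + r * A_mid)
  height_cm <- config$pipe_height / 10
  if (height_cm <= h_layer)
    stop("build_pipe: pipe shorter than one layer", call. = FALSE)
  dens <- .fill_density_table(materials, config$use_consolidated_density)
  if (!initial_material %in% names(dens))
    stop("build_pipe: unknown initial material '", initial_material, "'",
         call. = FALSE)
  key <- .key(initial_material, initial_lot)
  mk_parcel <- function(area) {
    vol <- area * height_cm
    mass <- vol * dens[[initial_material]]
    names(mass) <- key
    list(list(vol = vol, mass = mass))
  }
  structure(list(
    A_mid = A_mid, A_outer = A_outer, velocity_ratio = r,
    layer_height = h_layer, height_cm = height_cm,
    n_layers = height_cm / h_layer,
    share_outer = A_outer / (A_outer + r * A_mid),
    share_mid = r * A_mid / (A_outer + r * A_mid),
    v_dos = v_dos,
    fill_density = dens,
    outer = mk_parcel(A_outer), mid = mk_parcel(A_mid)
  ), class = "filling_pipe")
}

#' @export
print.filling_pipe <- function(x, ...) {
  cat(sprintf("Filling pipe: A_mid = %.4f cm^2, A_outer = %.4f cm^2, layer %.5f cm\n",
              x$A_mid, x$A_outer, x$layer_height))
  cat(sprintf("  %.1f layers, velocity ratio %.1f, %d/%d parcels (outer/mid)\n",
              x$n_layers, x$velocity_ratio, length(x$outer), length(x$mid)))
  invisible(x)
}

#' Advance the pipe and extract material at the bottom
#'
#' Removes `volume` cm^3 from the bottom of the pipe — split between the outer
#' ring and the midstream in the `1 : velocity_ratio` area-weighted ratio — and
#' tops both streams up with the hopper material active at time `t_min`, so
#' the pipe stays full.  With the default `volume = dosing volume`, one call
#' is one fill event: the outer ring advances one conceptual layer and the
#' midstream advances `velocity_ratio` layers.
#'
#' @param pipe a [build_pipe()] object.
#' @param hopper a [hopper_schedule()].
#' @param t_min current simulation time, min.
#' @param volume volume to extract, cm^3 (default one dosing volume).
#' @return list with `pipe` (updated), `composition` (a
#'   [blend_composition()] of the extracted material), `volume` (cm^3),
#'   `mass` (named mass vector, g) and `mass_in` (mass drawn from the hopper, g).
#' @export
advance_pipe_and_extract <- function(pipe, hopper, t_min,
                                     volume = pipe$v_dos) {
  stopifnot(inherits(pipe, "filling_pipe"), inherits(hopper, "hopper_schedule"),
            volume > 0)
  drawn <- .pipe_draw(pipe, hopper, t_min, volume)
  list(pipe = drawn$pipe,
       composition = .mass_to_blend(drawn$mass),
       volume = volume,
       mass = drawn$mass,
       mass_in = drawn$mass_in)
}

# internal extraction kernel: no composition object, used by the event loop
.pipe_draw <- function(pipe, hopper, t_min, volume) {
  v_out <- volume * pipe$share_outer
  v_mid <- volume * pipe$share_mid
  ex_o <- .queue_take(pipe$outer, v_out)
  ex_m <- .queue_take(pipe$mid, v_mid)
  feed <- schedule_at(hopper, t_min)
  if (!feed$material %in% names(pipe$fill_density))
    stop("advance_pipe_and_extract: schedule feeds unknown material '",
         feed$material, "'", call. = FALSE)
  dens <- pipe$fill_density[[feed$material]]
  key <- .key(feed$material, feed$lot)
  put <- function(parcels, vol) {
    mass <- vol * dens
    names(mass) <- key
    .queue_put(parcels, vol, mass)
  }
  pipe$outer <- put(ex_o$parcels, v_out)
  pipe$mid <- put(ex_m$parcels, v_mid)
  list(pipe = pipe, mass = .madd(ex_o$mass, ex_m$mass),
       mass_in = (v_out + v_mid) * dens)
}

#' Total volume and mass held in the pipe
#'
#' @param pipe a [build_pipe()] object.
#' @return list with `volume` (cm^3) and `mass` (g).
#' @export
pipe_contents <- function(pipe) {
  stopifnot(inherits(pipe, "filling_pipe"))
  vol <- sum(vapply(pipe$outer, `[[`, numeric(1), "vol")) +
    sum(vapply(pipe$mid, `[[`, numeric(1), "vol"))
  mass <- sum(vapply(pipe$outer, function(p) sum(p$mass), numeric(1))) +
    sum(vapply(pipe$mid, function(p) sum(p$mass), numeric(1)))
  list(volume = vol, mass = mass)
}
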