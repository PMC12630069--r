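#' Default configuration for the synthetic head phantom
#'
#' The phantom is a one-dimensional layer stack along the beam axis
#' (air / tissue / skull / brain / skull / tissue / air), centered on the
#' isocenter, with a mild lateral gradient in the thickness of the entry
#' tissue layer. The gradient makes the water-equivalent thickness (WET)
#' seen by a pencil beam depend linearly on its lateral position, so that
#' lateral couch shifts produce a nonzero, known range shift.
#'
#' @param tissue_mm Physical thickness of each tissue layer (mm).
#' @param skull_mm Physical thickness of each skull layer (mm).
#' @param brain_mm Physical thickness of the brain layer (mm).
#' @param spr_tissue,spr_skull,spr_brain Stopping-power ratios relative to
#'   water of the three materials (dimensionless). The brain value, 1.04,
#'   is the mean stopping-power ratio of the target region and is also used
#'   by the setup-error WET conversion (see [geom_to_wet()]).
#' @param grad_y,grad_z Lateral gradient of the entry tissue thickness
#'   (mm thickness per mm lateral offset, in BEV y and z).
#' @param slab_gap_mm Air gap between the upstream slab stack and the
#'   nominal phantom entry surface (mm).
#' @param mlic_x_mm Room-frame x position of the MLIC entrance window (mm).
#' @param mlic_aperture_mm Diameter of the MLIC entrance window (mm);
#'   enforced as a lateral acceptance check only.
#' @return A named list of phantom parameters.
#' @export
phantom_config <- function(tissue_mm = 9, skull_mm = 2, brain_mm = 130,
                           spr_tissue = 1.0, spr_skull = 1.5,
                           spr_brain = 1.04,
                           grad_y = 0.25, grad_z = 0.15,
                           slab_gap_mm = 20, mlic_x_mm = 150,
                           mlic_aperture_mm = 120) {
  list(tissue_mm = tissue_mm, skull_mm = skull_mm, brain_mm = brain_mm,
       spr_tissue = spr_tissue, spr_skull = spr_skull,
       spr_brain = spr_brain, grad_y = grad_y, grad_z = grad_z,
       slab_gap_mm = slab_gap_mm, mlic_x_mm = mlic_x_mm,
       mlic_aperture_mm = mlic_aperture_mm)
}

#' Build the synthetic phantom geometry
#'
#' @param config A list as returned by [phantom_config()].
#' @return An object of class `phantom`: the layer stack, the room-frame
#'   exit-surface position, the lateral gradient, an (initially zero) couch
#'   offset, and an (initially empty) slab list.
#' @examples
#' ph <- build_phantom()
#' trace_wet(ph)  # total WET along the central axis
#' @export
build_phantom <- function(config = phantom_config()) {
  thick <- c(config$tissue_mm, config$skull_mm, config$brain_mm,
             config$skull_mm, config$tissue_mm)
  spr <- c(config$spr_tissue, config$spr_skull, config$spr_brain,
           config$spr_skull, config$spr_tissue)
  if (any(thick <= 0)) abort("all layer thicknesses must be > 0")
  if (any(spr < 0)) abort("stopping-power ratios must be >= 0")
  layers <- tibble(
    material = c("tissue", "skull", "brain", "skull", "tissue"),
    thickness_mm = thick, spr = spr
  )
  total <- sum(thick)
  structure(list(
    layers = layers,
    exit_x_mm = total / 2,          # stack centered on the isocenter
    grad = c(y = config$grad_y, z = config$grad_z),
    couch_mm = c(x = 0, y = 0, z = 0),
    slabs = tibble(wet_mm = double(), spr = double(), position = character()),
    slab_gap_mm = config$slab_gap_mm,
    mlic_x_mm = config$mlic_x_mm,
    mlic_aperture_mm = config$mlic_aperture_mm,
    config = config
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> layer stack (beam along +x):\n")
  print(as.data.frame(x$layers), row.names = FALSE)
  cat(sprintf("exit surface at x = %+.1f mm; couch offset (%.1f, %.1f, %.1f) mm\n",
              x$exit_x_mm, x$couch_mm["x"], x$couch_mm["y"], x$couch_mm["z"]))
  if (nrow(x$slabs)) {
    cat("slabs:\n"); print(as.data.frame(x$slabs), row.names = FALSE)
  }
  invisible(x)
}

## Entry tissue thickness at phantom-frame lateral position (y, z); the
## other layers have fixed thickness.
.entry_tissue_mm <- function(geom, y_ph, z_ph) {
  t0 <- geom$layers$thickness_mm[1]
  t0 + geom$grad["y"] * y_ph + geom$grad["z"] * z_ph
}

#' Material segments traversed by a ray
#'
#' Returns the ordered room-frame intervals of non-air material crossed by
#' a ray parallel to the beam axis at BEV position (y, z): upstream slabs
#' (fixed in the room, ending `slab_gap_mm` upstream of the nominal entry
#' surface), the phantom layers (rigidly translated by the couch offset),
#' and downstream slabs (fixed in the room between phantom exit and the
#' MLIC).
#'
#' @param geom A `phantom` object.
#' @param y,z Ray BEV position (mm).
#' @return A tibble with columns `x0`, `x1` (mm, room frame) and `spr`.
#' @export
ray_segments <- function(geom, y = 0, z = 0) {
  stopifnot(inherits(geom, "phantom"))
  dx <- geom$couch_mm["x"]
  y_ph <- y - geom$couch_mm["y"]
  z_ph <- z - geom$couch_mm["z"]
  thick <- geom$layers$thickness_mm
  thick[1] <- .entry_tissue_mm(geom, y_ph, z_ph)
  if (thick[1] <= 0) {
    abort(sprintf("ray at (y=%.1f, z=%.1f) misses the phantom entry layer", y, z))
  }
  exit_x <- geom$exit_x_mm + dx
  bounds <- exit_x - rev(cumsum(rev(c(thick, 0))))  # entry .. exit nodes
  seg <- tibble(x0 = bounds[-length(bounds)], x1 = bounds[-1],
                spr = geom$layers$spr)
  nominal_entry <- -geom$exit_x_mm  # slab rack is fixed in the room
  up <- geom$slabs[geom$slabs$position == "upstream", , drop = FALSE]
  if (nrow(up)) {
    end <- nominal_entry - geom$slab_gap_mm
    w <- up$wet_mm / up$spr         # physical thickness, stacked upstream
    x1 <- end - c(0, cumsum(w))[seq_along(w)]
    seg <- bind_rows(tibble(x0 = x1 - w, x1 = x1, spr = up$spr), seg)
  }
  down <- geom$slabs[geom$slabs$position == "downstream", , drop = FALSE]
  if (nrow(down)) {
    start <- geom$exit_x_mm + (geom$mlic_x_mm - geom$exit_x_mm) / 2
    w <- down$wet_mm / down$spr
    x0 <- start + c(0, cumsum(w))[seq_along(w)]
    seg <- bind_rows(seg, tibble(x0 = x0, x1 = x0 + w, spr = down$spr))
  }
  arrange(seg, .data$x0)
}

#' Water-equivalent path length along a ray
#'
#' Line integral of the stopping-power ratio from the nozzle (far upstream)
#' to a room-frame depth `x_to`, for the ray at BEV position (y, z).
#' Upstream slabs are always included; downstream slabs contribute only
#' where `x_to` reaches beyond the phantom exit.
#'
#' @inheritParams ray_segments
#' @param x_to Room-frame x (mm) at which to stop the integral, or `NULL`
#'   for the MLIC entrance (full exit, including downstream slabs).
#' @return WET in mm (scalar, vectorized over `x_to`).
#' @export
trace_wet <- function(geom, y = 0, z = 0, x_to = NULL) {
  if (is.null(x_to)) x_to <- geom$mlic_x_mm
  seg <- ray_segments(geom, y, z)
  vapply(x_to, function(xt) {
    sum(seg$spr * pmax(0, pmin(seg$x1, xt) - seg$x0))
  }, numeric(1))
}

## Inverse of trace_wet along one ray: room-frame x at which the
## accumulated WET reaches `wet`. Returns NA if the ray's total WET up to
## the MLIC is below `wet`.
.x_at_wet <- function(geom, y = 0, z = 0, wet = 0) {
  seg <- ray_segments(geom, y, z)
  seg <- seg[seg$spr > 0, , drop = FALSE]
  acc <- 0
  for (i in seq_len(nrow(seg))) {
    w_seg <- seg$spr[i] * (seg$x1[i] - seg$x0[i])
    if (acc + w_seg >= wet) {
      return(seg$x0[i] + (wet - acc) / seg$spr[i])
    }
    acc <- acc + w_seg
  }
  NA_real_
}

#' Table of treatment-deviation scenarios
#'
#' The ten deviation scenarios: three upstream water-equivalent slabs
#' (2/3/5 mm) and one downstream slab (5 mm) mimicking anatomical changes
#' (AC), and six rigid couch movements (2/3 mm left in BEV, down in BEV,
#' and upstream) mimicking setup errors (SE). The `expected` column states
#' the expected range shift in the target in WET mm: the slab thickness for
#' upstream slabs, zero for the downstream slab (it sits beyond the
#' target), and a calculated value for couch movements.
#'
#' @return A tibble with one row per scenario.
#' @export
scenario_table <- function() {
  tibble(
    id = 1:10,
    label = c("slab upstream 2 mm", "slab upstream 3 mm", "slab upstream 5 mm",
              "slab downstream 5 mm",
              "couch left 2 mm", "couch left 3 mm",
              "couch down 2 mm", "couch down 3 mm",
              "couch upstream 2 mm", "couch upstream 3 mm"),
    kind = c(rep("AC_upstream", 3), "AC_downstream", rep("SE_couch", 6)),
    slab_wet_mm = c(2, 3, 5, 5, rep(NA_real_, 6)),
    couch_dir = c(rep(NA_character_, 4), "left_BEV", "left_BEV",
                  "down_BEV", "down_BEV", "upstream", "upstream"),
    couch_mm = c(rep(NA_real_, 4), 2, 3, 2, 3, 2, 3),
    expected = c("slab_wet", "slab_wet", "slab_wet", "zero",
                 rep("from_calc", 4), "close_to_zero", "close_to_zero")
  )
}

#' Apply a deviation scenario to a phantom geometry
#'
#' Upstream-slab scenarios insert a water-equivalent slab (SPR = 1) between
#' nozzle and phantom; the downstream-slab scenario inserts it between the
#' phantom exit and the MLIC. Couch scenarios translate the phantom
#' rigidly: left in BEV is +z, down in BEV is -y, upstream is toward the
#' nozzle (-x). Detectors never move.
#'
#' @param geom A `phantom` object (the undisturbed reference geometry).
#' @param scenario A scenario id (1-10), `"reference"`, or one row of
#'   [scenario_table()].
#' @return The modified `phantom`.
#' @export
apply_scenario <- function(geom, scenario) {
  stopifnot(inherits(geom, "phantom"))
  if (is.character(scenario) && identical(scenario, "reference")) return(geom)
  if (is.numeric(scenario)) {
    tab <- scenario_table()
    if (!scenario %in% tab$id) abort(sprintf("unknown scenario id: %s", scenario))
    scenario <- tab[tab$id == scenario, ]
  }
  if (!is.data.frame(scenario) || nrow(scenario) != 1) {
    abort("`scenario` must be a scenario id, \"reference\", or one scenario row")
  }
  if (scenario$kind %in% c("AC_upstream", "AC_downstream")) {
    pos <- if (scenario$kind == "AC_upstream") "upstream" else "downstream"
    geom$slabs <- bind_rows(geom$slabs,
                            tibble(wet_mm = scenario$slab_wet_mm, spr = 1,
                                   position = pos))
  } else if (scenario$kind == "SE_couch") {
    d <- scenario$couch_mm
    shift <- switch(scenario$couch_dir,
                    left_BEV = c(x = 0, y = 0, z = d),
                    down_BEV = c(x = 0, y = -d, z = 0),
                    upstream = c(x = -d, y = 0, z = 0),
                    abort(sprintf("unknown couch direction: %s", scenario$couch_dir)))
    geom$couch_mm <- geom$couch_mm + shift
  } else {
    abort(sprintf("unknown scenario kind: %s", scenario$kind))
  }
  geom
}
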