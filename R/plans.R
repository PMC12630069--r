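## Machine limits for pencil-beam spot energies (MeV).
.energy_limits <- c(70, 230)

## Delivery calibration: lowest deliverable spot weight, 0.04 MU = 6.2e6
## protons, used as the fixed linear MU-to-proton conversion.
.protons_per_mu <- 6.2e6 / 0.04

.new_spot_plan <- function(spots, kind, range_shifter_wet_mm,
                           gantry_deg = 270, couch_deg = 0) {
  stopifnot(all(spots$energy_mev >= .energy_limits[1]),
            all(spots$energy_mev <= .energy_limits[2]),
            all(spots$protons > 0))
  structure(spots,
            class = c("spot_plan", class(tibble())),
            kind = kind,
            gantry_deg = gantry_deg, couch_deg = couch_deg,
            range_shifter_wet_mm = range_shifter_wet_mm)
}

#' Build the range-probing spot plan
#'
#' A single-energy-layer probe field: 81 spots on a 9 x 9 grid with 5 mm
#' spacing (covering 4 x 4 cm around the isocenter), 210 MeV, delivered at
#' the lowest accepted spot weight of 0.04 MU (6.2e6 protons per spot), no
#' range shifter. The high energy lets every spot traverse the phantom and
#' reach the MLIC.
#'
#' @param energy_mev Spot energy (MeV).
#' @param n_side Spots per side of the square grid.
#' @param spacing_mm Grid pitch (mm).
#' @param mu Monitor units per spot.
#' @return A `spot_plan` tibble with columns `spot_id`, `layer`,
#'   `energy_mev`, `y_mm`, `z_mm`, `protons`.
#' @examples
#' plan <- build_rp_plan()
#' nrow(plan)            # 81
#' range(plan$y_mm)      # -20 .. 20
#' @export
build_rp_plan <- function(energy_mev = 210, n_side = 9, spacing_mm = 5,
                          mu = 0.04) {
  half <- (n_side - 1) / 2 * spacing_mm
  g <- tidyr::expand_grid(y_mm = seq(-half, half, by = spacing_mm),
                          z_mm = seq(-half, half, by = spacing_mm))
  spots <- tibble(
    spot_id = seq_len(nrow(g)),
    layer = 1L,
    energy_mev = energy_mev,
    y_mm = g$y_mm, z_mm = g$z_mm,
    protons = mu * .protons_per_mu
  )
  .new_spot_plan(spots, kind = "probe", range_shifter_wet_mm = 0)
}

#' Build a synthetic treatment spot plan
#'
#' A pencil-beam scanning field with `n_layers` energy layers spanning
#' `energy_range` (default 15 layers, 115-160 MeV) behind a range shifter
#' of 73.8 mm WET, with a square spot lattice per layer covering the target
#' cross-section. The lattice replaces a clinical spot optimizer: spot
#' positions are regular and per-spot proton numbers are drawn log-
#' uniformly from `protons_range`, which straddles the minimum-statistics
#' filter threshold of the PGI pipeline (see [filter_spots()]) so that the
#' filter is exercised. Layers are ordered from highest to lowest energy,
#' as delivered clinically.
#'
#' @param n_layers Number of energy layers (>= 1).
#' @param energy_range Lowest and highest layer energy (MeV).
#' @param n_side Spots per side of the per-layer lattice.
#' @param spacing_mm Lattice pitch (mm).
#' @param protons_range Bounds of the log-uniform per-spot proton number.
#' @param range_shifter_wet_mm Range shifter water-equivalent thickness (mm).
#' @param seed Seed for the proton-number draw, so the default plan is
#'   reproducible.
#' @return A `spot_plan` tibble.
#' @export
build_treatment_plan <- function(n_layers = 15, energy_range = c(115, 160),
                                 n_side = 7, spacing_mm = 5,
                                 protons_range = c(2e7, 3e8),
                                 range_shifter_wet_mm = 73.8, seed = 1L) {
  if (n_layers < 1) abort("need at least one energy layer")
  if (n_side < 1) abort("empty target lattice")
  energies <- if (n_layers == 1) mean(energy_range) else
    seq(energy_range[2], energy_range[1], length.out = n_layers)
  half <- (n_side - 1) / 2 * spacing_mm
  g <- tidyr::expand_grid(layer = seq_len(n_layers),
                          y_mm = seq(-half, half, by = spacing_mm),
                          z_mm = seq(-half, half, by = spacing_mm))
  withr_seed <- function(expr) {  # draw without disturbing the global RNG
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  protons <- withr_seed(
    exp(runif(nrow(g), log(protons_range[1]), log(protons_range[2])))
  )
  spots <- tibble(
    spot_id = seq_len(nrow(g)),
    layer = g$layer,
    energy_mev = energies[g$layer],
    y_mm = g$y_mm, z_mm = g$z_mm,
    protons = protons
  )
  .new_spot_plan(spots, kind = "treatment",
                 range_shifter_wet_mm = range_shifter_wet_mm)
}

#' Effective range of a plan's spots in water
#'
#' Power-law range in water minus the plan's range-shifter WET; the WET a
#' spot can still penetrate downstream of the nozzle.
#'
#' @param plan A `spot_plan`.
#' @param ... Passed to [proton_range()].
#' @return Numeric vector, mm WET, one value per spot.
#' @export
plan_effective_range <- function(plan, ...) {
  proton_range(plan$energy_mev, ...) - attr(plan, "range_shifter_wet_mm")
}

#' Write / read a spot plan as CSV
#'
#' One row per spot (`layer`, `energy_mev`, `y_mm`, `z_mm`, `protons`);
#' plan-level fields travel in a `# key: value` comment header. DICOM-RT is
#' deliberately not supported.
#'
#' @param plan A `spot_plan`.
#' @param path File path.
#' @return `write_plan_csv()` returns `path` invisibly; `read_plan_csv()`
#'   returns the `spot_plan`.
#' @export
write_plan_csv <- function(plan, path) {
  hdr <- sprintf("# %s: %s",
                 c("kind", "gantry_deg", "couch_deg", "range_shifter_wet_mm"),
                 c(attr(plan, "kind"), attr(plan, "gantry_deg"),
                   attr(plan, "couch_deg"), attr(plan, "range_shifter_wet_mm")))
  writeLines(hdr, path)
  readr::write_csv(as_tibble(plan), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_plan_csv
#' @export
read_plan_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), ": "))
  meta <- setNames(kv[, 2], kv[, 1])
  spots <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  attr(spots, "spec") <- NULL
  attr(spots, "problems") <- NULL
  spots$spot_id <- as.integer(spots$spot_id)
  spots$layer <- as.integer(spots$layer)
  .new_spot_plan(spots, kind = meta[["kind"]],
                 gantry_deg = as.numeric(meta[["gantry_deg"]]),
                 couch_deg = as.numeric(meta[["couch_deg"]]),
                 range_shifter_wet_mm = as.numeric(meta[["range_shifter_wet_mm"]]))
}
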