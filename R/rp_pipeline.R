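#' Range-shift maps from paired reference / modified IDD runs
#'
#' Pairs the k-th delivery of the modified scenario with the k-th delivery
#' of the undisturbed reference (strictly index-paired, never pooled) and
#' aligns the two IDD curves of every spot by least squares, producing one
#' 2-D range-shift map (RSM) per repeat on the probe-spot BEV lattice.
#'
#' @param ref_runs,mod_runs Lists of `idd_curves` objects of equal length
#'   (one per delivery), all on the same spot lattice.
#' @param plan The probe `spot_plan` (provides the BEV positions).
#' @param cfg An [rp_match_config()].
#' @return A tibble with one row per (repeat, spot): `repeat`, `spot_id`,
#'   `y_mm`, `z_mm`, `shift_wet_mm` (positive = WET added in the patient),
#'   `flag`.
#' @export
build_rsm <- function(ref_runs, mod_runs, plan, cfg = rp_match_config()) {
  if (length(ref_runs) != length(mod_runs)) {
    abort("reference and modified run lists must have the same length")
  }
  depth <- ref_runs[[1]]$depth_mm
  for (r in c(ref_runs, mod_runs)) {
    if (!identical(r$spot_id, plan$spot_id)) {
      abort("all runs must share the plan's spot lattice")
    }
  }
  purrr::map_dfr(seq_along(ref_runs), function(k) {
    rk <- ref_runs[[k]]; mk <- mod_runs[[k]]
    res <- lapply(seq_len(nrow(plan)), function(i) {
      if (rk$flag[i] != "ok" || mk$flag[i] != "ok") {
        return(list(shift_wet_mm = NA_real_,
                    flag = if (rk$flag[i] != "ok") rk$flag[i] else mk$flag[i]))
      }
      match_idd_shift(rk$dose[, i], mk$dose[, i], depth, cfg)
    })
    tibble(
      `repeat` = k,
      spot_id = plan$spot_id,
      y_mm = plan$y_mm, z_mm = plan$z_mm,
      shift_wet_mm = vapply(res, `[[`, numeric(1), "shift_wet_mm"),
      flag = vapply(res, `[[`, character(1), "flag")
    )
  })
}

#' Full RP shift table for one scenario
#'
#' Simulates `repeats` deliveries of the probe field in the reference and
#' the modified geometry and builds the index-paired range-shift maps.
#' With `noise_on = FALSE` a single noise-free pair is simulated.
#'
#' @inheritParams pgi_scenario_shifts
#' @param cfg An [rp_match_config()].
#' @return The [build_rsm()] tibble.
#' @export
rp_scenario_shifts <- function(plan, geom_ref, geom_mod,
                               noise = noise_model(), repeats = 10,
                               seeds = NULL, noise_on = TRUE,
                               cfg = rp_match_config()) {
  if (!noise_on) repeats <- 1L
  if (is.null(seeds)) seeds <- seq_len(2 * repeats)
  stopifnot(length(seeds) >= 2 * repeats)
  ref_runs <- lapply(seq_len(repeats), function(k)
    simulate_idd(geom_ref, plan, noise, seed = seeds[k], noise_on = noise_on))
  mod_runs <- lapply(seq_len(repeats), function(k)
    simulate_idd(geom_mod, plan, noise, seed = seeds[repeats + k],
                 noise_on = noise_on))
  build_rsm(ref_runs, mod_runs, plan, cfg)
}

#' Reshape one repeat of an RSM table into a matrix
#'
#' @param rsm The tibble from [build_rsm()].
#' @param which_repeat Repeat index to extract.
#' @return A numeric matrix indexed by sorted unique `y_mm` (rows) and
#'   `z_mm` (columns).
#' @export
rsm_matrix <- function(rsm, which_repeat = 1) {
  one <- rsm[rsm$`repeat` == which_repeat, ]
  ys <- sort(unique(one$y_mm)); zs <- sort(unique(one$z_mm))
  m <- matrix(NA_real_, length(ys), length(zs), dimnames = list(ys, zs))
  m[cbind(match(one$y_mm, ys), match(one$z_mm, zs))] <- one$shift_wet_mm
  m
}
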