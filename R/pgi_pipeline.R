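#' Accumulate repeated reference deliveries into one reference profile set
#'
#' The reference measurement sums the profiles of the repeated undisturbed
#' deliveries bin-wise per spot, giving smooth high-statistics reference
#' profiles.
#'
#' @param profile_sets A list of `pgi_profiles` objects sharing the same
#'   grid and spot list.
#' @return A single `pgi_profiles` object with summed counts.
#' @export
accumulate_reference <- function(profile_sets) {
  stopifnot(length(profile_sets) >= 1)
  first <- profile_sets[[1]]
  for (p in profile_sets[-1]) {
    if (!isTRUE(all.equal(p$x_mm, first$x_mm)) ||
        !identical(p$spot_id, first$spot_id)) {
      abort("all reference deliveries must share the same grid and spot list")
    }
  }
  out <- first
  out$counts <- Reduce(`+`, lapply(profile_sets, `[[`, "counts"))
  out
}

#' Filter treatment spots for PGI evaluation
#'
#' Keeps spots that (a) delivered at least `min_protons` protons (default
#' 0.5e8, the minimum-statistics threshold) and (b) have their expected
#' fall-off inside the camera field of view with a safety margin.
#' Order-preserving.
#'
#' @param plan A `spot_plan`.
#' @param geom The reference `phantom` geometry (fall-off positions are
#'   predicted on the undisturbed geometry).
#' @param camera A [pgi_camera()].
#' @param min_protons Minimum delivered protons per spot.
#' @param fov_margin_mm Margin inside the FOV bounds (mm).
#' @return Integer vector of kept `spot_id`s.
#' @export
filter_spots <- function(plan, geom, camera = pgi_camera(),
                         min_protons = 0.5e8, fov_margin_mm = 5) {
  stopifnot(min_protons > 0)
  fo <- falloff_position(geom, plan, camera)
  keep <- !is.na(fo) &
    fo >= camera$fov[1] + fov_margin_mm &
    fo <= camera$fov[2] - fov_margin_mm &
    plan$protons >= min_protons
  plan$spot_id[keep]
}

#' In-layer 2-D Gaussian aggregation of spot profiles
#'
#' For each spot of one energy layer, replaces its profile by the
#' normalized Gaussian-weighted sum of all profiles of that layer, with
#' weights `exp(-d^2 / (2 sigma^2))` over the BEV distance d between spot
#' positions (sigma = 7.8 mm by default). Aggregation never mixes energy
#' layers. The kernel is unweighted by spot proton numbers.
#'
#' @param counts A bins x spots count matrix for the spots of one layer.
#' @param y_mm,z_mm BEV spot positions (mm), one per column of `counts`.
#' @param sigma_mm Gaussian aggregation sigma (mm).
#' @return A matrix of the same shape with aggregated profiles.
#' @export
aggregate_layer <- function(counts, y_mm, z_mm, sigma_mm = 7.8) {
  n <- ncol(counts)
  if (n == 0) abort("empty energy layer")
  stopifnot(length(y_mm) == n, length(z_mm) == n)
  d2 <- outer(y_mm, y_mm, "-")^2 + outer(z_mm, z_mm, "-")^2
  w <- exp(-d2 / (2 * sigma_mm^2))
  w <- sweep(w, 2, colSums(w), "/")
  counts %*% w
}

## Aggregate every layer of a profile set (bins x all-spots matrix) using
## the plan's layer structure; returns the full aggregated matrix.
.aggregate_all_layers <- function(counts, plan, sigma_mm = 7.8) {
  out <- counts
  for (ly in unique(plan$layer)) {
    idx <- which(plan$layer == ly)
    out[, idx] <- aggregate_layer(counts[, idx, drop = FALSE],
                                  plan$y_mm[idx], plan$z_mm[idx], sigma_mm)
  }
  out
}

#' Spot-wise PGI range shifts of one delivery against a reference
#'
#' Applies the in-layer Gaussian aggregation to both the accumulated
#' reference and the measured profile set, then extracts the geometric
#' range shift of every kept spot by least-squares fall-off matching.
#' Reported shifts are pullback-positive: a spot whose range shortened by
#' 2 mm (e.g., 2 mm WET added upstream) gets `s_geom_mm = +2 / SPR`.
#'
#' @param ref A `pgi_profiles` object (accumulated reference).
#' @param meas A `pgi_profiles` object (one delivery).
#' @param plan The `spot_plan` both sets were simulated from.
#' @param keep_ids Spot ids to evaluate (from [filter_spots()]).
#' @param sigma_mm Aggregation sigma (mm).
#' @param match_cfg A [pgi_match_config()].
#' @return A tibble: `spot_id`, `s_geom_mm`, `flag`.
#' @export
pgi_delivery_shifts <- function(ref, meas, plan, keep_ids = plan$spot_id,
                                sigma_mm = 7.8,
                                match_cfg = pgi_match_config()) {
  stopifnot(identical(ref$spot_id, plan$spot_id),
            identical(meas$spot_id, plan$spot_id))
  ref_agg <- .aggregate_all_layers(ref$counts, plan, sigma_mm)
  meas_agg <- .aggregate_all_layers(meas$counts, plan, sigma_mm)
  idx <- match(keep_ids, plan$spot_id)
  res <- lapply(idx, function(i)
    match_profile_shift(ref$x_mm, ref_agg[, i], meas_agg[, i], match_cfg))
  tibble(
    spot_id = keep_ids,
    s_geom_mm = -vapply(res, `[[`, numeric(1), "shift_mm"),
    flag = vapply(res, `[[`, character(1), "flag")
  )
}

#' Full PGI shift table for one scenario
#'
#' Simulates the repeated reference deliveries, accumulates them into the
#' reference profile set, simulates `repeats` deliveries of the modified
#' geometry, and extracts the spot-wise geometric range shifts of each
#' repeat. With `noise_on = FALSE` a single noise-free repeat is simulated.
#'
#' @param plan A `spot_plan`.
#' @param geom_ref,geom_mod Reference and modified `phantom` geometries.
#' @param camera A [pgi_camera()].
#' @param noise A [noise_model()].
#' @param repeats Number of monitored deliveries of the modified scenario
#'   (and of reference deliveries accumulated into the reference).
#' @param seeds Integer vector of per-delivery seeds, length
#'   `2 * repeats` (reference deliveries first); ignored when noise is off.
#' @param noise_on Logical.
#' @param keep_ids Spots to evaluate; defaults to [filter_spots()] on the
#'   reference geometry.
#' @param sigma_mm,match_cfg Aggregation and matching settings.
#' @param min_protons,fov_margin_mm Passed to [filter_spots()].
#' @return A tibble: `spot_id`, `repeat`, `s_geom_mm`, `flag`.
#' @export
pgi_scenario_shifts <- function(plan, geom_ref, geom_mod,
                                camera = pgi_camera(),
                                noise = noise_model(), repeats = 10,
                                seeds = NULL, noise_on = TRUE,
                                keep_ids = NULL, sigma_mm = 7.8,
                                match_cfg = pgi_match_config(),
                                min_protons = 0.5e8, fov_margin_mm = 5) {
  if (!noise_on) repeats <- 1L
  if (is.null(seeds)) seeds <- seq_len(2 * repeats)
  stopifnot(length(seeds) >= 2 * repeats)
  if (is.null(keep_ids)) {
    keep_ids <- filter_spots(plan, geom_ref, camera, min_protons,
                             fov_margin_mm)
  }
  n_ref <- if (noise_on) repeats else 1L
  refs <- lapply(seq_len(n_ref), function(k)
    simulate_pgi_profiles(geom_ref, plan, camera, noise,
                          seed = seeds[k], noise_on = noise_on))
  ref <- accumulate_reference(refs)
  purrr::map_dfr(seq_len(repeats), function(k) {
    meas <- simulate_pgi_profiles(geom_mod, plan, camera, noise,
                                  seed = seeds[repeats + k],
                                  noise_on = noise_on)
    sh <- pgi_delivery_shifts(ref, meas, plan, keep_ids, sigma_mm, match_cfg)
    sh$`repeat` <- k
    sh
  })
}
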