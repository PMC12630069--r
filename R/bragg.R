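#' Proton range in water from a power-law range-energy relation
#'
#' R = alpha * E^p with alpha in cm/MeV^p; returned in mm of water.
#' The defaults (alpha = 0.0022, p = 1.77) give 283.6 mm at 210 MeV.
#'
#' @param energy_mev Beam energy (MeV), within the machine limits
#'   70-230 MeV.
#' @param alpha,p Power-law coefficients.
#' @return Range in mm water (vectorized).
#' @export
proton_range <- function(energy_mev, alpha = 0.0022, p = 1.77) {
  if (any(energy_mev < .energy_limits[1] | energy_mev > .energy_limits[2])) {
    abort(sprintf("energy outside machine limits [%g, %g] MeV",
                  .energy_limits[1], .energy_limits[2]))
  }
  10 * alpha * energy_mev^p
}

## Analytic noise-free integral depth-dose shape in residual-range
## coordinate r = (range - depth already traversed), i.e. the remaining WET
## before the protons stop. An exponentially rising peak on a unit plateau,
## cut off at r = 0 and convolved in closed form with a Gaussian range-
## straggling kernel of width sigma:
##   f(r) = Phi(r/sigma)
##        + A * exp(sigma^2/(2 tau^2) - r/tau) * Phi(r/sigma - sigma/tau)
## Both terms are exact Gaussian convolutions of step(r) and
## step(r)*exp(-r/tau), so a change of upstream WET translates the curve
## exactly -- the property the shift matching relies on.
.idd_shape <- function(r, sigma, peak_amp = 11, tail_tau = 12) {
  pnorm(r / sigma) +
    peak_amp * exp(sigma^2 / (2 * tail_tau^2) - r / tail_tau) *
      pnorm(r / sigma - sigma / tail_tau)
}

#' Analytic Bragg curve on a depth grid
#'
#' Noise-free integral depth-dose of a pencil beam of the given energy
#' after traversing `upstream_wet` mm of water-equivalent material,
#' evaluated at water-equivalent depths `depth_mm` beyond that material.
#' The distal edge sits at `proton_range(energy) - upstream_wet`; range
#' straggling is a Gaussian of width `straggling_frac * range`.
#'
#' @inheritParams proton_range
#' @param upstream_wet Water-equivalent thickness already traversed (mm).
#' @param depth_mm Depth grid (mm water) on which to evaluate.
#' @param straggling_frac Straggling width as a fraction of the range.
#' @param peak_amp,tail_tau Shape parameters of the Bragg peak (peak-to-
#'   plateau amplitude and exponential rise length in mm).
#' @return Numeric vector of dose values (arbitrary units) on `depth_mm`.
#' @export
bragg_curve <- function(energy_mev, upstream_wet = 0, depth_mm,
                        alpha = 0.0022, p = 1.77, straggling_frac = 0.012,
                        peak_amp = 11, tail_tau = 12) {
  R <- proton_range(energy_mev, alpha, p)
  sigma <- straggling_frac * R
  .idd_shape(R - upstream_wet - depth_mm, sigma, peak_amp, tail_tau)
}

#' MLIC depth grid
#'
#' Channel-center depths of the multi-layer ionization chamber: 180
#' channels at 2 mm pitch, treated as water-equivalent depths beyond the
#' entrance window, fixed in the room frame.
#'
#' @param n_channels Number of channels.
#' @param pitch_mm Channel pitch (mm).
#' @return Numeric vector of channel-center depths (mm).
#' @export
mlic_depth_grid <- function(n_channels = 180, pitch_mm = 2) {
  (seq_len(n_channels) - 0.5) * pitch_mm
}

#' Simulate MLIC integral depth-dose curves
#'
#' Forward model of the range-probing signal: for each spot, the analytic
#' Bragg curve is evaluated with the upstream WET set to the ray-traced
#' water-equivalent path through slabs and phantom up to the MLIC entrance,
#' sampled on the 180-channel grid, and (optionally) degraded with
#' per-channel multiplicative Gaussian noise. Deterministic for a fixed
#' seed.
#'
#' Spots whose protons stop before reaching the detector are flagged
#' `"range_out"` (the infeasibility case of probing a too-thick patient);
#' spots whose Bragg peak falls outside the channel range are flagged
#' `"clipped"`; spots outside the entrance-window aperture are flagged
#' `"aperture"`. Flagged spots get all-`NA` curves.
#'
#' @param geom A `phantom` geometry.
#' @param plan A `spot_plan` (or any tibble of spots with `energy_mev`,
#'   `y_mm`, `z_mm`; the range-shifter WET is taken from the plan).
#' @param noise A [noise_model()]; set `noise_on = FALSE` for the
#'   noise-free curves.
#' @param seed Integer seed used when noise is on.
#' @param noise_on Logical.
#' @return An object of class `idd_curves`: list with the depth grid
#'   `depth_mm`, a channels x spots matrix `dose`, `spot_id`, and `flag`.
#' @export
simulate_idd <- function(geom, plan, noise = noise_model(), seed = NULL,
                         noise_on = TRUE) {
  depth <- mlic_depth_grid()
  n <- nrow(plan)
  rs <- attr(plan, "range_shifter_wet_mm")
  if (is.null(rs)) rs <- 0
  wet <- vapply(seq_len(n), function(i)
    trace_wet(geom, plan$y_mm[i], plan$z_mm[i]), numeric(1))
  R_res <- proton_range(plan$energy_mev) - rs - wet
  flag <- rep("ok", n)
  flag[R_res <= 0] <- "range_out"
  flag[flag == "ok" & (R_res < depth[3] | R_res > depth[length(depth) - 2])] <- "clipped"
  r_lat <- sqrt(plan$y_mm^2 + plan$z_mm^2)
  flag[flag == "ok" & r_lat > geom$mlic_aperture_mm / 2] <- "aperture"

  sigma <- 0.012 * proton_range(plan$energy_mev)
  dose <- outer(-depth, R_res, "+")            # residual-range coordinate
  dose <- .idd_shape(dose, sigma = rep(sigma, each = length(depth)))
  dose[, flag != "ok"] <- NA_real_
  if (noise_on && (noise$rp_sigma > 0 || noise$rp_additive > 0)) {
    if (!is.null(seed)) set.seed(seed)
    mult <- matrix(rnorm(length(dose), 0, noise$rp_sigma), nrow = length(depth))
    addn <- matrix(rnorm(length(dose), 0, noise$rp_additive), nrow = length(depth))
    dose <- dose * (1 + mult) + addn
    dose[dose < 0] <- 0
  }
  structure(list(depth_mm = depth, dose = dose,
                 spot_id = plan$spot_id, flag = flag),
            class = "idd_curves")
}
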