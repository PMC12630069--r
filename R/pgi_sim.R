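#' Detector noise model
#'
#' Free parameters of the stochastic detector models; none of them is a
#' measured property of the real systems. PGI: prompt-gamma photon yield
#' and uniform background, both per proton and per mm of track, driving
#' Poisson counting statistics; the default yield gives roughly 1e4 counts
#' per 1 mm bin in the fall-off region for a 1e8-proton spot. RP:
#' per-channel multiplicative Gaussian relative sigma and an additive
#' Gaussian floor. A zero-noise configuration reproduces the deterministic
#' curves bit-identically.
#'
#' @param pgi_yield PGI photon yield per proton per mm.
#' @param pgi_background PGI uniform background rate per proton per mm.
#' @param rp_sigma RP multiplicative relative sigma per channel.
#' @param rp_additive RP additive Gaussian sigma (dose units).
#' @return A list of rates, class `noise_model`.
#' @export
noise_model <- function(pgi_yield = 1e-4, pgi_background = 5e-6,
                        rp_sigma = 0.01, rp_additive = 0) {
  stopifnot(pgi_yield >= 0, pgi_background >= 0,
            rp_sigma >= 0, rp_additive >= 0)
  structure(list(pgi_yield = pgi_yield, pgi_background = pgi_background,
                 rp_sigma = rp_sigma, rp_additive = rp_additive),
            class = "noise_model")
}

#' PGI camera configuration
#'
#' Geometry and resolution of the knife-edge-slit camera as simulation
#' parameters. The recorded profile lives on a fixed room-frame grid of
#' `bin_mm` bins inside the field of view `fov`; the 4 mm crystal pitch of
#' the detector is modeled as Gaussian resolution (`psf_sigma_mm`) rather
#' than as binning, decoupling sampling from resolution. The prompt-gamma
#' emission fall-off precedes the dose fall-off by `delta_mm` with a
#' logistic width `falloff_width_mm` (in WET); shifts between scenarios are
#' invariant to both.
#'
#' @param fov Field-of-view bounds along the beam axis (mm, room frame).
#' @param bin_mm Profile bin width (mm).
#' @param psf_sigma_mm Gaussian point-spread sigma of the camera (mm).
#' @param delta_mm WET offset of the emission fall-off upstream of the
#'   proton range (mm).
#' @param falloff_width_mm Logistic width of the emission fall-off (mm WET).
#' @param fine_mm Internal integration grid step (mm).
#' @return A list of camera parameters.
#' @export
pgi_camera <- function(fov = c(-70, 70), bin_mm = 1, psf_sigma_mm = 5,
                       delta_mm = 2, falloff_width_mm = 1.5, fine_mm = 0.5) {
  list(fov = fov, bin_mm = bin_mm, psf_sigma_mm = psf_sigma_mm,
       delta_mm = delta_mm, falloff_width_mm = falloff_width_mm,
       fine_mm = fine_mm)
}

## Fine-grid WET and material-occupancy matrices for all spots of a plan:
## x (rows) by spots (columns). The segment structure is identical for
## every spot (only the entry-surface position varies with the lateral
## gradient), so the boundaries are computed in closed form instead of
## calling ray_segments() per spot; a unit test pins the two paths to
## each other.
.ray_wet_matrix <- function(geom, plan, x) {
  n <- nrow(plan)
  nx <- length(x)
  wet <- matrix(0, nx, n)
  occ <- matrix(FALSE, nx, n)
  add_seg <- function(x0, x1, spr) {
    ## x0, x1: scalars or per-spot vectors (recycled across the x grid)
    lo <- matrix(x0, nx, n, byrow = TRUE)
    hi <- matrix(x1, nx, n, byrow = TRUE)
    wet <<- wet + spr * pmax(0, pmin(x, hi) - lo)
    occ <<- occ | (x >= lo & x < hi)
  }
  dx <- geom$couch_mm["x"]
  t1 <- .entry_tissue_mm(geom, plan$y_mm - geom$couch_mm["y"],
                         plan$z_mm - geom$couch_mm["z"])
  if (any(t1 <= 0)) abort("a ray misses the phantom entry layer")
  thick_rest <- geom$layers$thickness_mm[-1]
  nodes <- geom$exit_x_mm + dx - rev(c(0, cumsum(rev(thick_rest))))
  add_seg(nodes[1] - t1, nodes[1], geom$layers$spr[1])
  for (i in seq_along(thick_rest)) {
    add_seg(nodes[i], nodes[i + 1], geom$layers$spr[i + 1])
  }
  up <- geom$slabs[geom$slabs$position == "upstream", , drop = FALSE]
  if (nrow(up)) {
    end <- -geom$exit_x_mm - geom$slab_gap_mm
    w <- up$wet_mm / up$spr
    x1 <- end - c(0, cumsum(w))[seq_along(w)]
    for (s in seq_along(w)) add_seg(x1[s] - w[s], x1[s], up$spr[s])
  }
  down <- geom$slabs[geom$slabs$position == "downstream", , drop = FALSE]
  if (nrow(down)) {
    start <- geom$exit_x_mm + (geom$mlic_x_mm - geom$exit_x_mm) / 2
    w <- down$wet_mm / down$spr
    x0 <- start + c(0, cumsum(w))[seq_along(w)]
    for (s in seq_along(w)) add_seg(x0[s], x0[s] + w[s], down$spr[s])
  }
  list(wet = wet, occ = occ)
}

#' Simulate prompt-gamma profiles for a set of spots
#'
#' Forward model of the PGI signal: prompt-gamma emission is a constant-
#' density plateau along the proton track wherever material is present,
#' terminated by a logistic fall-off where the accumulated WET approaches
#' the spot's effective range (range minus range-shifter WET), offset
#' upstream by `delta_mm`. The emission density is convolved with the
#' camera's Gaussian point spread and integrated over fixed room-frame
#' bins; expected counts are `protons * (yield * density + background)`
#' per mm, Poisson-sampled when noise is on.
#'
#' The profile grid never moves with the phantom, so a rigid phantom
#' translation moves the recorded fall-off by exactly the translation.
#'
#' @inheritParams simulate_idd
#' @param camera A [pgi_camera()] configuration.
#' @return An object of class `pgi_profiles`: list with bin centers `x_mm`,
#'   a bins x spots count matrix `counts`, `spot_id`, `protons`, and the
#'   `fov`.
#' @export
simulate_pgi_profiles <- function(geom, plan, camera = pgi_camera(),
                                  noise = noise_model(), seed = NULL,
                                  noise_on = TRUE) {
  if (any(plan$protons <= 0)) abort("all spots must deliver protons > 0")
  pad <- 4 * camera$psf_sigma_mm + 2
  xf <- seq(camera$fov[1] - pad, camera$fov[2] + pad, by = camera$fine_mm)
  xb <- seq(camera$fov[1] + camera$bin_mm / 2, camera$fov[2],
            by = camera$bin_mm)
  rs <- attr(plan, "range_shifter_wet_mm")
  if (is.null(rs)) rs <- 0
  R_eff <- proton_range(plan$energy_mev) - rs

  rm <- .ray_wet_matrix(geom, plan, xf)
  arg <- sweep(-rm$wet, 2, R_eff - camera$delta_mm, "+") /
    camera$falloff_width_mm
  dens <- plogis(arg) * rm$occ

  ## point-spread convolution + bin sampling in one banded matrix product
  K <- outer(xb, xf, function(a, b)
    dnorm(a - b, sd = camera$psf_sigma_mm) * camera$fine_mm)
  dens_b <- K %*% dens                               # density per mm at bins
  expect <- sweep(dens_b * noise$pgi_yield + noise$pgi_background,
                  2, plan$protons, "*") * camera$bin_mm
  counts <- expect
  if (noise_on) {
    if (!is.null(seed)) set.seed(seed)
    counts <- matrix(rpois(length(expect), lambda = expect),
                     nrow = nrow(expect))
  }
  structure(list(x_mm = xb, counts = counts, spot_id = plan$spot_id,
                 protons = plan$protons, fov = camera$fov),
            class = "pgi_profiles")
}

#' Predicted fall-off position of each spot
#'
#' Room-frame x at which a spot's accumulated WET reaches its effective
#' range minus the emission fall-off offset -- the inflection point of the
#' noise-free prompt-gamma profile. Used by the field-of-view spot filter.
#'
#' @inheritParams simulate_pgi_profiles
#' @return Numeric vector (mm), `NA` where the spot does not stop.
#' @export
falloff_position <- function(geom, plan, camera = pgi_camera()) {
  rs <- attr(plan, "range_shifter_wet_mm")
  if (is.null(rs)) rs <- 0
  R_eff <- proton_range(plan$energy_mev) - rs
  vapply(seq_len(nrow(plan)), function(i)
    .x_at_wet(geom, plan$y_mm[i], plan$z_mm[i],
              wet = R_eff[i] - camera$delta_mm), numeric(1))
}
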