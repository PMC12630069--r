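#' Noise-free expected range shifts for a scenario
#'
#' Stand-in for an independent dose calculation: runs the noise-free
#' forward model of the requested system for the reference and the
#' modified geometry and extracts the spot-wise shift with the same
#' matcher the measurement pipeline uses. For RP the ray-traced
#' water-equivalent path difference to the detector (`delta_wet_mm`) is
#' reported alongside the matched shift.
#'
#' The result serves two purposes: it is the ground truth G for the
#' setup-error scenarios, and for anatomical-change scenarios its
#' spot-median geometric shift is the denominator of the SPR conversion
#' factor (see [spr_delta_r()]).
#'
#' @param geom_ref,geom_mod Reference and modified `phantom` geometries
#'   sharing the same plan.
#' @param plan The `spot_plan` of the system.
#' @param system `"PGI"` or `"RP"`.
#' @param camera,match_cfg,sigma_mm,keep_ids PGI settings (ignored for RP).
#' @param rp_cfg RP matcher settings (ignored for PGI).
#' @return A tibble: `spot_id`, `s_geom_mm` (PGI, pullback-positive) or
#'   `shift_wet_mm` plus `delta_wet_mm` (RP), and `flag`. Matcher failures
#'   propagate as flagged spots.
#' @export
expected_shifts <- function(geom_ref, geom_mod, plan,
                            system = c("PGI", "RP"),
                            camera = pgi_camera(), sigma_mm = 7.8,
                            match_cfg = pgi_match_config(),
                            keep_ids = NULL, rp_cfg = rp_match_config()) {
  system <- match.arg(system)
  if (system == "PGI") {
    sh <- pgi_scenario_shifts(plan, geom_ref, geom_mod, camera,
                              noise_on = FALSE, keep_ids = keep_ids,
                              sigma_mm = sigma_mm, match_cfg = match_cfg)
    sh$`repeat` <- NULL
    sh
  } else {
    sh <- rp_scenario_shifts(plan, geom_ref, geom_mod, noise_on = FALSE,
                             cfg = rp_cfg)
    dw <- vapply(seq_len(nrow(plan)), function(i)
      trace_wet(geom_mod, plan$y_mm[i], plan$z_mm[i]) -
        trace_wet(geom_ref, plan$y_mm[i], plan$z_mm[i]), numeric(1))
    tibble(spot_id = plan$spot_id,
           shift_wet_mm = sh$shift_wet_mm,
           delta_wet_mm = dw,
           flag = sh$flag)
  }
}
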