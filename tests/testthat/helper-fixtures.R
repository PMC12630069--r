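## Shared small fixtures, built in code at test time.

ref_phantom <- function(...) build_phantom(phantom_config(...))

## A small treatment field (3 layers x 3 x 3 spots) for fast pipeline
## tests; spot weights fixed above the statistics filter threshold.
small_tplan <- function(n_layers = 3, n_side = 3) {
  build_treatment_plan(n_layers = n_layers, n_side = n_side,
                       protons_range = c(1e8, 1.0000001e8), seed = 1)
}

small_camera <- function() pgi_camera()

## Analytic plateau-plus-fall-off profile family used by the matcher
## oracle tests: smooth, PGI-like, and evaluable at any x, so a
## translated pair is exact by construction. The distal edge is a
## Gaussian-error-function fall-off, as produced by the camera's Gaussian
## point spread dominating the edge shape.
analytic_profile <- function(x, onset, falloff, width, amp = 1000,
                             bg = 20) {
  amp * plogis((x - onset) / 3) * pnorm(-(x - falloff) / width) + bg
}
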