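test_that("phantom construction enforces physical parameters", {
  ph <- ref_phantom()
  expect_s3_class(ph, "phantom")
  expect_equal(ph$layers$spr[ph$layers$material == "brain"], 1.04)
  expect_error(build_phantom(phantom_config(skull_mm = -1)), "thickness")
  expect_error(build_phantom(phantom_config(spr_skull = -0.2)), "ratio")
})

test_that("WET tracing is a line integral of SPR along the ray", {
  ph <- ref_phantom()
  ## nothing upstream of the phantom: zero WET before the entry surface
  entry <- -ph$exit_x_mm
  expect_equal(trace_wet(ph, x_to = entry - 1), 0)
  ## 100 mm of SPR-1 material adds exactly 100 mm WET
  ph100 <- ph
  ph100$slabs <- tibble::tibble(wet_mm = 100, spr = 1, position = "upstream")
  expect_equal(trace_wet(ph100) - trace_wet(ph), 100)
  ## traversing the brain layer (130 mm at SPR 1.04) adds 135.2 mm WET
  brain_in <- entry + sum(ph$layers$thickness_mm[1:2])
  brain_out <- brain_in + ph$layers$thickness_mm[3]
  expect_equal(trace_wet(ph, x_to = brain_out) - trace_wet(ph, x_to = brain_in),
               130 * 1.04)
})

test_that("ray tracing is additive over stacked slabs", {
  ph <- ref_phantom()
  two <- ph
  two$slabs <- tibble::tibble(wet_mm = c(1.3, 2.9), spr = 1,
                              position = "upstream")
  one <- ph
  one$slabs <- tibble::tibble(wet_mm = 4.2, spr = 1, position = "upstream")
  expect_equal(trace_wet(two, 5, -5), trace_wet(one, 5, -5))
})

test_that("zero lateral gradient gives laterally uniform WET", {
  ph <- build_phantom(phantom_config(grad_y = 0, grad_z = 0))
  w <- vapply(c(-20, -5, 0, 12), function(y) trace_wet(ph, y, y / 2),
              numeric(1))
  expect_true(all(abs(w - w[1]) < 1e-12))
})

test_that("pure beam-axis couch translation leaves the exit WET unchanged", {
  ph <- ref_phantom()
  for (sc in c(9, 10)) {
    mod <- apply_scenario(ph, sc)
    expect_equal(trace_wet(mod, 3, -7), trace_wet(ph, 3, -7), tolerance = 1e-12)
  }
})

test_that("scenario matrix reproduces the full deviation protocol", {
  tab <- scenario_table()
  expect_identical(tab$id, 1:10)
  expect_equal(tab$slab_wet_mm[1:4], c(2, 3, 5, 5))
  expect_equal(tab$kind[1:4], c(rep("AC_upstream", 3), "AC_downstream"))
  se <- tab[tab$kind == "SE_couch", ]
  expect_equal(nrow(se), 6)
  expect_equal(se$couch_mm, c(2, 3, 2, 3, 2, 3))
  expect_equal(se$couch_dir,
               rep(c("left_BEV", "down_BEV", "upstream"), each = 2))
})

test_that("applying scenarios modifies the geometry as specified", {
  ph <- ref_phantom()
  expect_identical(apply_scenario(ph, "reference"), ph)
  s3 <- apply_scenario(ph, 3)
  expect_equal(nrow(s3$slabs), 1)
  expect_equal(s3$slabs$wet_mm, 5)
  expect_equal(s3$slabs$position, "upstream")
  s9 <- apply_scenario(ph, 9)
  expect_equal(unname(s9$couch_mm), c(-2, 0, 0))
  expect_equal(nrow(s9$slabs), 0)
  expect_error(apply_scenario(ph, 11), "unknown scenario")
  ## scenario (1) adds exactly 2 mm WET along any in-field ray
  s1 <- apply_scenario(ph, 1)
  expect_equal(trace_wet(s1, -10, 10) - trace_wet(ph, -10, 10), 2)
})

test_that("couch movements move the phantom, never the detectors", {
  ph <- ref_phantom()
  s9 <- apply_scenario(ph, 9)
  expect_equal(s9$mlic_x_mm, ph$mlic_x_mm)
  ## entry surface follows the couch
  seg_ref <- ray_segments(ph)
  seg_mod <- ray_segments(s9)
  expect_equal(seg_mod$x0[1], seg_ref$x0[1] - 2)
})
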