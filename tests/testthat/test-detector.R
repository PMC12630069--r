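test_that("the range-energy relation matches an independent evaluation", {
  ## independent numeric evaluation of the power law in log space
  oracle <- 10 * 0.0022 * exp(1.77 * log(210))
  expect_equal(proton_range(210), oracle, tolerance = 1e-12)
  expect_equal(proton_range(210), 283.63, tolerance = 1e-4)
  e <- seq(80, 220, by = 10)
  expect_true(all(diff(proton_range(e)) > 0))
  expect_error(proton_range(60), "limits")
  expect_error(proton_range(250), "limits")
})

test_that("the closed-form Bragg curve equals a numeric convolution", {
  R <- proton_range(150)
  sigma <- 0.012 * R
  r_eval <- seq(-15, 60, by = 2.5)
  oracle <- numeric_idd(r_eval, sigma)
  expect_equal(protonrv:::.idd_shape(r_eval, sigma), oracle,
               tolerance = 1e-4)
})

test_that("upstream WET translates the Bragg curve exactly", {
  d <- seq(0, 200, by = 0.5)
  a <- bragg_curve(160, upstream_wet = 0, depth_mm = d + 12.5)
  b <- bragg_curve(160, upstream_wet = 12.5, depth_mm = d)
  expect_equal(a, b, tolerance = 1e-13)
})

test_that("noise-free IDD curves have the required structure", {
  ph <- ref_phantom()
  idd <- simulate_idd(ph, build_rp_plan(), noise_on = FALSE)
  expect_equal(length(idd$depth_mm), 180)
  expect_equal(unique(diff(idd$depth_mm)), 2)
  expect_true(all(idd$flag == "ok"))
  expect_true(all(idd$dose >= 0))
  ## single global maximum per curve
  n_max <- apply(idd$dose, 2, function(v) sum(v == max(v)))
  expect_true(all(n_max == 1))
})

test_that("a downstream slab shifts the IDD by exactly its WET", {
  ph <- ref_phantom()
  plan <- build_rp_plan()
  mod <- ph
  mod$slabs <- tibble::tibble(wet_mm = 4, spr = 1, position = "downstream")
  a <- simulate_idd(ph, plan, noise_on = FALSE)
  b <- simulate_idd(mod, plan, noise_on = FALSE)
  ## 4 mm = 2 channels: the modified curve is the reference two channels on
  expect_equal(b$dose[1:178, 41], a$dose[3:180, 41], tolerance = 1e-12)
})

test_that("probing flags protons that stop before the detector", {
  ph <- ref_phantom()
  plan <- build_rp_plan(energy_mev = 130)  # range 130 MeV << phantom WET
  idd <- simulate_idd(ph, plan, noise_on = FALSE)
  expect_true(all(idd$flag == "range_out"))
  expect_true(all(is.na(idd$dose)))
})

test_that("detector simulations are bit-identical for identical seeds", {
  ph <- ref_phantom()
  rplan <- build_rp_plan()
  a <- simulate_idd(ph, rplan, noise_model(), seed = 11)
  b <- simulate_idd(ph, rplan, noise_model(), seed = 11)
  expect_identical(a$dose, b$dose)
  tplan <- small_tplan()
  p1 <- simulate_pgi_profiles(ph, tplan, seed = 11)
  p2 <- simulate_pgi_profiles(ph, tplan, seed = 11)
  expect_identical(p1$counts, p2$counts)
  p3 <- simulate_pgi_profiles(ph, tplan, seed = 12)
  expect_false(identical(p1$counts, p3$counts))
})

test_that("prompt-gamma profiles are blind to downstream material", {
  ph <- ref_phantom()
  plan <- small_tplan()
  mod <- ph
  mod$slabs <- tibble::tibble(wet_mm = 30, spr = 1, position = "downstream")
  a <- simulate_pgi_profiles(ph, plan, noise_on = FALSE)
  b <- simulate_pgi_profiles(mod, plan, noise_on = FALSE)
  expect_identical(a$counts, b$counts)
})

test_that("an upstream phantom translation moves the fall-off rigidly", {
  ph <- ref_phantom()
  plan <- small_tplan()
  mod <- ph
  mod$couch_mm["x"] <- -3   # 3 mm toward the nozzle
  a <- simulate_pgi_profiles(ph, plan, noise_on = FALSE)
  b <- simulate_pgi_profiles(mod, plan, noise_on = FALSE)
  ## profile translated by -3 mm on the fixed room grid (away from edges)
  i <- which(a$x_mm >= -50 & a$x_mm <= 50)
  expect_equal(b$counts[i - 3, ], a$counts[i, ], tolerance = 1e-9)
})

test_that("expected counts scale linearly with delivered protons", {
  ph <- ref_phantom()
  plan <- small_tplan()
  plan2 <- plan
  plan2$protons <- 2 * plan$protons
  a <- simulate_pgi_profiles(ph, plan, noise_on = FALSE)
  b <- simulate_pgi_profiles(ph, plan2, noise_on = FALSE)
  expect_equal(b$counts, 2 * a$counts, tolerance = 1e-12)
})

test_that("PGI counting noise is Poisson", {
  ph <- ref_phantom()
  plan <- build_treatment_plan(n_layers = 1, n_side = 1,
                               protons_range = c(1e8, 1.0000001e8))
  cam <- pgi_camera(fov = c(-20, 20))
  draws <- vapply(1:1000, function(k)
    simulate_pgi_profiles(ph, plan, cam, seed = k)$counts[, 1],
    numeric(40))
  mn <- rowMeans(draws)
  vr <- apply(draws, 1, var)
  keep <- mn >= 50
  expect_true(sum(keep) > 10)
  expect_true(all(vr[keep] / mn[keep] > 0.9 & vr[keep] / mn[keep] < 1.1))
})
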