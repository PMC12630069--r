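test_that("the SPR conversion factor is the slab-to-shift quotient", {
  expect_equal(spr_delta_r(5, 5), 1)
  expect_equal(spr_delta_r(5, 4.8), 1.0416667, tolerance = 1e-7)
  expect_error(spr_delta_r(2, 0), "nonzero")
  expect_error(spr_delta_r(2, -1.9), "same sign")
})

test_that("geometric shifts convert to WET by the mode's SPR", {
  expect_equal(geom_to_wet(1.0, mode = "SE"), 1.04)
  expect_equal(geom_to_wet(0, mode = "SE"), 0)
  expect_equal(geom_to_wet(4.8, mode = "AC", spr_factor = spr_delta_r(5, 4.8)),
               5)
  expect_error(geom_to_wet(1, mode = "AC"), "spr_factor")
})

test_that("geom-to-WET round trip is exact", {
  set.seed(7)
  for (k in 1:50) {
    w <- runif(1, 0.5, 8)
    g <- runif(1, 0.5, 8)
    expect_equal(geom_to_wet(g, "AC", spr_factor = spr_delta_r(w, g)),
                 w, tolerance = 1e-14)
  }
})

test_that("spot summaries use median, unbiased variance, floored weights", {
  tab <- function(vals, flags = rep("ok", length(vals)))
    tibble::tibble(spot_id = 1L, `repeat` = seq_along(vals),
                   shift_wet_mm = vals, flag = flags)
  ## repeats agreeing exactly: variance floored
  s <- summarize_spots(tab(rep(1, 10)))
  expect_equal(s$m_mm, 1)
  expect_equal(s$var_mm2, 0)
  expect_equal(s$w, 1e4)
  ## two-point case
  s <- summarize_spots(tab(c(0, 2)))
  expect_equal(s$m_mm, 1)
  expect_equal(s$var_mm2, 2)
  expect_equal(s$w, 0.5)
  ## flagged repeats are dropped from the summary
  vals <- c(1, 2, 3, 4, 5, 6, 7, NA, NA, NA)
  flags <- c(rep("ok", 7), rep("no_falloff", 3))
  s <- summarize_spots(tab(vals, flags))
  expect_equal(s$n_valid, 7)
  expect_equal(s$m_mm, 4)
  ## fewer than two valid repeats of a repeated run: flagged out
  s <- summarize_spots(tab(c(1, rep(NA, 9)), c("ok", rep("boundary", 9))))
  expect_true(is.na(s$m_mm))
  ## a deliberate single-delivery run keeps its spot
  s <- summarize_spots(tab(2.5))
  expect_equal(s$m_mm, 2.5)
  expect_equal(s$w, 1e4)
})

test_that("weighted scenario statistics implement the estimator", {
  mk <- function(m, w) tibble::tibble(spot_id = seq_along(m), n_valid = 10,
                                      m_mm = m, var_mm2 = 1 / w, w = w)
  st <- weighted_stats(mk(c(2, 4), c(1, 1)), g = 0)
  expect_equal(st$mu_hat_mm, 3)
  expect_equal(st$sigma2_hat_mm2, 2)
  expect_equal(st$accuracy_mm, 3)
  st <- weighted_stats(mk(c(0, 4), c(1, 3)), g = 3)
  expect_equal(st$mu_hat_mm, 3)
  expect_equal(st$accuracy_mm, 0)
  expect_error(weighted_stats(mk(2, 1), g = 0), "two valid spots")
  ## agreement with the naive formula transcription on random input
  set.seed(31)
  m <- rnorm(40); w <- runif(40, 0.2, 5)
  st <- weighted_stats(mk(m, w), g = 0.3)
  o <- naive_weighted_stats(m, w, 0.3)
  expect_equal(st$mu_hat_mm, unname(o["mu"]))
  expect_equal(st$sigma2_hat_mm2, unname(o["sigma2"]))
})

test_that("equal weights reduce the weighted variance to the sample variance", {
  set.seed(12)
  for (n in c(3, 10, 81)) {
    m <- rnorm(n, sd = 2)
    s <- tibble::tibble(spot_id = seq_len(n), n_valid = 10, m_mm = m,
                        var_mm2 = 1, w = rep(2.7, n))
    st <- weighted_stats(s, g = 0)
    expect_equal(st$sigma2_hat_mm2, var(m), tolerance = 1e-14)
  }
})

test_that("the weighted statistics are scale equivariant", {
  set.seed(5)
  m <- rnorm(20); w <- runif(20, 0.5, 2); g <- 0.7; c_ <- 3.7
  mk <- function(m, w) tibble::tibble(spot_id = seq_along(m), n_valid = 10,
                                      m_mm = m, var_mm2 = 1 / w, w = w)
  a <- weighted_stats(mk(m, w), g)
  b <- weighted_stats(mk(c_ * m, w), c_ * g)
  expect_equal(b$mu_hat_mm, c_ * a$mu_hat_mm)
  expect_equal(b$accuracy_mm, c_ * a$accuracy_mm)
  expect_equal(b$sigma2_hat_mm2, c_^2 * a$sigma2_hat_mm2)
})

test_that("boxplot statistics follow the 1.5 IQR outlier rule", {
  b <- iqr_box_stats(c(1, 2, 3, 4, 100))
  expect_equal(b$outliers, 100)
  expect_equal(b$whisker_hi, 4)
  ## against the base-graphics convention on random data
  set.seed(9)
  v <- c(rnorm(50), 8, -6)
  b <- iqr_box_stats(v)
  o <- grDevices::boxplot.stats(v, coef = 1.5, do.conf = FALSE)
  expect_equal(sort(b$outliers), sort(o$out))
  expect_equal(b$median, o$stats[3])
  ## symmetric values: median centered in the box
  b <- iqr_box_stats(c(-2, -1, 0, 1, 2))
  expect_equal(b$median - b$q1, b$q3 - b$median)
})
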