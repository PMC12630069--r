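reduced_cfg <- function(seed = 99, ...) {
  experiment_config(treatment = list(n_layers = 2, n_side = 2),
                    scenarios = c(1, 9), repeats = 2, seed = seed, ...)
}

test_that("a full experiment run produces coherent result tables", {
  res <- run_experiment(reduced_cfg(), quiet = TRUE)
  expect_s3_class(res, "rv_experiment")
  expect_setequal(unique(res$stats$scenario), c(1, 9))
  expect_setequal(unique(res$stats$system), c("PGI", "RP"))
  expect_equal(nrow(res$stats), 4)
  ## every (scenario, system) has repeats x spots shift rows
  counts <- dplyr::count(res$shifts, scenario, system)
  expect_true(all(counts$n[counts$system == "RP"] == 2 * 81))
  ## the slab scenario: both systems near 2 mm WET
  st <- res$stats
  expect_equal(st$mu_hat_mm[st$scenario == 1 & st$system == "RP"], 2,
               tolerance = 0.1)
  expect_equal(st$mu_hat_mm[st$scenario == 1 & st$system == "PGI"], 2,
               tolerance = 0.1)
  ## broom-style accessors
  expect_identical(tidy(res), res$summaries)
  expect_identical(glance(res), res$stats)
})

test_that("identical configuration and seed reproduce results bit-identically", {
  a <- run_experiment(reduced_cfg(), quiet = TRUE)
  b <- run_experiment(reduced_cfg(), quiet = TRUE)
  expect_identical(a$shifts, b$shifts)
  expect_identical(a$stats, b$stats)
  c_ <- run_experiment(reduced_cfg(seed = 100), quiet = TRUE)
  expect_false(identical(a$shifts$shift_wet_mm, c_$shifts$shift_wet_mm))
})

test_that("a single noise-free delivery still yields statistics", {
  cfg <- reduced_cfg(noise_on = FALSE)
  res <- run_experiment(cfg, quiet = TRUE)
  expect_true(all(res$summaries$var_mm2 == 0))
  expect_true(all(res$summaries$w == 1 / cfg$var_floor))
  expect_equal(nrow(res$stats), 4)
})

test_that("results survive the CSV round trip and reject alien files", {
  res <- run_experiment(reduced_cfg(), quiet = TRUE)
  dir <- withr::local_tempdir()
  write_experiment(res, dir)
  back <- read_experiment(dir)
  expect_equal(as.data.frame(back$shifts), as.data.frame(res$shifts),
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$stats), as.data.frame(res$stats),
               tolerance = 1e-12)
  expect_equal(back$manifest$seed, res$manifest$seed)
  ## NA shifts (flagged spots) survive
  tab <- tibble::tibble(spot_id = 1:2, shift_wet_mm = c(NA, 1),
                        flag = c("no_falloff", "ok"))
  p <- file.path(dir, "t.csv")
  write_result_csv(tab, p)
  expect_equal(read_result_csv(p)$shift_wet_mm, c(NA, 1))
  ## schema-version mismatch reports both versions
  writeLines(c("# schema: protonrv-csv-0", "a,b", "1,2"), p)
  expect_error(read_result_csv(p), "protonrv-csv-0.*protonrv-csv-1")
  writeLines("a,b", p)
  expect_error(read_result_csv(p), "schema header")
})

test_that("experiment configurations round trip through YAML", {
  cfg <- reduced_cfg(noise = noise_model(rp_sigma = 0.02))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config_yaml(cfg, path)
  back <- read_config_yaml(path)
  expect_equal(back$scenarios, cfg$scenarios)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$noise$rp_sigma, 0.02)
  expect_equal(back$treatment, cfg$treatment)
  ## and a re-run from the re-read config is bit-identical
  expect_identical(run_experiment(back, quiet = TRUE)$shifts,
                   run_experiment(cfg, quiet = TRUE)$shifts)
})

test_that("seed fan-out is deterministic, bounded, and collision-free", {
  seeds <- unlist(lapply(c("PGI", "RP"), function(sys)
    lapply(0:10, function(sc) vapply(1:10, function(k)
      child_seed(123, sys, sc, k), integer(1)))))
  expect_true(all(seeds > 0 & seeds < 2^31))
  expect_equal(length(unique(seeds)), length(seeds))
  expect_identical(child_seed(123, "PGI", 3, 2), child_seed(123, "PGI", 3, 2))
})

test_that("reports and plots assemble without missing scenarios", {
  res <- run_experiment(reduced_cfg(), quiet = TRUE)
  rep_ <- compare_report(res)
  expect_length(rep_$missing, 0)
  expect_equal(nrow(rep_$box_data), 4)
  rep2 <- compare_report(res, scenarios = c(1, 5, 9))
  expect_equal(rep2$missing, 5)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  p2 <- plot_rsm(res, 1)
  expect_s3_class(p2, "ggplot")
})
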