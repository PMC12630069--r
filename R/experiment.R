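#' Experiment configuration
#'
#' Bundles every knob of the virtual experiment: phantom, plans, detector
#' noise, the scenario subset, the number of monitored deliveries per
#' scenario (10, matching the experimental protocol), and the master seed.
#' A configuration can be written to and re-read from YAML and re-run
#' bit-identically.
#'
#' @param phantom A [phantom_config()].
#' @param treatment Arguments for [build_treatment_plan()] (list).
#' @param rp Arguments for [build_rp_plan()] (list).
#' @param camera A [pgi_camera()].
#' @param noise A [noise_model()].
#' @param scenarios Integer subset of scenario ids (1-10).
#' @param repeats Deliveries per scenario and of the reference (>= 1).
#' @param seed Master seed; every random draw derives from it.
#' @param noise_on Simulate detector noise (`FALSE` gives the
#'   deterministic noise-free experiment).
#' @param var_floor Variance floor for the spot weights (mm^2).
#' @param sigma_agg_mm PGI in-layer aggregation sigma (mm).
#' @param min_protons,fov_margin_mm PGI spot-filter settings.
#' @return A list of class `rv_config`.
#' @export
experiment_config <- function(phantom = phantom_config(),
                              treatment = list(), rp = list(),
                              camera = pgi_camera(),
                              noise = noise_model(),
                              scenarios = 1:10, repeats = 10,
                              seed = 1L, noise_on = TRUE,
                              var_floor = 1e-4, sigma_agg_mm = 7.8,
                              min_protons = 0.5e8, fov_margin_mm = 5) {
  stopifnot(repeats >= 1, all(scenarios %in% 1:10))
  structure(list(phantom = phantom, treatment = treatment, rp = rp,
                 camera = camera, noise = noise, scenarios = scenarios,
                 repeats = repeats, seed = as.integer(seed),
                 noise_on = noise_on, var_floor = var_floor,
                 sigma_agg_mm = sigma_agg_mm, min_protons = min_protons,
                 fov_margin_mm = fov_margin_mm),
            class = "rv_config")
}

#' @rdname experiment_config
#' @param cfg An `rv_config`.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(rapply(cfg, identity, how = "replace")), path)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- experiment_config()
  for (nm in names(raw)) {
    if (nm %in% c("camera", "noise", "phantom")) {
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$scenarios <- as.integer(unlist(cfg$scenarios))
  class(cfg$noise) <- "noise_model"
  cfg
}

#' Deterministic child seed from the master seed
#'
#' Counter-based fan-out: every (system, scenario, delivery) gets its own
#' seed derived arithmetically from the master seed, so running a subset
#' of scenarios never changes the draws of the others. Scenario 0 denotes
#' the undisturbed reference. Seeds stay below 2^31.
#'
#' @param master Master seed (integer).
#' @param system `"PGI"` or `"RP"`.
#' @param scenario Scenario id (0 = reference).
#' @param rep Delivery index.
#' @return An integer seed.
#' @export
child_seed <- function(master, system, scenario, rep) {
  sys_idx <- match(system, c("PGI", "RP"))
  m <- 2147483629
  as.integer(((as.numeric(master) %% m) * 1000003 + sys_idx * 7207201 +
                as.numeric(scenario) * 524287 + as.numeric(rep) * 8191) %% m) + 1L
}

## Simple deterministic fingerprint of a serialized configuration (for the
## run manifest; not cryptographic).
.config_fingerprint <- function(cfg) {
  s <- yaml::as.yaml(rapply(cfg, identity, how = "replace"))
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", h)
}

## Ground truth G (WET mm) and the WET conversion for one PGI scenario.
.pgi_wet_conversion <- function(shifts, scen, calc, spr_brain) {
  med_calc <- median(calc$s_geom_mm[calc$flag == "ok"], na.rm = TRUE)
  if (scen$kind == "AC_upstream" && abs(med_calc) > 0.05) {
    sprf <- spr_delta_r(scen$slab_wet_mm, med_calc)
    list(wet = shifts$s_geom_mm * sprf, g = scen$slab_wet_mm, sprf = sprf)
  } else if (scen$kind %in% c("AC_upstream", "AC_downstream")) {
    ## downstream slab (or degenerate calc): no Bragg-peak shift to
    ## calibrate on; fall back to the brain SPR. G = 0: the slab does not
    ## affect the monitored field.
    g <- if (scen$kind == "AC_downstream") 0 else scen$slab_wet_mm
    list(wet = shifts$s_geom_mm * spr_brain, g = g, sprf = NA_real_)
  } else {
    g <- median(calc$s_geom_mm[calc$flag == "ok"], na.rm = TRUE) * spr_brain
    list(wet = shifts$s_geom_mm * spr_brain, g = g, sprf = NA_real_)
  }
}

#' Run the full virtual comparison experiment
#'
#' Simulates the undisturbed reference and every requested deviation
#' scenario for both verification systems (`repeats` monitored deliveries
#' each), runs both evaluation pipelines, converts PGI geometric shifts to
#' WET, and assembles per-spot summaries and per-scenario weighted
#' accuracy/precision statistics.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Optional directory; when given, shift tables, summaries,
#'   statistics, and a manifest are written there (see
#'   [write_experiment()]).
#' @param quiet Suppress the per-scenario log lines.
#' @return An object of class `rv_experiment`: list with `shifts` (per
#'   spot and repeat, both systems), `summaries` (per spot), `stats` (per
#'   scenario and system: N, mu_hat, sigma_hat, G, A), the plans, the
#'   configuration, and a run manifest.
#' @export
run_experiment <- function(cfg = experiment_config(), out_dir = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(cfg, "rv_config"))
  geom_ref <- build_phantom(cfg$phantom)
  tplan <- do.call(build_treatment_plan, cfg$treatment)
  rplan <- do.call(build_rp_plan, cfg$rp)
  spr_brain <- cfg$phantom$spr_brain
  scen_tab <- scenario_table()
  scen_tab <- scen_tab[scen_tab$id %in% cfg$scenarios, ]
  keep_ids <- filter_spots(tplan, geom_ref, cfg$camera, cfg$min_protons,
                           cfg$fov_margin_mm)
  reps <- if (cfg$noise_on) cfg$repeats else 1L

  ## reference deliveries, shared by all scenarios
  pgi_refs <- lapply(seq_len(reps), function(k)
    simulate_pgi_profiles(geom_ref, tplan, cfg$camera, cfg$noise,
                          seed = child_seed(cfg$seed, "PGI", 0, k),
                          noise_on = cfg$noise_on))
  pgi_ref <- accumulate_reference(pgi_refs)
  rp_refs <- lapply(seq_len(reps), function(k)
    simulate_idd(geom_ref, rplan, cfg$noise,
                 seed = child_seed(cfg$seed, "RP", 0, k),
                 noise_on = cfg$noise_on))

  shifts <- list(); stats <- list()
  for (i in seq_len(nrow(scen_tab))) {
    scen <- scen_tab[i, ]
    geom_mod <- apply_scenario(geom_ref, scen)

    ## ---- PGI ----
    calc <- expected_shifts(geom_ref, geom_mod, tplan, "PGI",
                            camera = cfg$camera, sigma_mm = cfg$sigma_agg_mm,
                            keep_ids = keep_ids)
    pgi <- purrr::map_dfr(seq_len(reps), function(k) {
      meas <- simulate_pgi_profiles(geom_mod, tplan, cfg$camera, cfg$noise,
                                    seed = child_seed(cfg$seed, "PGI", scen$id, k),
                                    noise_on = cfg$noise_on)
      sh <- pgi_delivery_shifts(pgi_ref, meas, tplan, keep_ids,
                                cfg$sigma_agg_mm)
      sh$`repeat` <- k
      sh
    })
    conv <- .pgi_wet_conversion(pgi, scen, calc, spr_brain)
    pgi <- mutate(pgi, scenario = scen$id, system = "PGI",
                  shift_wet_mm = conv$wet)
    sum_pgi <- summarize_spots(pgi, var_floor = cfg$var_floor)
    st_pgi <- weighted_stats(sum_pgi, g = conv$g)

    ## ---- RP ----
    mod_runs <- lapply(seq_len(reps), function(k)
      simulate_idd(geom_mod, rplan, cfg$noise,
                   seed = child_seed(cfg$seed, "RP", scen$id, k),
                   noise_on = cfg$noise_on))
    rp <- build_rsm(rp_refs, mod_runs, rplan)
    g_rp <- if (scen$kind %in% c("AC_upstream", "AC_downstream")) {
      scen$slab_wet_mm
    } else {
      calc_rp <- expected_shifts(geom_ref, geom_mod, rplan, "RP")
      median(calc_rp$shift_wet_mm[calc_rp$flag == "ok"], na.rm = TRUE)
    }
    rp <- mutate(rp, scenario = scen$id, system = "RP")
    sum_rp <- summarize_spots(rp, var_floor = cfg$var_floor)
    st_rp <- weighted_stats(sum_rp, g = g_rp)

    shifts[[i]] <- bind_rows(
      select(pgi, "scenario", "system", "spot_id", "repeat",
             "s_geom_mm", "shift_wet_mm", "flag"),
      mutate(select(rp, "scenario", "system", "spot_id", "repeat",
                    "shift_wet_mm", "flag"), s_geom_mm = NA_real_)
    )
    stats[[i]] <- bind_rows(
      mutate(st_pgi, scenario = scen$id, system = "PGI",
             spr_delta_r = conv$sprf),
      mutate(st_rp, scenario = scen$id, system = "RP",
             spr_delta_r = NA_real_)
    )
    if (!quiet) {
      for (j in 1:2) {
        s <- stats[[i]][j, ]
        message(sprintf(
          "scenario %2d [%s] %-3s N=%3d mu=%+.3f mm sigma=%.3f mm G=%+.3f mm A=%+.3f mm",
          scen$id, scen$label, s$system, s$n, s$mu_hat_mm, s$sigma_hat_mm,
          s$g_mm, s$accuracy_mm))
      }
    }
  }

  shifts <- bind_rows(shifts)
  stats <- select(bind_rows(stats), "scenario", "system", dplyr::everything())
  summaries <- shifts |>
    group_by(.data$scenario, .data$system) |>
    dplyr::group_modify(~ summarize_spots(.x, var_floor = cfg$var_floor)) |>
    ungroup()
  res <- structure(list(
    shifts = shifts, summaries = summaries, stats = stats,
    treatment_plan = tplan, rp_plan = rplan, kept_spots = keep_ids,
    config = cfg,
    manifest = list(
      package_version = as.character(utils::packageVersion("protonrv")),
      r_version = as.character(getRversion()),
      seed = cfg$seed,
      config_fingerprint = .config_fingerprint(cfg),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  ), class = "rv_experiment")
  if (!is.null(out_dir)) write_experiment(res, out_dir)
  res
}

#' @export
print.rv_experiment <- function(x, ...) {
  cat(sprintf("<rv_experiment> %d scenario(s), %d repeats, seed %d\n",
              length(unique(x$shifts$scenario)), x$config$repeats,
              x$config$seed))
  print(as.data.frame(x$stats), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write / read experiment results
#'
#' Persists the shift tables, per-spot summaries, and per-scenario
#' statistics as schema-versioned CSV files plus a JSON manifest.
#' `read_experiment()` restores them field-wise identically.
#'
#' @param res An `rv_experiment`.
#' @param out_dir Output directory (created if needed).
#' @return `write_experiment()` returns `out_dir` invisibly;
#'   `read_experiment()` returns a list of the tables and the manifest.
#' @export
write_experiment <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_result_csv(res$shifts, file.path(out_dir, "shifts.csv"))
  write_result_csv(res$summaries, file.path(out_dir, "spot_summaries.csv"))
  write_result_csv(res$stats, file.path(out_dir, "scenario_stats.csv"))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(out_dir) {
  list(
    shifts = read_result_csv(file.path(out_dir, "shifts.csv")),
    summaries = read_result_csv(file.path(out_dir, "spot_summaries.csv")),
    stats = read_result_csv(file.path(out_dir, "scenario_stats.csv")),
    manifest = jsonlite::read_json(file.path(out_dir, "manifest.json"),
                                   simplifyVector = TRUE)
  )
}

.schema_version <- "protonrv-csv-1"

#' Schema-versioned CSV round trip for result tables
#'
#' Tables are written with a `# schema:` header line; reading a file with
#' a different schema version fails with both versions reported, and a
#' truncated or alien file fails with an explicit parse error. `NA` shift
#' values (flagged spots) survive the round trip.
#'
#' @param x A result tibble.
#' @param path File path.
#' @return `read_result_csv()` returns the tibble.
#' @export
write_result_csv <- function(x, path) {
  writeLines(sprintf("# schema: %s", .schema_version), path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_result_csv
#' @export
read_result_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# schema: ")) {
    abort(sprintf("not a protonrv result file (missing schema header): %s", path))
  }
  ver <- sub("^# schema: ", "", first)
  if (!identical(ver, .schema_version)) {
    abort(sprintf("schema version mismatch: file has '%s', package expects '%s'",
                  ver, .schema_version))
  }
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         na = "NA")
  attr(out, "spec") <- NULL
  attr(out, "problems") <- NULL
  out
}

#' @export
tidy.rv_experiment <- function(x, ...) x$summaries

#' @export
glance.rv_experiment <- function(x, ...) x$stats
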