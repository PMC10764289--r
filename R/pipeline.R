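# Run configuration and staged pipeline driver. Every stage reads its inputs
# from the previous stage's files, so a run is auditable and restartable; a
# manifest records the configuration, its hash, the seeds and every artifact.

#' Default run configuration
#'
#' All tunables of a full synthetic-data run with their documented defaults:
#' detection geometry, calibration dye settings, correlator settings, the
#' binding mixture under study, exclusion rule, FLIM settings and reporter
#' grid. Values mirror one FCCS/FLIM measurement session: 10-s recordings,
#' reference dyes at two dilutions per channel with a known 400 um^2/s
#' diffusion coefficient, and a 2,000 nM concentration exclusion.
#'
#' @return a nested list of settings.
#' @export
default_config <- function() {
  list(
    seed = 1,
    output_dir = "fccsfret-run",
    geometry = list(waist_green = 0.2, axial_green = 0.6,
                    waist_red = 0.2, axial_red = 0.6,
                    box_side = 2.0),
    calibration = list(dye_diffusion = 400,
                       green_concentrations = c(3, 6),
                       red_concentrations = c(4, 8),
                       dye_brightness = 50000, box_side = 6,
                       triplet_fraction = 0.03, triplet_tau = 2,
                       bin_width = 2, duration = 10),
    correlator = list(m = 16, n_segments = 10),
    fccs = list(total_green = 300, total_red = 300, kd_true = 440,
                n_measurements = 20, bin_width = 50, duration = 10,
                diffusion_free = 4, diffusion_complex = 2.5,
                brightness_green = 4000, brightness_red = 4000,
                triplet_fraction = 0.15, triplet_tau = 5),
    exclusion = list(threshold = 2000, rule = "either"),
    flim = list(donor_lifetime = 2.5, efficiency_true = 0.1092,
                n_photons = 1e5, irf_sigma = 0.1,
                n_donor = 10, n_roi = 10),
    forster_r0 = 52.4,
    ktr = list(threshold = 1, n_rows = 11, n_cols = 16,
               activity = c("1" = 0.8, "2" = 0.8, "3" = 0.8, "4" = 0.8,
                            "5" = 0.8, "6" = 0.1, "7" = 0.1),
               max_rows = 5),
    kd_bin_edges = c(0, 200, 400, 600, 800, 1600)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML file (or takes a list), merges it over [default_config()]
#' and rejects unknown keys at both nesting levels so typos never silently
#' fall back to defaults.
#'
#' @param x path to a YAML file, a list of overrides, or `NULL` for the
#'   defaults.
#' @return validated configuration list of class `run_config`.
#' @examples
#' cfg <- run_config(system.file("extdata", "demo_config.yaml",
#'                               package = "fccsfret"))
#' cfg$fccs$kd_true
#' @export
run_config <- function(x = NULL) {
  defaults <- default_config()
  overrides <- if (is.null(x)) {
    list()
  } else if (is.character(x)) {
    yaml::read_yaml(x)
  } else if (is.list(x)) {
    x
  } else {
    stop("config must be a path, a list, or NULL")
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(overrides)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      bad <- setdiff(names(overrides[[k]]), names(defaults[[k]]))
      if (length(bad)) {
        stop("unknown config key(s): ",
             paste(paste0(k, "$", bad), collapse = ", "))
      }
    }
  }
  cfg <- modifyList(defaults, overrides)
  stopifnot(cfg$exclusion$threshold > 0, cfg$forster_r0 > 0,
            cfg$correlator$m >= 1, cfg$fccs$n_measurements >= 1)
  class(cfg) <- c("run_config", "list")
  cfg
}

# stable small hash (djb2 over the canonical JSON encoding, mod 2^31 - 1);
# output paths are excluded so the same scientific configuration hashes
# identically wherever it is run
.config_hash <- function(x) {
  x <- unclass(x)
  x$output_dir <- NULL
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

.file_hash <- function(paths) {
  h <- 5381
  for (p in sort(paths)) {
    for (b in as.integer(readBin(p, "raw", file.info(p)$size))) {
      h <- (h * 33 + b) %% 2147483647
    }
  }
  sprintf("%08x", h)
}

.geometry_volumes <- function(cfg) {
  list(green = detection_volume(cfg$geometry$waist_green,
                                cfg$geometry$axial_green, "green"),
       red = detection_volume(cfg$geometry$waist_red,
                              cfg$geometry$axial_red, "red"))
}

.need <- function(paths, stage) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop(sprintf("missing upstream artifact(s) for stage '%s': %s",
                 stage, paste(missing, collapse = ", ")))
  }
  invisible(paths)
}

.stage_simulate <- function(cfg, dir) {
  vols <- .geometry_volumes(cfg)
  files <- character(0)
  # reference dye dilution series, both channels
  cal <- cfg$calibration
  i <- 0
  for (ch in c("green", "red")) {
    concs <- if (ch == "green") cal$green_concentrations
    else cal$red_concentrations
    for (conc in concs) {
      i <- i + 1
      box <- simulation_box(cal$box_side, cal$bin_width,
                            cal$duration, child_seed(cfg$seed, i))
      tr <- simulate_dye_trace(conc, ch, vols$green, vols$red, box,
                               diffusion = cal$dye_diffusion,
                               brightness = cal$dye_brightness,
                               triplet_fraction = cal$triplet_fraction,
                               triplet_tau = cal$triplet_tau)
      f <- file.path(dir, sprintf("dye_%s_%gnM.txt", ch, conc))
      write_trace(tr, f)
      files <- c(files, f)
    }
  }
  # sample mixture traces
  fc <- cfg$fccs
  mix <- equilibrium_mixture(
    fc$total_green, fc$total_red, fc$kd_true,
    diffusion = c(free_green = fc$diffusion_free,
                  free_red = fc$diffusion_free,
                  complex = fc$diffusion_complex),
    brightness_green = fc$brightness_green,
    brightness_red = fc$brightness_red,
    triplet_fraction = fc$triplet_fraction, triplet_tau = fc$triplet_tau)
  for (k in seq_len(fc$n_measurements)) {
    box <- simulation_box(cfg$geometry$box_side, fc$bin_width, fc$duration,
                          child_seed(cfg$seed, 100 + k))
    tr <- simulate_fccs_trace(mix, vols$green, vols$red, box)
    f <- file.path(dir, sprintf("sample_%03d.txt", k))
    write_trace(tr, f)
    files <- c(files, f)
  }
  truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(mixture = unclass(mix)[c(
    "total_green", "total_red", "kd_true", "free_green", "free_red",
    "complex")], seed = cfg$seed), truth, auto_unbox = TRUE, digits = NA)
  files <- c(files, truth)
  # TCSPC decay sets
  fl <- cfg$flim
  tau_da <- fl$donor_lifetime * (1 - fl$efficiency_true)
  for (k in seq_len(fl$n_donor)) {
    dec <- simulate_tcspc(list(c(1, fl$donor_lifetime)), fl$n_photons,
                          fl$irf_sigma, seed = child_seed(cfg$seed, 200 + k))
    f <- file.path(dir, sprintf("decay_donor_%02d.txt", k))
    write_decay(dec, f)
    files <- c(files, f)
  }
  for (k in seq_len(fl$n_roi)) {
    dec <- simulate_tcspc(list(c(1, tau_da)), fl$n_photons, fl$irf_sigma,
                          seed = child_seed(cfg$seed, 300 + k))
    f <- file.path(dir, sprintf("decay_roi_%02d.txt", k))
    write_decay(dec, f)
    files <- c(files, f)
  }
  # reporter cell grid
  kt <- cfg$ktr
  clone_rows <- seq_len(min(2, kt$n_rows))
  clone <- as.matrix(expand.grid(row = clone_rows, col = seq_len(kt$n_cols)))
  grid <- generate_cell_grid(kt$n_rows, kt$n_cols, clone, kt$activity,
                             seed = child_seed(cfg$seed, 400),
                             threshold = kt$threshold)
  f <- file.path(dir, "cell_grid.csv")
  write.table(as.data.frame(grid), f, sep = ",", row.names = FALSE)
  files <- c(files, f)
  files
}

.stage_calibrate <- function(cfg, dir) {
  cal <- cfg$calibration
  gfiles <- file.path(dir, sprintf("dye_green_%gnM.txt",
                                   cal$green_concentrations))
  rfiles <- file.path(dir, sprintf("dye_red_%gnM.txt",
                                   cal$red_concentrations))
  .need(c(gfiles, rfiles), "calibrate")
  calres <- calibrate_fccs(lapply(gfiles, read_trace),
                           cal$green_concentrations,
                           lapply(rfiles, read_trace),
                           cal$red_concentrations,
                           dye_diffusion = cal$dye_diffusion,
                           m = cfg$correlator$m,
                           n_segments = cfg$correlator$n_segments)
  f <- file.path(dir, "calibration.json")
  jsonlite::write_json(list(
    green = calres$green[c("waist", "axial", "v_eff",
                           "structure_parameter")],
    red = calres$red[c("waist", "axial", "v_eff", "structure_parameter")],
    v_cc = calres$v_cc, dye_diffusion = calres$dye_diffusion),
    f, auto_unbox = TRUE, digits = NA)
  f
}

.read_calibration <- function(dir) {
  f <- file.path(dir, "calibration.json")
  .need(f, "fit/kd")
  j <- jsonlite::fromJSON(f)
  structure(list(
    green = detection_volume(j$green$waist, j$green$axial, "green"),
    red = detection_volume(j$red$waist, j$red$axial, "red"),
    v_cc = j$v_cc, dye_diffusion = j$dye_diffusion),
    class = "calibration_result")
}

.sample_files <- function(cfg, dir) {
  file.path(dir, sprintf("sample_%03d.txt",
                         seq_len(cfg$fccs$n_measurements)))
}

.stage_correlate <- function(cfg, dir) {
  sf <- .sample_files(cfg, dir)
  .need(sf, "correlate")
  files <- character(0)
  for (k in seq_along(sf)) {
    tr <- read_trace(sf[k])
    for (kind in c("auto_green", "auto_red", "cross")) {
      cv <- multi_tau_correlate(tr, kind, cfg$correlator$m,
                                cfg$correlator$n_segments)
      f <- file.path(dir, sprintf("curve_%03d_%s.txt", k, kind))
      write_curve(cv, f)
      files <- c(files, f)
    }
  }
  files
}

.stage_kd <- function(cfg, dir, write_fit_table = FALSE) {
  calres <- .read_calibration(dir)
  n <- cfg$fccs$n_measurements
  meas <- vector("list", n)
  for (k in seq_len(n)) {
    cf <- file.path(dir, sprintf("curve_%03d_%s.txt", k,
                                 c("auto_green", "auto_red", "cross")))
    .need(cf, "kd")
    meas[[k]] <- measurement_from_curves(
      read_curve(cf[1]), read_curve(cf[2]), read_curve(cf[3]), calres,
      triplet_tau = cfg$fccs$triplet_tau,
      location_label = sprintf("measurement %d", k))
  }
  files <- character(0)
  if (write_fit_table) {
    f <- file.path(dir, "fits.jsonl")
    write_measurements(meas, f)
    return(f)
  }
  part <- apply_exclusion(meas, cfg$exclusion$threshold, cfg$exclusion$rule)
  f1 <- file.path(dir, "measurements.jsonl")
  write_measurements(c(part$retained, part$excluded), f1)
  agg <- aggregate_kd(part$retained)
  binned <- bin_kd(agg$values, cfg$kd_bin_edges)
  f2 <- file.path(dir, "kd_summary.json")
  jsonlite::write_json(list(
    kd_mean = agg$mean, kd_sd = agg$sd, n = agg$n,
    n_bounds = agg$n_bounds, min_bound = agg$min_bound,
    n_excluded = length(part$excluded),
    kd_true = cfg$fccs$kd_true), f2, auto_unbox = TRUE, digits = NA)
  f3 <- file.path(dir, "kd_bins.csv")
  write.table(binned, f3, sep = ",", row.names = FALSE)
  c(files, f1, f2, f3)
}

.stage_flim <- function(cfg, dir) {
  fl <- cfg$flim
  dfiles <- file.path(dir, sprintf("decay_donor_%02d.txt",
                                   seq_len(fl$n_donor)))
  rfiles <- file.path(dir, sprintf("decay_roi_%02d.txt", seq_len(fl$n_roi)))
  .need(c(dfiles, rfiles), "flim")
  res <- roi_fret_analysis(lapply(dfiles, read_decay),
                           lapply(rfiles, read_decay),
                           forster_r0 = cfg$forster_r0)
  f1 <- file.path(dir, "fret_results.csv")
  write.table(as.data.frame(res), f1, sep = ",", row.names = FALSE)
  f2 <- file.path(dir, "fret_summary.json")
  jsonlite::write_json(list(
    tau_donor_unquenched = attr(res, "tau_donor_unquenched"),
    mean_tau_da = mean(res$tau_da, na.rm = TRUE),
    mean_efficiency = mean(res$efficiency, na.rm = TRUE),
    mean_distance = mean(res$distance, na.rm = TRUE),
    forster_r0 = cfg$forster_r0), f2, auto_unbox = TRUE, digits = NA)
  c(f1, f2)
}

.stage_morpho <- function(cfg, dir) {
  f <- file.path(dir, "cell_grid.csv")
  .need(f, "morpho")
  grid <- read.table(f, header = TRUE, sep = ",")
  prof <- paracrine_profile(grid, cfg$ktr$max_rows, cfg$ktr$threshold)
  out <- file.path(dir, "paracrine_profile.csv")
  write.table(prof, out, sep = ",", row.names = FALSE)
  out
}

#' Run the staged analysis pipeline
#'
#' Executes one or all pipeline stages on a validated configuration:
#' `simulate` (traces, decays, reporter grid + ground-truth sidecar),
#' `calibrate` (detection volumes from the dye series), `correlate`
#' (auto/cross curves per measurement), `fit` (fit parameter audit table),
#' `kd` (measurements, exclusion, aggregation, binning), `flim` and
#' `morpho`. Every stage writes its artifacts under `config$output_dir` and
#' updates a JSON manifest with the configuration hash, seeds and output
#' hash; rerunning a stage with the same configuration is bit-identical.
#'
#' @param config a [run_config()] (or anything it accepts).
#' @param stage one of `"simulate"`, `"calibrate"`, `"correlate"`, `"fit"`,
#'   `"kd"`, `"flim"`, `"morpho"`, `"all"`.
#' @return the manifest (invisibly), with per-stage file lists.
#' @export
run_pipeline <- function(config = NULL,
                         stage = c("all", "simulate", "calibrate",
                                   "correlate", "fit", "kd", "flim",
                                   "morpho")) {
  stage <- match.arg(stage)
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir <- cfg$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  stages <- if (stage == "all") {
    c("simulate", "calibrate", "correlate", "fit", "kd", "flim", "morpho")
  } else {
    stage
  }
  manifest_file <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_file)) {
    jsonlite::fromJSON(manifest_file, simplifyVector = FALSE)
  } else {
    list(package = "fccsfret",
         version = as.character(utils::packageVersion("fccsfret")),
         config = unclass(cfg), config_hash = .config_hash(cfg),
         stages = list())
  }
  if (!identical(manifest$config_hash, .config_hash(cfg))) {
    stop("output_dir contains a manifest for a different configuration")
  }

  for (st in stages) {
    files <- switch(st,
      simulate = .stage_simulate(cfg, dir),
      calibrate = .stage_calibrate(cfg, dir),
      correlate = .stage_correlate(cfg, dir),
      fit = .stage_kd(cfg, dir, write_fit_table = TRUE),
      kd = .stage_kd(cfg, dir),
      flim = .stage_flim(cfg, dir),
      morpho = .stage_morpho(cfg, dir))
    manifest$stages[[st]] <- list(files = as.list(basename(files)),
                                  output_hash = .file_hash(files))
  }
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
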