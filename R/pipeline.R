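# Three-stage f-QCMD pipeline driver:
#   (i)  pimd-targets: PIMD sampling of quasi-centroid distributions,
#   (ii) ibi-fit:      regularized IBI fit of the correction potential,
#   (iii) spectra:     classical and f-QCMD dipole absorption spectra.
# Configuration is flat key-value text with one [block] per stage; every
# stage writes a manifest (config hash, seed, versions) and its artifacts
# under the configured output directory. Archival state uses R's native
# serialization.

pipeline_defaults <- function() {
  list(
    structure = list(phase = "liquid", n_molecules = 64,
                     temperature = 300, seed = 1, edges = NA),
    model = list(params_file = NA, r_cut = NA),
    pimd = list(P = 16, steps = 4000, equil_steps = 1000, frame_stride = 10,
                dt_fs = 0.25, tau_fs = 50),
    ibi = list(iterations = 10, epsilon = 1, md_steps = 8000,
               equil_steps = 1600, frame_stride = 4),
    spectra = list(segments = 6, segment_fs = 1500, equil_fs = 500,
                   reseed_fs = 250, window_tau_fs = 600, record_stride = 2),
    output = list(dir = "fqcmd_out")
  )
}

#' Read a pipeline configuration file
#'
#' Flat `key = value` text with one `[block]` per stage (blocks:
#' `structure`, `model`, `pimd`, `ibi`, `spectra`, `output`); unset keys
#' take the package defaults.
#'
#' @param file Path.
#' @return Object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  cfg <- pipeline_defaults()
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  block <- NULL
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      block <- gsub("[][]", "", ln)
      if (!block %in% names(cfg)) stop("unknown config block: ", block)
      next
    }
    if (is.null(block)) stop("key outside a [block]: ", ln)
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    if (!key %in% names(cfg[[block]]))
      stop("unknown key '", key, "' in block [", block, "]")
    cur <- cfg[[block]][[key]]
    cfg[[block]][[key]] <-
      if (is.character(cur)) val
      else if (key == "edges") as.numeric(strsplit(val, "\\s+")[[1]])
      else as.numeric(val)
  }
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration file
#'
#' @param config A `pipeline_config` (or plain list of blocks).
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_pipeline_config <- function(config, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (block in names(config)) {
    writeLines(sprintf("[%s]", block), con)
    for (key in names(config[[block]])) {
      val <- config[[block]][[key]]
      if (length(val) == 0 || (length(val) == 1 && is.na(val))) next
      writeLines(sprintf("%s = %s", key,
                         paste(format(val, digits = 15), collapse = " ")),
                 con)
    }
  }
  invisible(file)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- config
  cfg$output <- NULL  # hash the scientific configuration, not output paths
  write_pipeline_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

build_structure_from_config <- function(config, params) {
  s <- config$structure
  edges <- if (length(s$edges) == 3) s$edges else NULL
  spec <- structure_spec(s$phase, s$n_molecules, edges, s$temperature,
                         s$seed)
  if (s$phase == "iceIh") build_ice_cell(spec, params)
  else build_liquid_box(spec, params)
}

params_from_config <- function(config) {
  pf <- config$model$params_file
  p <- if (is.na(pf)) qtip4pf_params() else read_water_params(pf)
  if (!is.na(config$model$r_cut)) p$r_cut <- config$model$r_cut
  p
}

write_manifest <- function(config, stage, dir, extra = list()) {
  manifest <- c(list(
    stage = stage,
    config_md5 = config_hash(config),
    seed = config$structure$seed,
    package = "fqcmd",
    version = as.character(utils::packageVersion("fqcmd"))), extra)
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

stage_log <- function(dir, stage, msg) {
  cat(sprintf("[%s] %s %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              stage, msg),
      file = file.path(dir, "pipeline.log"), append = TRUE)
}

#' Run one f-QCMD pipeline stage
#'
#' Stages: `"pimd-targets"` (PIMD sampling of the quasi-centroid
#' distribution set), `"ibi-fit"` (regularized IBI; checkpointed per
#' iteration and resumable), `"spectra"` (classical and f-QCMD dipole
#' spectra from NVE segments). Each stage writes its artifacts plus a
#' deterministic manifest; rerunning with the same config reproduces them.
#'
#' @param config A `pipeline_config`.
#' @param stage Stage name.
#' @param resume Resume the IBI loop from its last checkpoint.
#' @return Invisibly, a list of artifact paths.
#' @export
run_stage <- function(config,
                      stage = c("pimd-targets", "ibi-fit", "spectra"),
                      resume = FALSE) {
  stage <- match.arg(stage)
  dir <- config$output$dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- params_from_config(config)
  seed <- config$structure$seed

  if (stage == "pimd-targets") {
    stage_log(dir, stage, "building structure and sampling PIMD targets")
    st <- build_structure_from_config(config, params)
    res <- sample_quasicentroid_ensemble(
      st, params, P = config$pimd$P,
      n_steps = config$pimd$steps, equil_steps = config$pimd$equil_steps,
      frame_stride = config$pimd$frame_stride,
      dt_fs = config$pimd$dt_fs, tau_fs = config$pimd$tau_fs,
      seed = derive_seed(seed, 101L))
    saveRDS(list(target = res$distributions, structure = st,
                 config = unclass(config)),
            file.path(dir, "pimd_targets.rds"))
    write_distribution_set(res$distributions, file.path(dir, "targets"))
    man <- write_manifest(config, stage, dir,
                          list(n_frames = res$distributions$n_frames,
                               P = config$pimd$P))
    return(invisible(list(state = file.path(dir, "pimd_targets.rds"),
                          manifest = man)))
  }

  if (stage == "ibi-fit") {
    tfile <- file.path(dir, "pimd_targets.rds")
    if (!file.exists(tfile))
      stop("missing PIMD targets (", tfile, "); run stage 'pimd-targets' ",
           "first")
    saved <- readRDS(tfile)
    st <- saved$structure
    ckpt_file <- file.path(dir, "ibi_checkpoint.rds")
    first <- 1L
    init_corr <- NULL
    init_config <- NULL
    if (resume && file.exists(ckpt_file)) {
      ck <- readRDS(ckpt_file)
      first <- ck$iteration + 1L
      init_corr <- ck$correction
      init_config <- ck$config
      stage_log(dir, stage, paste("resuming from iteration", ck$iteration))
    }
    settings <- integrator_settings(
      dt_fs = config$pimd$dt_fs, thermostat = "langevin",
      tau_fs = config$pimd$tau_fs,
      temperature = config$structure$temperature,
      seed = derive_seed(seed, 202L))
    system <- list(kind = "water", config = st$config, cell = st$cell,
                   topo = st$topo, params = params)
    n_total <- as.integer(config$ibi$iterations)
    history <- if (resume && file.exists(ckpt_file)) ck$history else NULL
    corr <- init_corr
    cfg_now <- init_config
    for (it in seq(from = first, length.out = max(0, n_total - first + 1))) {
      res <- run_ibi(saved$target, system, settings,
                     n_iterations = it, epsilon = config$ibi$epsilon,
                     md_steps = config$ibi$md_steps,
                     equil_steps = config$ibi$equil_steps,
                     frame_stride = config$ibi$frame_stride,
                     seed = derive_seed(seed, 303L),
                     init_correction = corr, init_config = cfg_now,
                     first_iteration = it)
      corr <- res$correction
      cfg_now <- res$final_config
      history <- rbind(history, res$history)
      saveRDS(list(iteration = it, correction = corr, config = cfg_now,
                   history = history), ckpt_file)
      stage_log(dir, stage, sprintf("iteration %d metric %.4f", it,
                                    utils::tail(history$total, 1)))
    }
    write_correction(corr, file.path(dir, "correction.txt"))
    utils::write.csv(history, file.path(dir, "ibi_history.csv"),
                     row.names = FALSE)
    saveRDS(list(correction = corr, history = history),
            file.path(dir, "ibi_fit.rds"))
    man <- write_manifest(config, stage, dir,
                          list(iterations = n_total,
                               epsilon = config$ibi$epsilon))
    return(invisible(list(correction = file.path(dir, "correction.txt"),
                          manifest = man)))
  }

  # stage == "spectra"
  ifile <- file.path(dir, "ibi_fit.rds")
  if (!file.exists(ifile))
    stop("missing IBI fit (", ifile, "); run stage 'ibi-fit' first")
  corr <- readRDS(ifile)$correction
  st <- build_structure_from_config(config, params)
  sp <- config$spectra
  specs <- list()
  for (which in c("classical", "fqcmd")) {
    cr <- if (which == "classical") NULL else corr
    specs[[which]] <- spectrum_from_segments(
      st, params, correction = cr,
      temperature = config$structure$temperature,
      n_segments = sp$segments, segment_fs = sp$segment_fs,
      equil_fs = sp$equil_fs, reseed_fs = sp$reseed_fs,
      window_tau_fs = sp$window_tau_fs, record_stride = sp$record_stride,
      dt_fs = config$pimd$dt_fs, seed = derive_seed(seed, 404L))
    write_spectrum(specs[[which]],
                   file.path(dir, paste0("spectrum_", which, ".csv")),
                   meta = c(potential = which,
                            temperature = config$structure$temperature,
                            seed = seed))
  }
  bands <- data.frame(name = c("libration", "bend", "stretch"),
                      lo = c(300, 1300, 2800), hi = c(1100, 1900, 4200))
  cmp <- compare_spectra(specs$classical, specs$fqcmd, bands)
  names(cmp)[names(cmp) == "peak_a"] <- "classical_cm1"
  names(cmp)[names(cmp) == "peak_b"] <- "fqcmd_cm1"
  utils::write.csv(cmp, file.path(dir, "band_positions.csv"),
                   row.names = FALSE)
  man <- write_manifest(config, stage, dir,
                        list(segments = sp$segments,
                             window_tau_fs = sp$window_tau_fs))
  stage_log(dir, stage, "spectra written")
  invisible(list(classical = file.path(dir, "spectrum_classical.csv"),
                 fqcmd = file.path(dir, "spectrum_fqcmd.csv"),
                 bands = file.path(dir, "band_positions.csv"),
                 manifest = man))
}

#' Dipole spectrum from NVE segments
#'
#' Equilibrates with a Langevin thermostat, then alternates short
#' thermostatted re-randomization stretches with NVE production segments;
#' the dipole-derivative autocorrelation is averaged over the segments and
#' Hann-windowed. Launching the correlation from NVE segments keeps the
#' thermostat from distorting line shapes.
#'
#' @param st A `water_structure`.
#' @param params A `water_params`.
#' @param correction Optional `correction_potential` (NULL = classical).
#' @param temperature Temperature (K).
#' @param n_segments Number of NVE segments.
#' @param segment_fs Segment length (fs).
#' @param equil_fs Initial NVT equilibration (fs).
#' @param reseed_fs NVT re-randomization between segments (fs).
#' @param window_tau_fs Hann window time constant (fs).
#' @param record_stride Recording stride (steps).
#' @param dt_fs Time step (fs).
#' @param seed Seed.
#' @param max_lag_fs Correlation length (default: window time constant).
#' @return An `absorption_spectrum`.
#' @export
spectrum_from_segments <- function(st, params, correction = NULL,
                                   temperature = 300, n_segments = 6,
                                   segment_fs = 1500, equil_fs = 500,
                                   reseed_fs = 250, window_tau_fs = 600,
                                   record_stride = 2, dt_fs = 0.25,
                                   seed = 1, max_lag_fs = window_tau_fs) {
  nvt <- integrator_settings(dt_fs, "langevin", tau_fs = 100,
                             temperature = temperature, seed = seed)
  nve <- integrator_settings(dt_fs, "none", temperature = temperature)
  n_eq <- max(1L, round(equil_fs / dt_fs))
  n_seg <- max(2L, round(segment_fs / dt_fs))
  n_rs <- max(1L, round(reseed_fs / dt_fs))
  cur <- run_water_md(st$config, st$cell, st$topo, params, nvt,
                      n_steps = n_eq, correction = correction,
                      record_stride = n_eq)$final
  segs <- vector("list", n_segments)
  for (s in seq_len(n_segments)) {
    run <- run_water_md(cur, st$cell, st$topo, params, nve,
                        n_steps = n_seg, correction = correction,
                        record_stride = record_stride)
    segs[[s]] <- run$mudot
    nvt$seed <- derive_seed(seed, 50L + s)
    cur <- run_water_md(run$final, st$cell, st$topo, params, nvt,
                        n_steps = n_rs, correction = correction,
                        record_stride = n_rs)$final
  }
  acf <- dipole_autocorrelation(segs, dt_fs * record_stride,
                                max_lag_fs = min(max_lag_fs,
                                                 n_seg * dt_fs / 2))
  windowed_spectrum(acf, window_tau_fs)
}
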