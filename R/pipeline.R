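#' Pipeline configuration
#'
#' Assembles stage parameters for [runPipeline()], defaulting every
#' threshold to the values the analyses are defined with: +/-80 uV spike
#' threshold (cortical default; 100 for DRG, 200 for organoids), 1 ms
#' histogram bin, 0.3 merge similarity, 100 ms coincidence window, 100
#' surrogates, Z = +/-3, 0.1 ms front-tracking step, 100 ms evoked bin,
#' k = 5 clusters. Values can be overridden per call or from a JSON/YAML
#' config file.
#'
#' @param preset generator preset name for `simulate`
#' @param seed integer seed; all pipeline randomness flows from it
#' @param ... overrides of the defaults listed above
#' @return named list
#' @export
pipelineConfig <- function(preset = "cortical_net", seed = 1L, ...) {
  cfg <- list(
    preset = preset, seed = as.integer(seed),
    spikeThreshold = 80, deadTimeMs = 1,
    mergeBinMs = 1, mergeSimThreshold = 0.3,
    isiThMs = 100, ibiThMs = 300, minSpikes = 5L, minUnits = 2L,
    psThreshold = 10, psMinSpikes = 3L, mfBinMs = 10,
    connWindow = 0.1, nSurrogates = 100L, zThreshold = 3,
    axonStepMs = 0.1, axonFireK = 5,
    evokedT0 = 5, evokedBinS = 0.1, evokedWindowS = 10, evokedK = 5L,
    lfpMinElectrodes = 3L
  )
  utils::modifyList(cfg, list(...))
}

#' Read a pipeline config file (JSON or YAML)
#' @param path config file; format chosen by extension
#' @return named list merged over [pipelineConfig()] defaults
#' @export
readPipelineConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  override <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
              else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, override)
}

stageArtifacts <- list(
  simulate = c("recording.rds", "truth.rds"),
  preprocess = "preprocessed.rds",
  units = c("units.json", "spikes.csv", "units.rds"),
  bursts = "burst_parameters.csv",
  connectivity = "connectivity",
  axon = "axon_velocity.csv",
  evoked = "evoked_clusters.csv",
  lfp = "lfp_events.csv"
)

requireArtifact <- function(runDir, stage) {
  f <- file.path(runDir, stageArtifacts[[stage]][1])
  if (!file.exists(f))
    stop(sprintf(
      "stage dependency missing: run '%s' first (expected artifact %s)",
      stage, f))
  invisible(f)
}

writeManifest <- function(runDir, stage, config) {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "hdmea",
    version = as.character(utils::packageVersion("hdmea")),
    stage = stage, seed = config$seed,
    config = config,
    config_hash = unname(tools::md5sum(tmp)))
  unlink(tmp)
  jsonlite::write_json(manifest,
                       file.path(runDir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run one pipeline stage
#'
#' Orchestrates the analysis stages over a run directory: `simulate`
#' generates a preset recording with ground truth; `preprocess` detrends
#' and spike-band filters it; `units` detects spikes and merges somata;
#' `bursts`, `connectivity`, `axon`, `evoked` and `lfp` run the
#' corresponding analyses; `report` collates the burst tables. Each stage
#' writes its exports plus a JSON manifest (package version, seed, config
#' hash) and fails with an explicit message naming the missing prerequisite
#' artifact if run out of order.
#'
#' @param stage one of simulate, preprocess, units, bursts, connectivity,
#'   axon, evoked, lfp, report
#' @param runDir run directory (created if needed)
#' @param config list from [pipelineConfig()] / [readPipelineConfig()]
#' @param quiet suppress progress messages
#' @return invisibly, the paths written
#' @export
runPipeline <- function(stage, runDir, config = pipelineConfig(),
                        quiet = FALSE) {
  stages <- c("simulate", "preprocess", "units", "bursts", "connectivity",
              "axon", "evoked", "lfp", "report")
  if (!stage %in% stages)
    stop(sprintf("unknown stage '%s'; expected one of: %s", stage,
                 paste(stages, collapse = ", ")))
  dir.create(runDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  out <- switch(stage,
    simulate = {
      sim <- simulateRecording(synthPreset(config$preset,
                                           seed = config$seed))
      writeRecording(sim$recording, file.path(runDir, "recording.rds"))
      saveRDS(sim$truth, file.path(runDir, "truth.rds"))
      c("recording.rds", "truth.rds")
    },
    preprocess = {
      requireArtifact(runDir, "simulate")
      rec <- readRecording(file.path(runDir, "recording.rds"))
      v <- voltage(rec)
      for (e in seq_len(nrow(v)))
        v[e, ] <- spikeBandpass(detrendBlocks(v[e, ]), samplingRate(rec))
      writeRecording(meaRecording(v, electrodeGrid(rec),
                                  samplingRate(rec), rec@meta),
                     file.path(runDir, "preprocessed.rds"))
      "preprocessed.rds"
    },
    units = {
      requireArtifact(runDir, "preprocess")
      rec <- readRecording(file.path(runDir, "preprocessed.rds"))
      v <- voltage(rec)
      trains <- lapply(seq_len(nrow(v)), function(e)
        detectSpikes(v[e, ], samplingRate(rec), config$spikeThreshold,
                     config$deadTimeMs))
      units <- mergeSomata(trains, electrodeGrid(rec), duration(rec),
                           config$mergeBinMs, config$mergeSimThreshold)
      writeUnitsJson(units, file.path(runDir, "units.json"),
                     file.path(runDir, "spikes.csv"))
      saveRDS(units, file.path(runDir, "units.rds"))
      c("units.json", "spikes.csv", "units.rds")
    },
    bursts = {
      requireArtifact(runDir, "units")
      units <- readRDS(file.path(runDir, "units.rds"))
      trains <- spikeTrains(units)
      nb <- detectNetworkBursts(trains, config$isiThMs, config$ibiThMs,
                                config$minSpikes, config$minUnits)
      tab <- burstParameterTable(nb, trains, duration(units),
                                 config$mfBinMs)
      utils::write.csv(
        data.frame(parameter = names(tab), value = unname(tab)),
        file.path(runDir, "burst_parameters.csv"), row.names = FALSE)
      "burst_parameters.csv"
    },
    connectivity = {
      requireArtifact(runDir, "units")
      units <- readRDS(file.path(runDir, "units.rds"))
      res <- connectivityAnalysis(units, config$nSurrogates,
                                  config$connWindow, config$zThreshold,
                                  seed = config$seed)
      writeConnectivity(res, file.path(runDir, "connectivity"))
      "connectivity"
    },
    axon = {
      requireArtifact(runDir, "simulate")
      rec <- readRecording(file.path(runDir, "recording.rds"))
      soma <- identifySoma(rec, ampThreshold = 200)
      sta <- spikeTriggeredAverage(rec, soma$train)
      paths <- trackPropagationFront(sta, electrodeGrid(rec),
                                     soma$centroid,
                                     stepMs = config$axonStepMs,
                                     k = config$axonFireK,
                                     exclude = soma$electrodes)
      fit <- fitConductionVelocity(paths$forward)
      utils::write.csv(
        data.frame(direction = "forward",
                   velocity_m_s = fit$velocity, r2 = fit$r2,
                   endpoint_m_s = fit$endpointVelocity,
                   distance_mm = fit$totalDistanceMm,
                   time_ms = fit$totalTimeMs),
        file.path(runDir, "axon_velocity.csv"), row.names = FALSE)
      writePathCsv(paths$forward, electrodeGrid(rec),
                   file.path(runDir, "axon_path.csv"))
      "axon_velocity.csv"
    },
    evoked = {
      requireArtifact(runDir, "units")
      units <- readRDS(file.path(runDir, "units.rds"))
      hist <- responseHistograms(units, config$evokedT0,
                                 config$evokedWindowS, config$evokedBinS)
      k <- min(config$evokedK, nrow(hist$counts))
      cl <- wardCluster(hist$counts, k = k)
      utils::write.csv(
        data.frame(id = hist$ids, cluster = cl$labels),
        file.path(runDir, "evoked_clusters.csv"), row.names = FALSE)
      "evoked_clusters.csv"
    },
    lfp = {
      requireArtifact(runDir, "simulate")
      rec <- readRecording(file.path(runDir, "recording.rds"))
      truth <- readRDS(file.path(runDir, "truth.rds"))
      regions <- if (length(truth@lfp))
        stats::setNames(lapply(truth@lfp, `[[`, "electrodes"),
                        vapply(truth@lfp, `[[`, "", "region"))
        else list(all = seq_len(nElectrodes(rec)))
      events <- lapply(regions, function(e)
        detectLfpEvents(rec, e, minElectrodes = config$lfpMinElectrodes))
      writeLfpEventsCsv(events, file.path(runDir, "lfp_events.csv"))
      "lfp_events.csv"
    },
    report = {
      requireArtifact(runDir, "bursts")
      df <- utils::read.csv(file.path(runDir, "burst_parameters.csv"))
      utils::write.csv(df, file.path(runDir, "report.csv"),
                       row.names = FALSE)
      "report.csv"
    })
  writeManifest(runDir, stage, config)
  say("stage %s done in %.1f s (seed %d): %s", stage,
      as.numeric(difftime(Sys.time(), t0, units = "secs")), config$seed,
      paste(out, collapse = ", "))
  invisible(file.path(runDir, out))
}
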