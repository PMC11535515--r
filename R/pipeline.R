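#' Run a simulate-analyze-report pipeline from a config
#'
#' Executes one of the built-in stage sequences with a validated,
#' seeded configuration and (optionally) writes a JSON report plus CSV
#' artifacts. Identical configurations produce byte-identical reports.
#'
#' Config structure (a named list, or the path of a YAML file):
#' \describe{
#'   \item{stage}{"pinch" (simulate a pinch recording, analyze it,
#'     report thickness/modulus recovery), "tether" (simulate a tether
#'     dataset, Monte-Carlo fit Alpha) or "tracks" (simulate migration
#'     tracks, filter and summarize).}
#'   \item{seed}{integer seed for every random stage.}
#'   \item{out}{optional output directory for the report and tables.}
#'   \item{params}{named list forwarded to the stage's generator and
#'     analyzer (unknown keys are rejected; physical parameters must be
#'     positive).}
#' }
#'
#' @param config named list or YAML file path.
#' @return list with the stage results (also written to
#'   `<out>/report.json` when `out` is set), invisibly.
#' @examples
#' res <- runPipeline(list(stage = "tracks", seed = 1,
#'                         params = list(nTracks = 5, duration = 7200)))
#' res$n_tracks_kept
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("stage", "seed", "out", "params")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  stage <- config$stage
  stopIfNot(is.character(stage) && length(stage) == 1L,
            "config$stage must be a single string")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  params <- if (is.null(config$params)) list() else config$params
  checkPositive <- function(keys)
    for (k in intersect(keys, names(params)))
      stopIfNot(is.numeric(params[[k]]) && all(params[[k]] > 0),
                paste0("config parameter '", k, "' must be positive"))
  allow <- function(keys) {
    bad <- setdiff(names(params), keys)
    if (length(bad))
      stop("unknown parameter(s) for stage '", stage, "': ",
           paste(bad, collapse = ", "))
  }
  results <- switch(stage,
    pinch = {
      allow(c("h0", "E", "beadDiameter", "locNoiseXY", "locNoiseZ",
              "nCycles", "frameRate", "window"))
      checkPositive(c("h0", "E", "beadDiameter", "nCycles", "frameRate"))
      prot <- genFieldProtocol(
        nCycles = if (is.null(params$nCycles)) 8 else params$nCycles,
        frameRate = if (is.null(params$frameRate)) 100 else params$frameRate)
      genArgs <- params[intersect(names(params),
                                  c("h0", "E", "beadDiameter",
                                    "locNoiseXY", "locNoiseZ"))]
      rec <- do.call(genPinchRecording,
                     c(genArgs, list(protocol = prot, seed = seed)))
      window <- if (is.null(params$window)) c(150, 350) else params$window
      an <- analyzePinchRecording(rec, window = window)
      gt <- groundTruth(rec)
      list(stage = "pinch", seed = seed,
           h0_true_nm = gt$h0, E_true_Pa = gt$E,
           h_med_nm = an$h_med_nm, E_tan_Pa = an$E_tan_Pa,
           n_cycles_ok = an$n_cycles_ok,
           E_rel_error = abs(an$E_tan_Pa - gt$E) / gt$E)
    },
    tether = {
      allow(c("alpha", "f0", "velocities", "nCells", "forceNoiseCv", "nSim"))
      checkPositive(c("alpha", "nCells", "nSim", "velocities"))
      genArgs <- params[intersect(names(params),
                                  c("alpha", "f0", "velocities", "nCells",
                                    "forceNoiseCv"))]
      ds <- do.call(genTetherDataset, c(genArgs, list(seed = seed)))
      fit <- fitAlphaMC(ds, nSim = if (is.null(params$nSim)) 5000
                        else params$nSim, seed = seed)
      gt <- groundTruth(ds)
      list(stage = "tether", seed = seed, alpha_true = gt$alpha,
           alpha_mean = alphaMean(fit), alpha_sd = alphaSd(fit),
           f0 = staticForce(fit))
    },
    tracks = {
      allow(c("nTracks", "dt", "duration", "meanSpeed", "persistenceTime",
              "driftSpeed", "minDuration"))
      checkPositive(c("nTracks", "dt", "duration", "persistenceTime"))
      genArgs <- params[intersect(names(params),
                                  c("nTracks", "dt", "duration", "meanSpeed",
                                    "persistenceTime", "driftSpeed"))]
      tr <- do.call(genTracks, c(genArgs, list(seed = seed)))
      kept <- filterTracks(tr, minDuration = if (is.null(params$minDuration))
        60 else params$minDuration)
      st <- summarizeTracks(kept)
      ch <- chemotaxisMetrics(kept)
      list(stage = "tracks", seed = seed,
           n_tracks = length(unique(tr$track_id)),
           n_tracks_kept = length(unique(kept$track_id)),
           median_speed_um_min = median(st$median_speed),
           mean_confinement_ratio = mean(st$confinement_ratio),
           mean_fmi = mean(ch$fmi))
    },
    stop("unknown stage '", stage, "'; expected pinch, tether or tracks")
  )
  if (!is.null(config$out)) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    writeReport(results, file.path(config$out, "report.json"))
  }
  invisible(results)
}
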