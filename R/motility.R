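#' Per-track migration statistics
#'
#' For a single track: instantaneous speeds from consecutive samples
#' (step length over actual time step, reported in um/min), the median
#' of those speeds, the net (start-to-end) and total (path length)
#' distances, and the confinement ratio `net / total` (0 for a track
#' that never moves). The confinement ratio is also reported as
#' `directionality` (the two are synonymous here).
#'
#' @param track data.frame with columns `t_s`, `x_um`, `y_um` and
#'   optionally `z_um`; at least 2 samples, `t_s` strictly increasing.
#' @return one-row data.frame with `median_speed`, `net_distance`,
#'   `total_distance`, `confinement_ratio`, `directionality`,
#'   `duration_min`.
#' @examples
#' tr <- data.frame(t_s = c(0, 60, 120), x_um = c(0, 3, 6),
#'                  y_um = c(0, 4, 8))
#' summarizeTrack(tr)  # speeds 5 um/min, confinement ratio 1
#' @export
summarizeTrack <- function(track) {
  stopIfNot(nrow(track) >= 2, "a track needs at least 2 samples")
  stopIfNot(!is.unsorted(track$t_s, strictly = TRUE),
            "t_s must be strictly increasing")
  cols <- intersect(c("x_um", "y_um", "z_um"), names(track))
  P <- as.matrix(track[, cols, drop = FALSE])
  steps <- sqrt(rowSums((P[-1, , drop = FALSE] -
                           P[-nrow(P), , drop = FALSE])^2))
  dtv <- diff(track$t_s)
  speeds <- steps / dtv * 60
  total <- sum(steps)
  net <- sqrt(sum((P[nrow(P), ] - P[1, ])^2))
  cr <- if (total > 0) net / total else 0
  data.frame(median_speed = median(speeds), net_distance = net,
             total_distance = total, confinement_ratio = cr,
             directionality = cr,
             duration_min = (track$t_s[nrow(track)] - track$t_s[1]) / 60)
}

#' @rdname summarizeTrack
#' @param tracks data.frame of several tracks (column `track_id`).
#' @return `summarizeTracks()`: one row per track (with `track_id`).
#' @export
summarizeTracks <- function(tracks) {
  res <- lapply(split(tracks, tracks$track_id), function(g) {
    s <- summarizeTrack(g[order(g$t_s), , drop = FALSE])
    cbind(data.frame(track_id = g$track_id[1]), s)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Keep only tracks longer than a minimum duration
#'
#' Strict inequality: a track is retained when its duration exceeds
#' `minDuration` (a track lasting exactly the minimum is dropped),
#' mirroring a "longer than 1 h" selection rule.
#'
#' @param tracks data.frame with columns `track_id`, `t_s`.
#' @param minDuration minimum duration in minutes (default 60).
#' @return the filtered tracks data.frame.
#' @export
filterTracks <- function(tracks, minDuration = 60) {
  if (!nrow(tracks)) return(tracks)
  dur <- vapply(split(tracks$t_s, tracks$track_id),
                function(t) (max(t) - min(t)) / 60, numeric(1))
  keep <- names(dur)[dur > minDuration]
  tracks[tracks$track_id %in% keep, , drop = FALSE]
}

#' Chemotaxis metrics along a gradient axis
#'
#' Per track: the forward migration index along the gradient axis
#' (`FMIx` = net displacement projected on the axis / total path
#' length), the directionality (net / total, identical to the
#' confinement ratio) and the median speed. The axis defaults to +x,
#' the conventional gradient direction.
#'
#' @param tracks data.frame with `track_id`, `t_s`, `x_um`, `y_um`.
#' @param axis gradient axis (unit vector, 2D).
#' @return data.frame with one row per track: `track_id`, `fmi`,
#'   `directionality`, `median_speed`, `flag` ("zero-total" when the
#'   track never moves, in which case the metrics are 0).
#' @export
chemotaxisMetrics <- function(tracks, axis = c(1, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  res <- lapply(split(tracks, tracks$track_id), function(g) {
    g <- g[order(g$t_s), , drop = FALSE]
    s <- summarizeTrack(g)
    netVec <- c(g$x_um[nrow(g)] - g$x_um[1], g$y_um[nrow(g)] - g$y_um[1])
    if (s$total_distance > 0) {
      fmi <- sum(netVec * axis) / s$total_distance
      flag <- ""
    } else {
      fmi <- 0; flag <- "zero-total"
    }
    data.frame(track_id = g$track_id[1], fmi = fmi,
               directionality = s$confinement_ratio,
               median_speed = s$median_speed, flag = flag)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Transwell 3D migration summary from per-layer cell counts
#'
#' The z-series is acquired at the matrix surface (layer 0) and inside
#' the matrix at fixed intervals; the percentage of migration is the
#' number of cells within the matrix divided by the total number of
#' cells, and each in-matrix cell is assigned the migration distance of
#' its layer (layer index x interval).
#'
#' @param counts named or plain integer vector of cell counts per
#'   layer, in layer order starting at the surface (layer 0), or a
#'   data.frame with columns `layer`, `count`.
#' @param layerInterval z-interval between layers (um), default 30.
#' @return list with `percent_migration`, `distances_um` (one entry per
#'   in-matrix cell), `total_cells`.
#' @examples
#' transwellSummary(c(10, 3, 2))  # 33.3% migration, distances 30/60 um
#' @export
transwellSummary <- function(counts, layerInterval = 30) {
  if (is.data.frame(counts)) {
    counts <- counts[order(counts$layer), ]
    layer <- counts$layer
    n <- counts$count
  } else {
    n <- as.numeric(counts)
    layer <- seq_along(n) - 1
  }
  stopIfNot(all(n >= 0), "counts must be >= 0")
  total <- sum(n)
  if (total == 0) stop("no cells counted")
  inside <- layer > 0
  list(percent_migration = sum(n[inside]) / total * 100,
       distances_um = rep(layer[inside] * layerInterval, n[inside]),
       total_cells = total)
}

#' Rolling and sticking fractions per vessel
#'
#' The rolling fraction is the percentage of rolling cells in the total
#' flux of cells in each vessel; the sticking fraction is the
#' percentage of rolling cells that firmly adhered for at least
#' `stickThreshold` seconds (default 30 s). With no rolling cells the
#' sticking fraction is undefined and reported as `NA`, not 0.
#'
#' @param events data.frame with columns `vessel`, `rolling` (logical)
#'   and `adhesion_s` (s).
#' @param stickThreshold minimum firm-adhesion duration (s).
#' @return data.frame with one row per vessel: `vessel`, `flux`,
#'   `rolling`, `stuck`, `rolling_fraction`, `sticking_fraction` (%).
#' @examples
#' ev <- data.frame(vessel = 1, rolling = rep(c(TRUE, FALSE), c(20, 80)),
#'                  adhesion_s = rep(c(45, 10, 0), c(5, 15, 80)))
#' adhesionFractions(ev)  # rolling 20%, sticking 25%
#' @export
adhesionFractions <- function(events, stickThreshold = 30) {
  res <- lapply(split(events, events$vessel), function(g) {
    flux <- nrow(g)
    rolling <- sum(g$rolling)
    stuck <- sum(g$rolling & g$adhesion_s >= stickThreshold)
    data.frame(vessel = g$vessel[1], flux = flux, rolling = rolling,
               stuck = stuck,
               rolling_fraction = rolling / flux * 100,
               sticking_fraction = if (rolling > 0) stuck / rolling * 100
               else NA_real_)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Tissue infiltration summary from per-cell depths
#'
#' A cell counts as infiltrated when it lies deeper than `threshold`
#' below the tissue surface (default 10 um).
#'
#' @param depths numeric vector of per-cell depths (um, >= 0).
#' @param threshold infiltration depth threshold (um).
#' @return list with `percent_infiltrated`, `depths_um`, `threshold_um`,
#'   `n_cells`.
#' @examples
#' infiltrationSummary(c(5, 12, 30))  # 66.7%
#' @export
infiltrationSummary <- function(depths, threshold = 10) {
  stopIfNot(length(depths) > 0, "depths must not be empty")
  stopIfNot(all(depths >= 0), "depths must be >= 0")
  list(percent_infiltrated = mean(depths > threshold) * 100,
       depths_um = depths, threshold_um = threshold,
       n_cells = length(depths))
}
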