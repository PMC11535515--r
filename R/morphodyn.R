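#' Podosome population dynamics from point sets
#'
#' Between each pair of consecutive frames, podosome cores are matched
#' one-to-one within `matchRadius` by exact minimum-distance assignment
#' ([matchPoints()]): matched cores are "maintained", cores present
#' only in the later frame are "appearing", cores present only in the
#' earlier frame are "disappearing". Percentages are aggregated over
#' the intervals relative to the mean podosome count across frames
#' (each interval's counts are divided by the mean count and the
#' per-interval percentages averaged).
#'
#' @param pointSets list of >= 2 data.frames (or matrices) of core
#'   positions with columns `x_um`, `y_um` (or `x`, `y`), one per
#'   frame at fixed intervals; a data.frame with a `frame` column is
#'   split automatically. Empty frames are allowed.
#' @param matchRadius maximum displacement (um) for a core to count as
#'   maintained; default 0.5 (podosome core scale).
#' @return A [PodosomeDynamics-class].
#' @examples
#' pts <- data.frame(frame = rep(1:4, each = 3),
#'                   x_um = rep(c(1, 5, 9), 4), y_um = rep(c(1, 5, 9), 4))
#' podosomeDynamics(pts)  # 100% maintained
#' @export
podosomeDynamics <- function(pointSets, matchRadius = 0.5) {
  if (is.data.frame(pointSets)) {
    stopIfNot("frame" %in% names(pointSets),
              "a single data.frame needs a 'frame' column")
    fr <- sort(unique(pointSets$frame))
    pointSets <- lapply(fr, function(f)
      pointSets[pointSets$frame == f, , drop = FALSE])
  }
  stopIfNot(length(pointSets) >= 2, "need at least 2 frames")
  getXY <- function(d) {
    d <- as.data.frame(d)
    cx <- intersect(c("x_um", "x"), names(d))[1]
    cy <- intersect(c("y_um", "y"), names(d))[1]
    if (is.na(cx) || is.na(cy)) stop("point sets need x/y columns")
    as.matrix(d[, c(cx, cy)])
  }
  pts <- lapply(pointSets, getXY)
  counts <- vapply(pts, nrow, integer(1))
  meanCount <- mean(counts)
  iv <- lapply(seq_len(length(pts) - 1L), function(k) {
    m <- matchPoints(pts[[k]], pts[[k + 1L]], radius = matchRadius)
    data.frame(from = k, to = k + 1L,
               appearing = length(m$unmatched2),
               maintained = nrow(m$pairs),
               disappearing = length(m$unmatched1))
  })
  ivTab <- do.call(rbind, iv)
  flags <- character()
  if (meanCount == 0) {
    pct <- c(appearing = 0, maintained = 0, disappearing = 0)
    flags <- "all-empty"
  } else {
    pct <- c(appearing = mean(ivTab$appearing),
             maintained = mean(ivTab$maintained),
             disappearing = mean(ivTab$disappearing)) / meanCount * 100
  }
  new("PodosomeDynamics", intervals = ivTab, percentages = pct,
      meanCount = meanCount, flags = flags)
}

#' Ruffle retraction metrics from a length trace
#'
#' From a protrusion length-vs-time trace: the maximal elongation, the
#' time from that maximum until the protrusion disappears (first sample
#' at or below `threshold` after the maximum), and the retraction speed
#' `max_length / time_to_disappearance`.
#'
#' @param trace data.frame with columns `t_s`, `length_um` (>= 3
#'   samples), or a numeric vector of lengths with `dt` giving the
#'   sampling interval (s).
#' @param dt sampling interval (s) when `trace` is a plain vector.
#' @param threshold disappearance threshold (um), default 0 (a
#'   configurable noise floor).
#' @return list with `max_length_um`, `time_to_disappearance_s`,
#'   `retraction_speed_um_s` (the last two `NA` when the protrusion
#'   never disappears).
#' @examples
#' ruffleRetraction(c(1, 3, 5, 4, 2, 0), dt = 10)  # 5 um, 30 s, 1/6 um/s
#' @export
ruffleRetraction <- function(trace, dt = NULL, threshold = 0) {
  if (!is.data.frame(trace)) {
    stopIfNot(!is.null(dt) && dt > 0, "dt must be given for a plain vector")
    trace <- data.frame(t_s = (seq_along(trace) - 1) * dt, length_um = trace)
  }
  stopIfNot(nrow(trace) >= 3, "need at least 3 samples")
  len <- trace$length_um
  iMax <- which.max(len)
  gone <- which(seq_along(len) > iMax & len <= threshold)
  if (!length(gone))
    return(list(max_length_um = len[iMax], time_to_disappearance_s = NA_real_,
                retraction_speed_um_s = NA_real_))
  tGone <- trace$t_s[gone[1]] - trace$t_s[iMax]
  list(max_length_um = len[iMax], time_to_disappearance_s = tGone,
       retraction_speed_um_s = len[iMax] / tGone)
}

#' Bleb size and retraction speed from a size trace
#'
#' The maximum bleb size, and the retraction speed taken as the
#' magnitude of the least-squares slope of the trace over the
#' decreasing phase that follows the maximum (from the maximum to the
#' subsequent minimum).
#'
#' @param trace data.frame with columns `t_s`, `size_um` (or
#'   `length_um`), or a numeric vector with `dt`.
#' @param dt sampling interval (s) when `trace` is a plain vector.
#' @return list with `max_size_um`, `retraction_speed_um_s`.
#' @examples
#' blebMetrics(c(0, 2, 4, 2, 0), dt = 10)  # max 4 um, speed 0.2 um/s
#' @export
blebMetrics <- function(trace, dt = NULL) {
  if (!is.data.frame(trace)) {
    stopIfNot(!is.null(dt) && dt > 0, "dt must be given for a plain vector")
    trace <- data.frame(t_s = (seq_along(trace) - 1) * dt, size_um = trace)
  }
  if (!"size_um" %in% names(trace)) trace$size_um <- trace$length_um
  stopIfNot(nrow(trace) >= 3, "need at least 3 samples")
  sz <- trace$size_um
  iMax <- which.max(sz)
  after <- iMax:nrow(trace)
  iMin <- after[which.min(sz[after])]
  # end the retraction at the first near-zero sample so a flat
  # post-collapse tail does not dilute the slope
  floorSz <- sz[iMax] * 0.05
  hit <- after[after > iMax & sz[after] <= floorSz]
  iEnd <- if (length(hit)) hit[1] else iMin
  if (iEnd <= iMax || sz[iEnd] >= sz[iMax])
    stop("no decreasing phase after the maximum")
  seg <- trace[iMax:iEnd, , drop = FALSE]
  slope <- unname(coef(lm(size_um ~ t_s, data = seg))[2])
  list(max_size_um = sz[iMax], retraction_speed_um_s = abs(slope))
}
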