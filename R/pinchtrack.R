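#' Detect bead centers in a single frame with subpixel resolution
#'
#' Coarse detection by thresholded local maxima with non-maximum
#' suppression, followed by subpixel refinement with a
#' background-subtracted intensity centroid computed on a window around
#' each maximum (re-centered once so the window is symmetric about the
#' spot). Coordinates are in pixel units, with the center of pixel
#' `[i, j]` at `(x, y) = (j - 0.5, i - 0.5)`.
#'
#' @param img numeric matrix (one frame, rows = y, columns = x).
#' @param expectedRadiusPx approximate spot radius in px (> 1); sets the
#'   refinement window (half-width `ceiling(3 * expectedRadiusPx)`) and
#'   the suppression distance.
#' @param threshold absolute intensity threshold for coarse maxima;
#'   when `NULL`, `median(img) + 0.25 * (max(img) - median(img))` is
#'   used, which yields no detections on a constant frame.
#' @return data.frame with columns `x`, `y` (px) and `quality`
#'   (integrated background-subtracted intensity), sorted by decreasing
#'   quality. Empty for a blank frame.
#' @examples
#' rec <- genPinchRecording(locNoiseXY = 0, locNoiseZ = 0,
#'                          protocol = genFieldProtocol(nCycles = 1), seed = 1)
#' stack <- renderBeadFrames(rec)
#' detectBeadCenters(stack[, , 1], expectedRadiusPx = 2)
#' @export
detectBeadCenters <- function(img, expectedRadiusPx = 2, threshold = NULL) {
  stopIfNot(is.matrix(img) && is.numeric(img), "img must be a numeric matrix")
  stopIfNot(expectedRadiusPx > 1, "expectedRadiusPx must be > 1")
  empty <- data.frame(x = numeric(), y = numeric(), quality = numeric())
  ny <- nrow(img); nx <- ncol(img)
  if (ny < 3L || nx < 3L) return(empty)
  if (is.null(threshold)) {
    md <- median(img)
    threshold <- md + 0.25 * (max(img) - md)
    if (max(img) <= md) return(empty)
  }
  # strict local maxima over the 8-neighborhood (interior pixels only)
  core <- img[2:(ny - 1), 2:(nx - 1)]
  isMax <- core > threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    isMax <- isMax & core >= img[2:(ny - 1) + di, 2:(nx - 1) + dj]
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  cand <- data.frame(i = idx[, 1] + 1L, j = idx[, 2] + 1L)
  cand$int <- img[cbind(cand$i, cand$j)]
  cand <- cand[order(-cand$int), , drop = FALSE]
  # non-maximum suppression within the expected spot radius
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    sel <- which(keep)
    d2 <- (cand$i[sel] - cand$i[k])^2 + (cand$j[sel] - cand$j[k])^2
    if (all(d2 > (2 * expectedRadiusPx)^2)) keep[k] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  w <- as.integer(ceiling(3 * expectedRadiusPx))
  refine <- function(ci, cj) {
    i0 <- max(1L, ci - w); i1 <- min(ny, ci + w)
    j0 <- max(1L, cj - w); j1 <- min(nx, cj + w)
    win <- img[i0:i1, j0:j1, drop = FALSE]
    border <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
    bg <- median(border)
    sig <- pmax(win - bg, 0)
    s <- sum(sig)
    if (s <= 0) return(c(cj - 0.5, ci - 0.5, 0))
    yy <- (i0:i1) - 0.5; xx <- (j0:j1) - 0.5
    # Gaussian-masked centroid, mask re-centered on the running
    # estimate: at its fixed point the mask is concentric with a
    # symmetric spot, so the estimate is unbiased and the mask
    # suppresses far-field noise
    cy <- sum(rowSums(sig) * yy) / s
    cx <- sum(colSums(sig) * xx) / s
    s2 <- 2 * expectedRadiusPx^2
    for (pass in 1:6) {
      mask <- exp(-outer((yy - cy)^2, (xx - cx)^2, "+") / s2)
      wgt <- sig * mask
      sw <- sum(wgt)
      if (sw <= 0) break
      cy <- sum(rowSums(wgt) * yy) / sw
      cx <- sum(colSums(wgt) * xx) / sw
    }
    c(cx, cy, s)
  }
  out <- t(mapply(refine, cand$i, cand$j))
  det <- data.frame(x = out[, 1], y = out[, 2], quality = out[, 3])
  det <- det[det$quality > 0, , drop = FALSE]
  det[order(-det$quality), , drop = FALSE]
}

#' Link per-frame detections into bead trajectories
#'
#' Frame-to-frame linking by globally optimal (minimum total
#' displacement) one-to-one assignment between active trajectories and
#' new detections, solved exactly with [lapMinAssign()]. A detection
#' farther than `maxDisp` (per frame of gap) from every active
#' trajectory starts a new trajectory rather than being force-assigned;
#' trajectories missing a detection are kept alive for up to `maxGap`
#' frames and re-joined when a detection reappears nearby.
#'
#' @param detections list of per-frame data.frames with columns `x`, `y`
#'   and optionally `z` (um); list order is frame order.
#' @param maxDisp maximum displacement per frame (um).
#' @param maxGap number of consecutive missing frames to bridge
#'   (default 1).
#' @return data.frame with columns `track_id`, `frame`, `x`, `y`
#'   (and `z` when present), sorted by track then frame.
#' @export
linkBeads <- function(detections, maxDisp, maxGap = 1L) {
  stopIfNot(maxDisp > 0, "maxDisp must be > 0")
  stopIfNot(is.list(detections), "detections must be a list of data.frames")
  hasZ <- any(vapply(detections,
                     function(d) !is.null(d) && "z" %in% names(d), logical(1)))
  cols <- c("x", "y", if (hasZ) "z")
  tracks <- list()   # each: list(id, pos, lastFrame, rows = data.frame)
  nextId <- 1L
  out <- list()
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    if (is.null(det)) det <- data.frame(x = numeric(), y = numeric())
    if (hasZ && !"z" %in% names(det)) det$z <- 0
    P <- as.matrix(det[, cols, drop = FALSE])
    live <- which(vapply(tracks, function(tr) f - tr$lastFrame <= maxGap + 1L,
                         logical(1)))
    nT <- length(live); nD <- nrow(P)
    assigned <- rep(NA_integer_, nD)
    if (nT > 0L && nD > 0L) {
      Tpos <- do.call(rbind, lapply(tracks[live], function(tr) tr$pos))
      gap <- vapply(tracks[live], function(tr) f - tr$lastFrame, numeric(1))
      rad <- maxDisp * gap
      d2 <- outer(rowSums(Tpos^2), rowSums(P^2), "+") - 2 * Tpos %*% t(P)
      d2[d2 < 0] <- 0
      d <- sqrt(d2)
      n <- nT + nD
      cost <- matrix(Inf, n, n)
      cost[seq_len(nT), seq_len(nD)] <- ifelse(d <= rad, d, Inf)
      cost[cbind(seq_len(nT), nD + seq_len(nT))] <- rad
      cost[cbind(nT + seq_len(nD), seq_len(nD))] <- maxDisp
      cost[nT + seq_len(nD), nD + seq_len(nT)] <- 0
      a <- lapMinAssign(cost)
      for (k in seq_len(nT)) {
        j <- a[k]
        if (!is.na(j) && j <= nD) assigned[j] <- live[k]
      }
    }
    for (j in seq_len(nD)) {
      ti <- assigned[j]
      if (is.na(ti)) {               # start a new trajectory
        ti <- length(tracks) + 1L
        tracks[[ti]] <- list(id = nextId, pos = P[j, ], lastFrame = f,
                             rows = list())
        nextId <- nextId + 1L
      }
      tracks[[ti]]$pos <- P[j, ]
      tracks[[ti]]$lastFrame <- f
      row <- c(list(track_id = tracks[[ti]]$id, frame = f),
               as.list(P[j, ]))
      tracks[[ti]]$rows[[length(tracks[[ti]]$rows) + 1L]] <- row
    }
  }
  rows <- unlist(lapply(tracks, function(tr) tr$rows), recursive = FALSE)
  if (!length(rows))
    return(data.frame(track_id = integer(), frame = integer(),
                      x = numeric(), y = numeric()))
  res <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  names(res) <- c("track_id", "frame", cols)
  res <- res[order(res$track_id, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cortex thickness from a pair of bead trajectories
#'
#' The pinched cortex thickness is the bead surface-to-surface gap:
#' `h = 1000 * (||c1 - c2|| - beadDiameter)` nm. Frames where the
#' center distance falls below the bead diameter are flagged "overlap"
#' (tracking error or membrane wrap) and must be excluded from metrics.
#'
#' @param traj1,traj2 data.frames with columns `frame`, `x`, `y` and
#'   optionally `z` (um).
#' @param beadDiameter bead diameter (um).
#' @return data.frame with columns `frame`, `D_um`, `h_nm`, `overlap`.
#' @examples
#' t1 <- data.frame(frame = 1, x = 0, y = 0, z = 0)
#' t2 <- data.frame(frame = 1, x = 4.8, y = 0, z = 0)
#' pairToThickness(t1, t2, beadDiameter = 4.5)  # h = 300 nm
#' @export
pairToThickness <- function(traj1, traj2, beadDiameter) {
  stopIfNot(beadDiameter > 0, "beadDiameter must be > 0")
  common <- intersect(traj1$frame, traj2$frame)
  if (!length(common)) stop("trajectories have disjoint frame spans")
  a <- traj1[match(common, traj1$frame), , drop = FALSE]
  b <- traj2[match(common, traj2$frame), , drop = FALSE]
  cols <- intersect(c("x", "y", "z"), intersect(names(a), names(b)))
  D <- sqrt(rowSums((as.matrix(a[, cols]) - as.matrix(b[, cols]))^2))
  data.frame(frame = common, D_um = D,
             h_nm = ifelse(D >= beadDiameter, 1000 * (D - beadDiameter), NA_real_),
             overlap = D < beadDiameter)
}
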