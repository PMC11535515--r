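#' Read and write multi-page TIFF stacks
#'
#' Thin wrappers around the tiff package that convert between the
#' `ny x nx x nframes` arrays used here and multi-page files.
#' Intensities are scaled to [0, 1] on write (the scale is stored in
#' the result's `"scale"` attribute on read only if provided on write
#' via the sidecar-free convention of dividing by `scale`).
#'
#' @param path file path.
#' @param expectedFrames if given, the frame count is validated against
#'   it and a mismatch is an error.
#' @return `readStack()`: numeric array `ny x nx x nframes`.
#' @export
readStack <- function(path, expectedFrames = NULL) {
  stopIfNot(file.exists(path), paste0("file not found: ", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  if (!is.null(expectedFrames) && length(pages) != expectedFrames)
    stop(sprintf("frame count mismatch: stack has %d frames, metadata says %d",
                 length(pages), expectedFrames))
  if (!length(pages)) return(array(numeric(0), dim = c(0L, 0L, 0L)))
  array(unlist(pages), dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                               length(pages)))
}

#' @rdname readStack
#' @param stack numeric array `ny x nx x nframes`.
#' @param scale intensity divisor applied before writing (TIFF floats
#'   must lie in [0, 1]); default scales by the stack maximum.
#' @export
writeStack <- function(stack, path, scale = max(stack, 1)) {
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(f) pmin(pmax(stack[, , f] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a typed CSV table with schema validation
#'
#' Column names carry their units (e.g. `t_s`, `x_um`, `F_pN`);
#' analyzers refuse tables whose required columns are absent, naming
#' the offending column.
#'
#' @param path CSV file path.
#' @param schema character vector of required column names.
#' @return data.frame.
#' @export
readTable <- function(path, schema = character()) {
  stopIfNot(file.exists(path), paste0("file not found: ", path))
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(schema, names(tab))
  if (length(missing))
    stop("table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  tab
}

# full-precision CSV so that write -> read round-trips doubles exactly
writeTableExact <- function(tab, path) {
  out <- tab
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a pinch recording as CSV + JSON sidecar
#'
#' The per-frame table goes to `<path>` (CSV, full precision: numeric
#' values round-trip exactly) and the metadata (bead diameter,
#' magnetization model, scalar ground-truth parameters and seed) to
#' `<path>.json`.
#'
#' @param rec a [PinchRecording-class].
#' @param path CSV file path.
#' @return `readPinchRecording()` returns the reconstructed
#'   [PinchRecording-class] (per-frame ground-truth series are not
#'   persisted, scalar ground truth is).
#' @export
writePinchRecording <- function(rec, path) {
  writeTableExact(frames(rec), path)
  gt <- groundTruth(rec)
  gt <- gt[!vapply(gt, function(x) is(x, "FieldProtocol") || length(x) > 16,
                   logical(1))]
  meta <- list(bead_diameter_um = beadDiameter(rec),
               magnetization = list(m_sat = rec@magnetization@mSat,
                                    b_half_mT = rec@magnetization@bHalf),
               ground_truth = gt)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writePinchRecording
#' @export
readPinchRecording <- function(path) {
  fr <- readTable(path, schema = c("t_s", "B_mT", "phase", "cycle",
                                   "x1_um", "y1_um", "z1_um",
                                   "x2_um", "y2_um", "z2_um",
                                   "D_um", "h_nm", "F_pN", "flagged"))
  fr$flagged <- as.logical(fr$flagged)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mag <- magnetizationModel(mSat = meta$magnetization$m_sat,
                            bHalf = meta$magnetization$b_half_mT)
  gt <- if (is.null(meta$ground_truth)) list() else as.list(meta$ground_truth)
  new("PinchRecording", frames = fr, beadDiameter = meta$bead_diameter_um,
      magnetization = mag, groundTruth = gt)
}

#' Read a migration track table
#'
#' Reads a CSV of track points with a configurable column mapping, so
#' exports from external trackers can be consumed directly.
#'
#' @param path CSV file path.
#' @param mapping named character vector mapping the canonical names
#'   `track_id`, `t_s`, `x_um`, `y_um` (and optionally `z_um`) to the
#'   file's column names.
#' @return data.frame with canonical column names.
#' @export
readTrackTable <- function(path,
                           mapping = c(track_id = "track_id", t_s = "t_s",
                                       x_um = "x_um", y_um = "y_um")) {
  tab <- readTable(path, schema = unname(mapping))
  out <- tab[, unname(mapping), drop = FALSE]
  names(out) <- names(mapping)
  out
}

#' Write an analysis report as JSON
#'
#' Serializes a (nested) list of results deterministically: same
#' results, byte-identical file. The package version is included for
#' provenance; no timestamps are written.
#'
#' @param results named list.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeReport <- function(results, path) {
  payload <- c(list(package = "macromech",
                    version = as.character(utils::packageVersion("macromech"))),
               results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
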