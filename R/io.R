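# File formats: multi-page TIFF stacks with sidecar JSON calibration, ROI
# JSON, kymograph CSV, vessel-record CSV and fit-report JSON.

#' Write a time-lapse stack as multi-page TIFF plus sidecar JSON
#'
#' TIFF samples are stored rescaled to `[0, 1]`; the original intensity
#' range and the calibration live in the sidecar, so a read round-trips to
#' float32 precision.
#'
#' @param stack a [time_lapse_stack()].
#' @param path output TIFF path.
#' @param sidecar sidecar JSON path (default `path` + `".json"`).
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, sidecar = paste0(path, ".json")) {
  vf_check(inherits(stack, "time_lapse_stack"), "vascflow_parameter_error",
           "stack must be a time_lapse_stack")
  arr <- unclass(stack)
  rng <- range(arr)
  scaled <- if (rng[2] > rng[1])
    (arr - rng[1]) / (rng[2] - rng[1]) else arr * 0
  pages <- lapply(seq_len(dim(arr)[1]), function(t) scaled[t, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(
    pixel_size_um = attr(stack, "pixel_size_um"),
    frame_interval_s = attr(stack, "frame_interval_s"),
    intensity_min = rng[1], intensity_max = rng[2],
    n_frames = dim(arr)[1]
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a time-lapse stack written by [write_stack_tiff()]
#'
#' @param path TIFF path.
#' @param sidecar sidecar JSON path.
#' @return a [time_lapse_stack()].
#' @export
read_stack_tiff <- function(path, sidecar = paste0(path, ".json")) {
  vf_check(file.exists(path) && file.exists(sidecar),
           "vascflow_parameter_error", "stack TIFF or sidecar JSON missing")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0, dim = c(length(pages), h, w))
  span <- meta$intensity_max - meta$intensity_min
  for (t in seq_along(pages))
    arr[t, , ] <- pages[[t]] * span + meta$intensity_min
  time_lapse_stack(arr, meta$pixel_size_um, meta$frame_interval_s)
}

#' Write / read a line ROI as JSON
#'
#' @param roi a [line_roi()].
#' @param path JSON path.
#' @return `path` (write) or a [line_roi()] (read).
#' @export
write_roi_json <- function(roi, path) {
  vf_check(inherits(roi, "line_roi"), "vascflow_parameter_error",
           "roi must be a line_roi")
  jsonlite::write_json(list(points = roi$points,
                            thickness_um = roi$thickness_um,
                            kind = roi$kind),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  line_roi(obj$points, thickness_um = obj$thickness_um, kind = obj$kind)
}

#' Write / read a kymograph as CSV
#'
#' Calibration and the normalized flag travel in `#`-prefixed header lines
#' above the matrix (rows = frames, columns = axial positions).
#'
#' @param kymo a [kymograph()].
#' @param path CSV path.
#' @return `path` (write) or a [kymograph()] (read).
#' @export
write_kymograph_csv <- function(kymo, path) {
  vf_check(inherits(kymo, "kymograph"), "vascflow_parameter_error",
           "kymo must be a kymograph")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# pixel_size_um=%.17g", attr(kymo, "pixel_size_um")),
    sprintf("# frame_interval_s=%.17g", attr(kymo, "frame_interval_s")),
    sprintf("# normalized=%s", isTRUE(attr(kymo, "normalized")))
  ), con)
  utils::write.table(unclass(kymo), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_kymograph_csv
#' @export
read_kymograph_csv <- function(path) {
  hdr <- readLines(path, n = 3)
  get_val <- function(key) sub(sprintf("^# %s=", key), "", grep(
    sprintf("^# %s=", key), hdr, value = TRUE))
  vals <- as.matrix(utils::read.table(path, sep = ",", comment.char = "#"))
  dimnames(vals) <- NULL
  kymograph(vals, as.numeric(get_val("pixel_size_um")),
            as.numeric(get_val("frame_interval_s")),
            normalized = identical(get_val("normalized"), "TRUE"))
}

#' Write a vessel-record table as CSV with a metadata header
#'
#' @param records data frame of vessel records.
#' @param path CSV path.
#' @param config_hash optional configuration hash recorded in the header.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(sprintf("# config_hash=%s", config_hash), con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write a branching-fit report as JSON
#'
#' @param fit a [fit_branching_exponent()] result.
#' @param path JSON path.
#' @param config_hash optional configuration hash.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, config_hash = NULL) {
  vf_check(inherits(fit, "branching_fit"), "vascflow_parameter_error",
           "fit must be a branching_fit")
  out <- unclass(fit)
  if (!is.null(config_hash)) out$config_hash <- config_hash
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
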