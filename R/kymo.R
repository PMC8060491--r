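# Kymograph construction and normalization.
#
# Conventions: arrays are (time, y, x); coordinates are 1-based with pixel
# centers at integer (x = column, y = row) positions, matching R indexing.

#' Calibrated time-lapse stack
#'
#' @param frames numeric array with dimensions `(time, y, x)`; at least two
#'   frames, all intensities finite.
#' @param pixel_size_um um per pixel (> 0).
#' @param frame_interval_s seconds per frame (> 0).
#' @return object of class `time_lapse_stack` (the array with calibration
#'   attributes).
#' @export
time_lapse_stack <- function(frames, pixel_size_um, frame_interval_s) {
  vf_check(is.array(frames) && length(dim(frames)) == 3,
           "vascflow_parameter_error", "frames must be a (time, y, x) array")
  vf_check(dim(frames)[1] >= 2, "vascflow_parameter_error",
           "a stack needs at least 2 frames")
  vf_check(all(is.finite(frames)), "vascflow_parameter_error",
           "stack intensities must be finite")
  vf_check(is_num1(pixel_size_um, 0, strict = TRUE) &&
             is_num1(frame_interval_s, 0, strict = TRUE),
           "vascflow_parameter_error", "calibrations must be > 0")
  structure(frames, pixel_size_um = pixel_size_um,
            frame_interval_s = frame_interval_s,
            class = c("time_lapse_stack", "array"))
}

#' Line / polyline region of interest
#'
#' @param points matrix or data frame with columns `x` (column index) and
#'   `y` (row index), at least two points, 1-based pixel-center coordinates.
#' @param thickness_um ROI thickness in um (> 0); intensity is averaged
#'   across this thickness perpendicular to the line. The default 3 um
#'   matches the conventional center-line ROI width for these vessels.
#' @param kind `"axial"` (center line, for kymographs) or `"cross"`
#'   (across the vessel, for diameter).
#' @return object of class `line_roi`.
#' @export
line_roi <- function(points, thickness_um = 3, kind = c("axial", "cross")) {
  kind <- match.arg(kind)
  points <- as.data.frame(points)
  vf_check(all(c("x", "y") %in% names(points)) && nrow(points) >= 2,
           "vascflow_geometry_error",
           "an ROI needs >= 2 points with x and y coordinates")
  vf_check(all(is.finite(points$x)) && all(is.finite(points$y)),
           "vascflow_geometry_error", "ROI coordinates must be finite")
  vf_check(is_num1(thickness_um, 0, strict = TRUE),
           "vascflow_parameter_error", "thickness_um must be > 0")
  structure(list(points = points[, c("x", "y")], thickness_um = thickness_um,
                 kind = kind), class = "line_roi")
}

#' Kymograph container
#'
#' @param values time x axial-position matrix (rows = frames).
#' @param pixel_size_um,frame_interval_s calibration copied from the stack.
#' @param normalized logical flag; set by [normalize_kymograph()].
#' @return object of class `kymograph`.
#' @export
kymograph <- function(values, pixel_size_um, frame_interval_s,
                      normalized = FALSE) {
  vf_check(is.matrix(values) && nrow(values) >= 2 && ncol(values) >= 2,
           "vascflow_parameter_error",
           "a kymograph needs >= 2 rows (time) and >= 2 columns (position)")
  vf_check(all(is.finite(values)), "vascflow_parameter_error",
           "kymograph values must be finite")
  structure(values, pixel_size_um = pixel_size_um,
            frame_interval_s = frame_interval_s, normalized = normalized,
            class = c("kymograph", "matrix"))
}

# Resample a polyline at unit arc-length spacing; returns positions and unit
# normals at each sample.
resample_polyline <- function(points, step = 1) {
  x <- points$x; y <- points$y
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  vf_check(sum(seg) >= step, "vascflow_geometry_error",
           "ROI polyline shorter than one sampling step")
  s <- c(0, cumsum(seg))
  si <- seq(0, s[length(s)], by = step)
  xi <- stats::approx(s, x, xout = si)$y
  yi <- stats::approx(s, y, xout = si)$y
  n <- length(si)
  tx <- c(xi[2] - xi[1], (xi[-(1:2)] - xi[-c(n - 1, n)]) / 2,
          xi[n] - xi[n - 1])
  ty <- c(yi[2] - yi[1], (yi[-(1:2)] - yi[-c(n - 1, n)]) / 2,
          yi[n] - yi[n - 1])
  norm <- sqrt(tx^2 + ty^2)
  list(x = xi, y = yi, nx = -ty / norm, ny = tx / norm)
}

# Bilinear interpolation of matrix `img` at (row = y, col = x) vectors.
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x0 <- pmin(pmax(floor(x), 1), w - 1); y0 <- pmin(pmax(floor(y), 1), h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0, x0)]; i01 <- img[cbind(y0, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x0)]; i11 <- img[cbind(y0 + 1, x0 + 1)]
  i00 * (1 - fy) * (1 - fx) + i01 * (1 - fy) * fx +
    i10 * fy * (1 - fx) + i11 * fy * fx
}

#' Extract a kymograph along a vessel center line
#'
#' One row per frame; each column is the intensity sampled along the
#' polyline at 1-px arc-length steps (bilinear interpolation) and averaged
#' across the ROI thickness, using samples at 1-px steps along the local
#' normal spanning +/- thickness/2.
#'
#' @param stack a [time_lapse_stack()].
#' @param roi an axial [line_roi()] lying inside the image bounds.
#' @return a raw (unnormalized) [kymograph()] with the stack's calibration.
#' @export
extract_kymograph <- function(stack, roi) {
  vf_check(inherits(stack, "time_lapse_stack"), "vascflow_parameter_error",
           "stack must be a time_lapse_stack")
  vf_check(inherits(roi, "line_roi") && roi$kind == "axial",
           "vascflow_parameter_error", "roi must be an axial line_roi")
  px <- attr(stack, "pixel_size_um")
  d <- dim(stack)
  rs <- resample_polyline(roi$points)
  n_pos <- length(rs$x)
  vf_check(n_pos >= 2, "vascflow_geometry_error",
           "ROI yields fewer than 2 sample positions")
  half <- floor((roi$thickness_um / px) / 2)
  offs <- (-half):half
  # offsets applied along the local normal at each sample
  sx <- rs$x + outer(rs$nx, offs)
  sy <- rs$y + outer(rs$ny, offs)
  vf_check(all(sx >= 1 & sx <= d[3] & sy >= 1 & sy <= d[2]),
           "vascflow_bounds_error",
           "ROI (including its thickness) extends outside the image")
  vals <- matrix(0, d[1], n_pos)
  for (t in seq_len(d[1])) {
    fr <- stack[t, , ]
    samp <- bilinear_sample(fr, as.vector(sx), as.vector(sy))
    vals[t, ] <- rowMeans(matrix(samp, n_pos, length(offs)))
  }
  kymograph(vals, px, attr(stack, "frame_interval_s"))
}

# Per-column rolling temporal mean with a truncated (shrinking) symmetric
# window at the edges, via cumulative sums.
rolling_mean_columns <- function(m, window) {
  n <- nrow(m)
  lo_off <- floor((window - 1) / 2)
  hi_off <- ceiling((window - 1) / 2)
  i <- seq_len(n)
  lo <- pmax(i - lo_off, 1)
  hi <- pmin(i + hi_off, n)
  cs <- apply(m, 2, cumsum)
  cs <- rbind(0, cs)
  (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

# Core normalization (no precondition check); used to verify idempotency.
kymo_normalize_core <- function(values, window_frames) {
  bg <- rolling_mean_columns(values, window_frames)
  res <- values - bg
  s <- stats::sd(res)
  vf_check(is.finite(s) && s > 0, "vascflow_degenerate_error",
           "zero variance after background subtraction")
  (res - mean(res)) / s
}

#' Normalize a kymograph
#'
#' Removes static structure (vertical stripes from immobile objects and
#' axial intensity variation) by subtracting, in each position column, that
#' column's rolling temporal average (default window 20 frames, truncated
#' symmetrically at the first/last frames), then standardizes globally to
#' mean 0 and standard deviation 1.
#'
#' @param kymo a raw [kymograph()] (not yet normalized).
#' @param window_frames rolling-average window in frames (>= 1).
#' @return the normalized [kymograph()] (`normalized` flag set).
#' @export
normalize_kymograph <- function(kymo, window_frames = 20) {
  vf_check(inherits(kymo, "kymograph"), "vascflow_parameter_error",
           "kymo must be a kymograph")
  vf_check(!isTRUE(attr(kymo, "normalized")), "vascflow_state_error",
           "kymograph is already normalized")
  vf_check(is_count(window_frames, min = 1), "vascflow_parameter_error",
           "window_frames must be an integer >= 1")
  vals <- kymo_normalize_core(unclass(kymo), window_frames)
  kymograph(vals, attr(kymo, "pixel_size_um"),
            attr(kymo, "frame_interval_s"), normalized = TRUE)
}
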