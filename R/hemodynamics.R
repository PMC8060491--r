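# Vessel diameter, volumetric flow, Murray's-law branching-exponent fit and
# group comparisons.

#' Minimal projection of a time-lapse stack
#'
#' Per-pixel minimum over time. Passing blood cells darken the lumen, so the
#' minimal projection outlines the vessel interior.
#'
#' @param stack a [time_lapse_stack()].
#' @return 2D intensity matrix (y, x).
#' @export
min_projection <- function(stack) {
  vf_check(inherits(stack, "time_lapse_stack"), "vascflow_parameter_error",
           "stack must be a time_lapse_stack")
  apply(unclass(stack), c(2, 3), min)
}

#' Measure vessel diameter from an intensity profile
#'
#' The default method samples the intensity profile along a cross-vessel
#' line (1-px arc-length steps, bilinear interpolation) and returns the
#' full width at half minimum: the lumen is darker than the background in a
#' minimal projection, the baseline is taken from the outer 10% of samples
#' at each end, and the outermost crossings of the half-depth level (the
#' first from each end of the profile) are located by linear interpolation.
#' Taking the outermost crossings makes the measurement robust to texture
#' inside the lumen (cell tracks darker than the vessel floor); for a clean
#' unimodal dip it coincides with the usual nearest-crossing definition.
#' The measurement is invariant to affine intensity transforms.
#' `method = "endpoints"`
#' reproduces a fully manual measurement: the ROI's polyline length.
#'
#' @param image 2D intensity matrix (typically a [min_projection()]).
#' @param cross_roi a [line_roi()] of kind `"cross"` spanning the vessel.
#' @param pixel_size_um um per pixel.
#' @param method `"fwhm"` or `"endpoints"`.
#' @return diameter in um.
#' @export
measure_diameter <- function(image, cross_roi, pixel_size_um,
                             method = c("fwhm", "endpoints")) {
  method <- match.arg(method)
  vf_check(inherits(cross_roi, "line_roi") && cross_roi$kind == "cross",
           "vascflow_parameter_error", "cross_roi must be a cross line_roi")
  vf_check(is_num1(pixel_size_um, 0, strict = TRUE),
           "vascflow_parameter_error", "pixel_size_um must be > 0")
  rs <- resample_polyline(cross_roi$points)
  if (method == "endpoints") {
    seg <- sqrt(diff(cross_roi$points$x)^2 + diff(cross_roi$points$y)^2)
    return(sum(seg) * pixel_size_um)
  }
  vf_check(is.matrix(image), "vascflow_parameter_error",
           "image must be a 2D matrix")
  vf_check(all(rs$x >= 1 & rs$x <= ncol(image) &
                 rs$y >= 1 & rs$y <= nrow(image)),
           "vascflow_bounds_error", "cross ROI extends outside the image")
  prof <- bilinear_sample(image, rs$x, rs$y)
  n <- length(prof)
  k <- max(1, floor(0.1 * n))
  baseline <- mean(c(prof[1:k], prof[(n - k + 1):n]))
  i_min <- which.min(prof)
  depth <- baseline - prof[i_min]
  vf_check(depth > 1e-9 * max(abs(baseline), 1),
           "vascflow_measurement_failure",
           "profile has no discernible minimum (flat profile?)")
  level <- baseline - depth / 2
  cross_at <- function(i, j) {
    # linear interpolation of the crossing between samples i and j
    i + (level - prof[i]) / (prof[j] - prof[i]) * (j - i)
  }
  below <- which(prof < level)
  left <- NA_real_; right <- NA_real_
  if (length(below) && below[1] > 1 && below[length(below)] < n) {
    left <- cross_at(below[1] - 1, below[1])
    right <- cross_at(below[length(below)], below[length(below)] + 1)
  }
  vf_check(is.finite(left) && is.finite(right),
           "vascflow_measurement_failure",
           "profile lacks two half-level crossings")
  (right - left) * pixel_size_um
}

#' Volumetric flow from maximum velocity and diameter
#'
#' `plug` assumes a flat velocity profile, `Q = v_max * pi d^2 / 4`;
#' `poiseuille` assumes a parabolic profile whose mean is half the maximum,
#' `Q = (v_max / 2) * pi d^2 / 4`. The constant profile factor cancels in
#' the branching-exponent fit, so the model choice does not affect the
#' fitted exponent.
#'
#' @param v_max_um_s maximum flow speed (um/s, >= 0).
#' @param diameter_um vessel diameter (um, > 0).
#' @param profile_model `"plug"` (default) or `"poiseuille"`.
#' @return volumetric flow rate in um^3/s, with the model recorded in the
#'   `"profile_model"` attribute.
#' @export
volumetric_flow <- function(v_max_um_s, diameter_um,
                            profile_model = c("plug", "poiseuille")) {
  profile_model <- match.arg(profile_model)
  vf_check(is.numeric(v_max_um_s) && all(is.finite(v_max_um_s)) &&
             all(v_max_um_s >= 0), "vascflow_parameter_error",
           "v_max_um_s must be >= 0")
  vf_check(is.numeric(diameter_um) && all(is.finite(diameter_um)) &&
             all(diameter_um > 0), "vascflow_parameter_error",
           "diameter_um must be > 0")
  fac <- if (profile_model == "plug") 1 else 0.5
  structure(fac * v_max_um_s * pi * diameter_um^2 / 4,
            profile_model = profile_model)
}

#' Fit the Murray's-law branching exponent
#'
#' Ordinary least squares of `log(Q)` on `log(d)` across vessels; the slope
#' is the branching exponent. A network optimized in the sense of Murray's
#' law has exponent 3. The fit is invariant to rescaling Q by any positive
#' constant, hence to the plug/poiseuille prefactor.
#'
#' @param records data frame with columns `diameter_um` and `q_flow` (one
#'   row per vessel). Rows with non-positive values are dropped with a
#'   warning; at least 3 usable rows are required.
#' @return object of class `branching_fit`: `exponent`, `intercept`,
#'   `exponent_stderr`, `r_squared`, `n_vessels`.
#' @export
fit_branching_exponent <- function(records) {
  vf_check(is.data.frame(records) &&
             all(c("diameter_um", "q_flow") %in% names(records)),
           "vascflow_parameter_error",
           "records must have diameter_um and q_flow columns")
  ok <- is.finite(records$diameter_um) & is.finite(records$q_flow) &
    records$diameter_um > 0 & records$q_flow > 0
  if (any(!ok))
    warning(sprintf("dropping %d record(s) with non-positive d or Q",
                    sum(!ok)))
  d <- records$diameter_um[ok]; q <- records$q_flow[ok]
  vf_check(length(d) >= 3, "vascflow_fit_error",
           "need at least 3 vessels with positive d and Q")
  fit <- ols_loglog(d, q)
  structure(list(exponent = fit$slope, intercept = fit$intercept,
                 exponent_stderr = fit$stderr, r_squared = fit$r_squared,
                 n_vessels = fit$n), class = "branching_fit")
}

#' @export
print.branching_fit <- function(x, ...) {
  cat(sprintf("branching exponent n = %.3f +/- %.3f (r^2 = %.3f, %d vessels)\n",
              x$exponent, x$exponent_stderr, x$r_squared, x$n_vessels))
  invisible(x)
}

#' Compare a vessel measurement between two age groups
#'
#' Two-sample two-tailed t-test (pooled variance by default) on a chosen
#' column of the vessel records, optionally restricted to a closed-open
#' diameter band `[lo, hi)` — the standard way to compare flow velocities
#' between age groups within vessels of similar diameter.
#'
#' @param young,old data frames of vessel records (need `diameter_um` and
#'   the `value` column).
#' @param value column to compare (default `"diameter_um"`).
#' @param band optional numeric `c(lo, hi)` diameter band, um.
#' @param variance `"pooled"` or `"welch"`.
#' @return a `vf_t_test` (see [t_test_groups()]); signals
#'   `vascflow_empty_comparison` if a group has fewer than 2 records after
#'   band restriction.
#' @export
compare_diameter_groups <- function(young, old, value = "diameter_um",
                                    band = NULL,
                                    variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  pick <- function(df) {
    vf_check(is.data.frame(df) && value %in% names(df) &&
               "diameter_um" %in% names(df), "vascflow_parameter_error",
             sprintf("records need diameter_um and %s columns", value))
    if (!is.null(band)) {
      vf_check(is.numeric(band) && length(band) == 2 && band[1] < band[2],
               "vascflow_parameter_error", "band must be c(lo, hi)")
      df <- df[df$diameter_um >= band[1] & df$diameter_um < band[2], ,
               drop = FALSE]
    }
    df[[value]]
  }
  a <- pick(young); b <- pick(old)
  if (length(a) < 2 || length(b) < 2)
    vf_error("vascflow_empty_comparison",
             "fewer than 2 records per group after band restriction")
  t_test_groups(a, b, design = "two_sample", variance = variance)
}
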