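# Vascular-bed size and percent-regression scoring from colony outlines.

#' Perimeter of a closed polygon
#'
#' Sum of edge lengths; the closing edge from the last vertex back to the
#' first is included.
#'
#' @param poly data frame (or matrix) with `x` and `y` vertex coordinates
#'   (>= 3 vertices).
#' @return perimeter in the polygon's units.
#' @export
polygon_perimeter <- function(poly) {
  poly <- as.data.frame(poly)
  vf_check(all(c("x", "y") %in% names(poly)) && nrow(poly) >= 3,
           "vascflow_geometry_error",
           "a polygon needs >= 3 vertices with x and y")
  vf_check(all(is.finite(poly$x)) && all(is.finite(poly$y)),
           "vascflow_geometry_error", "polygon coordinates must be finite")
  x <- poly$x; y <- poly$y
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

#' Vascular-bed size from the two border perimeters
#'
#' `s_vb = p_a - p_b`: the perimeter of the border traced around the
#' peripheral ampullae minus the perimeter of the border around the zooid
#' bodies. Both must be in the same units (enforced by the `units` tags,
#' never inferred). A fully regressed bed (`p_a == p_b`) gives 0; `p_a <
#' p_b` is a geometry error.
#'
#' @param p_a,p_b border perimeters (ampullae and bodies), `p_a >= p_b >= 0`.
#' @param units unit tag carried on the result (default `"um"`); if either
#'   input carries a `"units"` attribute the tags must agree.
#' @return bed size `s_vb` with a `"units"` attribute.
#' @export
bed_size <- function(p_a, p_b, units = "um") {
  for (v in list(p_a, p_b)) {
    u <- attr(v, "units")
    if (!is.null(u))
      vf_check(identical(u, units), "vascflow_parameter_error",
               "perimeter unit tags disagree")
  }
  vf_check(is_num1(as.numeric(p_a), 0) && is_num1(as.numeric(p_b), 0),
           "vascflow_parameter_error", "perimeters must be >= 0")
  vf_check(as.numeric(p_a) >= as.numeric(p_b), "vascflow_geometry_error",
           "ampullae border perimeter must not be smaller than body border")
  structure(as.numeric(p_a) - as.numeric(p_b), units = units)
}

#' Bed size of a simulated or traced outline pair
#'
#' @param outline list with `ampullae` and `body` polygons (as accepted by
#'   [polygon_perimeter()]) and optionally a `units` tag.
#' @return `s_vb` via [bed_size()].
#' @export
measure_bed <- function(outline) {
  vf_check(is.list(outline) && all(c("ampullae", "body") %in% names(outline)),
           "vascflow_parameter_error",
           "outline must have ampullae and body polygons")
  units <- if (!is.null(outline$units)) outline$units else "um"
  bed_size(polygon_perimeter(outline$ampullae),
           polygon_perimeter(outline$body), units = units)
}

#' Percent vascular regression
#'
#' `100 * (s_ctrl - s_regres) / s_ctrl`, the percent loss of vascular-bed
#' size after treatment relative to before. Negative values indicate the
#' bed grew. Scale-invariant: multiplying both bed sizes by a positive
#' constant leaves the percentage unchanged.
#'
#' @param s_ctrl bed size before treatment (> 0).
#' @param s_regres bed size after treatment (>= 0).
#' @return percent regression.
#' @export
percent_regression <- function(s_ctrl, s_regres) {
  s_ctrl <- as.numeric(s_ctrl); s_regres <- as.numeric(s_regres)
  vf_check(is_num1(s_ctrl, 0, strict = TRUE), "vascflow_parameter_error",
           "s_ctrl must be > 0")
  vf_check(is_num1(s_regres), "vascflow_parameter_error",
           "s_regres must be finite")
  vf_check(s_regres >= 0, "vascflow_parameter_error",
           "s_regres must be >= 0")
  100 * (s_ctrl - s_regres) / s_ctrl
}

#' Compare percent-regression values between two groups
#'
#' Paired (default, matching the before/after design applied per colony)
#' or unpaired two-tailed t-test on per-colony percent-regression values.
#'
#' @param young,old numeric vectors of percent regression (each >= 2).
#' @param paired logical.
#' @return a `vf_t_test` (see [t_test_groups()]).
#' @export
compare_regression <- function(young, old, paired = FALSE) {
  t_test_groups(young, old,
                design = if (paired) "paired" else "two_sample",
                variance = "pooled")
}
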