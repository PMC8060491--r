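# Shift-maximizing autocorrelation velocimetry on normalized kymographs.
#
# For each timepoint a short local section of the kymograph is taken and the
# signed axial shift that maximizes the mean Pearson correlation between
# row pairs one frame apart is found; the correlation magnitude at the peak
# gates low-contrast (particle-free) regions out of the analysis.

#' Velocimetry configuration
#'
#' @param section_frames length of the local kymograph section in frames
#'   (>= 2; default 3, i.e. two one-frame row pairs per timepoint).
#' @param corr_threshold validity gate on the peak correlation magnitude
#'   (strictly between 0 and 1; default 0.8 — timepoints whose peak
#'   correlation does not exceed it carry no velocity).
#' @param max_shift_px half-range of the signed shift search (>= 1).
#' @param subpixel logical; refine the integer-lag argmax by three-point
#'   parabolic interpolation (reduces quantization at low speeds).
#' @return object of class `velocimetry_config`.
#' @export
velocimetry_config <- function(section_frames = 3, corr_threshold = 0.8,
                               max_shift_px = 15, subpixel = TRUE) {
  vf_check(is_count(section_frames, min = 2), "vascflow_parameter_error",
           "section_frames must be an integer >= 2")
  vf_check(is_num1(corr_threshold) && corr_threshold > 0 &&
             corr_threshold < 1, "vascflow_parameter_error",
           "corr_threshold must lie strictly in (0, 1)")
  vf_check(is_count(max_shift_px, min = 1), "vascflow_parameter_error",
           "max_shift_px must be an integer >= 1")
  structure(list(section_frames = as.integer(section_frames),
                 corr_threshold = corr_threshold,
                 max_shift_px = as.integer(max_shift_px),
                 subpixel = isTRUE(subpixel)),
            class = "velocimetry_config")
}

# Pearson correlation between a[i] and b[i + s] over their overlap; 0-length
# or zero-variance overlaps give NA.
shifted_cor <- function(a, b, s) {
  L <- length(a)
  i0 <- max(1, 1 - s); i1 <- min(L, L - s)
  if (i1 - i0 < 2) return(NA_real_)
  x <- a[i0:i1]; y <- b[(i0 + s):(i1 + s)]
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0)
    return(NA_real_)
  stats::cor(x, y)
}

#' Estimate a signed velocity trace from a normalized kymograph
#'
#' For each timepoint `t` the rows `t .. t + section_frames - 1` are taken;
#' for every candidate signed shift `s` in `-max_shift_px .. max_shift_px`
#' the Pearson correlation between row pairs one frame apart (second row
#' displaced by `s`) is averaged over the section. The shift maximizing this
#' mean correlation gives the per-frame displacement; ties resolve toward
#' the smaller `|s|` (bias toward no flow under ambiguity). A timepoint is
#' valid only if the peak correlation exceeds `corr_threshold`; invalid
#' timepoints carry `NA` velocity. Velocity is converted with the
#' kymograph's calibration: `v = shift * pixel_size_um / frame_interval_s`.
#'
#' @param kymo a normalized [kymograph()] with at least `section_frames`
#'   rows and wider than `2 * max_shift_px` columns.
#' @param cfg a [velocimetry_config()].
#' @return object of class `velocity_trace`: data frame with one row per
#'   timepoint (`t`, `shift_px`, `velocity_um_s`, `peak_corr`, `valid`),
#'   calibration and config kept as attributes.
#' @export
estimate_velocity_trace <- function(kymo, cfg = velocimetry_config()) {
  vf_check(inherits(kymo, "kymograph"), "vascflow_parameter_error",
           "kymo must be a kymograph")
  vf_check(isTRUE(attr(kymo, "normalized")), "vascflow_state_error",
           "kymograph must be normalized first (see normalize_kymograph)")
  vf_check(inherits(cfg, "velocimetry_config"), "vascflow_parameter_error",
           "cfg must be a velocimetry_config")
  vals <- unclass(kymo)
  n_t <- nrow(vals); L <- ncol(vals)
  vf_check(n_t >= cfg$section_frames, "vascflow_parameter_error",
           "kymograph has fewer rows than section_frames")
  vf_check(L > 2 * cfg$max_shift_px, "vascflow_geometry_error",
           "kymograph narrower than 2 * max_shift_px")
  shifts <- (-cfg$max_shift_px):cfg$max_shift_px

  # correlation of each consecutive row pair at each shift, computed once
  # and shared by the overlapping sections
  pair_cor <- matrix(NA_real_, n_t - 1, length(shifts))
  for (r in seq_len(n_t - 1))
    for (k in seq_along(shifts))
      pair_cor[r, k] <- shifted_cor(vals[r, ], vals[r + 1, ], shifts[k])

  n_pts <- n_t - cfg$section_frames + 1
  shift_px <- rep(NA_real_, n_pts)
  peak_corr <- rep(NA_real_, n_pts)
  order_pref <- order(abs(shifts), shifts)  # small |s| first for tie-breaks
  for (t in seq_len(n_pts)) {
    rows <- t:(t + cfg$section_frames - 2)
    cur <- colMeans(pair_cor[rows, , drop = FALSE])
    if (all(!is.finite(cur))) next
    best <- order_pref[which.max(cur[order_pref])]
    pc <- cur[best]
    peak_corr[t] <- pc
    s_hat <- shifts[best]
    if (cfg$subpixel && best > 1 && best < length(shifts) &&
        is.finite(cur[best - 1]) && is.finite(cur[best + 1])) {
      denom <- cur[best - 1] - 2 * cur[best] + cur[best + 1]
      if (is.finite(denom) && denom < 0) {
        delta <- 0.5 * (cur[best - 1] - cur[best + 1]) / denom
        if (abs(delta) <= 1) s_hat <- s_hat + delta
      }
    }
    shift_px[t] <- s_hat
  }
  valid <- !is.na(peak_corr) & peak_corr > cfg$corr_threshold
  px <- attr(kymo, "pixel_size_um"); dt <- attr(kymo, "frame_interval_s")
  velocity <- ifelse(valid, shift_px * px / dt, NA_real_)
  structure(data.frame(t = seq_len(n_pts), shift_px = shift_px,
                       velocity_um_s = velocity, peak_corr = peak_corr,
                       valid = valid),
            pixel_size_um = px, frame_interval_s = dt, config = cfg,
            class = c("velocity_trace", "data.frame"))
}

#' Summarize a vessel's velocity trace
#'
#' Per-vessel summary over the valid timepoints: maximum flow speed (the
#' quantity used against vessel diameter in branching fits), median speed,
#' valid fraction, and the number of flow-direction reversals (sign changes
#' between consecutive valid nonzero velocities; exact zeros do not break a
#' run).
#'
#' @param trace a [estimate_velocity_trace()] result with at least one valid
#'   timepoint; a trace with none signals a `vascflow_empty_summary` error
#'   (the vessel is excluded, as low-contrast vessels are).
#' @return list with `v_max_um_s`, `v_median_um_s`, `valid_fraction`,
#'   `n_valid`, `n_reversals`.
#' @export
summarize_vessel_velocity <- function(trace) {
  vf_check(inherits(trace, "velocity_trace"), "vascflow_parameter_error",
           "trace must be a velocity_trace")
  v <- trace$velocity_um_s[trace$valid]
  if (length(v) == 0)
    vf_error("vascflow_empty_summary",
             "no valid timepoints: vessel excluded (low contrast)")
  signs <- sign(v)
  signs <- signs[signs != 0]
  n_rev <- if (length(signs) > 1) sum(diff(signs) != 0) else 0L
  list(v_max_um_s = max(abs(v)),
       v_median_um_s = stats::median(abs(v)),
       valid_fraction = mean(trace$valid),
       n_valid = length(v),
       n_reversals = as.integer(n_rev))
}
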