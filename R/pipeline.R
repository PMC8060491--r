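# End-to-end flow pipeline: stack -> kymograph -> velocimetry -> diameter ->
# volumetric flow -> branching-exponent fit, with per-vessel failure
# isolation and a reproducible configuration record.

#' Pipeline configuration
#'
#' One object holding every tunable of the flow pipeline. Serializes to
#' JSON and round-trips unchanged ([write_pipeline_config()] /
#' [read_pipeline_config()]); [config_hash()] gives a digest recorded in
#' every output file.
#'
#' @param pixel_size_um,frame_interval_s acquisition calibration.
#' @param velocimetry a [velocimetry_config()].
#' @param normalize_window rolling-average window (frames) for
#'   [normalize_kymograph()].
#' @param profile_model `"plug"` or `"poiseuille"` for [volumetric_flow()].
#' @param diameter_method `"fwhm"` or `"endpoints"` for
#'   [measure_diameter()].
#' @param variance `"pooled"` or `"welch"` for group comparisons.
#' @param out_dir optional output directory; when set the pipeline writes
#'   kymographs, traces, the record table and the fit report there.
#' @param seed RNG seed recorded with the run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_um = 0.313,
                            frame_interval_s = 0.177,
                            velocimetry = velocimetry_config(),
                            normalize_window = 20,
                            profile_model = c("plug", "poiseuille"),
                            diameter_method = c("fwhm", "endpoints"),
                            variance = c("pooled", "welch"),
                            out_dir = NULL,
                            seed = 1) {
  profile_model <- match.arg(profile_model)
  diameter_method <- match.arg(diameter_method)
  variance <- match.arg(variance)
  vf_check(is_num1(pixel_size_um, 0, strict = TRUE) &&
             is_num1(frame_interval_s, 0, strict = TRUE),
           "vascflow_parameter_error", "calibrations must be > 0")
  vf_check(inherits(velocimetry, "velocimetry_config"),
           "vascflow_parameter_error",
           "velocimetry must be a velocimetry_config")
  vf_check(is_count(normalize_window, min = 1), "vascflow_parameter_error",
           "normalize_window must be an integer >= 1")
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 velocimetry = velocimetry,
                 normalize_window = as.integer(normalize_window),
                 profile_model = profile_model,
                 diameter_method = diameter_method,
                 variance = variance,
                 out_dir = out_dir,
                 seed = seed),
            class = "pipeline_config")
}

config_to_list <- function(config, for_hash = FALSE) {
  lst <- unclass(config)
  lst$velocimetry <- unclass(lst$velocimetry)
  if (for_hash) lst$out_dir <- NULL  # output location is not analysis identity
  lst
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  vf_check(inherits(config, "pipeline_config"), "vascflow_parameter_error",
           "config must be a pipeline_config")
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    pixel_size_um = obj$pixel_size_um,
    frame_interval_s = obj$frame_interval_s,
    velocimetry = velocimetry_config(
      section_frames = obj$velocimetry$section_frames,
      corr_threshold = obj$velocimetry$corr_threshold,
      max_shift_px = obj$velocimetry$max_shift_px,
      subpixel = obj$velocimetry$subpixel),
    normalize_window = obj$normalize_window,
    profile_model = obj$profile_model,
    diameter_method = obj$diameter_method,
    variance = obj$variance,
    out_dir = obj$out_dir,
    seed = obj$seed)
}

#' @rdname pipeline_config
#' @export
config_hash <- function(config) {
  vf_check(inherits(config, "pipeline_config"), "vascflow_parameter_error",
           "config must be a pipeline_config")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config_to_list(config, for_hash = TRUE),
                              auto_unbox = TRUE, digits = NA, null = "null"),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full flow pipeline over a set of vessels
#'
#' For each vessel: extract the kymograph along the axial ROI, normalize
#' it, estimate the velocity trace, summarize the maximum flow speed,
#' measure the diameter on the minimal projection along the cross ROI, and
#' compute the volumetric flow. A vessel failing any stage (out-of-bounds
#' ROI, no valid timepoints, no measurable profile, ...) is skipped with
#' the reason logged, and the pipeline continues — mirroring the exclusion
#' of low-contrast vessels in practice. If at least 3 vessels survive, the
#' branching exponent is fitted across them.
#'
#' @param config a [pipeline_config()].
#' @param stacks list of [time_lapse_stack()] objects or TIFF paths
#'   (read with [read_stack_tiff()]); one per vessel, non-empty.
#' @param rois list (same length) of lists with elements `axial` and
#'   `cross`, each a [line_roi()].
#' @return list with `records` (data frame: vessel_id, diameter_um,
#'   v_max_um_s, q_flow, valid_fraction, n_reversals), `fit` (a
#'   `branching_fit`, or `NULL` if fewer than 3 vessels survived), and
#'   `log` (character vector of per-vessel messages).
#' @export
run_flow_pipeline <- function(config, stacks, rois) {
  vf_check(inherits(config, "pipeline_config"), "vascflow_parameter_error",
           "config must be a pipeline_config")
  vf_check(is.list(stacks) && length(stacks) >= 1, "vascflow_usage_error",
           "stacks must be a non-empty list")
  vf_check(is.list(rois) && length(rois) == length(stacks),
           "vascflow_usage_error", "need one ROI pair per stack")
  hash <- config_hash(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  log <- character(0)
  recs <- list()
  for (i in seq_along(stacks)) {
    res <- tryCatch({
      stack <- stacks[[i]]
      if (is.character(stack)) stack <- read_stack_tiff(stack)
      roi <- rois[[i]]
      vf_check(is.list(roi) && all(c("axial", "cross") %in% names(roi)),
               "vascflow_parameter_error",
               "each ROI entry needs `axial` and `cross` line_rois")
      kym <- extract_kymograph(stack, roi$axial)
      kymn <- normalize_kymograph(kym, config$normalize_window)
      trace <- estimate_velocity_trace(kymn, config$velocimetry)
      summ <- summarize_vessel_velocity(trace)
      proj <- min_projection(stack)
      d_um <- measure_diameter(proj, roi$cross, config$pixel_size_um,
                               method = config$diameter_method)
      q <- volumetric_flow(summ$v_max_um_s, d_um,
                           profile_model = config$profile_model)
      if (!is.null(out_dir)) {
        write_kymograph_csv(kymn, file.path(out_dir,
                                            sprintf("kymo_%03d.csv", i)))
        trace_df <- as.data.frame(trace)
        write_records_csv(trace_df,
                          file.path(out_dir, sprintf("trace_%03d.csv", i)),
                          config_hash = hash)
      }
      data.frame(vessel_id = i, diameter_um = d_um,
                 v_max_um_s = summ$v_max_um_s, q_flow = as.numeric(q),
                 valid_fraction = summ$valid_fraction,
                 n_reversals = summ$n_reversals)
    }, vascflow_error = function(e) {
      conditionMessage(e)
    })
    if (is.character(res)) {
      log <- c(log, sprintf("vessel %d skipped: %s", i, res))
    } else {
      log <- c(log, sprintf("vessel %d ok", i))
      recs[[length(recs) + 1]] <- res
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(vessel_id = integer(0), diameter_um = numeric(0),
               v_max_um_s = numeric(0), q_flow = numeric(0),
               valid_fraction = numeric(0), n_reversals = integer(0))
  fit <- NULL
  if (nrow(records) >= 3) {
    fit <- fit_branching_exponent(records)
  } else {
    log <- c(log, "fewer than 3 usable vessels: no branching fit")
  }
  if (!is.null(out_dir)) {
    write_records_csv(records, file.path(out_dir, "vessel_records.csv"),
                      config_hash = hash)
    if (!is.null(fit))
      write_fit_json(fit, file.path(out_dir, "branching_fit.json"),
                     config_hash = hash)
    writeLines(c(sprintf("# config_hash=%s", hash), log),
               file.path(out_dir, "pipeline_log.txt"))
  }
  list(records = records, fit = fit, log = log, config_hash = hash)
}

#' Render time-lapse movies for segments of a simulated network
#'
#' Bridges [simulate_murray_network()] to the imaging chain: each selected
#' segment is rendered as a movie whose lumen width is the segment's true
#' diameter (in pixels at the stated calibration) and whose particles
#' advect at the segment's true maximum velocity (converted to px/frame).
#' Particles are dark against a bright background, so the minimal
#' projection carries the lumen for diameter measurement; background
#' margins are added so the cross ROI reaches past the vessel wall.
#'
#' Correlation velocimetry resolves per-frame displacements only up to the
#' shift search half-range, so the synthetic acquisition uses a fast frame
#' interval (default 4 ms) that keeps the fastest segment's displacement
#' within it — the same constraint that governs frame-rate choice on a real
#' microscope.
#'
#' @param net data frame from [simulate_murray_network()] (rows to render).
#' @param n_frames frames per movie.
#' @param length_px movie length along the vessel axis.
#' @param margin_px background margin above/below the lumen; scaled up for
#'   wide segments so the outer ends of the cross profile (used as the
#'   diameter baseline) always lie in background.
#' @param particle_density particles per 100 px of vessel length for a
#'   40-px-wide lumen; scaled in proportion to each segment's lumen width,
#'   since a wider vessel carries proportionally more cells across its
#'   section.
#' @param particle_contrast particle intensity (negative = dark cells).
#' @param lumen_contrast static darkening of the lumen (makes the vessel
#'   measurable on the minimal projection).
#' @param noise_sigma camera noise.
#' @param pixel_size_um,frame_interval_s calibration.
#' @param seed base RNG seed (segment i uses `seed + i`).
#' @return list with one element per segment: `stack`, `axial`, `cross`
#'   ROIs and the segment's `truth` row.
#' @export
simulate_network_movies <- function(net,
                                    n_frames = 150,
                                    length_px = 220,
                                    margin_px = 16,
                                    particle_density = 10,
                                    particle_contrast = -60,
                                    lumen_contrast = 80,
                                    noise_sigma = 4,
                                    pixel_size_um = 0.313,
                                    frame_interval_s = 0.004,
                                    seed = 1) {
  vf_check(is.data.frame(net) && nrow(net) >= 1 &&
             all(c("d_true", "v_true") %in% names(net)),
           "vascflow_parameter_error",
           "net must be a simulate_murray_network() data frame")
  lapply(seq_len(nrow(net)), function(i) {
    d_px <- max(6L, round(net$d_true[i] / pixel_size_um))
    marg <- max(margin_px, ceiling(0.2 * d_px))
    v_pxf <- net$v_true[i] * frame_interval_s / pixel_size_um
    p <- flow_sim_params(
      n_frames = n_frames, length_px = length_px, width_px = d_px,
      velocity_profile = v_pxf,
      particle_density = particle_density * d_px / 40,
      particle_contrast = particle_contrast,
      lumen_contrast = lumen_contrast, noise_sigma = noise_sigma,
      margin_px = marg, pixel_size_um = pixel_size_um,
      frame_interval_s = frame_interval_s, seed = seed + i)
    stack <- simulate_vessel_movie(p)
    h <- d_px + 2 * marg
    cy <- marg + (d_px + 1) / 2
    axial <- line_roi(data.frame(x = c(8, length_px - 8), y = c(cy, cy)),
                      thickness_um = 3, kind = "axial")
    cross <- line_roi(data.frame(x = c(length_px / 2, length_px / 2),
                                 y = c(2, h - 1)), kind = "cross")
    list(stack = stack, axial = axial, cross = cross, truth = net[i, ])
  })
}
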