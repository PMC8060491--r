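# Synthetic-data generators: every downstream stage (kymograph velocimetry,
# branching-exponent fit, morphometrics, regression scoring) can be validated
# by parameter recovery against the ground truth these functions emit.

#' Parameters for a synthetic vessel time-lapse
#'
#' Describes a single straight vessel segment imaged end-on: advected
#' high-contrast particles (blood cells) ride along the vessel axis (x),
#' stationary speckles sit still (they become vertical stripes in a
#' kymograph), an axial intensity gradient models uneven illumination, and
#' i.i.d. Gaussian noise models the camera. Defaults reproduce the texture of
#' a young, particle-rich vessel recorded at 0.313 um/px and 0.177 s/frame.
#'
#' @param n_frames number of frames (>= 2).
#' @param length_px,width_px lumen size in pixels (x is the vessel axis).
#' @param velocity_profile signed particle speed in px/frame: a scalar for
#'   constant flow or a vector of length `n_frames` (entry t is the
#'   displacement between frames t and t+1; the last entry is unused).
#' @param particle_density particles per 100 px of vessel length. The
#'   default (30) gives the dense streak coverage characteristic of young
#'   vessels, where most of the kymograph is textured by passing cells; old
#'   vessels are emulated by lowering it.
#' @param particle_radius_px Gaussian sigma of the rendered particle blob.
#' @param particle_contrast peak particle intensity above (or, if negative,
#'   below) the background level.
#' @param background_level baseline intensity.
#' @param background_gradient additive axial gradient, intensity units per px.
#' @param lumen_contrast static darkening of the lumen rows relative to the
#'   background (>= 0). In a brightfield minimal projection the vessel
#'   interior is darker than the surrounding tunic; a nonzero value makes
#'   the rendered lumen measurable by full-width at half-minimum. It is
#'   static, so kymograph normalization removes it.
#' @param n_immobile number of stationary speckles inside the lumen.
#' @param noise_sigma Gaussian noise standard deviation (>= 0).
#' @param margin_px background rows added above and below the lumen (for
#'   diameter measurement across the vessel wall).
#' @param pixel_size_um,frame_interval_s spatial / temporal calibration.
#' @param seed RNG seed; the same parameters and seed give a bit-identical
#'   movie.
#' @return object of class `flow_sim_params`.
#' @export
flow_sim_params <- function(n_frames = 300,
                            length_px = 256,
                            width_px = 40,
                            velocity_profile = 2,
                            particle_density = 30,
                            particle_radius_px = 2,
                            particle_contrast = 60,
                            background_level = 100,
                            background_gradient = 0.1,
                            lumen_contrast = 0,
                            n_immobile = 3,
                            noise_sigma = 4,
                            margin_px = 0,
                            pixel_size_um = 0.313,
                            frame_interval_s = 0.177,
                            seed = 1) {
  vf_check(is_count(n_frames, min = 2), "vascflow_parameter_error",
           "n_frames must be an integer >= 2")
  for (nm in c("length_px", "width_px"))
    vf_check(is_count(get(nm), min = 1), "vascflow_parameter_error",
             sprintf("%s must be a positive integer", nm))
  vf_check(is.numeric(velocity_profile) && all(is.finite(velocity_profile)) &&
             length(velocity_profile) %in% c(1L, n_frames),
           "vascflow_parameter_error",
           "velocity_profile must be a finite scalar or length-n_frames vector")
  vf_check(is_num1(particle_density, 0), "vascflow_parameter_error",
           "particle_density must be >= 0")
  vf_check(is_num1(particle_radius_px, 0, strict = TRUE),
           "vascflow_parameter_error", "particle_radius_px must be > 0")
  vf_check(is_num1(noise_sigma, 0), "vascflow_parameter_error",
           "noise_sigma must be >= 0")
  vf_check(is_num1(lumen_contrast, 0), "vascflow_parameter_error",
           "lumen_contrast must be >= 0")
  vf_check(is_num1(n_immobile, 0) && n_immobile == round(n_immobile),
           "vascflow_parameter_error", "n_immobile must be a count >= 0")
  vf_check(is_num1(margin_px, 0) && margin_px == round(margin_px),
           "vascflow_parameter_error", "margin_px must be a count >= 0")
  vf_check(is_num1(pixel_size_um, 0, strict = TRUE) &&
             is_num1(frame_interval_s, 0, strict = TRUE),
           "vascflow_parameter_error", "calibration values must be > 0")
  structure(list(
    n_frames = as.integer(n_frames), length_px = as.integer(length_px),
    width_px = as.integer(width_px), velocity_profile = velocity_profile,
    particle_density = particle_density,
    particle_radius_px = particle_radius_px,
    particle_contrast = particle_contrast,
    background_level = background_level,
    background_gradient = background_gradient,
    lumen_contrast = lumen_contrast,
    n_immobile = as.integer(n_immobile), noise_sigma = noise_sigma,
    margin_px = as.integer(margin_px), pixel_size_um = pixel_size_um,
    frame_interval_s = frame_interval_s, seed = seed
  ), class = "flow_sim_params")
}

# Gaussian blob (sigma r, peak amp) added in place around (cy, cx); x wraps
# over [x0, x0 + len) so advected particles re-enter the segment.
add_blob <- function(frame, cy, cx, amp, r, wrap_x = NULL) {
  h <- nrow(frame); w <- ncol(frame)
  win <- ceiling(4 * r)
  ys <- max(1, floor(cy - win)):min(h, ceiling(cy + win))
  if (!length(ys)) return(frame)
  gy <- exp(-(ys - cy)^2 / (2 * r^2))
  if (is.null(wrap_x)) {
    xs <- max(1, floor(cx - win)):min(w, ceiling(cx + win))
    if (!length(xs)) return(frame)
    gx <- exp(-(xs - cx)^2 / (2 * r^2))
  } else {
    x0 <- wrap_x[1]; len <- wrap_x[2]
    xs <- floor(cx - win):ceiling(cx + win)
    dx <- xs - cx
    xs <- ((xs - x0) %% len) + x0
    keep <- xs >= 1 & xs <= w
    xs <- xs[keep]; dx <- dx[keep]
    if (!length(xs)) return(frame)
    gx <- exp(-dx^2 / (2 * r^2))
  }
  frame[ys, xs] <- frame[ys, xs] + amp * outer(gy, gx)
  frame
}

#' Simulate a vessel time-lapse movie
#'
#' Renders a calibrated `(time, y, x)` intensity stack following
#' [flow_sim_params()]: particles advect along x at the requested velocity
#' profile and wrap periodically at the segment ends (so particle density is
#' stationary in time), immobile speckles stay put, and an axial background
#' gradient plus Gaussian noise are added. Ground truth (particle tracks,
#' per-frame velocity) is attached as `attr(stack, "truth")`.
#'
#' @param params a [flow_sim_params()] object.
#' @return a [time_lapse_stack()].
#' @export
simulate_vessel_movie <- function(params) {
  vf_check(inherits(params, "flow_sim_params"), "vascflow_parameter_error",
           "params must be created by flow_sim_params()")
  p <- params
  h <- p$width_px + 2L * p$margin_px
  w <- p$length_px
  lum0 <- p$margin_px + 1L          # first lumen row
  lum1 <- p$margin_px + p$width_px  # last lumen row
  v <- if (length(p$velocity_profile) == 1)
    rep(p$velocity_profile, p$n_frames) else p$velocity_profile

  with_seed(p$seed, {
    n_part <- round(p$particle_density * p$length_px / 100)
    x0 <- stats::runif(n_part, 1, w + 1)
    y0 <- stats::runif(n_part, lum0 + 0.5, lum1 - 0.5)
    imm_x <- stats::runif(p$n_immobile, 1, w + 1)
    imm_y <- stats::runif(p$n_immobile, lum0 + 0.5, lum1 - 0.5)

    static <- matrix(p$background_level, h, w) +
      matrix(p$background_gradient * (seq_len(w) - 1), h, w, byrow = TRUE)
    if (p$lumen_contrast > 0)
      static[lum0:lum1, ] <- static[lum0:lum1, ] - p$lumen_contrast
    for (i in seq_len(p$n_immobile))
      static <- add_blob(static, imm_y[i], imm_x[i], p$particle_contrast,
                         p$particle_radius_px)

    disp <- cumsum(c(0, v[-p$n_frames]))
    frames <- array(0, dim = c(p$n_frames, h, w))
    tracks <- if (n_part > 0)
      matrix(NA_real_, p$n_frames, n_part) else matrix(0, p$n_frames, 0)
    for (t in seq_len(p$n_frames)) {
      fr <- static
      if (n_part > 0) {
        xt <- ((x0 + disp[t] - 1) %% w) + 1
        tracks[t, ] <- xt
        for (i in seq_len(n_part))
          fr <- add_blob(fr, y0[i], xt[i], p$particle_contrast,
                         p$particle_radius_px, wrap_x = c(1, w))
      }
      if (p$noise_sigma > 0)
        fr <- fr + matrix(stats::rnorm(h * w, 0, p$noise_sigma), h, w)
      frames[t, , ] <- fr
    }
    stack <- time_lapse_stack(frames, p$pixel_size_um, p$frame_interval_s)
    attr(stack, "truth") <- list(
      velocity_px_frame = v, particle_x = tracks, particle_y = y0,
      lumen_rows = c(lum0, lum1), params = p)
    stack
  })
}

#' Parameters for a synthetic Murray-law vascular tree
#'
#' A symmetric bifurcating tree in which child diameters obey
#' `d_parent^n = sum(d_child^n)` for branching exponent `n`, volumetric flow
#' is conserved at every branch point, and velocity follows `v = Q / (pi
#' d^2 / 4)`. Multiplicative lognormal noise of the stated sigma is applied
#' to the reported diameter and velocity (the `*_true` columns keep the
#' noiseless values).
#'
#' @param n_levels tree depth (>= 2; level 1 is the root).
#' @param exponent branching exponent `n` (> 0); 3 is Murray's law.
#' @param root_diameter_um root vessel diameter (um).
#' @param root_flow root volumetric flow (um^3/s). Default gives the root a
#'   maximum flow velocity of 300 um/s, typical of a wide young vessel.
#' @param children_per_branch children per branch point (default 2).
#' @param noise_sigma sdlog of the multiplicative measurement noise on
#'   reported d and v (0 = noiseless).
#' @param seed RNG seed.
#' @return object of class `murray_net_params`.
#' @export
murray_net_params <- function(n_levels = 5,
                              exponent = 3,
                              root_diameter_um = 60,
                              root_flow = NULL,
                              children_per_branch = 2,
                              noise_sigma = 0.05,
                              seed = 1) {
  vf_check(is_count(n_levels, min = 2), "vascflow_parameter_error",
           "n_levels must be an integer >= 2")
  vf_check(is_num1(exponent, 0, strict = TRUE), "vascflow_parameter_error",
           "exponent must be > 0")
  vf_check(is_num1(root_diameter_um, 0, strict = TRUE),
           "vascflow_parameter_error", "root_diameter_um must be > 0")
  vf_check(is_count(children_per_branch, min = 2), "vascflow_parameter_error",
           "children_per_branch must be an integer >= 2")
  vf_check(is_num1(noise_sigma, 0), "vascflow_parameter_error",
           "noise_sigma must be >= 0")
  if (is.null(root_flow))
    root_flow <- 300 * pi * root_diameter_um^2 / 4
  vf_check(is_num1(root_flow, 0, strict = TRUE), "vascflow_parameter_error",
           "root_flow must be > 0")
  structure(list(n_levels = as.integer(n_levels), exponent = exponent,
                 root_diameter_um = root_diameter_um, root_flow = root_flow,
                 children_per_branch = as.integer(children_per_branch),
                 noise_sigma = noise_sigma, seed = seed),
            class = "murray_net_params")
}

#' Simulate a flow-conserving bifurcating vascular network
#'
#' @param params a [murray_net_params()] object.
#' @return data frame of vessel records, one row per segment: `vessel_id`,
#'   `parent_id`, `level`, reported `diameter_um`, `v_max_um_s`, `q_flow`
#'   (recomputed from the noisy d and v under the plug-flow model), and the
#'   noiseless `d_true`, `v_true`, `q_true`.
#' @export
simulate_murray_network <- function(params) {
  vf_check(inherits(params, "murray_net_params"), "vascflow_parameter_error",
           "params must be created by murray_net_params()")
  p <- params
  k <- p$children_per_branch
  rows <- list()
  id <- 0L
  # level l: k^(l-1) segments, d = d_root * k^-( (l-1)/n ), Q split equally
  prev_ids <- NA_integer_
  for (l in seq_len(p$n_levels)) {
    n_seg <- k^(l - 1)
    d <- p$root_diameter_um * k^(-(l - 1) / p$exponent)
    q <- p$root_flow / n_seg
    v <- q / (pi * d^2 / 4)
    ids <- id + seq_len(n_seg)
    parents <- if (l == 1) NA_integer_ else rep(prev_ids, each = k)
    rows[[l]] <- data.frame(vessel_id = ids, parent_id = parents, level = l,
                            d_true = d, v_true = v, q_true = q)
    prev_ids <- ids
    id <- id + n_seg
  }
  net <- do.call(rbind, rows)
  with_seed(p$seed, {
    nr <- nrow(net)
    fd <- if (p$noise_sigma > 0)
      exp(stats::rnorm(nr, 0, p$noise_sigma)) else rep(1, nr)
    fv <- if (p$noise_sigma > 0)
      exp(stats::rnorm(nr, 0, p$noise_sigma)) else rep(1, nr)
    net$diameter_um <- net$d_true * fd
    net$v_max_um_s <- net$v_true * fv
    net$q_flow <- net$v_max_um_s * pi * net$diameter_um^2 / 4
  })
  net[, c("vessel_id", "parent_id", "level", "diameter_um", "v_max_um_s",
          "q_flow", "d_true", "v_true", "q_true")]
}

#' Parameters for a synthetic labeled cell mosaic
#'
#' Non-overlapping elliptical cells with controlled mean area, area spread
#' and elongation, rasterized as an integer label image at a stated pixel
#' size. Ground truth per cell carries the intended area and the closed-form
#' circularity of the generating ellipse (Ramanujan perimeter).
#'
#' @param n_cells number of cells (>= 1).
#' @param mean_area_um2 mean cell area in um^2.
#' @param area_cv coefficient of variation of the (lognormal) area
#'   distribution; 0 gives identical areas.
#' @param elongation major/minor axis ratio (>= 1; 1 gives disks).
#' @param image_size_px side of the square label image.
#' @param pixel_size_um um per pixel.
#' @param seed RNG seed.
#' @return object of class `shape_sim_params`.
#' @export
shape_sim_params <- function(n_cells = 100,
                             mean_area_um2 = 31,
                             area_cv = 0.2,
                             elongation = 1.3,
                             image_size_px = 512,
                             pixel_size_um = 0.25,
                             seed = 1) {
  vf_check(is_count(n_cells, min = 1), "vascflow_parameter_error",
           "n_cells must be an integer >= 1")
  vf_check(is_num1(mean_area_um2, 0, strict = TRUE),
           "vascflow_parameter_error", "mean_area_um2 must be > 0")
  vf_check(is_num1(area_cv, 0), "vascflow_parameter_error",
           "area_cv must be >= 0")
  vf_check(is_num1(elongation, 1), "vascflow_parameter_error",
           "elongation must be >= 1")
  vf_check(is_count(image_size_px, min = 8), "vascflow_parameter_error",
           "image_size_px must be an integer >= 8")
  vf_check(is_num1(pixel_size_um, 0, strict = TRUE),
           "vascflow_parameter_error", "pixel_size_um must be > 0")
  structure(list(n_cells = as.integer(n_cells),
                 mean_area_um2 = mean_area_um2, area_cv = area_cv,
                 elongation = elongation,
                 image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um, seed = seed),
            class = "shape_sim_params")
}

# Circularity of an ellipse with semi-axes a >= b, via Ramanujan's
# perimeter approximation (error < 1e-6 for the aspect ratios used here).
ellipse_circularity <- function(a, b) {
  if (a == b) return(1)
  h <- ((a - b) / (a + b))^2
  per <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  4 * pi * (pi * a * b) / per^2
}

#' Simulate a labeled cell mosaic with known shape ground truth
#'
#' Places non-overlapping ellipses (>= 1 px separation, so a boundary pixel
#' always exists between neighbours) by bounded rejection sampling.
#'
#' @param params a [shape_sim_params()] object.
#' @return list with `labels` (integer label matrix, 0 = background),
#'   `truth` (data frame: `label`, `area_um2`, `circularity`, semi-axes in
#'   px, orientation), and `pixel_size_um`.
#' @export
simulate_cell_mosaic <- function(params) {
  vf_check(inherits(params, "shape_sim_params"), "vascflow_parameter_error",
           "params must be created by shape_sim_params()")
  p <- params
  n <- p$image_size_px
  with_seed(p$seed, {
    if (p$area_cv > 0) {
      sdlog <- sqrt(log(1 + p$area_cv^2))
      areas <- stats::rlnorm(p$n_cells,
                             meanlog = log(p$mean_area_um2) - sdlog^2 / 2,
                             sdlog = sdlog)
    } else {
      areas <- rep(p$mean_area_um2, p$n_cells)
    }
    area_px <- areas / p$pixel_size_um^2
    b_px <- sqrt(area_px / (pi * p$elongation))
    a_px <- p$elongation * b_px

    labels <- matrix(0L, n, n)
    occupied <- matrix(FALSE, n, n)   # placed cells dilated by 1 px
    truth <- vector("list", p$n_cells)
    for (i in seq_len(p$n_cells)) {
      a <- a_px[i]; b <- b_px[i]
      if (a + 2 >= n - a - 1)
        vf_error("vascflow_placement_error", sprintf(
          "cell %d (semi-major %.1f px) cannot fit in a %d-px image", i, a, n))
      placed <- FALSE
      for (try in seq_len(400)) {
        th <- stats::runif(1, 0, pi)
        cy <- stats::runif(1, a + 2, n - a - 1)
        cx <- stats::runif(1, a + 2, n - a - 1)
        r0 <- floor(cy - a); r1 <- ceiling(cy + a)
        c0 <- floor(cx - a); c1 <- ceiling(cx + a)
        ys <- r0:r1; xs <- c0:c1
        dy <- ys - cy; dx <- xs - cx
        u <- outer(dy, dx, function(Y, X) (X * cos(th) + Y * sin(th)) / a)
        w <- outer(dy, dx, function(Y, X) (-X * sin(th) + Y * cos(th)) / b)
        inside <- u^2 + w^2 <= 1
        if (!any(inside)) next
        sub_occ <- occupied[ys, xs, drop = FALSE]
        if (any(sub_occ[inside])) next
        idx <- which(inside, arr.ind = TRUE)
        rr <- ys[idx[, 1]]; cc <- xs[idx[, 2]]
        labels[cbind(rr, cc)] <- i
        for (dr in -1:1) for (dc in -1:1)
          occupied[cbind(pmin(pmax(rr + dr, 1), n),
                         pmin(pmax(cc + dc, 1), n))] <- TRUE
        truth[[i]] <- data.frame(
          label = i, area_um2 = areas[i],
          circularity = ellipse_circularity(a, b),
          semi_major_px = a, semi_minor_px = b, theta = th,
          n_pixels = sum(inside))
        placed <- TRUE
        break
      }
      if (!placed)
        vf_error("vascflow_placement_error", sprintf(
          "could not place cell %d without overlap after 400 retries", i))
    }
    list(labels = labels, truth = do.call(rbind, truth),
         pixel_size_um = p$pixel_size_um)
  })
}

#' Render a boundary-stained image from a label mosaic
#'
#' Emulates a membrane stain: everything that is not cell interior (the
#' inter-cell gaps and the open background) is bright, cell interiors are
#' dark. The inverse operation is [segment_boundary_image()].
#'
#' @param labels integer label matrix (0 = background/boundary).
#' @param boundary_value,interior_value intensities of stain and interior.
#' @param noise_sigma optional Gaussian noise; `seed` used when > 0.
#' @param seed RNG seed for the noise.
#' @return numeric intensity matrix.
#' @export
boundary_image_from_labels <- function(labels, boundary_value = 200,
                                       interior_value = 20,
                                       noise_sigma = 0, seed = 1) {
  img <- matrix(ifelse(labels == 0, boundary_value, interior_value),
                nrow(labels), ncol(labels))
  if (noise_sigma > 0)
    img <- with_seed(seed, img + matrix(stats::rnorm(length(img), 0,
                                                     noise_sigma),
                                        nrow(img), ncol(img)))
  img
}

#' Simulate before/after vascular-bed outlines
#'
#' Builds a control pair of closed polygons (a lobed outer border traced
#' around the ampullae and a smooth inner border around the zooid bodies)
#' and a post-treatment pair whose bed size is reduced by exactly
#' `area_loss_fraction`: the treated ampullae border is rescaled about its
#' centroid so that `s_treated = (1 - fraction) * s_control`, where
#' `s = p_ampullae - p_body`.
#'
#' @param area_loss_fraction requested fractional loss of bed size, in
#'   `[0, 1]`.
#' @param seed RNG seed (small vertex jitter on the control outlines).
#' @param n_vertices vertices per polygon.
#' @param ampulla_lobes number of finger-like lobes on the ampullae border.
#' @return object of class `vf_bed_outlines`: `control` and `treated`, each
#'   a list with `ampullae` and `body` polygons (data frames with `x`, `y`),
#'   plus a shared `units` tag ("px").
#' @export
simulate_bed_outlines <- function(area_loss_fraction, seed = 1,
                                  n_vertices = 720, ampulla_lobes = 24) {
  vf_check(is_num1(area_loss_fraction, 0) && area_loss_fraction <= 1,
           "vascflow_parameter_error",
           "area_loss_fraction must lie in [0, 1]")
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  with_seed(seed, {
    r_body <- 300 * (1 + 0.02 * sin(3 * th + stats::runif(1, 0, 2 * pi)))
    r_amp <- 500 * (1 + 0.12 * sin(ampulla_lobes * th) +
                      0.01 * stats::rnorm(1))
    body <- data.frame(x = r_body * cos(th), y = r_body * sin(th))
    amp <- data.frame(x = r_amp * cos(th), y = r_amp * sin(th))
    p_b <- polygon_perimeter(body)
    p_a <- polygon_perimeter(amp)
    s_ctrl <- p_a - p_b
    target_pa <- p_b + (1 - area_loss_fraction) * s_ctrl
    k <- target_pa / p_a
    amp_t <- data.frame(x = mean(amp$x) + k * (amp$x - mean(amp$x)),
                        y = mean(amp$y) + k * (amp$y - mean(amp$y)))
    structure(list(
      control = list(ampullae = amp, body = body),
      treated = list(ampullae = amp_t, body = body),
      units = "px"
    ), class = "vf_bed_outlines")
  })
}
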