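test_that("identical parameters and seed give bit-identical movies", {
  p <- flow_sim_params(n_frames = 20, length_px = 64, width_px = 16, seed = 9)
  expect_identical(simulate_vessel_movie(p), simulate_vessel_movie(p))
  p2 <- flow_sim_params(n_frames = 20, length_px = 64, width_px = 16,
                        seed = 10)
  expect_false(identical(unclass(simulate_vessel_movie(p)),
                         unclass(simulate_vessel_movie(p2))))
})

test_that("zero flow with zero noise gives identical frames", {
  p <- flow_sim_params(n_frames = 6, length_px = 48, width_px = 12,
                       velocity_profile = 0, noise_sigma = 0, seed = 1)
  st <- simulate_vessel_movie(p)
  for (t in 2:6) expect_equal(st[t, , ], st[1, , ], tolerance = 0)
})

test_that("the default acquisition calibration is carried on the stack", {
  st <- simulate_vessel_movie(flow_sim_params(n_frames = 4, length_px = 32,
                                              width_px = 8))
  expect_equal(attr(st, "pixel_size_um"), 0.313)
  expect_equal(attr(st, "frame_interval_s"), 0.177)
})

test_that("a single particle advances exactly v px/frame (argmax tracking)", {
  # density chosen so exactly one particle is placed; no other structure
  p <- flow_sim_params(n_frames = 40, length_px = 256, width_px = 24,
                       velocity_profile = 2, particle_density = 0.4,
                       n_immobile = 0, background_gradient = 0,
                       noise_sigma = 0, seed = 5)
  st <- simulate_vessel_movie(p)
  expect_equal(nrow(attr(st, "truth")$particle_x), 40)
  expect_equal(ncol(attr(st, "truth")$particle_x), 1)
  argx <- vapply(seq_len(40), function(t) {
    fr <- st[t, , ]
    which(fr == max(fr), arr.ind = TRUE)[1, 2]
  }, 0L)
  steps <- (diff(argx)) %% 256
  expect_true(all(steps == 2))
})

test_that("mean intensity of a clean movie matches the closed form", {
  p <- flow_sim_params(n_frames = 10, length_px = 256, width_px = 40,
                       velocity_profile = 1.5, particle_density = 0.4,
                       particle_radius_px = 2, particle_contrast = 50,
                       background_level = 80, background_gradient = 0,
                       n_immobile = 0, noise_sigma = 0, seed = 2)
  st <- simulate_vessel_movie(p)
  y0 <- attr(st, "truth")$particle_y
  # Gaussian integrals: x wraps (full mass), y clipped at the frame edges
  mass_x <- sqrt(2 * pi * 2^2)
  mass_y <- sqrt(2 * pi * 2^2) *
    (pnorm((40.5 - y0) / 2) - pnorm((0.5 - y0) / 2))
  expected <- 80 + 50 * mass_x * mass_y / (40 * 256)
  for (t in 1:10)
    expect_equal(mean(st[t, , ]), expected, tolerance = 1e-6)
})

test_that("invalid movie parameters are rejected", {
  expect_error(flow_sim_params(n_frames = 1), class = "vascflow_parameter_error")
  expect_error(flow_sim_params(length_px = 0), class = "vascflow_parameter_error")
  expect_error(flow_sim_params(noise_sigma = -1),
               class = "vascflow_parameter_error")
})

test_that("Murray children follow the closed-form diameter split", {
  p <- murray_net_params(n_levels = 2, exponent = 3, root_diameter_um = 60,
                         noise_sigma = 0)
  net <- simulate_murray_network(p)
  kids <- net$diameter_um[net$level == 2]
  expect_equal(kids, rep(60 / 2^(1 / 3), 2), tolerance = 1e-12)
  expect_equal(kids, rep(47.62203, 2), tolerance = 1e-4)
})

test_that("flow is conserved at every branch point before noise", {
  net <- simulate_murray_network(murray_net_params(n_levels = 5,
                                                   exponent = 2.6,
                                                   children_per_branch = 3,
                                                   noise_sigma = 0.1,
                                                   seed = 3))
  for (pid in net$vessel_id[net$level < max(net$level)]) {
    kids <- net[!is.na(net$parent_id) & net$parent_id == pid, ]
    expect_equal(sum(kids$q_true), net$q_true[net$vessel_id == pid],
                 tolerance = 1e-9)
  }
  # velocity is flow over cross-section by construction
  expect_equal(net$v_true, net$q_true / (pi * net$d_true^2 / 4),
               tolerance = 1e-12)
})

test_that("network generation is deterministic and rejects bad exponents", {
  p <- murray_net_params(seed = 11)
  expect_identical(simulate_murray_network(p), simulate_murray_network(p))
  expect_error(murray_net_params(exponent = 0),
               class = "vascflow_parameter_error")
  expect_error(murray_net_params(n_levels = 1),
               class = "vascflow_parameter_error")
})

test_that("mosaic ground truth carries the intended circularity", {
  disks <- simulate_cell_mosaic(shape_sim_params(n_cells = 20,
                                                 elongation = 1, seed = 4))
  expect_equal(disks$truth$circularity, rep(1, 20))
  stretched <- simulate_cell_mosaic(shape_sim_params(n_cells = 10,
                                                     elongation = 2, seed = 4))
  expect_true(all(stretched$truth$circularity < 1))
  # labels are non-overlapping by construction: counts match truth pixels
  counts <- tabulate(disks$labels[disks$labels > 0])
  expect_equal(counts, disks$truth$n_pixels)
})

test_that("mosaic rejects empty or impossible requests", {
  expect_error(shape_sim_params(n_cells = 0),
               class = "vascflow_parameter_error")
  # far more area than the frame can hold -> placement failure
  expect_error(
    simulate_cell_mosaic(shape_sim_params(n_cells = 200,
                                          mean_area_um2 = 400,
                                          area_cv = 0, elongation = 1,
                                          image_size_px = 64,
                                          pixel_size_um = 0.25, seed = 1)),
    class = "vascflow_placement_error")
})

test_that("bed outlines reproduce the requested regression fraction", {
  for (f in c(0, 0.25, 0.964, 1)) {
    out <- simulate_bed_outlines(f, seed = 6)
    s_ctrl <- measure_bed(out$control)
    s_treat <- measure_bed(out$treated)
    expect_equal(percent_regression(s_ctrl, s_treat), 100 * f,
                 tolerance = 1e-9)
  }
  expect_error(simulate_bed_outlines(1.2), class = "vascflow_parameter_error")
  expect_error(simulate_bed_outlines(-0.1), class = "vascflow_parameter_error")
})
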