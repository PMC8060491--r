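test_that("a noiseless diagonal-streak kymograph gives shift 2 everywhere", {
  k <- streak_kymograph(slope = 2)
  tr <- estimate_velocity_trace(k, velocimetry_config(subpixel = FALSE))
  expect_true(all(tr$valid))
  expect_true(all(tr$shift_px == 2))
  expect_true(all(tr$peak_corr > 0.8))
})

test_that("velocity conversion uses the kymograph calibration", {
  k <- streak_kymograph(slope = 1)
  tr <- estimate_velocity_trace(k, velocimetry_config(subpixel = FALSE))
  # 1 px/frame at 0.313 um/px and 0.177 s/frame
  expect_equal(unique(tr$velocity_um_s[tr$valid]), 0.313 / 0.177,
               tolerance = 1e-9)
  expect_equal(0.313 / 0.177, 1.768, tolerance = 1e-3)
})

test_that("velocity recovery across speeds at default particle density", {
  for (v in c(0.5, 1, 2, 4)) {
    st <- simulate_vessel_movie(flow_sim_params(n_frames = 150,
                                                velocity_profile = v,
                                                seed = 20 + v * 10))
    k <- normalize_kymograph(extract_kymograph(st, center_roi(st)))
    tr <- estimate_velocity_trace(k)
    expect_gte(mean(tr$valid), 0.8)
    med <- median(abs(tr$shift_px[tr$valid]))
    expect_lt(abs(med - v), max(0.5, 0.1 * v))
  }
})

test_that("mirroring the kymograph negates every valid shift", {
  st <- simulate_vessel_movie(flow_sim_params(n_frames = 60, seed = 31))
  k <- normalize_kymograph(extract_kymograph(st, center_roi(st)))
  cfg <- velocimetry_config(subpixel = FALSE)
  tr <- estimate_velocity_trace(k, cfg)
  km <- kymograph(unclass(k)[, rev(seq_len(ncol(k)))],
                  attr(k, "pixel_size_um"), attr(k, "frame_interval_s"),
                  normalized = TRUE)
  trm <- estimate_velocity_trace(km, cfg)
  both <- tr$valid & trm$valid
  expect_gt(sum(both), 40)
  expect_equal(trm$shift_px[both], -tr$shift_px[both])
})

test_that("raising the threshold never increases the valid count", {
  st <- simulate_vessel_movie(flow_sim_params(n_frames = 80, noise_sigma = 12,
                                              particle_density = 2,
                                              seed = 13))
  k <- normalize_kymograph(extract_kymograph(st, center_roi(st)))
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8, 0.95), function(th) {
    sum(estimate_velocity_trace(k, velocimetry_config(corr_threshold = th))$valid)
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("pure-noise kymographs are gated out at the 0.8 threshold", {
  st <- simulate_vessel_movie(flow_sim_params(n_frames = 120,
                                              velocity_profile = 0,
                                              particle_density = 0,
                                              n_immobile = 0, noise_sigma = 5,
                                              seed = 17))
  k <- normalize_kymograph(extract_kymograph(st, center_roi(st)))
  tr <- estimate_velocity_trace(k)
  expect_gte(mean(!tr$valid), 0.9)
})

test_that("sign reversals are detected exactly once in a two-phase movie", {
  vp <- c(rep(2, 60), rep(-2, 60))
  st <- simulate_vessel_movie(flow_sim_params(n_frames = 120,
                                              velocity_profile = vp,
                                              noise_sigma = 0, seed = 23))
  k <- normalize_kymograph(extract_kymograph(st, center_roi(st)))
  s <- summarize_vessel_velocity(estimate_velocity_trace(k))
  expect_equal(s$n_reversals, 1L)
  # sign correctness away from the reversal frame
  tr <- estimate_velocity_trace(k)
  early <- tr$valid[1:50]
  late <- tr$valid[65:118]
  expect_gt(mean(sign(tr$shift_px[1:50][early]) == 1), 0.95)
  expect_gt(mean(sign(tr$shift_px[65:118][late]) == -1), 0.95)
})

test_that("trace summary reports max speed and reversal counts", {
  tr <- structure(data.frame(t = 1:4, shift_px = c(1, 1, -1, 1),
                             velocity_um_s = c(200, 300, -250, 200),
                             peak_corr = rep(0.9, 4),
                             valid = rep(TRUE, 4)),
                  pixel_size_um = 0.313, frame_interval_s = 0.177,
                  class = c("velocity_trace", "data.frame"))
  s <- summarize_vessel_velocity(tr)
  expect_equal(s$v_max_um_s, 300)
  expect_equal(s$n_reversals, 2L)
  expect_equal(s$valid_fraction, 1)

  tr$valid[] <- FALSE
  tr$velocity_um_s[] <- NA
  expect_error(summarize_vessel_velocity(tr),
               class = "vascflow_empty_summary")
})

test_that("velocimetry preconditions are enforced", {
  raw <- kymograph(matrix(rnorm(200), 10, 20), 0.313, 0.177)
  expect_error(estimate_velocity_trace(raw), class = "vascflow_state_error")
  kn <- normalize_kymograph(raw)
  expect_error(estimate_velocity_trace(kn,
                                       velocimetry_config(max_shift_px = 12)),
               class = "vascflow_geometry_error")
  expect_error(velocimetry_config(corr_threshold = 1),
               class = "vascflow_parameter_error")
  expect_error(velocimetry_config(section_frames = 1),
               class = "vascflow_parameter_error")
})
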