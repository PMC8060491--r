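make_projection <- function(width_px, depth = 60, size = c(120, 160),
                            background = 150) {
  img <- matrix(background, size[1], size[2])
  r0 <- (size[1] - width_px) / 2
  img[(floor(r0) + 1):(floor(r0) + width_px), ] <- background - depth
  img
}

test_that("FWHM recovers a rendered lumen width within one pixel", {
  img <- make_projection(40)
  roi <- line_roi(data.frame(x = c(80, 80), y = c(5, 116)), kind = "cross")
  d <- measure_diameter(img, roi, 0.313)
  expect_lt(abs(d - 40 * 0.313), 1 * 0.313)
  expect_equal(40 * 0.313, 12.52, tolerance = 1e-9)
})

test_that("FWHM is invariant to affine intensity transforms", {
  img <- make_projection(36)
  roi <- line_roi(data.frame(x = c(60, 60), y = c(5, 116)), kind = "cross")
  d0 <- measure_diameter(img, roi, 0.313)
  d1 <- measure_diameter(2.5 * img + 40, roi, 0.313)
  expect_equal(d0, d1, tolerance = 1e-9)
})

test_that("manual endpoint measurement is a plain ruler", {
  roi <- line_roi(data.frame(x = c(10, 110), y = c(20, 20)), kind = "cross")
  expect_equal(measure_diameter(matrix(0, 40, 200), roi, 0.5,
                                method = "endpoints"), 100 * 0.5)
})

test_that("flat profiles signal a measurement failure", {
  img <- matrix(100, 60, 60)
  roi <- line_roi(data.frame(x = c(30, 30), y = c(3, 58)), kind = "cross")
  expect_error(measure_diameter(img, roi, 0.313),
               class = "vascflow_measurement_failure")
})

test_that("volumetric flow follows the two profile models", {
  expect_equal(as.numeric(volumetric_flow(0, 20)), 0)
  q_plug <- volumetric_flow(100, 20, "plug")
  expect_equal(as.numeric(q_plug), 100 * pi * 100, tolerance = 1e-12)
  q_pois <- volumetric_flow(100, 20, "poiseuille")
  expect_equal(as.numeric(q_pois), as.numeric(q_plug) / 2, tolerance = 1e-12)
  expect_equal(attr(q_pois, "profile_model"), "poiseuille")
})

test_that("noiseless cubic data yields exponent 3 to machine precision", {
  d <- c(10, 15, 22, 30, 41, 60)
  rec <- data.frame(diameter_um = d, q_flow = 0.7 * d^3)
  fit <- fit_branching_exponent(rec)
  expect_equal(fit$exponent, 3, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$exponent_stderr, 1e-9)
})

test_that("the exponent is invariant to the flow-model prefactor", {
  net <- simulate_murray_network(murray_net_params(seed = 8))
  f1 <- fit_branching_exponent(net)
  net2 <- net
  net2$q_flow <- net2$q_flow / 2   # poiseuille instead of plug
  f2 <- fit_branching_exponent(net2)
  expect_equal(f1$exponent, f2$exponent, tolerance = 1e-12)
})

test_that("generating exponents are recovered from noisy networks", {
  for (n_true in c(2.8, 3)) {
    fits <- vapply(1:10, function(s) {
      net <- simulate_murray_network(
        murray_net_params(n_levels = 5, exponent = n_true,
                          noise_sigma = 0.05, seed = 100 + s))
      fit_branching_exponent(net)$exponent
    }, 0)
    expect_lt(abs(median(fits) - n_true), 0.15)
  }
})

test_that("noiseless trees return the generating exponent to 1e-6", {
  for (n_true in c(2.5, 3, 3.4)) {
    net <- simulate_murray_network(
      murray_net_params(n_levels = 6, exponent = n_true, noise_sigma = 0))
    expect_equal(fit_branching_exponent(net)$exponent, n_true,
                 tolerance = 1e-6)
  }
})

test_that("non-positive records are filtered with a warning", {
  rec <- data.frame(diameter_um = c(10, 20, 30, -5, 40),
                    q_flow = c(1000, 8000, 27000, 100, 0))
  expect_warning(fit <- fit_branching_exponent(rec), "non-positive")
  expect_equal(fit$n_vessels, 3)
  expect_error(suppressWarnings(
    fit_branching_exponent(data.frame(diameter_um = c(1, 2),
                                      q_flow = c(1, 8)))),
    class = "vascflow_fit_error")
})

test_that("group comparison matches the t oracle and honors the band", {
  young <- data.frame(diameter_um = c(40, 50, 55, 60),
                      v_max_um_s = c(250, 300, 310, 330))
  old <- data.frame(diameter_um = c(30, 35, 40, 45),
                    v_max_um_s = c(180, 200, 240, 260))
  cmp <- compare_diameter_groups(young, old)
  orc <- oracle_t_test(young$diameter_um, old$diameter_um)
  expect_equal(cmp$t_statistic, orc$t, tolerance = 1e-10)
  expect_equal(cmp$p_two_tailed, orc$p, tolerance = 1e-10)

  # closed-open band [35, 50): keeps only young 40 -> too few records
  expect_error(compare_diameter_groups(young, old, band = c(35, 50)),
               class = "vascflow_empty_comparison")
  # [30, 56) drops young 60 (upper edge open) but keeps all old
  cmp_v <- compare_diameter_groups(young, old, value = "v_max_um_s",
                                   band = c(30, 56))
  expect_equal(cmp_v$n, c(3, 4))
})

test_that("groups drawn from the reported age statistics separate reliably", {
  # young ~ N(49.6, 10.4^2) n=55, old ~ N(37.3, 13.1^2) n=64. The exact
  # power of the pooled test at alpha = 1e-4 under these settings is
  #   pt(crit, 117, ncp, lower = FALSE) + pt(-crit, 117, ncp) = 0.9376
  # so the empirical rejection rate is compared with that value.
  sp2 <- (54 * 10.4^2 + 63 * 13.1^2) / 117
  ncp <- (49.6 - 37.3) / sqrt(sp2 * (1 / 55 + 1 / 64))
  crit <- qt(1 - 5e-5, 117)
  power <- pt(crit, 117, ncp = ncp, lower.tail = FALSE) +
    pt(-crit, 117, ncp = ncp)
  set.seed(500)
  hits <- vapply(1:500, function(i) {
    young <- data.frame(diameter_um = rnorm(55, 49.6, 10.4))
    old <- data.frame(diameter_um = rnorm(64, 37.3, 13.1))
    compare_diameter_groups(young, old)$p_two_tailed < 1e-4
  }, TRUE)
  expect_lt(abs(mean(hits) - power), 3 * sqrt(power * (1 - power) / 500))
  expect_gte(mean(hits), 0.9)
})
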