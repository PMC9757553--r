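test_that("joint power follows the moment x angular-velocity sign convention", {
  expect_equal(compute_joint_power(c(0.5, -0.5, 1), c(2, 2, 0)),
               c(1, -1, 0))
  expect_equal(compute_joint_power(rep(0.7, 5), rep(0, 5)), rep(0, 5))
  expect_error(compute_joint_power(1:3, 1:4), "equal length")
  # bilinear: scaling either input scales the power identically
  mx <- rnorm(50); om <- rnorm(50)
  expect_equal(compute_joint_power(3 * mx, om),
               3 * compute_joint_power(mx, om))
  expect_equal(compute_joint_power(mx, -2 * om),
               -2 * compute_joint_power(mx, om))
})

test_that("rate of force development divides peak by time-to-peak", {
  rate <- 1200
  fz <- numeric(121); fz[91] <- 2.4   # peak at (91-1)/1200 = 0.075 s
  expect_equal(compute_rfd(fz, 91, rate), 2.4 / 0.075)  # 32 BW/s
  # single-peak fallback: 100 ms
  fz1 <- numeric(200); fz1[150] <- 2.0
  expect_equal(compute_rfd(fz1, NA, rate, single_peak = TRUE), 20.0)
  expect_error(compute_rfd(fz, 1, rate), "degenerate peak timing")
})

test_that("discrete extraction matches the defining arithmetic", {
  set.seed(11)
  jp <- c(seq(-2, 0, length.out = 51), rnorm(950))
  fy <- seq(-0.14, 0.27, length.out = 1001)
  norm <- structure(list(channels = list(fx_bw = sin(seq(0, 2 * pi,
                                                         length.out = 1001)) * 0.08,
                                         fy_bw = fy,
                                         fz_bw = rep(1, 1001), jp = jp),
                         target_nodes = 1001, single_peak = FALSE),
                    class = "hop_norm")
  dv <- extract_discrete_vars(norm, rfd = 30)
  expect_equal(unname(dv["jp_mean_first5"]), -1.0)
  expect_equal(unname(dv["peak_fy_post"]), -0.14)
  expect_equal(unname(dv["peak_fy_ant"]), 0.27)
  expect_equal(unname(dv["peak_fx_med"]), -0.08, tolerance = 1e-3)
  expect_equal(unname(dv["peak_fx_lat"]), 0.08, tolerance = 1e-3)
  expect_true(dv["jp_peak_con"] <= dv["jp_peak_ecc"])
  # all-zero trajectories give all-zero extrema
  z <- structure(list(channels = list(fx_bw = numeric(1001),
                                      fy_bw = numeric(1001),
                                      fz_bw = numeric(1001),
                                      jp = numeric(1001)),
                      target_nodes = 1001, single_peak = FALSE),
                 class = "hop_norm")
  dz <- extract_discrete_vars(z, rfd = NA)
  expect_true(all(dz[-1] == 0))
})

test_that("noiseless pipeline recovers generator ground truth", {
  # Force-rate quantities are exact through the chain; kinematic-rate
  # (120 Hz) joint-power quantities carry a sampling-resolution error of
  # order 1e-3 relative.
  tr <- simulate_trial(noiseless_spec(), test_meta(), 1200, 120, seed = 1)
  p <- prep_one(tr)
  anch <- c(p$peaks$peak1 - 1, p$peaks$peak2 - 1) /
    (length(p$channels$fz_bw) - 1)
  nm <- piecewise_time_normalize(p$channels, p$peaks, anch)
  rfd <- compute_rfd(p$channels$fz_bw, p$peaks$peak1, p$stance$rate)
  dv <- extract_discrete_vars(nm, rfd)
  tv <- tr$truth
  expect_equal(unname(dv["peak_fz"]), tv$peak_fz_bw, tolerance = 1e-6)
  expect_equal(unname(dv["rfd"]), tv$rfd, tolerance = 1e-6)
  expect_equal(unname(dv["peak_fx_med"]), tv$peak_fx_med, tolerance = 1e-6)
  expect_equal(unname(dv["peak_fx_lat"]), tv$peak_fx_lat, tolerance = 1e-6)
  expect_equal(unname(dv["peak_fy_post"]), tv$peak_fy_post, tolerance = 1e-6)
  expect_equal(unname(dv["peak_fy_ant"]), tv$peak_fy_ant, tolerance = 1e-6)
  expect_equal(unname(dv["jp_mean_first5"]), tv$jp_mean_first5,
               tolerance = 5e-3)
  expect_equal(unname(dv["jp_peak_ecc"]), tv$jp_peak_ecc, tolerance = 5e-3)
  expect_equal(unname(dv["jp_peak_con"]), tv$jp_peak_con, tolerance = 5e-3)
})

test_that("warp anchors change node positions, not attained peak values", {
  tr <- simulate_trial(noiseless_spec(), test_meta(), 1200, 120, seed = 2)
  p <- prep_one(tr)
  for (anch in list(c(0.15, 0.70), c(0.25, 0.60), c(0.40, 0.80))) {
    nm <- piecewise_time_normalize(p$channels, p$peaks, anch)
    # the first-peak sample maps exactly onto its anchor node
    expect_equal(nm$channels$fz_bw[nm$n_peak1 + 1],
                 p$channels$fz_bw[p$peaks$peak1], tolerance = 1e-12)
    expect_equal(nm$channels$fz_bw[nm$n_peak2 + 1],
                 p$channels$fz_bw[p$peaks$peak2], tolerance = 1e-12)
    dv <- extract_discrete_vars(nm, rfd = 1)
    expect_equal(unname(dv["peak_fz"]), max(p$channels$fz_bw),
                 tolerance = 1e-12)
    expect_equal(unname(dv["peak_fy_ant"]), max(p$channels$fy_bw),
                 tolerance = 1e-3)
  }
})
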