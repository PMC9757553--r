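test_that("stance bounds follow the 20 N crossing definition", {
  fz <- c(0, 5, 30, 500, 30, 5, 0)
  tr <- structure(list(t_force = (0:6) / 100, fz = fz,
                       fx = numeric(7), fy = numeric(7),
                       meta = test_meta()),
                  class = "hop_trial")
  st <- detect_stance(tr, threshold_n = 20, debounce_s = 0)
  expect_equal(st$i_start, 3)   # first sample above 20 N
  expect_equal(st$i_end, 5)     # last sample above 20 N
  expect_equal(st$duration_s, 2 / 100)
})

test_that("all-zero vertical force raises a no-stance error", {
  tr <- structure(list(t_force = (0:99) / 100, fz = numeric(100),
                       fx = numeric(100), fy = numeric(100),
                       meta = test_meta()),
                  class = "hop_trial")
  expect_error(detect_stance(tr), "no stance detected")
})

test_that("stance duration of synthetic trials is recovered to the sample", {
  for (dur in c(0.40, 0.45)) {
    tr <- simulate_trial(noiseless_spec(stance_dur_s = dur), test_meta(),
                         2400, 120, seed = 1)
    st <- detect_stance(tr)
    expect_lt(abs(st$duration_s - dur), 2 / 2400)
  }
})

test_that("body-weight normalisation is exact and scale-equivariant", {
  tr <- simulate_trial(noiseless_spec(), test_meta(mass_kg = 75), 1200, 120,
                       seed = 1)
  tr$fz[1] <- 735.5   # 75 kg * 9.80665 = 735.5 N is one body weight
  nb <- normalize_by_bw(tr)
  expect_equal(nb$fz[1], 1.000, tolerance = 1e-4)
  # scaling forces and mass by the same factor leaves BW traces unchanged
  tr2 <- tr
  tr2$fx <- tr$fx * 1.3; tr2$fy <- tr$fy * 1.3; tr2$fz <- tr$fz * 1.3
  tr2$meta$mass_kg <- tr$meta$mass_kg * 1.3
  nb2 <- normalize_by_bw(tr2)
  expect_equal(nb2$fz, nb$fz, tolerance = 1e-12)
  tr$meta$mass_kg <- 0
  expect_error(normalize_by_bw(tr), "mass_kg")
})

test_that("peak detection finds two bumps, classifies single bumps, rejects flat", {
  s <- seq(0, 1, length.out = 501)
  two <- exp(-((s - 0.25) / 0.08)^2) + 0.8 * exp(-((s - 0.70) / 0.08)^2)
  pk <- detect_fz_peaks(two)
  expect_false(pk$single_peak)
  expect_equal(s[pk$peak1], 0.25, tolerance = 0.01)
  expect_equal(s[pk$peak2], 0.70, tolerance = 0.01)
  one <- exp(-((s - 0.5) / 0.15)^2)
  expect_true(detect_fz_peaks(one)$single_peak)
  expect_error(detect_fz_peaks(rep(1, 100)), "flat")
})

test_that("noisy peak times track generator truth at the noise-predicted scale", {
  # With small sensor-scale noise (0.003 BW) the detected peaks sit within
  # 3 nodes of truth; under the default trial-to-trial noise (sd 0.05 BW, FWHM
  # 25 nodes) the peak location wanders by design — the noise model predicts
  # a shift SD of (noise gradient SD)/(peak curvature) ~ 9 nodes, and the
  # detected times must stay within 3 SD of that.
  m <- test_meta()
  rel_times <- function(noise_sd, seeds) {
    eff <- effect_spec(noise_sd = noise_sd)
    t(vapply(seeds, function(s) {
      tr <- simulate_trial(eff, m, 1200, 120, seed = 2000 + s)
      st <- detect_stance(tr)
      pk <- detect_fz_peaks(tr$fz[st$i_start:st$i_end])
      L <- st$i_end - st$i_start + 1
      c((pk$peak1 - 1) / (L - 1), (pk$peak2 - 1) / (L - 1))
    }, numeric(2)))
  }
  eff <- effect_spec()
  small <- rel_times(0.003, 1:100)
  hits <- abs(small[, 1] - eff$peak1_time_frac) < 0.003 &
    abs(small[, 2] - eff$peak2_time_frac) < 0.003
  expect_gte(mean(hits), 0.95)
  deflt <- rel_times(eff$noise_sd, 1:100)
  hits2 <- abs(deflt[, 1] - eff$peak1_time_frac) < 0.035 &
    abs(deflt[, 2] - eff$peak2_time_frac) < 0.035
  expect_gte(mean(hits2), 0.95)
})

test_that("three-phase warp pins the peaks to the anchor nodes", {
  # constant signals are invariant to any warp
  s <- seq(0, 1, length.out = 801)
  fz <- exp(-((s - 0.20) / 0.06)^2) + 0.8 * exp(-((s - 0.60) / 0.06)^2)
  pk <- detect_fz_peaks(fz)
  out <- piecewise_time_normalize(list(fz_bw = fz, const = rep(3.5, 801)),
                                  pk, anchors = c(0.30, 0.65))
  expect_equal(out$channels$const, rep(3.5, 1001), tolerance = 1e-12)
  expect_length(out$channels$fz_bw, 1001)
  expect_equal(out$n_peak1, 300)
  expect_equal(out$n_peak2, 650)
  expect_equal(which.max(out$channels$fz_bw), 301)  # node 300, 1-based 301
  w <- out$channels$fz_bw
  expect_equal(w[301], fz[pk$peak1], tolerance = 1e-12)
  expect_equal(w[651], fz[pk$peak2], tolerance = 1e-12)
  # endpoints preserved
  expect_equal(w[1], fz[1]); expect_equal(w[1001], fz[801])
  # invalid anchors
  expect_error(piecewise_time_normalize(list(a = fz), pk, c(0.7, 0.3)),
               "anchors")
  # single-peak fallback: uniform resampling
  one <- exp(-((s - 0.5) / 0.15)^2)
  u <- piecewise_time_normalize(list(a = one), detect_fz_peaks(one),
                                c(0.3, 0.65))
  expect_true(u$single_peak)
  expect_length(u$channels$a, 1001)
})

test_that("trial averaging is the node-wise mean and reduces noise", {
  s <- seq(0, 1, length.out = 801)
  fz <- exp(-((s - 0.20) / 0.06)^2) + 0.8 * exp(-((s - 0.60) / 0.06)^2)
  pk <- detect_fz_peaks(fz)
  mk <- function(x) piecewise_time_normalize(list(fz_bw = x), pk, c(0.2, 0.6))
  n1 <- mk(fz); n2 <- mk(fz + 2)
  expect_warning(avg <- average_trials(list(n1, n2)), "2 trial")
  expect_equal(avg$norm$channels$fz_bw, n1$channels$fz_bw + 1,
               tolerance = 1e-12)
  idem <- suppressWarnings(average_trials(list(n1, n1)))
  expect_equal(idem$norm$channels$fz_bw, n1$channels$fz_bw)
  expect_error(average_trials(list()), "empty cell")
  # averaging five noisy replicates beats every single replicate vs truth
  eff <- effect_spec(noise_sd = 0.08)
  truth_tr <- simulate_trial(noiseless_spec(), test_meta(), 1200, 120, seed = 1)
  cfg <- analysis_config()
  truth_p <- prep_one(truth_tr, cfg)
  anchors <- c(truth_p$peaks$peak1 - 1, truth_p$peaks$peak2 - 1) /
    (length(truth_p$channels$fz_bw) - 1)
  truth_n <- piecewise_time_normalize(truth_p$channels, truth_p$peaks, anchors)
  wins <- vapply(1:20, function(rep) {
    norms <- lapply(1:5, function(k) {
      tr <- simulate_trial(eff, test_meta(), 1200, 120, seed = rep * 100 + k)
      p <- prep_one(tr, cfg)
      piecewise_time_normalize(p$channels, p$peaks, anchors)
    })
    rmse <- function(n) sqrt(mean((n$channels$fz_bw - truth_n$channels$fz_bw)^2))
    avg <- average_trials(norms)$norm
    rmse(avg) < min(vapply(norms, rmse, numeric(1)))
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("discrete averaging of a single trial returns it unchanged", {
  st <- simulate_crossover_study(small_design(n = 1, trials = 1,
                                              conditions = "uninjured-unsleeved"),
                                 seed = 3)
  pr <- suppressWarnings(prepare_study(st))
  cell <- pr$cells[[1]]
  expect_equal(cell$n_trials, 1)
  tr <- st$trials[[1]]
  p <- prep_one(tr)
  anch <- pr$anchors
  nm <- piecewise_time_normalize(p$channels, p$peaks, anch)
  expect_equal(cell$norm$channels$fz_bw, nm$channels$fz_bw, tolerance = 1e-12)
})
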