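test_that("t trajectory matches hand-computed values and symmetries", {
  # constant curves {1,2,3} vs {4,5,6}: two-sample t = -3/(1*sqrt(2/3))
  a <- matrix(rep(c(1, 2, 3), 5), 3, 5)
  b <- matrix(rep(c(4, 5, 6), 5), 3, 5)
  tt <- t_trajectory(a, b, paired = FALSE)
  expect_equal(tt$z, rep(-3.674235, 5), tolerance = 1e-6)
  expect_equal(tt$df, 4)
  # identity case and odd symmetry
  set.seed(1)
  x <- matrix(rnorm(60), 6, 10)
  expect_warning(z0 <- t_trajectory(x, x, paired = TRUE)$z, "zero-variance")
  expect_equal(z0, rep(0, 10))
  y <- matrix(rnorm(60), 6, 10)
  expect_equal(t_trajectory(-x, -y, paired = TRUE)$z,
               -t_trajectory(x, y, paired = TRUE)$z)
})

test_that("Hotelling's T2 reduces to t2 and matches the matrix formula", {
  set.seed(2)
  x <- matrix(rnorm(80), 8, 10); y <- matrix(rnorm(80), 8, 10)
  T2 <- hotellings_T2_trajectory(array(x, c(8, 10, 1)),
                                 array(y, c(8, 10, 1)), paired = TRUE)$z
  tz <- t_trajectory(x, y, paired = TRUE)$z
  expect_equal(T2, tz^2, tolerance = 1e-10)
  # paired identical sets -> 0 (ridge-regularised singular covariance)
  suppressWarnings({
    T0 <- hotellings_T2_trajectory(array(x, c(8, 10, 1)),
                                   array(x, c(8, 10, 1)), paired = TRUE)$z
  })
  expect_equal(T0, rep(0, 10))
  # two-component brute force at node 1, computed independently
  d <- array(rnorm(2 * 5 * 6), c(5, 6, 2))
  fit <- hotellings_T2_trajectory(d, paired = TRUE)
  X <- d[, 1, ]
  m <- colMeans(X)
  S <- crossprod(sweep(X, 2, m)) / 4
  expect_equal(fit$z[1], 5 * drop(t(m) %*% solve(S) %*% m),
               tolerance = 1e-10)
  expect_equal(fit$df, c(2, 4))
})

test_that("smoothness estimator is well defined and calibrated", {
  set.seed(3)
  # white noise: smoothness in the low single digits
  W <- matrix(rnorm(20 * 1001), 20, 1001)
  expect_lt(estimate_fwhm(W), 5)
  # duplicated identical fields with gradient: finite positive
  f <- sin(seq(0, 4 * pi, length.out = 200))
  est <- estimate_fwhm(rbind(f, f))
  expect_true(is.finite(est) && est > 0)
  # constant fields clamp with a warning
  expect_warning(up <- estimate_fwhm(matrix(1, 4, 100)), "clamped")
  expect_equal(up, 1000)
})

test_that("RFT threshold has the right limits and monotonicity", {
  # infinite smoothness -> ordinary two-sided critical value
  expect_equal(rft_threshold("t", df = 9, fwhm = 1e9, alpha = 0.05),
               qt(0.975, 9), tolerance = 1e-4)
  # strictly decreasing in alpha
  z1 <- rft_threshold("t", df = 12, fwhm = 20, alpha = 0.01)
  z2 <- rft_threshold("t", df = 12, fwhm = 20, alpha = 0.05)
  z3 <- rft_threshold("t", df = 12, fwhm = 20, alpha = 0.10)
  expect_true(z1 > z2 && z2 > z3)
  # T2 threshold with one component equals the squared t threshold
  zt <- rft_threshold("t", df = 9, fwhm = 20, alpha = 0.05)
  zT2 <- rft_threshold("T2", df = c(1, 9), fwhm = 20, alpha = 0.05)
  expect_equal(zT2, zt^2, tolerance = 1e-4)
})

test_that("permutation threshold is deterministic and exchangeable", {
  set.seed(4)
  d <- smooth_gaussian_fields(12, 301, 15)
  p1 <- permutation_threshold(d, stat = "t", paired = TRUE, alpha = 0.05,
                              n_perm = 800, seed = 7)
  p2 <- permutation_threshold(d, stat = "t", paired = TRUE, alpha = 0.05,
                              n_perm = 800, seed = 7)
  expect_identical(p1, p2)
  expect_error(permutation_threshold(d[1:3, ], stat = "t", paired = TRUE,
                                     alpha = 0.01, n_perm = 500),
               "too few distinct permutations")
})

test_that("RFT and exhaustive permutation thresholds agree on smooth nulls", {
  ratios <- vapply(1:3, function(s) {
    set.seed(s)
    d <- smooth_gaussian_fields(10, 1001, 20)
    fit <- t_trajectory(d)
    fw <- estimate_fwhm(fit$residuals)
    zr <- rft_threshold("t", df = 9, fwhm = fw, alpha = 0.05)
    zp <- permutation_threshold(d, stat = "t", paired = TRUE, alpha = 0.05,
                                n_perm = 1024)
    zp / zr
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.10)
})

test_that("spm_test finds no clusters for identical conditions and is
           invariant to common affine rescaling", {
  set.seed(5)
  x <- smooth_gaussian_fields(8, 301, 15)
  s0 <- suppressWarnings(spm_test(x, x, stat = "t", paired = TRUE,
                                  alpha = 0.05, fwhm = 15))
  expect_equal(nrow(s0$clusters), 0)
  expect_false(s0$significant)
  y <- smooth_gaussian_fields(8, 301, 15) + 0.5
  s1 <- spm_test(x, y, stat = "t", paired = TRUE, alpha = 0.05)
  s2 <- spm_test(2.7 * x + 3, 2.7 * y + 3, stat = "t", paired = TRUE,
                 alpha = 0.05)
  expect_equal(s1$z, s2$z, tolerance = 1e-9)
  expect_equal(s1$zstar, s2$zstar, tolerance = 1e-6)
})

test_that("spm_test localises a large injected early-stance power deficit", {
  set.seed(6)
  n <- 12; Q <- 1001
  base <- smooth_gaussian_fields(n, Q, 25)
  effect <- c(rep(1, 51), exp(-((1:950) / 40)^2)) * 5
  a <- base + matrix(effect, n, Q, byrow = TRUE)
  b <- smooth_gaussian_fields(n, Q, 25)
  s <- spm_test(a, b, stat = "t", paired = TRUE, alpha = 0.017)
  expect_true(s$significant)
  expect_true(any(s$clusters$start <= 50))
  expect_true(all(s$clusters$p_cluster >= 0 & s$clusters$p_cluster <= 1))
})
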