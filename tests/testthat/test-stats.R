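test_that("repeated-measures ANOVA matches the base multivariate machinery", {
  set.seed(42)
  Y <- matrix(rnorm(30), 10, 3) + outer(rnorm(10), rep(1, 3))
  Y[, 2] <- Y[, 2] + 0.8
  Y[, 3] <- Y[, 3] * 1.5
  res <- rm_anova(Y)
  fit <- lm(Y ~ 1)
  id <- data.frame(cond = factor(1:3))
  av <- anova(fit, idata = id, X = ~1, M = ~cond, test = "Spherical")
  expect_equal(res$f_stat, av$F[1], tolerance = 1e-10)
  expect_equal(res$p_uncorrected, av$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(res$p_gg, av$`G-G Pr`[1], tolerance = 1e-10)
  mt <- mauchly.test(fit, idata = id, X = ~1, M = ~cond)
  expect_equal(res$mauchly_w, unname(mt$statistic), tolerance = 1e-10)
  expect_equal(res$mauchly_p, mt$p.value, tolerance = 1e-10)
})

test_that("repeated-measures F matches a brute-force sums-of-squares oracle", {
  Y <- matrix(c(3, 5, 4, 6, 4, 6, 5, 8, 6, 7, 8, 9), 4, 3)
  res <- rm_anova(Y)
  gm <- mean(Y); rm_ <- rowMeans(Y); cm <- colMeans(Y)
  ss_cond <- 4 * sum((cm - gm)^2)
  ss_err <- sum((Y - outer(rm_, rep(1, 3)) - outer(rep(1, 4), cm) + gm)^2)
  f_oracle <- (ss_cond / 2) / (ss_err / 6)
  expect_equal(res$f_stat, f_oracle, tolerance = 1e-12)
  expect_equal(res$df_num, 2)
  expect_equal(res$df_den, 6)
  # shift invariance
  expect_equal(rm_anova(Y + 100)$f_stat, res$f_stat, tolerance = 1e-10)
})

test_that("two conditions trivially satisfy sphericity", {
  set.seed(8)
  Y <- matrix(rnorm(20), 10, 2)
  res <- rm_anova(Y)
  expect_equal(res$gg_epsilon, 1)
  expect_equal(res$mauchly_p, 1)
  expect_false(res$used_gg)
})

test_that("compound-symmetric data rarely trigger the sphericity correction", {
  set.seed(9)
  hits <- vapply(1:40, function(i) {
    Y <- outer(rnorm(40, sd = 2), rep(1, 3)) + matrix(rnorm(120), 40, 3)
    rm_anova(Y)$mauchly_p > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("covariates are accepted and adjust the error degrees of freedom", {
  set.seed(10)
  Y <- matrix(rnorm(45), 15, 3)
  cv <- data.frame(sex = sample(c("male", "female"), 15, TRUE),
                   months = rnorm(15, 16, 5))
  res <- rm_anova(Y, cv)
  expect_equal(res$df_den, 2 * (15 - 1 - 2))
  expect_identical(res$covariates, c("sex", "months"))
  expect_error(rm_anova(Y[1:4, ], data.frame(a = rnorm(4), b = rnorm(4),
                                             c = rnorm(4))),
               "too few participants")
})

test_that("paired post-hocs cap Bonferroni p at 1 and bracket the mean", {
  set.seed(12)
  Y <- matrix(rnorm(60), 20, 3)
  colnames(Y) <- c("A", "B", "C")
  ph <- posthoc_paired_bonferroni(Y)
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$ci95_low <= ph$mean_diff & ph$mean_diff <= ph$ci95_high))
  expect_true(all(ph$p_bonferroni <= 1))
  expect_equal(ph$p_bonferroni, pmin(1, ph$p_raw * 3))
  # identical conditions
  ph0 <- posthoc_paired_bonferroni(cbind(Y[, 1], Y[, 1]))
  expect_equal(ph0$mean_diff, 0)
  expect_equal(ph0$p_bonferroni, 1)
  # a raw p of ~0.4 reports as 1.000 after the x3 cap
  repeat {
    d <- rnorm(15)
    p <- t.test(d)$p.value
    if (p > 0.35 && p < 0.45) break
  }
  ph3 <- posthoc_paired_bonferroni(cbind(numeric(15), d, d),
                                   pairs = list(c(1, 2), c(1, 3), c(2, 3)))
  expect_equal(ph3$p_raw[1], p, tolerance = 1e-12)
  expect_equal(ph3$p_bonferroni[1], 1)
})

test_that("paired-t confidence intervals have nominal coverage", {
  set.seed(13)
  n <- 30; reps <- 2000; delta <- 0.4
  D <- matrix(rnorm(reps * n, mean = delta), reps, n)
  m <- rowMeans(D)
  se <- sqrt((rowSums(D^2) - n * m^2) / (n - 1) / n)
  half <- qt(0.975, n - 1) * se
  cover <- mean(m - half <= delta & delta <= m + half)
  expect_gte(cover, 0.935)
  expect_lte(cover, 0.965)
})

test_that("change scores subtract baseline from follow-up per participant", {
  bl <- c(P1 = 2.43, P2 = 2.0)
  fu <- c(P2 = 2.1, P1 = 2.26)
  cs <- change_scores(bl, fu)
  expect_equal(cs$delta[cs$participant == "P1"], -0.17)
  expect_equal(cs$delta[cs$participant == "P2"], 0.1)
  # identical sessions -> zero; shift invariance
  expect_equal(change_scores(bl, bl)$delta, c(0, 0))
  expect_equal(change_scores(bl + 5, fu + 5)$delta, cs$delta)
  expect_error(change_scores(bl, c(P1 = 1, P3 = 2)), "unmatched")
})

test_that("Mann-Whitney matches exhaustive enumeration for all small designs", {
  expect_equal(mann_whitney_exact(c(1, 2), c(3, 4))$U, 0)
  expect_equal(mann_whitney_exact(c(1, 2), c(3, 4))$p_value, 1 / 3,
               tolerance = 1e-12)
  set.seed(14)
  for (na in 1:5) {
    for (nb in na:(10 - na)) {
      vals <- sample(seq_len(50), na + nb)   # distinct, no ties
      a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
      got <- mann_whitney_exact(a, b)
      oracle <- mw_enum_oracle(a, b)
      expect_equal(got$U, oracle$U)
      expect_equal(got$p_value, oracle$p, tolerance = 1e-12)
      # label symmetry
      swap <- mann_whitney_exact(b, a)
      expect_equal(swap$U, na * nb - got$U)
      expect_equal(swap$p_value, got$p_value, tolerance = 1e-12)
    }
  }
  # identical groups: maximal p
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # degenerate n = 1 per group
  expect_equal(mann_whitney_exact(5, 9)$p_value, 1)
})
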