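#' Node-wise Student t trajectory
#'
#' Computes the t statistic at every node of a set of 1D responses: paired
#' (one-sample on the matched differences) or two-sample with pooled
#' variance. Nodes with zero variance get statistic 0 with a warning.
#'
#' @param a Numeric matrix, responses x nodes.
#' @param b Second set (same node count; for `paired = TRUE` also the same
#'   row count and matched row order). `NULL` for a one-sample test on `a`.
#' @param paired Flag.
#' @return List: statistic trajectory `z`, degrees of freedom `df`,
#'   `stat_name`, and the residual fields used for smoothness estimation.
#' @export
t_trajectory <- function(a, b = NULL, paired = is.null(b)) {
  a <- as.matrix(a)
  if (paired) {
    d <- if (is.null(b)) a else {
      b <- as.matrix(b)
      stopifnot(identical(dim(a), dim(b)))
      a - b
    }
    n <- nrow(d)
    if (n < 2) stop("need at least 2 responses", call. = FALSE)
    m <- colMeans(d)
    v <- apply(d, 2, stats::var)
    se <- sqrt(v / n)
    z <- numeric(length(m))
    ok <- se > 0
    if (!all(ok)) warning(sprintf("%d zero-variance node(s); statistic set to 0",
                                  sum(!ok)))
    z[ok] <- m[ok] / se[ok]
    res <- sweep(d, 2, m)
    list(z = z, df = n - 1, stat_name = "t_paired", residuals = res,
         n = n)
  } else {
    b <- as.matrix(b)
    stopifnot(ncol(a) == ncol(b))
    n1 <- nrow(a); n2 <- nrow(b)
    if (n1 < 2 || n2 < 2) stop("need at least 2 responses per group",
                               call. = FALSE)
    m1 <- colMeans(a); m2 <- colMeans(b)
    v1 <- apply(a, 2, stats::var); v2 <- apply(b, 2, stats::var)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    z <- numeric(length(m1))
    ok <- se > 0
    if (!all(ok)) warning(sprintf("%d zero-variance node(s); statistic set to 0",
                                  sum(!ok)))
    z[ok] <- (m1[ok] - m2[ok]) / se[ok]
    res <- rbind(sweep(a, 2, m1), sweep(b, 2, m2))
    list(z = z, df = n1 + n2 - 2, stat_name = "t_two_sample",
         residuals = res, n = c(n1, n2))
  }
}

#' Node-wise Hotelling's T-squared trajectory
#'
#' Multivariate generalisation of the t field for vector-valued responses
#' (e.g. the three GRF components): one-sample on paired differences, or
#' two-sample with pooled covariance. A singular node covariance is
#' regularised by a ridge of `1e-10 * trace` with a warning.
#'
#' @param a 3D array, responses x nodes x components.
#' @param b Matching array (or `NULL` for one-sample on `a`).
#' @param paired Flag.
#' @return List: `z` (T-squared trajectory), `df = c(p, v)` with `p` the
#'   component count and `v` the error degrees of freedom (`n - 1` paired,
#'   `n1 + n2 - 2` two-sample), `stat_name`, stacked residual fields.
#' @export
hotellings_T2_trajectory <- function(a, b = NULL, paired = is.null(b)) {
  stopifnot(length(dim(a)) == 3)
  p <- dim(a)[3]
  Q <- dim(a)[2]
  ridge_warned <- FALSE
  t2_one <- function(d) {
    n <- dim(d)[1]
    if (n <= p) stop("need n > number of components", call. = FALSE)
    z <- numeric(Q)
    for (q in seq_len(Q)) {
      X <- d[, q, , drop = TRUE]
      if (p == 1) X <- matrix(X, ncol = 1)
      m <- colMeans(X)
      S <- stats::cov(X)
      if (sum(diag(S)) < .Machine$double.eps) {
        z[q] <- 0   # degenerate zero-variance node
        next
      }
      if (!is.finite(rcond_safe(S)) || rcond_safe(S) < 1e-12) {
        S <- S + diag(1e-10 * sum(diag(S)), p)
        ridge_warned <<- TRUE
      }
      z[q] <- n * drop(crossprod(m, solve(S, m)))
    }
    z
  }
  if (paired) {
    d <- if (is.null(b)) a else {
      stopifnot(identical(dim(a), dim(b)))
      a - b
    }
    n <- dim(d)[1]
    z <- t2_one(d)
    res <- do.call(rbind, lapply(seq_len(p), function(k) {
      sweep(d[, , k, drop = TRUE], 2, colMeans(d[, , k, drop = TRUE]))
    }))
    out <- list(z = z, df = c(p, n - 1), stat_name = "hotellings_T2",
                residuals = res, n = n, p = p, design = "paired")
  } else {
    stopifnot(length(dim(b)) == 3, dim(b)[2] == Q, dim(b)[3] == p)
    n1 <- dim(a)[1]; n2 <- dim(b)[1]
    if (n1 + n2 - 2 < p) stop("need n > number of components", call. = FALSE)
    z <- numeric(Q)
    for (q in seq_len(Q)) {
      X <- matrix(a[, q, , drop = TRUE], ncol = p)
      Y <- matrix(b[, q, , drop = TRUE], ncol = p)
      m <- colMeans(X) - colMeans(Y)
      S <- ((n1 - 1) * stats::cov(X) + (n2 - 1) * stats::cov(Y)) / (n1 + n2 - 2)
      if (sum(diag(S)) < .Machine$double.eps) {
        z[q] <- 0
        next
      }
      if (!is.finite(rcond_safe(S)) || rcond_safe(S) < 1e-12) {
        S <- S + diag(1e-10 * sum(diag(S)), p)
        ridge_warned <<- TRUE
      }
      z[q] <- (n1 * n2 / (n1 + n2)) * drop(crossprod(m, solve(S, m)))
    }
    res <- do.call(rbind, lapply(seq_len(p), function(k) {
      rbind(sweep(a[, , k, drop = TRUE], 2, colMeans(a[, , k, drop = TRUE])),
            sweep(b[, , k, drop = TRUE], 2, colMeans(b[, , k, drop = TRUE])))
    }))
    out <- list(z = z, df = c(p, n1 + n2 - 2), stat_name = "hotellings_T2",
                residuals = res, n = c(n1, n2), p = p, design = "two_sample")
  }
  if (ridge_warned) warning("singular node covariance regularised by ridge")
  out
}

rcond_safe <- function(S) {
  tryCatch(rcond(S), error = function(e) 0)
}

#' Residual-field smoothness (FWHM)
#'
#' Standard SPM residual smoothness estimator: the full width at half
#' maximum of the equivalent Gaussian kernel, from the per-node variance of
#' the normalised residual gradients. Clamped to [1, 1000]; constant
#' residual fields return the upper clamp with a warning.
#'
#' @param residuals Matrix of residual fields, fields x nodes (>= 2 rows).
#' @return Estimated FWHM in nodes.
#' @export
estimate_fwhm <- function(residuals) {
  R <- as.matrix(residuals)
  if (nrow(R) < 2) stop("need at least 2 residual fields", call. = FALSE)
  n <- ncol(R)
  grad <- t(apply(R, 1, function(x) {
    c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
  }))
  ssq <- colSums(R^2)
  v <- colSums(grad^2) / (ssq + .Machine$double.eps)
  v <- v[ssq > .Machine$double.eps]
  if (length(v) == 0 || all(v <= 0)) {
    warning("constant residual fields; smoothness clamped to 1000 nodes")
    return(1000)
  }
  rpn <- sqrt(v / (4 * log(2)))   # resels per node
  fwhm <- 1 / mean(rpn)
  min(max(fwhm, 1), 1000)
}

# 1D Euler-characteristic densities (unit-resel) for t and F fields; the
# expected EC of the excursion set above u over R resels is
# rho0(u) + R * rho1(u).
ec_density <- function(stat_name, u, df) {
  if (stat_name == "t") {
    v <- df
    rho0 <- stats::pt(u, v, lower.tail = FALSE)
    rho1 <- sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / v)^(-(v - 1) / 2)
  } else if (stat_name == "F") {
    k <- df[1]; v <- df[2]
    rho0 <- stats::pf(u, k, v, lower.tail = FALSE)
    lg <- lgamma((v + k - 1) / 2) - lgamma(v / 2) - lgamma(k / 2)
    rho1 <- sqrt(4 * log(2) / (2 * pi)) * sqrt(2) * exp(lg) *
      (k * u / v)^((k - 1) / 2) * (1 + k * u / v)^(-(v + k - 2) / 2)
  } else {
    stop("unknown field type: ", stat_name, call. = FALSE)
  }
  c(rho0 = rho0, rho1 = rho1)
}

# Family-wise exceedance probability P(max field > u) under the 1D
# Euler-characteristic approximation with R = (n_nodes - 1)/fwhm resels.
rft_pmax <- function(stat_name, u, df, resels) {
  d <- ec_density(stat_name, u, df)
  min(1, d[["rho0"]] + resels * d[["rho1"]])
}

#' Random-field-theory critical threshold for a 1D statistic field
#'
#' Solves `P(max > zstar) = alpha` under the 1D Euler-characteristic
#' approximation with `resels = (n_nodes - 1) / fwhm`, by bisection to
#' `|dP| < 1e-8`. t fields are handled two-sided (alpha/2 on the upper tail
#' of |t|); Hotelling's T-squared fields are thresholded through their
#' F-field transformation (upper tail).
#'
#' @param stat_name `"t"` or `"T2"`.
#' @param df Degrees of freedom: scalar `v` for t; `c(p, v)` for T-squared
#'   (`p` components, `v` error df).
#' @param n_nodes Field length (default 1001).
#' @param fwhm Field smoothness in nodes.
#' @param alpha Family-wise error level in (0, 1).
#' @param two_sided Two-sided handling for t fields (default TRUE).
#' @return Critical threshold on the statistic's own scale.
#' @export
rft_threshold <- function(stat_name = c("t", "T2"), df, n_nodes = 1001,
                          fwhm, alpha = 0.05, two_sided = TRUE) {
  stat_name <- match.arg(stat_name)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (!(is.numeric(fwhm) && fwhm > 0)) stop("fwhm must be > 0", call. = FALSE)
  resels <- (n_nodes - 1) / fwhm
  if (stat_name == "t") {
    target <- if (two_sided) alpha / 2 else alpha
    f <- function(u) rft_pmax("t", u, df, resels) - target
    lo <- 0; hi <- stats::qt(1 - target, df) + 1
  } else {
    p <- df[1]; v <- df[2]
    if (v - p + 1 < 2) {
      stop("error df too small for a T2 random-field threshold ",
           "(need at least p + 2 effective observations)", call. = FALSE)
    }
    fdf <- c(p, v - p + 1)
    t2_to_f <- (v - p + 1) / (p * v)
    f <- function(u) rft_pmax("F", u, fdf, resels) - alpha
    lo <- 0; hi <- stats::qf(1 - alpha, fdf[1], fdf[2]) + 1
  }
  for (i in 1:200) {
    if (f(hi) < 0) break
    hi <- hi * 2
    if (hi > 1e8) stop("no solution in bracket for the RFT threshold",
                       call. = FALSE)
  }
  if (f(lo) < 0) stop("no solution in bracket for the RFT threshold",
                      call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < 1e-8 || (hi - lo) < 1e-12) break
    if (fm > 0) lo <- mid else hi <- mid
  }
  u <- (lo + hi) / 2
  if (stat_name == "T2") u <- u / t2_to_f
  u
}

#' Permutation threshold for the maximum statistic of a 1D field
#'
#' Non-parametric oracle for [rft_threshold()]: the `(1 - alpha)` quantile
#' of the maximum-statistic distribution under sign flips (paired/one-sample)
#' or group relabelling (two-sample). Exhaustive when the number of distinct
#' permutations does not exceed `n_perm`, random otherwise.
#'
#' @param a,b Response matrices (t fields) or 3D arrays (T-squared fields);
#'   `b = NULL` for one-sample sign flipping of `a`.
#' @param stat `"t"` or `"T2"`.
#' @param paired Flag.
#' @param alpha Level in (0, 1).
#' @param n_perm Permutation budget (>= 500).
#' @param seed Integer seed for random permutations.
#' @return Threshold on the statistic's own scale (max |t| for t fields).
#' @export
permutation_threshold <- function(a, b = NULL, stat = c("t", "T2"),
                                  paired = is.null(b), alpha = 0.05,
                                  n_perm = 10000, seed = 1L) {
  stat <- match.arg(stat)
  if (n_perm < 500) stop("n_perm must be >= 500", call. = FALSE)
  max_stat <- function(x, y) {
    if (stat == "t") max(abs(t_trajectory(x, y, paired = paired)$z))
    else max(hotellings_T2_trajectory(x, y, paired = paired)$z)
  }
  maxs <- NULL
  if (paired) {
    d <- if (is.null(b)) a else (a - b)
    n <- if (stat == "t") nrow(d) else dim(d)[1]
    n_distinct <- 2^n
    if (n_distinct < 1 / alpha) {
      stop("too few distinct permutations for this alpha", call. = FALSE)
    }
    flip_once <- function(sgn) {
      ds <- if (stat == "t") d * sgn else d * array(sgn, dim = dim(d))
      max_stat(ds, NULL)
    }
    if (n_distinct <= n_perm) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      maxs <- apply(signs, 1, flip_once)
    } else {
      maxs <- with_seed(seed, {
        vapply(seq_len(n_perm), function(i) {
          flip_once(sample(c(-1, 1), n, replace = TRUE))
        }, numeric(1))
      })
    }
  } else {
    n1 <- if (stat == "t") nrow(a) else dim(a)[1]
    n2 <- if (stat == "t") nrow(b) else dim(b)[1]
    pool <- if (stat == "t") rbind(a, b) else {
      abind3(a, b)
    }
    n <- n1 + n2
    n_distinct <- choose(n, n1)
    if (n_distinct < 1 / alpha) {
      stop("too few distinct permutations for this alpha", call. = FALSE)
    }
    take <- function(idx) {
      if (stat == "t") max_stat(pool[idx, , drop = FALSE],
                                pool[setdiff(seq_len(n), idx), , drop = FALSE])
      else max_stat(pool[idx, , , drop = FALSE],
                    pool[setdiff(seq_len(n), idx), , , drop = FALSE])
    }
    if (n_distinct <= n_perm) {
      combos <- utils::combn(n, n1)
      maxs <- apply(combos, 2, take)
    } else {
      maxs <- with_seed(seed, {
        vapply(seq_len(n_perm), function(i) take(sample(n, n1)), numeric(1))
      })
    }
  }
  unname(stats::quantile(maxs, 1 - alpha, type = 7))
}

abind3 <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# Suprathreshold clusters of a statistic trajectory; for two-sided t fields
# the excursion set is on |z|.
find_clusters <- function(z, zstar, two_sided) {
  x <- if (two_sided) abs(z) else z
  supra <- x > zstar
  if (!any(supra)) {
    return(data.frame(start = integer(0), end = integer(0),
                      max_stat = numeric(0)))
  }
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] - 1L, end = ends[keep] - 1L,
             max_stat = mapply(function(s, e) z[which.max(x[s:e]) + s - 1L],
                               starts[keep], ends[keep]))
}

# Descriptive cluster-level p under the standard random-field cluster-extent
# approximation (Poisson clumping heuristic, D = 1).
cluster_p_rft <- function(extent_nodes, stat_name, zstar, df, fwhm, n_nodes,
                          two_sided) {
  resels <- (n_nodes - 1) / fwhm
  dens_name <- if (stat_name == "t") "t" else "F"
  d <- ec_density(dens_name, zstar, df)
  mult <- if (two_sided) 2 else 1
  E_m <- mult * resels * d[["rho1"]]
  E_n <- mult * resels * d[["rho0"]]
  if (E_m <= 0 || E_n <= 0) return(NA_real_)
  k <- extent_nodes / fwhm
  beta <- (gamma(1.5) * E_m / E_n)^2
  p_ext <- exp(-beta * k^2)
  max(0, min(1, 1 - exp(-E_m * p_ext)))
}

#' One-dimensional SPM test
#'
#' Assembles the full inference for one comparison: statistic trajectory,
#' residual smoothness, random-field critical threshold, and suprathreshold
#' clusters with descriptive cluster-level p values.
#'
#' @param a,b Response matrices (`stat = "t"`) or responses x nodes x
#'   components arrays (`stat = "T2"`); `b = NULL` for a one-sample test
#'   (e.g. follow-up minus baseline difference trajectories).
#' @param stat `"t"` or `"T2"`.
#' @param paired Flag (one-sample on matched differences when `TRUE`).
#' @param alpha Family-wise level for this comparison (e.g. 0.017 after
#'   Bonferroni correction over three comparisons).
#' @param fwhm Optional smoothness override; estimated from the residual
#'   fields when `NULL`.
#' @param two_sided Two-sided inference for t fields (default TRUE; T-squared
#'   fields are upper-tail by construction).
#' @return An object of class `hop_spm`: `stat_name`, `z`, `df`, `alpha`,
#'   `fwhm`, `zstar`, `clusters` (0-based node ranges), `significant`.
#' @export
spm_test <- function(a, b = NULL, stat = c("t", "T2"), paired = is.null(b),
                     alpha = 0.05, fwhm = NULL, two_sided = TRUE) {
  stat <- match.arg(stat)
  fit <- if (stat == "t") t_trajectory(a, b, paired = paired)
  else hotellings_T2_trajectory(a, b, paired = paired)
  n_nodes <- length(fit$z)
  if (is.null(fwhm)) fwhm <- estimate_fwhm(fit$residuals)
  two <- (stat == "t") && two_sided
  zstar <- rft_threshold(stat, fit$df, n_nodes = n_nodes, fwhm = fwhm,
                         alpha = alpha, two_sided = two)
  cl <- find_clusters(fit$z, zstar, two_sided = two)
  if (nrow(cl)) {
    cl_df <- if (stat == "t") fit$df else c(fit$df[1], fit$df[2] - fit$df[1] + 1)
    cl_star <- if (stat == "t") zstar else {
      p <- fit$df[1]; v <- fit$df[2]
      zstar * (v - p + 1) / (p * v)
    }
    cl$p_cluster <- vapply(seq_len(nrow(cl)), function(i) {
      cluster_p_rft(cl$end[i] - cl$start[i] + 1, stat, cl_star, cl_df,
                    fwhm, n_nodes, two)
    }, numeric(1))
  } else {
    cl$p_cluster <- numeric(0)
  }
  structure(list(stat_name = fit$stat_name, z = fit$z, df = fit$df,
                 alpha = alpha, fwhm = fwhm, zstar = zstar, clusters = cl,
                 significant = nrow(cl) > 0, n = fit$n),
            class = "hop_spm")
}

#' @export
print.hop_spm <- function(x, ...) {
  cat(sprintf("1D SPM %s: df = %s, FWHM = %.1f nodes, z* = %.3f (alpha = %.3f)\n",
              x$stat_name, paste(x$df, collapse = ","), x$fwhm, x$zstar,
              x$alpha))
  if (nrow(x$clusters)) {
    cat(sprintf("  %d suprathreshold cluster(s):\n", nrow(x$clusters)))
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("    nodes %d-%d, max stat %.2f, cluster p ~ %.4f\n",
                  x$clusters$start[i], x$clusters$end[i],
                  x$clusters$max_stat[i], x$clusters$p_cluster[i]))
    }
  } else cat("  no suprathreshold clusters\n")
  invisible(x)
}
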