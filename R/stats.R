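#' One-way repeated-measures ANOVA with sphericity handling and covariates
#'
#' Within-subject F test for a condition effect across `k` repeated
#' conditions, via the orthonormal-contrast general linear model: the
#' participant-by-condition matrix is projected onto `k - 1` orthonormal
#' contrasts, each contrast score is regressed on an intercept plus the
#' (mean-centred) between-subject covariates, and the condition effect is
#' the joint univariate test of the intercepts. Without covariates this is
#' the classic repeated-measures decomposition. Mauchly's W tests
#' sphericity of the contrast covariance; when its p-value is at or below
#' 0.05 the Greenhouse-Geisser epsilon-corrected p is adopted.
#'
#' @param values Numeric matrix, participants x conditions (complete cases).
#' @param covariates Optional data frame / matrix of between-subject
#'   covariates (one row per participant); factors are converted to
#'   numeric codes and all columns are mean-centred.
#' @return List of class `hop_anova`: `f_stat`, `df_num`, `df_den`,
#'   `mauchly_w`, `mauchly_p`, `gg_epsilon`, `p_uncorrected`, `p_gg`,
#'   `p_value` (the adopted one), `used_gg`, `covariates`.
#' @export
rm_anova <- function(values, covariates = NULL) {
  Y <- as.matrix(values)
  n <- nrow(Y); k <- ncol(Y)
  if (n < 3) stop("need at least 3 participants", call. = FALSE)
  if (k < 2) stop("need at least 2 conditions", call. = FALSE)
  if (any(!is.finite(Y))) {
    bad <- which(rowSums(!is.finite(Y)) > 0)
    stop("missing cells for participant row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  # orthonormal contrast basis (columns of C: k x (k-1), C'C = I, C'1 = 0)
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  Z <- Y %*% C
  q <- 0L
  X <- matrix(1, n, 1)
  cov_names <- character(0)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    cov_names <- names(cv)
    M <- vapply(cv, function(col) {
      col <- if (is.numeric(col)) col else as.numeric(as.factor(col))
      col - mean(col)
    }, numeric(n))
    X <- cbind(X, M)
    q <- ncol(M)
  }
  if (n - 1 - q < k - 1) stop("too few participants for the covariate model",
                              call. = FALSE)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Z)
  E <- Z - X %*% B
  df_err <- n - 1 - q
  ss_hyp <- sum(B[1, ]^2) / XtXi[1, 1]
  ss_err <- sum(E^2)
  df1 <- k - 1
  df2 <- df1 * df_err
  f_stat <- (ss_hyp / df1) / (ss_err / df2)
  p_unc <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)

  # sphericity of the contrast covariance
  S <- crossprod(E) / df_err
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  gg_eps <- if (k == 2) 1 else sum(lam)^2 / (df1 * sum(lam^2))
  gg_eps <- min(max(gg_eps, 1 / df1), 1)
  if (k == 2) {
    mauchly_w <- 1
    mauchly_p <- 1
  } else {
    mauchly_w <- prod(lam) / (sum(lam) / df1)^df1
    dcorr <- 1 - (2 * df1^2 + df1 + 2) / (6 * df1 * df_err)
    chi2 <- -df_err * dcorr * log(max(mauchly_w, .Machine$double.xmin))
    mauchly_p <- stats::pchisq(chi2, df1 * (df1 + 1) / 2 - 1,
                               lower.tail = FALSE)
  }
  p_gg <- stats::pf(f_stat, gg_eps * df1, gg_eps * df2, lower.tail = FALSE)
  used_gg <- mauchly_p <= 0.05
  structure(list(f_stat = f_stat, df_num = df1, df_den = df2,
                 mauchly_w = mauchly_w, mauchly_p = mauchly_p,
                 gg_epsilon = gg_eps, p_uncorrected = p_unc, p_gg = p_gg,
                 p_value = if (used_gg) p_gg else p_unc,
                 used_gg = used_gg, covariates = cov_names),
            class = "hop_anova")
}

#' Bonferroni-corrected paired post-hoc comparisons
#'
#' Paired t-test for every condition pair, with the p-value multiplied by
#' the number of pairs and capped at 1 (the convention under which
#' non-significant entries print as 1.000). Confidence intervals are the
#' unadjusted paired-t 95% intervals.
#'
#' @param values Participants x conditions matrix (matched rows).
#' @param pairs Optional list of 2-column index/name pairs; default all
#'   `choose(k, 2)` pairs in column order, differenced as
#'   `second - first`.
#' @return Data frame: `pair`, `mean_diff`, `ci95_low`, `ci95_high`,
#'   `p_raw`, `p_bonferroni`.
#' @export
posthoc_paired_bonferroni <- function(values, pairs = NULL) {
  Y <- as.matrix(values)
  if (nrow(Y) < 2) stop("need at least 2 matched observations", call. = FALSE)
  k <- ncol(Y)
  cn <- colnames(Y)
  if (is.null(cn)) cn <- paste0("cond", seq_len(k))
  if (is.null(pairs)) {
    pairs <- utils::combn(k, 2, simplify = FALSE)
  }
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    i <- if (is.character(pr)) match(pr, cn) else pr
    d <- Y[, i[2]] - Y[, i[1]]
    if (stats::sd(d) == 0) {
      md <- mean(d)
      data.frame(pair = paste(cn[i[2]], "-", cn[i[1]]),
                 mean_diff = md, ci95_low = md, ci95_high = md,
                 p_raw = 1, p_bonferroni = 1, stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(d)
      data.frame(pair = paste(cn[i[2]], "-", cn[i[1]]),
                 mean_diff = unname(tt$estimate),
                 ci95_low = tt$conf.int[1], ci95_high = tt$conf.int[2],
                 p_raw = tt$p.value,
                 p_bonferroni = min(1, tt$p.value * m),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Individual change scores (follow-up minus baseline)
#'
#' @param baseline,followup Numeric vectors named by participant, or data
#'   frames with columns `participant` and `value`. Participants must match
#'   one-to-one.
#' @return Data frame: `participant`, `delta`.
#' @export
change_scores <- function(baseline, followup) {
  to_named <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$value, x$participant)
    else if (!is.null(names(x))) x
    else stats::setNames(x, seq_along(x))
  }
  bl <- to_named(baseline)
  fu <- to_named(followup)
  unmatched <- c(setdiff(names(bl), names(fu)), setdiff(names(fu), names(bl)))
  if (length(unmatched)) {
    stop("unmatched participant(s): ", paste(unique(unmatched), collapse = ", "),
         call. = FALSE)
  }
  fu <- fu[names(bl)]
  data.frame(participant = names(bl), delta = unname(fu - bl),
             stringsAsFactors = FALSE)
}

#' Mann-Whitney U test for two independent groups
#'
#' Exact two-sided p by enumeration of the U distribution when the combined
#' sample size is at most 20 and there are no ties; otherwise the mid-rank
#' normal approximation without continuity correction (so identical groups
#' give p = 1 exactly).
#'
#' @param group_a,group_b Numeric vectors (each nonempty).
#' @param alpha Decision level (default 0.05).
#' @return List: `U` (for `group_a`), `p_value`, `method`, `significant`.
#' @export
mann_whitney_exact <- function(group_a, group_b, alpha = 0.05) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 1 || length(b) < 1) stop("each group must be nonempty",
                                           call. = FALSE)
  ties <- any(duplicated(c(a, b)))
  use_exact <- (length(a) + length(b) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                            correct = FALSE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (use_exact) "exact" else "normal approximation (mid-ranks)",
       significant = wt$p.value <= alpha)
}
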