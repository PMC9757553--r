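#' Analysis configuration
#'
#' Fixed constants of the processing and inference chain. The per-test
#' alpha is the family-wise level Bonferroni-divided across the planned
#' comparisons and rounded to 3 decimals: 0.05 over 3 comparisons gives
#' 0.017.
#'
#' @param stance_threshold_n Stance detection threshold (N), default 20.
#' @param debounce_s Sustained-crossing window for stance detection (s).
#' @param target_nodes Nodes of the normalised trajectories, default 1001.
#' @param alpha_family Family-wise alpha, default 0.05.
#' @param n_comparisons Comparisons sharing the family, default 3.
#' @param rfd_fallback_s RFD fallback duration for single-peak trials (s).
#' @param seed Seed recorded for provenance.
#' @return List of class `hop_config`, including the derived
#'   `alpha_per_test`.
#' @export
analysis_config <- function(stance_threshold_n = 20, debounce_s = 0.005,
                            target_nodes = 1001, alpha_family = 0.05,
                            n_comparisons = 3, rfd_fallback_s = 0.100,
                            seed = 20180628) {
  structure(list(stance_threshold_n = stance_threshold_n,
                 debounce_s = debounce_s,
                 target_nodes = target_nodes,
                 alpha_family = alpha_family,
                 n_comparisons = n_comparisons,
                 alpha_per_test = round(alpha_family / n_comparisons, 3),
                 rfd_fallback_s = rfd_fallback_s,
                 seed = seed),
            class = "hop_config")
}

# Stance-crop one raw trial, express forces in BW, bring the joint power
# onto the stance force time base, and detect the vertical-GRF peaks.
prepare_trial <- function(trial, config) {
  st <- detect_stance(trial, threshold_n = config$stance_threshold_n,
                      debounce_s = config$debounce_s)
  trial <- normalize_by_bw(trial)
  idx <- st$i_start:st$i_end
  t_st <- trial$t_force[idx]
  jp_kin <- compute_joint_power(trial$mx, trial$omega_x)
  channels <- list(fx_bw = trial$fx[idx], fy_bw = trial$fy[idx],
                   fz_bw = trial$fz[idx],
                   jp = interp_zero(trial$t_kin, jp_kin, t_st))
  peaks <- detect_fz_peaks(channels$fz_bw)
  list(channels = channels, peaks = peaks, stance = st,
       rate = st$rate, trial = trial)
}

#' Prepare a study: stance extraction, peak-aligned normalisation, averaging
#'
#' Runs the full preprocessing chain on every trial of a `hop_study`:
#' body-weight normalisation, 20 N stance cropping, joint-power derivation
#' on the kinematic base, dataset-wide peak-time anchors, three-phase
#' 1001-node warping, per-trial discrete variables, and the
#' participant/condition/session cell means of both.
#'
#' @param study A `hop_study` from the simulators or [read_study()].
#' @param config An [analysis_config()].
#' @return List of class `hop_prepared`: `cells` (one entry per cell with
#'   the averaged `hop_norm`, mean `discrete` vector and metadata),
#'   `cell_info` data frame, `anchors`, `config`.
#' @export
prepare_study <- function(study, config = analysis_config()) {
  stopifnot(inherits(study, "hop_study"))
  if (length(study$trials) == 0) stop("empty study: no trials", call. = FALSE)
  pts <- lapply(study$trials, prepare_trial, config = config)
  anchors <- fz_peak_anchors(lapply(pts, `[[`, "peaks"),
                             vapply(pts, function(p) length(p$channels$fz_bw),
                                    integer(1)))
  man <- study$manifest
  key <- paste(man$participant, man$condition, man$session, sep = "|")
  cells <- list()
  info <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    norms <- list()
    discs <- list()
    for (r in rows) {
      pt <- pts[[r]]
      norm <- piecewise_time_normalize(pt$channels, pt$peaks, anchors,
                                       target_nodes = config$target_nodes)
      rfd <- compute_rfd(pt$channels$fz_bw, pt$peaks$peak1, pt$rate,
                         single_peak = pt$peaks$single_peak,
                         fallback_s = config$rfd_fallback_s)
      norms[[length(norms) + 1L]] <- norm
      discs[[length(discs) + 1L]] <- extract_discrete_vars(norm, rfd)
    }
    avg <- suppressWarnings(average_trials(norms, discs))
    r1 <- rows[1]
    cells[[k]] <- list(norm = avg$norm, discrete = avg$discrete,
                       participant = man$participant[r1],
                       condition = man$condition[r1],
                       session = man$session[r1],
                       group = man$group[r1], sex = man$sex[r1],
                       months_post_surgery = man$months_post_surgery[r1],
                       n_trials = length(rows))
    info[[length(info) + 1L]] <- data.frame(
      participant = man$participant[r1], condition = man$condition[r1],
      session = man$session[r1], group = man$group[r1], sex = man$sex[r1],
      months_post_surgery = man$months_post_surgery[r1],
      n_trials = length(rows), stringsAsFactors = FALSE)
  }
  structure(list(cells = cells, cell_info = do.call(rbind, info),
                 anchors = anchors, config = config),
            class = "hop_prepared")
}

# Stack cell-mean trajectories into SPM inputs: participants x nodes matrix
# for one channel, or participants x nodes x 3 array for the GRF components.
cell_matrix <- function(prepared, participants, condition, session, channel) {
  t(vapply(participants, function(p) {
    prepared$cells[[paste(p, condition, session, sep = "|")]]$norm$channels[[channel]]
  }, numeric(prepared$config$target_nodes)))
}

cell_grf_array <- function(prepared, participants, condition, session) {
  comps <- c("fx_bw", "fy_bw", "fz_bw")
  out <- array(0, dim = c(length(participants), prepared$config$target_nodes, 3))
  for (j in 1:3) {
    out[, , j] <- cell_matrix(prepared, participants, condition, session,
                              comps[j])
  }
  out
}

cell_discrete <- function(prepared, participants, condition, session, var) {
  vapply(participants, function(p) {
    prepared$cells[[paste(p, condition, session, sep = "|")]]$discrete[[var]]
  }, numeric(1))
}

#' Part 1: cross-over analysis (immediate effects)
#'
#' For each of the three condition pairs, runs the paired Hotelling's
#' T-squared SPM on the three GRF components and the paired-t SPM on joint
#' power, both at the Bonferroni per-test alpha; then the discrete-variable
#' analysis (repeated-measures ANOVA with sex and months-post-surgery as
#' covariates, and Bonferroni-corrected paired post-hocs). Mean differences
#' follow the conventions: between sides, injured minus uninjured; between
#' conditions, sleeved minus unsleeved.
#'
#' @param study A `hop_study` with the three baseline conditions.
#' @param config An [analysis_config()].
#' @param prepared Optional pre-computed [prepare_study()] result.
#' @return List of class `hop_part1`: `spm_grf`, `spm_jp` (named by
#'   comparison), `discrete_table`, `anova`, `posthoc`, `participants`,
#'   `anchors`.
#' @export
run_part1 <- function(study, config = analysis_config(), prepared = NULL) {
  if (is.null(prepared)) prepared <- prepare_study(study, config)
  info <- prepared$cell_info
  conds <- unique(info$condition)
  if (length(conds) != 3) {
    stop("part 1 expects three conditions per participant", call. = FALSE)
  }
  keep <- character(0)
  for (p in unique(info$participant)) {
    have <- info$condition[info$participant == p]
    if (all(conds %in% have)) keep <- c(keep, p) else {
      message(sprintf("dropping participant %s: missing condition(s) %s",
                      p, paste(setdiff(conds, have), collapse = ", ")))
    }
  }
  if (length(keep) < 2) stop("not enough complete participants", call. = FALSE)
  A <- conds[1]; B <- conds[2]; C <- conds[3]
  cmp <- list(c(A, B), c(B, C), c(A, C))
  cmp_names <- vapply(cmp, function(x) paste(x[2], "vs", x[1]), character(1))
  alpha <- config$alpha_per_test
  spm_grf <- list(); spm_jp <- list()
  for (i in seq_along(cmp)) {
    a <- cell_grf_array(prepared, keep, cmp[[i]][2], "baseline")
    b <- cell_grf_array(prepared, keep, cmp[[i]][1], "baseline")
    spm_grf[[cmp_names[i]]] <- spm_test(a, b, stat = "T2", paired = TRUE,
                                        alpha = alpha)
    aj <- cell_matrix(prepared, keep, cmp[[i]][2], "baseline", "jp")
    bj <- cell_matrix(prepared, keep, cmp[[i]][1], "baseline", "jp")
    spm_jp[[cmp_names[i]]] <- spm_test(aj, bj, stat = "t", paired = TRUE,
                                       alpha = alpha)
  }
  covs <- data.frame(
    sex = vapply(keep, function(p)
      prepared$cells[[paste(p, A, "baseline", sep = "|")]]$sex, character(1)),
    months_post_surgery = vapply(keep, function(p)
      prepared$cells[[paste(p, A, "baseline", sep = "|")]]$months_post_surgery,
      numeric(1)))
  anova_list <- list(); posthoc_list <- list(); tab <- list()
  for (v in discrete_var_names()) {
    Y <- cbind(cell_discrete(prepared, keep, A, "baseline", v),
               cell_discrete(prepared, keep, B, "baseline", v),
               cell_discrete(prepared, keep, C, "baseline", v))
    colnames(Y) <- c(A, B, C)
    an <- rm_anova(Y, covariates = covs)
    an_nocov <- rm_anova(Y)
    ph <- posthoc_paired_bonferroni(Y, pairs = list(c(1, 2), c(2, 3), c(1, 3)))
    anova_list[[v]] <- list(with_covariates = an, without_covariates = an_nocov)
    posthoc_list[[v]] <- ph
    tab[[v]] <- data.frame(
      variable = v,
      mean_uninjured = mean(Y[, 1]), sd_uninjured = stats::sd(Y[, 1]),
      mean_injured = mean(Y[, 2]), sd_injured = stats::sd(Y[, 2]),
      mean_sleeved = mean(Y[, 3]), sd_sleeved = stats::sd(Y[, 3]),
      anova_p = an$p_value,
      side_diff = ph$mean_diff[1], side_ci_low = ph$ci95_low[1],
      side_ci_high = ph$ci95_high[1], side_p = ph$p_bonferroni[1],
      cond_diff = ph$mean_diff[2], cond_ci_low = ph$ci95_low[2],
      cond_ci_high = ph$ci95_high[2], cond_p = ph$p_bonferroni[2],
      cross_diff = ph$mean_diff[3], cross_ci_low = ph$ci95_low[3],
      cross_ci_high = ph$ci95_high[3], cross_p = ph$p_bonferroni[3],
      stringsAsFactors = FALSE)
  }
  structure(list(spm_grf = spm_grf, spm_jp = spm_jp,
                 discrete_table = do.call(rbind, tab),
                 anova = anova_list, posthoc = posthoc_list,
                 participants = keep, anchors = prepared$anchors,
                 config = config),
            class = "hop_part1")
}

#' Part 2: randomised-trial analysis (6-week effects)
#'
#' Builds follow-up-minus-baseline difference trajectories per participant,
#' compares them between groups with a two-sample Hotelling's T-squared SPM
#' (GRF components) and a two-sample t SPM (joint power), and compares
#' discrete-variable change scores between groups with exact Mann-Whitney U
#' tests at alpha 0.05.
#'
#' @param study A `hop_study` with sessions baseline and follow-up and two
#'   groups in the manifest.
#' @param config An [analysis_config()].
#' @param prepared Optional pre-computed [prepare_study()] result.
#' @return List of class `hop_part2`: `spm_grf`, `spm_jp`,
#'   `change_table`, `groups`, `participants`.
#' @export
run_part2 <- function(study, config = analysis_config(), prepared = NULL) {
  if (is.null(prepared)) prepared <- prepare_study(study, config)
  info <- prepared$cell_info
  if (!all(c("baseline", "follow-up") %in% info$session)) {
    stop("part 2 expects baseline and follow-up sessions", call. = FALSE)
  }
  cond <- unique(info$condition)[1]
  keep <- character(0)
  for (p in unique(info$participant)) {
    have <- info$session[info$participant == p]
    if (all(c("baseline", "follow-up") %in% have)) keep <- c(keep, p) else {
      message(sprintf("dropping participant %s: missing session", p))
    }
  }
  grp <- vapply(keep, function(p)
    prepared$cells[[paste(p, cond, "baseline", sep = "|")]]$group, character(1))
  groups <- sort(unique(grp))
  if (length(groups) != 2) stop("part 2 expects exactly two groups", call. = FALSE)
  ga <- keep[grp == groups[1]]; gb <- keep[grp == groups[2]]
  alpha <- config$alpha_per_test
  diff_grf <- function(ps) {
    cell_grf_array(prepared, ps, cond, "follow-up") -
      cell_grf_array(prepared, ps, cond, "baseline")
  }
  diff_jp <- function(ps) {
    cell_matrix(prepared, ps, cond, "follow-up", "jp") -
      cell_matrix(prepared, ps, cond, "baseline", "jp")
  }
  spm_grf <- spm_test(diff_grf(ga), diff_grf(gb), stat = "T2",
                      paired = FALSE, alpha = alpha)
  spm_jp <- spm_test(diff_jp(ga), diff_jp(gb), stat = "t",
                     paired = FALSE, alpha = alpha)
  tab <- list()
  for (v in discrete_var_names()) {
    d_by_group <- lapply(list(ga, gb), function(ps) {
      bl <- stats::setNames(cell_discrete(prepared, ps, cond, "baseline", v), ps)
      fu <- stats::setNames(cell_discrete(prepared, ps, cond, "follow-up", v), ps)
      change_scores(bl, fu)$delta
    })
    ci <- lapply(d_by_group, function(d) {
      n <- length(d)
      if (n < 2) return(c(mean(d), NA, NA))
      half <- stats::qt(0.975, n - 1) * stats::sd(d) / sqrt(n)
      c(mean(d), mean(d) - half, mean(d) + half)
    })
    mw <- mann_whitney_exact(d_by_group[[1]], d_by_group[[2]])
    tab[[v]] <- data.frame(
      variable = v,
      group_a = groups[1], mean_change_a = ci[[1]][1],
      ci_low_a = ci[[1]][2], ci_high_a = ci[[1]][3],
      group_b = groups[2], mean_change_b = ci[[2]][1],
      ci_low_b = ci[[2]][2], ci_high_b = ci[[2]][3],
      mw_u = mw$U, mw_p = mw$p_value, stringsAsFactors = FALSE)
  }
  structure(list(spm_grf = spm_grf, spm_jp = spm_jp,
                 change_table = do.call(rbind, tab),
                 groups = groups,
                 participants = list(keep = keep, group = grp),
                 config = config),
            class = "hop_part2")
}

MANIFEST_COLUMNS <- c("participant", "sex", "mass_kg", "height_m",
                      "months_post_surgery", "group", "condition", "session",
                      "trial")

#' Read and validate a study manifest CSV
#'
#' @param path Manifest file with one row per trial and the columns
#'   participant, sex, mass_kg, height_m, months_post_surgery, group,
#'   condition, session, trial (plus optional force_file / kin_file).
#' @return Validated data frame.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(man))
  if (length(missing_cols)) {
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("mass_kg", "height_m")) {
    bad <- which(!is.finite(man[[col]]) | man[[col]] <= 0)
    if (length(bad)) {
      stop(sprintf("manifest column '%s' invalid at row(s) %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  man
}

#' Write a study to disk as per-trial CSV files plus a manifest
#'
#' One force CSV (`time_s, fx_n, fy_n, fz_n`) and one kinematic CSV
#' (`time_s, mx_norm, omega_x_rad_s`) per trial; UTF-8, comma-separated,
#' dot decimal, header row.
#'
#' @param study A `hop_study`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "hop_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- study$manifest
  man$force_file <- sprintf("trial%04d_force.csv", seq_len(nrow(man)))
  man$kin_file <- sprintf("trial%04d_kin.csv", seq_len(nrow(man)))
  for (i in seq_len(nrow(man))) {
    tr <- study$trials[[i]]
    utils::write.csv(data.frame(time_s = tr$t_force, fx_n = tr$fx,
                                fy_n = tr$fy, fz_n = tr$fz),
                     file.path(dir, man$force_file[i]), row.names = FALSE)
    utils::write.csv(data.frame(time_s = tr$t_kin, mx_norm = tr$mx,
                                omega_x_rad_s = tr$omega_x),
                     file.path(dir, man$kin_file[i]), row.names = FALSE)
  }
  man$row <- NULL
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory containing `manifest.csv` and the per-trial files.
#' @return A `hop_study`.
#' @export
read_study <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.csv"))
  if (!all(c("force_file", "kin_file") %in% names(man))) {
    stop("manifest is missing column(s): force_file, kin_file", call. = FALSE)
  }
  trials <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- utils::read.csv(file.path(dir, man$force_file[i]))
    k <- utils::read.csv(file.path(dir, man$kin_file[i]))
    meta <- participant_meta(id = man$participant[i], sex = man$sex[i],
                             mass_kg = man$mass_kg[i],
                             height_m = man$height_m[i],
                             months_post_surgery = man$months_post_surgery[i],
                             group = man$group[i])
    trials[[i]] <- structure(list(t_force = f$time_s, fx = f$fx_n,
                                  fy = f$fy_n, fz = f$fz_n,
                                  t_kin = k$time_s, mx = k$mx_norm,
                                  omega_x = k$omega_x_rad_s,
                                  meta = meta, condition = man$condition[i],
                                  session = man$session[i],
                                  trial = man$trial[i]),
                             class = "hop_trial")
  }
  fs_force <- round(1 / mean(diff(trials[[1]]$t_force)))
  fs_kin <- round(1 / mean(diff(trials[[1]]$t_kin)))
  design <- study_design(n_participants = length(unique(man$participant)),
                         conditions = unique(man$condition),
                         sessions = unique(man$session),
                         trials_per_cell = max(man$trial),
                         fs_force_hz = fs_force, fs_kin_hz = fs_kin)
  man$force_file <- NULL; man$kin_file <- NULL
  new_hop_study(trials, man, design)
}

#' Write a report bundle to disk
#'
#' Flat CSV summaries: the discrete-variable table and one row per SPM
#' comparison (statistic, smoothness, threshold, cluster count, flag).
#'
#' @param bundle A `hop_part1` or `hop_part2` result.
#' @param dir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  spm_rows <- function(spms) {
    do.call(rbind, lapply(names(spms), function(nm) {
      s <- spms[[nm]]
      data.frame(comparison = nm, stat = s$stat_name,
                 df = paste(s$df, collapse = ","), fwhm = s$fwhm,
                 zstar = s$zstar, max_stat = max(abs(s$z)),
                 n_clusters = nrow(s$clusters),
                 significant = s$significant, stringsAsFactors = FALSE)
    }))
  }
  if (inherits(bundle, "hop_part1")) {
    p1 <- file.path(dir, "part1_discrete.csv")
    utils::write.csv(bundle$discrete_table, p1, row.names = FALSE)
    p2 <- file.path(dir, "part1_spm.csv")
    utils::write.csv(rbind(cbind(channel = "grf", spm_rows(bundle$spm_grf)),
                           cbind(channel = "jp", spm_rows(bundle$spm_jp))),
                     p2, row.names = FALSE)
    paths <- c(p1, p2)
  } else if (inherits(bundle, "hop_part2")) {
    p1 <- file.path(dir, "part2_changes.csv")
    utils::write.csv(bundle$change_table, p1, row.names = FALSE)
    p2 <- file.path(dir, "part2_spm.csv")
    utils::write.csv(spm_rows(list(grf = bundle$spm_grf,
                                   jp = bundle$spm_jp)),
                     p2, row.names = FALSE)
    paths <- c(p1, p2)
  } else stop("unknown bundle type", call. = FALSE)
  invisible(paths)
}
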