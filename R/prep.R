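#' Detect the stance phase from the vertical ground reaction force
#'
#' Stance onset is the first sample of the first sustained run where the
#' vertical force exceeds `threshold_n`; stance offset is the last
#' supra-threshold sample before the force returns below the threshold for a
#' sustained run. "Sustained" means at least `debounce_s` seconds
#' (default 5 ms), a robustness guard against noise spikes around the
#' crossing; set `debounce_s = 0` to disable.
#'
#' @param trial A `hop_trial` (raw Newtons or body-weight normalised).
#' @param threshold_n Force threshold in Newtons (default 20).
#' @param debounce_s Minimum sustained duration of a crossing, seconds.
#' @return A `hop_stance` list with 1-based force-sample indices `i_start`
#'   and `i_end` (first and last supra-threshold samples),
#'   `duration_s = (i_end - i_start) / rate`, and the number of candidate
#'   stance episodes found. If several disjoint episodes qualify, the
#'   longest is returned with a warning.
#' @export
detect_stance <- function(trial, threshold_n = 20, debounce_s = 0.005) {
  stopifnot(inherits(trial, "hop_trial"))
  rate <- 1 / mean(diff(trial$t_force))
  thr <- threshold_n
  if (isTRUE(trial$bw_units)) thr <- threshold_n / (trial$meta$mass_kg * GRAVITY)
  supra <- trial$fz > thr
  if (!any(supra)) stop("no stance detected", call. = FALSE)
  debounce_n <- max(1L, round(debounce_s * rate))
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  episodes <- list()
  cur_start <- NA_integer_
  cur_end <- NA_integer_
  for (j in seq_along(r$lengths)) {
    if (r$values[j]) {
      if (is.na(cur_start)) {
        if (r$lengths[j] >= debounce_n) cur_start <- starts[j]
      }
      if (!is.na(cur_start)) cur_end <- ends[j]
    } else if (!is.na(cur_start) && r$lengths[j] >= debounce_n) {
      episodes[[length(episodes) + 1L]] <- c(cur_start, cur_end)
      cur_start <- NA_integer_
    }
  }
  if (!is.na(cur_start)) episodes[[length(episodes) + 1L]] <- c(cur_start, cur_end)
  if (length(episodes) == 0) stop("no stance detected", call. = FALSE)
  lens <- vapply(episodes, function(e) e[2] - e[1], numeric(1))
  if (length(episodes) > 1) {
    warning(sprintf("%d disjoint supra-threshold episodes; taking the longest",
                    length(episodes)))
  }
  ep <- episodes[[which.max(lens)]]
  min_run <- 0.025 * rate
  if (ep[2] - ep[1] + 1 < min_run) stop("no stance detected", call. = FALSE)
  structure(list(i_start = ep[1], i_end = ep[2],
                 duration_s = (ep[2] - ep[1]) / rate,
                 n_episodes = length(episodes), rate = rate),
            class = "hop_stance")
}

#' Express the ground reaction forces in body-weight units
#'
#' Divides each force component by `mass_kg * 9.80665` N. The knee moment is
#' left unchanged (already normalised by body weight and height upstream).
#'
#' @param trial A `hop_trial` in Newtons.
#' @param meta A [participant_meta()]; defaults to the trial's own.
#' @return The trial with `fx`, `fy`, `fz` in BW units and `bw_units = TRUE`.
#' @export
normalize_by_bw <- function(trial, meta = trial$meta) {
  stopifnot(inherits(trial, "hop_trial"))
  if (!is.numeric(meta$mass_kg) || meta$mass_kg <= 0) {
    stop("parameter 'mass_kg' must be > 0", call. = FALSE)
  }
  if (isTRUE(trial$bw_units)) return(trial)
  bw <- meta$mass_kg * GRAVITY
  trial$fx <- trial$fx / bw
  trial$fy <- trial$fy / bw
  trial$fz <- trial$fz / bw
  trial$bw_units <- TRUE
  trial
}

# Topographic prominence of each local maximum: height above the higher of
# the two minima separating it from higher terrain (or the signal edge).
peak_prominences <- function(x, idx) {
  vapply(idx, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1)]
    higher_l <- which(left > h)
    lmin <- if (length(higher_l)) min(left[(max(higher_l)):(i - 1)]) else min(c(left, h))
    right <- x[(i + 1):length(x)]
    higher_r <- which(right > h)
    rmin <- if (length(higher_r)) min(right[1:(min(higher_r))]) else min(c(right, h))
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Locate the two vertical-GRF peaks of a stance phase
#'
#' Finds local maxima of the stance-cropped vertical force, ranks them by
#' topographic prominence, and returns the two most prominent ordered by
#' time. A trial is classified single-peak when the second-ranked maximum
#' has prominence below 10% of the global maximum value.
#'
#' @param stance_fz Stance-cropped vertical force trajectory.
#' @return List with 1-based indices `peak1`, `peak2` (`NA` when
#'   single-peak) and flag `single_peak`.
#' @export
detect_fz_peaks <- function(stance_fz) {
  x <- as.numeric(stance_fz)
  if (length(x) < 3 || max(x) - min(x) < .Machine$double.eps * 100) {
    stop("cannot detect peaks of a flat or too-short signal", call. = FALSE)
  }
  n <- length(x)
  i <- 2:(n - 1)
  is_max <- x[i] > x[i - 1] & x[i] >= x[i + 1]
  idx <- i[is_max]
  if (length(idx) == 0) stop("no local maxima found", call. = FALSE)
  prom <- peak_prominences(x, idx)
  ord <- order(prom, decreasing = TRUE)
  if (length(idx) == 1 || prom[ord[2]] < 0.10 * max(x)) {
    return(list(peak1 = idx[ord[1]], peak2 = NA_integer_, single_peak = TRUE))
  }
  two <- sort(idx[ord[1:2]])
  list(peak1 = two[1], peak2 = two[2], single_peak = FALSE)
}

#' Three-phase peak-aligned time normalisation to 1001 nodes
#'
#' Warps stance-cropped trajectories onto a common 1001-node grid in three
#' linearly resampled phases — onset to first vertical-GRF peak, first to
#' second peak, second peak to offset — so that the two peaks land on the
#' anchor nodes `round(1000 * anchor)` shared by the whole analysis set.
#' Every channel is warped with the same mapping. Single-peak trials are
#' uniformly resampled to 1001 nodes.
#'
#' @param channels Named list of equal-length stance-cropped trajectories on
#'   the force time base.
#' @param peaks Output of [detect_fz_peaks()] for this trial.
#' @param anchors Length-2 numeric, the analysis-set mean relative times of
#'   the first and second peaks; strictly ordered within (0, 1).
#' @param target_nodes Number of output nodes (default 1001).
#' @return A `hop_norm` list: warped `channels` (each `target_nodes` long),
#'   anchor node indices `n_peak1`, `n_peak2`, and `single_peak`.
#' @export
piecewise_time_normalize <- function(channels, peaks, anchors,
                                     target_nodes = 1001) {
  stopifnot(is.list(channels), length(channels) >= 1)
  L <- unique(vapply(channels, length, integer(1)))
  if (length(L) != 1) stop("all channels must have equal length", call. = FALSE)
  N <- target_nodes
  single <- isTRUE(peaks$single_peak)
  if (!single) {
    if (!(is.numeric(anchors) && length(anchors) == 2 &&
          anchors[1] > 0 && anchors[1] < anchors[2] && anchors[2] < 1)) {
      stop("anchors must be strictly ordered within (0, 1)", call. = FALSE)
    }
    n1 <- round((N - 1) * anchors[1])
    n2 <- round((N - 1) * anchors[2])
    p1 <- peaks$peak1
    p2 <- peaks$peak2
    if (!(p1 > 1 && p2 > p1 && L > p2)) {
      stop("peak indices must satisfy 1 < peak1 < peak2 < length", call. = FALSE)
    }
    pos <- c(1 + (p1 - 1) * (0:n1) / n1,
             p1 + (p2 - p1) * (1:(n2 - n1)) / (n2 - n1),
             p2 + (L - p2) * (1:(N - 1 - n2)) / (N - 1 - n2))
  } else {
    n1 <- NA_integer_
    n2 <- NA_integer_
    pos <- seq(1, L, length.out = N)
  }
  warped <- lapply(channels, function(ch) {
    stats::approx(seq_len(L), ch, xout = pos)$y
  })
  structure(list(channels = warped, n_peak1 = n1, n_peak2 = n2,
                 single_peak = single, target_nodes = N),
            class = "hop_norm")
}

#' Analysis-set peak-time anchors
#'
#' Mean relative stance times of the first and second vertical-GRF peaks over
#' all two-peak trials of the analysis set; these define the anchor nodes of
#' the three-phase normalisation.
#'
#' @param peak_list List of [detect_fz_peaks()] results.
#' @param len_list Integer vector of the corresponding stance lengths (in
#'   samples).
#' @return Length-2 numeric anchors.
#' @export
fz_peak_anchors <- function(peak_list, len_list) {
  keep <- !vapply(peak_list, function(p) isTRUE(p$single_peak), logical(1))
  if (!any(keep)) stop("no two-peak trials to anchor on", call. = FALSE)
  r1 <- mapply(function(p, L) (p$peak1 - 1) / (L - 1), peak_list[keep],
               len_list[keep])
  r2 <- mapply(function(p, L) (p$peak2 - 1) / (L - 1), peak_list[keep],
               len_list[keep])
  c(mean(r1), mean(r2))
}

#' Average the normalised trials of one participant/condition/session cell
#'
#' Node-wise mean of the warped trajectories; discrete variables are computed
#' per trial first and averaged here.
#'
#' @param norm_trials List of `hop_norm` objects (>= 1; a warning is issued
#'   below 3 trials).
#' @param discrete Optional list of per-trial discrete-variable vectors to
#'   average alongside.
#' @return List with the averaged `hop_norm` and, if supplied, the mean
#'   `discrete` vector.
#' @export
average_trials <- function(norm_trials, discrete = NULL) {
  if (length(norm_trials) == 0) stop("empty cell: no trials to average",
                                     call. = FALSE)
  if (length(norm_trials) < 3) {
    warning(sprintf("averaging only %d trial(s)", length(norm_trials)))
  }
  ch_names <- names(norm_trials[[1]]$channels)
  avg <- norm_trials[[1]]
  avg$channels <- lapply(ch_names, function(nm) {
    rowMeans(vapply(norm_trials, function(tr) tr$channels[[nm]],
                    numeric(avg$target_nodes)))
  })
  names(avg$channels) <- ch_names
  out <- list(norm = avg)
  if (!is.null(discrete)) {
    m <- do.call(rbind, lapply(discrete, unlist))
    out$discrete <- colMeans(m)
  }
  out
}
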