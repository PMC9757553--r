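# Base amplitudes of the joint-power bump pair; jp_ecc_scale / jp_con_scale
# multiply these, so scale 1 gives an eccentric peak of +28.8 and a
# concentric trough of -14.2 normalised power units.
JP_ECC_BASE <- 28.8
JP_CON_BASE <- 14.2

# Support floor of the vertical GRF: a mid-stance valley with a very steep
# rise at the stance edges, so the 20 N crossing sits within one sample of
# the nominal stance boundary and mid-stance noise cannot dip below it. The
# floor amplitude is a fixed fraction of the smaller vertical-GRF peak, so
# both peaks always rise above it whatever the participant's force level.
FZ_VALLEY_FRAC <- 0.45
FZ_BUMP_WIDTH <- 0.09

gauss_bump <- function(s, mu, w) exp(-((s - mu) / w)^2)

fz_valley <- function(s, v0) {
  v <- numeric(length(s))
  inside <- s > 0 & s < 1
  v[inside] <- v0 * sin(pi * s[inside])^0.25
  v
}

fz_valley_d <- function(s, v0) {
  d <- numeric(length(s))
  inside <- s > 0 & s < 1
  si <- s[inside]
  d[inside] <- v0 * 0.25 * sin(pi * si)^(-0.75) * pi * cos(pi * si)
  d
}

# Solve bump parameters (a1, m1, a2, m2) so that the vertical-GRF curve
# valley(s) + a1 G(s; m1) + a2 G(s; m2) attains local maxima of exactly
# (p1, p2) BW at relative times (t1, t2). Newton iteration with a numeric
# Jacobian; the valley slope shifts the bump centres slightly off (t1, t2).
.bump_cache <- new.env(parent = emptyenv())

solve_fz_bumps <- function(p1, t1, p2, t2, w = FZ_BUMP_WIDTH) {
  if (min(p1, p2) <= 0) {
    stop("vertical-GRF peak magnitudes must be > 0", call. = FALSE)
  }
  key <- paste(format(c(p1, t1, p2, t2, w), digits = 15), collapse = "|")
  hit <- .bump_cache[[key]]
  if (!is.null(hit)) return(hit)
  v0 <- FZ_VALLEY_FRAC * min(p1, p2)
  fz_val <- function(s, th) {
    fz_valley(s, v0) + th[1] * gauss_bump(s, th[2], w) + th[3] * gauss_bump(s, th[4], w)
  }
  fz_der <- function(s, th) {
    fz_valley_d(s, v0) +
      th[1] * gauss_bump(s, th[2], w) * (-2 * (s - th[2]) / w^2) +
      th[3] * gauss_bump(s, th[4], w) * (-2 * (s - th[4]) / w^2)
  }
  resid <- function(th) {
    c(fz_val(t1, th) - p1, fz_der(t1, th), fz_val(t2, th) - p2, fz_der(t2, th))
  }
  th <- c(max(p1 - fz_valley(t1, v0), 0.05), t1,
          max(p2 - fz_valley(t2, v0), 0.05), t2)
  for (iter in 1:50) {
    r <- resid(th)
    if (max(abs(r)) < 1e-12) break
    J <- matrix(0, 4, 4)
    for (j in 1:4) {
      h <- 1e-7 * max(1, abs(th[j]))
      thp <- th; thp[j] <- th[j] + h
      J[, j] <- (resid(thp) - r) / h
    }
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) break
    th <- th - step
  }
  if (max(abs(resid(th))) > 1e-6) {
    stop("vertical-GRF bump construction did not converge; ",
         "peak magnitudes may be too small relative to the support floor",
         call. = FALSE)
  }
  out <- list(a1 = th[1], m1 = th[2], a2 = th[3], m2 = th[4], w = w, v0 = v0)
  if (length(ls(.bump_cache)) > 4096) rm(list = ls(.bump_cache),
                                         envir = .bump_cache)
  .bump_cache[[key]] <- out
  out
}

# Noiseless channel values at relative stance times s. Forces have compact
# support on [0, 1]; the kinematic pair (and hence joint power) is defined
# continuously across the stance edges so that resampling the low-rate
# kinematic channels onto the force base does not ramp the early-stance
# power plateau through zero at onset.
waveform_channels <- function(s, spec, bumps) {
  inside <- s >= 0 & s <= 1
  si <- s[inside]
  zero <- numeric(length(s))
  fz <- zero
  fz[inside] <- fz_valley(si, bumps$v0) +
    bumps$a1 * gauss_bump(si, bumps$m1, bumps$w) +
    bumps$a2 * gauss_bump(si, bumps$m2, bumps$w)
  fy <- zero
  fy[inside] <- spec$fy_post_bw * gauss_bump(si, 0.20, 0.12) +
    spec$fy_ant_bw * gauss_bump(si, 0.75, 0.12)
  fx <- zero
  fx[inside] <- spec$fx_amp_bw * sin(2 * pi * si)
  jp <- jp_curve(s, spec)
  om <- omega_curve(pmin(pmax(s, 0), 1))
  mx <- jp / om
  list(fx = fx, fy = fy, fz = fz, mx = mx, omega_x = om, jp = jp)
}

# Early-stance plateau: exactly 1 over the first 5% of stance, then a smooth
# Gaussian decay, so an additive jp_early_offset shifts the first-5% mean
# power one-for-one.
jp_early_window <- function(s) ifelse(s <= 0.05, 1, exp(-((s - 0.05) / 0.05)^2))

jp_curve <- function(s, spec) {
  spec$jp_early_offset * jp_early_window(s) +
    spec$jp_ecc_scale * JP_ECC_BASE * gauss_bump(s, 0.30, 0.10) -
    spec$jp_con_scale * JP_CON_BASE * gauss_bump(s, 0.75, 0.10)
}

# Knee flexion-extension angular velocity (rad/s): strictly positive so the
# moment channel mx = jp / omega is well defined everywhere in stance.
omega_curve <- function(s) 2 + 6 * sin(pi * s)

#' Smooth Gaussian random fields
#'
#' White Gaussian noise convolved with a Gaussian kernel whose squared
#' weights sum to one, so the per-node standard deviation equals `sd` and the
#' field smoothness equals the kernel FWHM. This is both the generator's
#' waveform-noise model and the null-field generator used for random-field
#' calibration.
#'
#' @param n Number of fields (rows).
#' @param len Field length in nodes/samples.
#' @param fwhm Kernel full width at half maximum, in the same units as `len`.
#' @param sd Per-node standard deviation of the smoothed field.
#' @return `n x len` numeric matrix.
#' @export
smooth_gaussian_fields <- function(n, len, fwhm, sd = 1) {
  if (fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  sigma <- fwhm / sqrt(8 * log(2))
  hw <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-hw:hw)^2) / (2 * sigma^2))
  k <- k / sqrt(sum(k^2))
  klen <- length(k)
  out <- matrix(0, n, len)
  for (i in seq_len(n)) {
    white <- stats::rnorm(len + klen - 1, sd = sd)
    out[i, ] <- stats::convolve(white, rev(k), type = "filter")
  }
  out
}

# Trapezoidal taper confining waveform noise to stance with clean edges
# (full amplitude from 8% to 92% of stance, zero at the boundaries).
noise_taper <- function(s) pmax(0, pmin(1, s / 0.08, (1 - s) / 0.08))

#' Simulate one step-down-hop trial
#'
#' Builds a dual-rate analog record of a single hop: three GRF components in
#' Newtons sampled at the force rate, plus the knee flexion-extension moment
#' (normalised by body weight and height) and angular velocity at the
#' kinematic rate. The record has pre- and post-stance padding where the
#' vertical force is zero, and within stance the vertical force is a smooth
#' bimodal curve whose two local maxima hit the specified body-weight
#' magnitudes at the specified relative times (up to the added noise).
#'
#' The returned object carries a `truth` element with the generator's
#' ground-truth discrete variables, computed from the noiseless sampled
#' channels (peak magnitudes/times, RFD, force extrema, and joint-power
#' summaries on the canonical 1001-node grid).
#'
#' @param effect An [effect_spec()].
#' @param meta A [participant_meta()].
#' @param fs_force,fs_kin Sampling rates in Hz (force >= kinematic).
#' @param seed Integer seed; identical seeds give bitwise-identical records.
#' @param condition,session,trial Metadata labels stored on the record.
#' @return An object of class `hop_trial`.
#' @export
simulate_trial <- function(effect, meta, fs_force = 2400, fs_kin = 120,
                           seed = 1L, condition = "uninjured-unsleeved",
                           session = "baseline", trial = 1L) {
  stopifnot(inherits(effect, "hop_effect"), inherits(meta, "hop_meta"))
  check_finite_scalar(fs_force, "fs_force", positive = TRUE)
  check_finite_scalar(fs_kin, "fs_kin", positive = TRUE)
  dur <- effect$stance_dur_s
  pad <- 0.15
  bw_n <- meta$mass_kg * GRAVITY

  bumps <- solve_fz_bumps(effect$fz_peak1_bw, effect$peak1_time_frac,
                          effect$fz_peak2_bw, effect$peak2_time_frac)

  nf <- round((dur + 2 * pad) * fs_force)
  t_force <- (seq_len(nf) - 0.5) / fs_force - pad
  nk <- floor((dur + 2 * pad) * fs_kin)
  t_kin <- (seq_len(nk) - 0.5) / fs_kin - pad
  t_kin <- t_kin[t_kin <= max(t_force)]

  sf <- t_force / dur
  sk <- t_kin / dur
  chf <- waveform_channels(sf, effect, bumps)
  chk <- waveform_channels(sk, effect, bumps)

  fx <- chf$fx; fy <- chf$fy; fz <- chf$fz
  mx <- chk$mx; omega_x <- chk$omega_x

  if (effect$noise_sd > 0) {
    with_seed(seed, {
      inf <- sf >= 0 & sf <= 1
      ink <- sk >= 0 & sk <= 1
      n_in_f <- sum(inf)
      n_in_k <- sum(ink)
      # FWHM is specified on the 1001-node normalised-stance scale; convert
      # to samples of each rate.
      fwhm_f <- max(1, effect$noise_fwhm_nodes * n_in_f / 1000)
      fwhm_k <- max(1, effect$noise_fwhm_nodes * n_in_k / 1000)
      tap_f <- noise_taper(sf[inf])
      tap_k <- noise_taper(sk[ink])
      nz_f <- smooth_gaussian_fields(3, n_in_f, fwhm_f, sd = 1)
      fz[inf] <- fz[inf] + effect$noise_sd * tap_f * nz_f[1, ]
      fy[inf] <- fy[inf] + 0.3 * effect$noise_sd * tap_f * nz_f[2, ]
      fx[inf] <- fx[inf] + 0.3 * effect$noise_sd * tap_f * nz_f[3, ]
      nz_k <- smooth_gaussian_fields(2, n_in_k, fwhm_k, sd = 1)
      mx[ink] <- mx[ink] + 1.0 * effect$noise_sd * tap_k * nz_k[1, ]
      omega_x[ink] <- omega_x[ink] + 2.0 * effect$noise_sd * tap_k * nz_k[2, ]
    })
  }

  truth <- trial_truth(effect, bumps, chf, chk, sf, sk, fs_force)

  structure(list(t_force = t_force,
                 fx = fx * bw_n, fy = fy * bw_n, fz = fz * bw_n,
                 t_kin = t_kin, mx = mx, omega_x = omega_x,
                 meta = meta, condition = condition, session = session,
                 trial = as.integer(trial), effect = effect, truth = truth),
            class = "hop_trial")
}

# Ground-truth discrete variables of the noiseless sampled record. Forces are
# taken from the force-rate samples; joint power from the kinematic-rate
# samples interpolated onto the canonical 1001-node stance grid, mirroring
# the measurement chain the pipeline applies.
trial_truth <- function(effect, bumps, chf, chk, sf, sk, fs_force) {
  inf <- sf >= 0 & sf <= 1
  ink <- sk >= 0 & sk <= 1
  s_in <- sf[inf]
  fz_in <- chf$fz[inf]
  i1 <- which.min(abs(s_in - effect$peak1_time_frac))
  i2 <- which.min(abs(s_in - effect$peak2_time_frac))
  p1 <- fz_in[i1]; p2 <- fz_in[i2]
  t_peak1 <- effect$peak1_time_frac * effect$stance_dur_s
  nodes <- seq(0, 1, length.out = 1001)
  jp_nodes <- interp_zero(sk, chk$jp, nodes)
  list(stance_dur_s = effect$stance_dur_s,
       peak1_time_frac = effect$peak1_time_frac,
       peak2_time_frac = effect$peak2_time_frac,
       peak_fz1_bw = p1, peak_fz2_bw = p2,
       peak_fz_bw = max(fz_in),
       rfd = p1 / t_peak1,
       peak_fx_med = min(chf$fx[inf]), peak_fx_lat = max(chf$fx[inf]),
       peak_fy_post = min(chf$fy[inf]), peak_fy_ant = max(chf$fy[inf]),
       jp_mean_first5 = mean(jp_nodes[1:51]),
       jp_peak_ecc = max(jp_nodes), jp_peak_con = min(jp_nodes))
}

# Draw participant-level waveform parameters: lognormal multiplicative
# factors on magnitudes, additive spread on the early-stance power offset,
# jitter on peak times and stance duration. Shared across conditions and
# sessions of the same participant, so paired contrasts isolate the injected
# condition deltas.
draw_participant_factors <- function(between_subject_sd, jp_early_sd) {
  # One overall force level scales both vertical-GRF peaks (their ratio only
  # wobbles slightly), so a shift injected on the first peak stays the
  # global maximum for essentially every participant.
  list(force = stats::rlnorm(1, sdlog = between_subject_sd),
       fz_wobble = stats::rlnorm(2, sdlog = 0.05),
       mag = stats::rlnorm(3, sdlog = between_subject_sd),  # fy-, fy+, fx
       jp_scale = stats::rlnorm(2, sdlog = between_subject_sd),
       jp_early = stats::rnorm(1, sd = jp_early_sd),
       dt1 = stats::rnorm(1, sd = 0.010),
       dt2 = stats::rnorm(1, sd = 0.015),
       dur_fac = stats::rlnorm(1, sdlog = 0.06))
}

apply_participant_factors <- function(spec, fac) {
  out <- unclass(spec)
  out$fz_peak1_bw <- out$fz_peak1_bw * fac$force * fac$fz_wobble[1]
  out$fz_peak2_bw <- out$fz_peak2_bw * fac$force * fac$fz_wobble[2]
  out$fy_post_bw <- out$fy_post_bw * fac$mag[1]
  out$fy_ant_bw <- out$fy_ant_bw * fac$mag[2]
  out$fx_amp_bw <- out$fx_amp_bw * fac$mag[3]
  out$jp_ecc_scale <- out$jp_ecc_scale * fac$jp_scale[1]
  out$jp_con_scale <- out$jp_con_scale * fac$jp_scale[2]
  out$jp_early_offset <- out$jp_early_offset + fac$jp_early
  out$peak1_time_frac <- min(max(out$peak1_time_frac + fac$dt1, 0.08), 0.30)
  out$peak2_time_frac <- min(max(out$peak2_time_frac + fac$dt2, 0.55), 0.88)
  if (out$peak2_time_frac - out$peak1_time_frac < 0.2) {
    out$peak2_time_frac <- out$peak1_time_frac + 0.2
  }
  out$stance_dur_s <- out$stance_dur_s * fac$dur_fac
  do.call(effect_spec, out)
}

draw_meta <- function(id, group = "none") {
  sex <- if (stats::runif(1) < 16 / 30) "male" else "female"
  participant_meta(id = id, sex = sex,
                   mass_kg = max(45, stats::rnorm(1, 75.9, 11.3)),
                   height_m = max(1.4, stats::rnorm(1, 1.72, 0.10)),
                   months_post_surgery = max(6, round(stats::rlnorm(1, log(16), 0.5))),
                   group = group)
}

new_hop_study <- function(trials, manifest, design) {
  manifest$row <- seq_len(nrow(manifest))
  structure(list(trials = trials, manifest = manifest, design = design),
            class = "hop_study")
}

#' Simulate a cross-over cohort
#'
#' Every participant is measured under every condition (default: uninjured
#' side, injured side unsleeved, injured side sleeved) with
#' `design$trials_per_cell` trials per cell. Condition effects are injected
#' as additive deltas on the effect-specification fields and are shared
#' across participants, on top of participant-level between-subject
#' variability.
#'
#' @param design A [study_design()] with a single `"baseline"` session.
#' @param base An [effect_spec()] describing the reference (uninjured) side.
#' @param side_effects Named list mapping each condition label to a delta
#'   vector for [apply_effect_delta()]; defaults to
#'   [default_condition_effects()].
#' @param between_subject_sd Log-scale SD of the participant-level
#'   multiplicative factors on waveform magnitudes (default 0.30).
#' @param jp_early_sd Between-subject SD of the early-stance power offset
#'   (additive, default 3.0 normalised power units).
#' @param seed Integer seed; defaults to `design$seed`.
#' @return A `hop_study`: list of `hop_trial` objects plus a manifest
#'   data frame (participant, sex, mass_kg, height_m, months_post_surgery,
#'   group, condition, session, trial).
#' @export
simulate_crossover_study <- function(design = study_design(),
                                     base = effect_spec(),
                                     side_effects = default_condition_effects(),
                                     between_subject_sd = 0.30,
                                     jp_early_sd = 3.0,
                                     seed = design$seed) {
  stopifnot(inherits(design, "hop_design"))
  if (length(design$conditions) < 1) stop("conditions nonempty", call. = FALSE)
  missing_cond <- setdiff(design$conditions, names(side_effects))
  side_effects[missing_cond] <- list(c())
  trials <- list()
  rows <- list()
  with_seed(seed, {
    for (i in seq_len(design$n_participants)) {
      id <- sprintf("P%02d", i)
      meta <- draw_meta(id)
      fac <- draw_participant_factors(between_subject_sd, jp_early_sd)
      for (cond in design$conditions) {
        spec_c <- apply_effect_delta(base, side_effects[[cond]])
        spec_c <- apply_participant_factors(spec_c, fac)
        for (k in seq_len(design$trials_per_cell)) {
          tr_seed <- child_seed(seed, length(trials) + 1L)
          tr <- simulate_trial(spec_c, meta, design$fs_force_hz,
                               design$fs_kin_hz, seed = tr_seed,
                               condition = cond, session = "baseline",
                               trial = k)
          trials[[length(trials) + 1L]] <- tr
          rows[[length(rows) + 1L]] <- data.frame(
            participant = id, sex = meta$sex, mass_kg = meta$mass_kg,
            height_m = meta$height_m,
            months_post_surgery = meta$months_post_surgery,
            group = meta$group, condition = cond, session = "baseline",
            trial = k, stringsAsFactors = FALSE)
        }
      }
    }
  })
  new_hop_study(trials, do.call(rbind, rows), design)
}

#' Simulate a two-group randomised-trial cohort
#'
#' Two sessions (baseline and follow-up) of the injured side for two
#' parallel groups; follow-up trials embed group-specific deltas on top of
#' each participant's baseline parameters.
#'
#' @param design A [study_design()] with
#'   `sessions = c("baseline", "follow-up")`; `n_participants` is the total
#'   and is split evenly across groups (default 18, i.e. 9 per group).
#' @param base Baseline [effect_spec()] (default: uninjured spec shifted by
#'   the injured-unsleeved condition deltas, since the trial tracks injured
#'   sides).
#' @param group_followup_deltas Named list mapping group label to a
#'   follow-up delta vector; defaults to [default_group_effects()].
#' @param between_subject_sd,jp_early_sd As in [simulate_crossover_study()].
#' @param seed Integer seed.
#' @return A `hop_study`.
#' @export
simulate_rct_study <- function(design = study_design(n_participants = 18,
                                                     conditions = "injured",
                                                     sessions = c("baseline", "follow-up")),
                               base = apply_effect_delta(
                                 effect_spec(),
                                 default_condition_effects()[["injured-unsleeved"]]),
                               group_followup_deltas = default_group_effects(),
                               between_subject_sd = 0.30,
                               jp_early_sd = 3.0,
                               seed = design$seed) {
  stopifnot(inherits(design, "hop_design"))
  if (!setequal(design$sessions, c("baseline", "follow-up"))) {
    stop("design must have sessions {baseline, follow-up}", call. = FALSE)
  }
  groups <- names(group_followup_deltas)
  if (length(groups) != 2) stop("exactly two groups are required", call. = FALSE)
  n_per <- floor(design$n_participants / length(groups))
  if (n_per < 1) stop("each group must have at least one participant", call. = FALSE)
  assignment <- rep(groups, length.out = design$n_participants)
  trials <- list()
  rows <- list()
  with_seed(seed, {
    for (i in seq_len(design$n_participants)) {
      id <- sprintf("R%02d", i)
      grp <- assignment[i]
      meta <- draw_meta(id, group = grp)
      fac <- draw_participant_factors(between_subject_sd, jp_early_sd)
      spec_bl <- apply_participant_factors(base, fac)
      for (sess in c("baseline", "follow-up")) {
        spec_s <- if (sess == "baseline") spec_bl else
          apply_effect_delta(spec_bl, group_followup_deltas[[grp]])
        for (k in seq_len(design$trials_per_cell)) {
          tr_seed <- child_seed(seed, length(trials) + 1L)
          tr <- simulate_trial(spec_s, meta, design$fs_force_hz,
                               design$fs_kin_hz, seed = tr_seed,
                               condition = design$conditions[1],
                               session = sess, trial = k)
          trials[[length(trials) + 1L]] <- tr
          rows[[length(rows) + 1L]] <- data.frame(
            participant = id, sex = meta$sex, mass_kg = meta$mass_kg,
            height_m = meta$height_m,
            months_post_surgery = meta$months_post_surgery,
            group = grp, condition = design$conditions[1], session = sess,
            trial = k, stringsAsFactors = FALSE)
        }
      }
    }
  })
  new_hop_study(trials, do.call(rbind, rows), design)
}
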