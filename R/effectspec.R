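#' Waveform effect specification for a synthetic hop trial
#'
#' Parameterises the deterministic stance-phase waveforms of one simulated
#' step-down-hop trial: a bimodal vertical ground-reaction-force (GRF)
#' profile, posterior/anterior and medio-lateral GRF components, and a knee
#' moment / angular-velocity pair whose product (the knee joint power) has a
#' brief early phase of controllable sign, an eccentric peak and a concentric
#' propulsion trough.
#'
#' Default magnitudes emulate the uninjured-side group means of the
#' cross-over cohort this generator is calibrated to: first vertical peak
#' 2.38 BW, anterior GRF peak 0.27 BW, posterior peak -0.14 BW,
#' medio-lateral amplitude 0.08 BW, eccentric power peak 28.8 and
#' concentric trough -14.2 (normalised power units), early-stance power
#' offset +0.4.
#'
#' @param fz_peak1_bw,fz_peak2_bw First/second vertical-GRF peak magnitude in
#'   body-weight (BW) multiples.
#' @param peak1_time_frac,peak2_time_frac Relative stance times (0-1) of the
#'   two vertical-GRF peaks; must satisfy `0 < peak1 < peak2 < 1`.
#' @param stance_dur_s Stance duration in seconds.
#' @param fy_post_bw Posterior (negative) antero-posterior GRF peak (BW).
#' @param fy_ant_bw Anterior (positive) antero-posterior GRF peak (BW).
#' @param fx_amp_bw Medio-lateral GRF amplitude (BW); the lateral peak is
#'   `+fx_amp_bw`, the medial peak `-fx_amp_bw`.
#' @param jp_early_offset Additive shift of joint power over the first 5% of
#'   stance (normalised power units, positive = eccentric).
#' @param jp_ecc_scale,jp_con_scale Multiplicative scalings of the eccentric
#'   power peak (base 28.8) and the concentric trough (base -14.2).
#' @param noise_sd Per-node standard deviation of the smooth waveform noise
#'   added to the vertical GRF, in BW (other channels use fixed fractions of
#'   it; see [simulate_trial()]).
#' @param noise_fwhm_nodes Full width at half maximum of the noise smoothing
#'   kernel, expressed in 1001-node normalised-stance units.
#' @return An object of class `hop_effect` (a validated named list).
#' @export
effect_spec <- function(fz_peak1_bw = 2.38, fz_peak2_bw = 1.90,
                        peak1_time_frac = 0.15, peak2_time_frac = 0.70,
                        stance_dur_s = 0.45,
                        fy_post_bw = -0.14, fy_ant_bw = 0.27,
                        fx_amp_bw = 0.08,
                        jp_early_offset = 0.4,
                        jp_ecc_scale = 1.0, jp_con_scale = 1.0,
                        noise_sd = 0.05, noise_fwhm_nodes = 25) {
  spec <- list(fz_peak1_bw = fz_peak1_bw, fz_peak2_bw = fz_peak2_bw,
               peak1_time_frac = peak1_time_frac,
               peak2_time_frac = peak2_time_frac,
               stance_dur_s = stance_dur_s,
               fy_post_bw = fy_post_bw, fy_ant_bw = fy_ant_bw,
               fx_amp_bw = fx_amp_bw,
               jp_early_offset = jp_early_offset,
               jp_ecc_scale = jp_ecc_scale, jp_con_scale = jp_con_scale,
               noise_sd = noise_sd, noise_fwhm_nodes = noise_fwhm_nodes)
  for (nm in names(spec)) check_finite_scalar(spec[[nm]], nm)
  if (!(spec$peak1_time_frac > 0 && spec$peak1_time_frac < spec$peak2_time_frac &&
        spec$peak2_time_frac < 1)) {
    stop("peak times must satisfy 0 < peak1_time_frac < peak2_time_frac < 1",
         call. = FALSE)
  }
  check_finite_scalar(spec$stance_dur_s, "stance_dur_s", positive = TRUE)
  if (spec$noise_fwhm_nodes < 1) {
    stop("parameter 'noise_fwhm_nodes' must be >= 1", call. = FALSE)
  }
  if (spec$noise_sd < 0) stop("parameter 'noise_sd' must be >= 0", call. = FALSE)
  structure(spec, class = "hop_effect")
}

#' Apply additive deltas to an effect specification
#'
#' Deltas are added field-wise; for the multiplicative `jp_*_scale` fields the
#' delta is still additive on the scale itself (e.g. a delta of -0.281 turns a
#' scale of 1 into 0.719).
#'
#' @param spec A [effect_spec()] object.
#' @param deltas Named numeric vector/list of shifts on `hop_effect` fields.
#' @return A validated `hop_effect`.
#' @export
apply_effect_delta <- function(spec, deltas) {
  if (is.null(deltas) || length(deltas) == 0) return(spec)
  deltas <- unlist(deltas)
  bad <- setdiff(names(deltas), names(unclass(spec)))
  if (length(bad)) {
    stop("unknown effect fields in delta: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- unclass(spec)
  for (nm in names(deltas)) out[[nm]] <- out[[nm]] + deltas[[nm]]
  do.call(effect_spec, out)
}

#' Participant metadata
#'
#' @param id Participant label.
#' @param sex `"male"` or `"female"` (entered as a covariate downstream).
#' @param mass_kg Body mass in kg (> 0); used for body-weight normalisation.
#' @param height_m Stature in m (> 0).
#' @param months_post_surgery Integer months since ACL reconstruction (>= 0).
#' @param group Randomised group label (`"Sleeve"`, `"Control"`, or `"none"`
#'   for the cross-over part).
#' @return An object of class `hop_meta`.
#' @export
participant_meta <- function(id, sex = c("male", "female"),
                             mass_kg = 75.9, height_m = 1.72,
                             months_post_surgery = 16, group = "none") {
  sex <- match.arg(sex)
  check_finite_scalar(mass_kg, "mass_kg", positive = TRUE)
  check_finite_scalar(height_m, "height_m", positive = TRUE)
  check_finite_scalar(months_post_surgery, "months_post_surgery")
  if (months_post_surgery < 0) {
    stop("parameter 'months_post_surgery' must be >= 0", call. = FALSE)
  }
  structure(list(id = as.character(id), sex = sex, mass_kg = mass_kg,
                 height_m = height_m,
                 months_post_surgery = as.integer(months_post_surgery),
                 group = group),
            class = "hop_meta")
}

#' Study design for synthetic cohorts
#'
#' @param n_participants Number of participants (total across groups).
#' @param conditions Ordered condition labels tested within participant.
#' @param sessions `"baseline"` or `c("baseline", "follow-up")`.
#' @param trials_per_cell Trials per participant x condition x session cell
#'   (the analysis averages these; default 5).
#' @param fs_force_hz Force-plate sampling rate (default 2400 Hz).
#' @param fs_kin_hz Kinematic sampling rate (default 120 Hz).
#' @param seed Integer seed driving all randomness of the cohort.
#' @return An object of class `hop_design`.
#' @export
study_design <- function(n_participants = 30,
                         conditions = c("uninjured-unsleeved",
                                        "injured-unsleeved",
                                        "injured-sleeved"),
                         sessions = "baseline",
                         trials_per_cell = 5,
                         fs_force_hz = 2400, fs_kin_hz = 120,
                         seed = 20180628) {
  check_finite_scalar(n_participants, "n_participants", positive = TRUE)
  if (length(conditions) < 1) stop("conditions must be nonempty", call. = FALSE)
  if (!all(sessions %in% c("baseline", "follow-up"))) {
    stop("sessions must be a subset of {baseline, follow-up}", call. = FALSE)
  }
  check_finite_scalar(trials_per_cell, "trials_per_cell", positive = TRUE)
  if (trials_per_cell < 1) stop("trials_per_cell must be >= 1", call. = FALSE)
  check_finite_scalar(fs_force_hz, "fs_force_hz", positive = TRUE)
  check_finite_scalar(fs_kin_hz, "fs_kin_hz", positive = TRUE)
  if (fs_force_hz < fs_kin_hz) {
    stop("fs_force_hz must be >= fs_kin_hz", call. = FALSE)
  }
  structure(list(n_participants = as.integer(n_participants),
                 conditions = conditions, sessions = sessions,
                 trials_per_cell = as.integer(trials_per_cell),
                 fs_force_hz = fs_force_hz, fs_kin_hz = fs_kin_hz,
                 seed = as.integer(seed)),
            class = "hop_design")
}

#' Default condition deltas for the cross-over cohort
#'
#' Shifts of the injured-unsleeved and injured-sleeved conditions relative to
#' the uninjured side, chosen so that the cohort-level discrete-variable means
#' emulate the cross-over group means (first-5% power 0.4 / -1.5 / -0.2,
#' eccentric peak 28.8 / 20.7 / 21.3, concentric trough -14.2 / -9.7 / -10.4,
#' peak Fz 2.38 / 2.30 / 2.25, anterior Fy 0.27 / 0.237 / 0.24).
#'
#' @return Named list mapping condition label to a delta vector for
#'   [apply_effect_delta()].
#' @export
default_condition_effects <- function() {
  list(
    "uninjured-unsleeved" = c(),
    "injured-unsleeved" = c(jp_early_offset = -1.9,
                            jp_ecc_scale = 20.7 / 28.8 - 1,
                            jp_con_scale = 9.7 / 14.2 - 1,
                            fz_peak1_bw = -0.08,
                            fy_ant_bw = -0.033),
    "injured-sleeved" = c(jp_early_offset = -0.6,
                          jp_ecc_scale = 21.3 / 28.8 - 1,
                          jp_con_scale = 10.4 / 14.2 - 1,
                          fz_peak1_bw = -0.13,
                          fy_ant_bw = -0.03)
  )
}

#' Default 6-week follow-up deltas for the two randomised groups
#'
#' Emulates the directional findings of the parallel-group part: the Control
#' group's vertical-GRF peak decreases by 0.17 BW while its anterior GRF peak
#' increases by 0.07 BW; the Sleeve group's vertical peak increases by
#' 0.27 BW with a small anterior decrease.
#'
#' @return Named list mapping group to a delta vector.
#' @export
default_group_effects <- function() {
  list(Control = c(fz_peak1_bw = -0.17, fy_ant_bw = 0.07),
       Sleeve = c(fz_peak1_bw = 0.27, fy_ant_bw = -0.02))
}
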