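# Shared fixtures: small, fast parameterisations used across test files.
# Unit tests run at 1200 Hz force / 120 Hz kinematics (the 2400 Hz default
# is exercised implicitly through the same code path).

test_meta <- function(mass_kg = 75) {
  participant_meta("T01", "male", mass_kg = mass_kg, height_m = 1.75,
                   months_post_surgery = 16)
}

noiseless_spec <- function(...) effect_spec(noise_sd = 0, ...)

small_design <- function(n = 3, trials = 2, conditions = c("uninjured-unsleeved",
                                                           "injured-unsleeved",
                                                           "injured-sleeved")) {
  study_design(n_participants = n, conditions = conditions,
               trials_per_cell = trials, fs_force_hz = 1200, fs_kin_hz = 120)
}

# Prepare a single trial up to peak detection (mirrors the pipeline's
# internal chain, re-composed from the public operations).
prep_one <- function(trial, config = analysis_config()) {
  st <- detect_stance(trial, config$stance_threshold_n, config$debounce_s)
  trial <- normalize_by_bw(trial)
  idx <- st$i_start:st$i_end
  jp_kin <- compute_joint_power(trial$mx, trial$omega_x)
  channels <- list(fx_bw = trial$fx[idx], fy_bw = trial$fy[idx],
                   fz_bw = trial$fz[idx],
                   jp = approx(trial$t_kin, jp_kin,
                               xout = trial$t_force[idx], rule = 2)$y)
  peaks <- detect_fz_peaks(channels$fz_bw)
  list(channels = channels, peaks = peaks, stance = st)
}

# Exhaustive Mann-Whitney oracle: enumerate all C(n, n_a) group labelings of
# the pooled data and derive the exact two-sided p the same way the
# large-sample convention defines it (doubled smaller tail, capped at 1).
mw_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) # U for first sample, no ties
  u_obs <- u_of(a, b)
  combos <- utils::combn(n, na)
  u_all <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mu <- na * (n - na) / 2
  p <- if (u_obs > mu) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  list(U = u_obs, p = min(1, p))
}
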