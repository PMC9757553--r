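#' Knee joint power from moment and angular velocity
#'
#' Node-wise product `JP = Mx * omega_x`. With a positive (external) flexion
#' moment and positive (flexing) angular velocity, positive joint power
#' indicates net eccentric muscle contraction and negative power a
#' concentric contraction.
#'
#' @param mx Knee flexion-extension moment trajectory (normalised by body
#'   weight and height).
#' @param omega_x Knee flexion-extension angular velocity (rad/s), same
#'   length and time base as `mx`.
#' @return Numeric joint-power trajectory.
#' @export
compute_joint_power <- function(mx, omega_x) {
  if (length(mx) != length(omega_x)) {
    stop("mx and omega_x must have equal length", call. = FALSE)
  }
  mx * omega_x
}

#' Rate of force development
#'
#' First vertical-GRF peak divided by the time from stance onset to that
#' peak. For single-peak trials a fixed duration of 100 ms is used instead.
#'
#' @param stance_fz_bw Stance-cropped vertical force in BW units (sample 1 =
#'   onset).
#' @param peak1 1-based index of the first peak within the stance, or `NA`
#'   for a single-peak trial.
#' @param rate Force sampling rate (samples/s).
#' @param single_peak Flag; when `TRUE` the global maximum and the 100 ms
#'   fallback duration are used.
#' @param fallback_s Fallback duration for single-peak trials (default 0.1).
#' @return RFD in BW/s.
#' @export
compute_rfd <- function(stance_fz_bw, peak1, rate, single_peak = FALSE,
                        fallback_s = 0.100) {
  if (single_peak || is.na(peak1)) {
    return(max(stance_fz_bw) / fallback_s)
  }
  if (peak1 <= 1) stop("degenerate peak timing", call. = FALSE)
  stance_fz_bw[peak1] / ((peak1 - 1) / rate)
}

#' The nine discrete outcome variables of one normalised trial
#'
#' Extrema are global over the stance (no phase restriction); the first-5%
#' power mean is the arithmetic mean of joint power over nodes 0-50 of the
#' 1001-node trajectory.
#'
#' @param norm A `hop_norm` with channels `fx_bw`, `fy_bw`, `fz_bw`, `jp`.
#' @param rfd Pre-computed rate of force development for this trial (RFD is
#'   a real-time quantity, so it is computed on the un-warped stance; see
#'   [compute_rfd()]).
#' @return Named numeric vector: `rfd`, `peak_fz`, `peak_fx_med`,
#'   `peak_fx_lat`, `peak_fy_post`, `peak_fy_ant`, `jp_mean_first5`,
#'   `jp_peak_ecc`, `jp_peak_con`.
#' @export
extract_discrete_vars <- function(norm, rfd = NA_real_) {
  stopifnot(inherits(norm, "hop_norm"))
  ch <- norm$channels
  needed <- c("fx_bw", "fy_bw", "fz_bw", "jp")
  if (!all(needed %in% names(ch))) {
    stop("normalised trial must carry channels: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  c(rfd = rfd,
    peak_fz = max(ch$fz_bw),
    peak_fx_med = min(ch$fx_bw),
    peak_fx_lat = max(ch$fx_bw),
    peak_fy_post = min(ch$fy_bw),
    peak_fy_ant = max(ch$fy_bw),
    jp_mean_first5 = mean(ch$jp[1:51]),
    jp_peak_ecc = max(ch$jp),
    jp_peak_con = min(ch$jp))
}

#' Names of the nine discrete outcome variables
#' @return Character vector in reporting order.
#' @export
discrete_var_names <- function() {
  c("rfd", "peak_fz", "peak_fx_med", "peak_fx_lat",
    "peak_fy_post", "peak_fy_ant",
    "jp_mean_first5", "jp_peak_ecc", "jp_peak_con")
}
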