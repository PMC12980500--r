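# Parametric median-beat model: each lead is a sum of Gaussian bumps, one per
# wave (P, Q, R, S, T), with timing governed by the PR and R-T intervals.

ECG_LEADS <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")
WAVE_IDS <- c("P", "Q", "R", "S", "T")

#' Baseline (sinus-rhythm) beat parameters
#'
#' Defines one median cardiac cycle as a sum of Gaussian wave components over
#' the 8 standard independent leads (I, II, V1-V6). Amplitudes are in
#' millivolts, timings in seconds. The P-wave center sits `pr_interval` before
#' the R apex and the T-wave center `rt_interval` after it; Q and S flank the
#' R wave at fixed relative offsets. These values are ordinary adult surface
#' ECG magnitudes, not fits to any particular dataset.
#'
#' @param r_center R-wave apex position in seconds from record start.
#' @param pr_interval P-to-R center spacing, seconds.
#' @param rt_interval R-to-T center spacing, seconds.
#' @return A `beat_params` list with components `waves` (per-wave amplitude
#'   vector over 8 leads, relative offset, Gaussian width), `r_center`,
#'   `pr_interval`, `rt_interval`.
#' @export
#' @examples
#' p <- baseline_beat_params()
#' names(p$waves)
baseline_beat_params <- function(r_center = 0.42, pr_interval = 0.16,
                                 rt_interval = 0.30) {
  amp <- function(...) stats::setNames(c(...), ECG_LEADS)
  waves <- list(
    P = list(amp = amp(0.08, 0.12, 0.06, 0.07, 0.08, 0.08, 0.07, 0.06),
             offset = NA_real_, width = 0.025),
    Q = list(amp = amp(-0.05, -0.08, 0.00, -0.02, -0.03, -0.06, -0.08, -0.06),
             offset = -0.024, width = 0.009),
    R = list(amp = amp(0.60, 0.90, 0.20, 0.45, 0.80, 1.30, 1.20, 0.90),
             offset = 0.0, width = 0.012),
    S = list(amp = amp(-0.10, -0.15, -0.90, -1.10, -0.70, -0.30, -0.15, -0.10),
             offset = 0.024, width = 0.011),
    T = list(amp = amp(0.15, 0.20, 0.06, 0.25, 0.35, 0.30, 0.25, 0.20),
             offset = NA_real_, width = 0.060)
  )
  structure(list(waves = waves, r_center = r_center,
                 pr_interval = pr_interval, rt_interval = rt_interval),
            class = "beat_params")
}

# Resolve absolute wave centers from intervals.
wave_centers <- function(params) {
  r <- params$r_center
  c(P = r - params$pr_interval,
    Q = r + params$waves$Q$offset,
    R = r,
    S = r + params$waves$S$offset,
    T = r + params$rt_interval)
}

#' Render the noiseless signal for a set of beat parameters
#'
#' @param params A `beat_params` object.
#' @param sampling_rate Hz.
#' @param duration Record length in seconds.
#' @return An 8 x L matrix in millivolts, rows named by lead.
#' @export
noiseless_signal <- function(params, sampling_rate = 500, duration = 1.2) {
  L <- round(duration * sampling_rate)
  t <- (seq_len(L) - 1) / sampling_rate
  centers <- wave_centers(params)
  sig <- matrix(0, nrow = length(ECG_LEADS), ncol = L,
                dimnames = list(ECG_LEADS, NULL))
  for (w in WAVE_IDS) {
    comp <- params$waves[[w]]
    bump <- exp(-(t - centers[[w]])^2 / (2 * comp$width^2))
    sig <- sig + outer(comp$amp, bump)
  }
  sig
}

# Per-patient latent offsets: shared across all of a patient's records.
sample_patient_latent <- function(amp_sd = 0.08, wave_amp_sd = 0.05,
                                  timing_sd = 0.008) {
  list(
    amp_scale = stats::rnorm(1, 1, amp_sd),
    wave_amp = stats::setNames(stats::rnorm(5, 1, wave_amp_sd), WAVE_IDS),
    pr_shift = stats::rnorm(1, 0, timing_sd),
    rt_shift = stats::rnorm(1, 0, timing_sd),
    r_shift = stats::rnorm(1, 0, timing_sd)
  )
}

apply_latent <- function(params, latent) {
  if (is.null(latent)) return(params)
  for (w in WAVE_IDS) {
    params$waves[[w]]$amp <- params$waves[[w]]$amp *
      latent$amp_scale * latent$wave_amp[[w]]
  }
  params$pr_interval <- max(0.08, params$pr_interval + latent$pr_shift)
  params$rt_interval <- max(0.12, params$rt_interval + latent$rt_shift)
  params$r_center <- params$r_center + latent$r_shift
  params
}
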