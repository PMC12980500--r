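# Diagnostic class specifications: each class is a named modifier of the
# baseline beat parameters. The discriminative region of a realized record is
# recovered by differencing its noiseless signal against the baseline beat
# rendered with the same patient latent, so the mask is exactly where the
# class modifiers changed the waveform.

#' Diagnostic class names
#'
#' The nine binary classification targets: sinus rhythm, atrial fibrillation,
#' sinus bradycardia, sinus tachycardia, first-degree AV block, right and left
#' bundle branch block, low QRS voltage, and left ventricular hypertrophy.
#'
#' @return Character vector of 9 canonical class identifiers.
#' @export
ecg_class_names <- function() {
  c("sinus_rhythm", "atrial_fibrillation", "sinus_bradycardia",
    "sinus_tachycardia", "first_degree_av_block", "right_bundle_branch_block",
    "left_bundle_branch_block", "low_qrs_voltage",
    "left_ventricular_hypertrophy")
}

qrs_scale <- function(p, f) {
  for (w in c("Q", "R", "S")) p$waves[[w]]$amp <- p$waves[[w]]$amp * f
  p
}

qrs_widen <- function(p, width_f = 2.2, offset_f = 2.0) {
  for (w in c("Q", "R", "S")) p$waves[[w]]$width <- p$waves[[w]]$width * width_f
  p$waves$Q$offset <- p$waves$Q$offset * offset_f
  p$waves$S$offset <- p$waves$S$offset * offset_f
  p
}

#' Build the nine diagnostic class specifications
#'
#' Each specification is a morphological proxy on a single median beat:
#' * first-degree AV block forces PR = 240 ms (> 200 ms);
#' * atrial fibrillation removes the P wave entirely;
#' * sinus bradycardia/tachycardia stretch/compress the R-T spacing (a
#'   single-beat stand-in for heart rate, since a median beat carries no
#'   rhythm strip);
#' * right/left bundle branch block widen the QRS beyond 120 ms, with lead V1
#'   polarity (tall R vs deep S) distinguishing right from left;
#' * low QRS voltage scales QRS amplitudes to below 0.5 mV;
#' * left ventricular hypertrophy scales QRS amplitudes up.
#'
#' @param baseline A `beat_params` object defining the sinus-rhythm beat.
#' @return Named list of 9 `ecg_class_spec` objects, each with fields `label`
#'   and `modify` (a function `beat_params -> beat_params`).
#' @export
#' @examples
#' specs <- make_class_specs(baseline_beat_params())
#' names(specs)
make_class_specs <- function(baseline = baseline_beat_params()) {
  if (!inherits(baseline, "beat_params") ||
      !all(WAVE_IDS %in% names(baseline$waves)) ||
      is.null(baseline$pr_interval)) {
    abort_config("baseline beat parameters must define P/Q/R/S/T components and a PR interval")
  }
  spec <- function(label, modify) {
    structure(list(label = label, modify = modify), class = "ecg_class_spec")
  }
  specs <- list(
    sinus_rhythm = spec("sinus_rhythm", identity),
    atrial_fibrillation = spec("atrial_fibrillation", function(p) {
      p$waves$P$amp[] <- 0
      p
    }),
    sinus_bradycardia = spec("sinus_bradycardia", function(p) {
      p$rt_interval <- p$rt_interval + 0.08
      p
    }),
    sinus_tachycardia = spec("sinus_tachycardia", function(p) {
      p$rt_interval <- p$rt_interval - 0.08
      p
    }),
    first_degree_av_block = spec("first_degree_av_block", function(p) {
      p$pr_interval <- 0.24
      p
    }),
    right_bundle_branch_block = spec("right_bundle_branch_block", function(p) {
      p <- qrs_widen(p)
      p$waves$R$amp[["V1"]] <- p$waves$R$amp[["V1"]] + 0.8  # tall R in V1
      p$waves$S$amp[["I"]] <- p$waves$S$amp[["I"]] * 2.5    # slurred lateral S
      p$waves$S$amp[["V6"]] <- p$waves$S$amp[["V6"]] * 2.5
      p
    }),
    left_bundle_branch_block = spec("left_bundle_branch_block", function(p) {
      p <- qrs_widen(p)
      p$waves$R$amp[["V1"]] <- 0.05                         # dominant S in V1
      p$waves$S$amp[["V1"]] <- p$waves$S$amp[["V1"]] * 1.5
      for (l in c("I", "V5", "V6")) p$waves$R$amp[[l]] <- p$waves$R$amp[[l]] * 1.4
      p
    }),
    low_qrs_voltage = spec("low_qrs_voltage", function(p) qrs_scale(p, 0.33)),
    left_ventricular_hypertrophy = spec("left_ventricular_hypertrophy",
                                        function(p) qrs_scale(p, 1.8))
  )
  specs[ecg_class_names()]
}

# Morphology used for records whose rhythm is none of the four labeled rhythm
# classes (ectopic atrial proxy: inverted P wave). Unlabeled; keeps the
# sinus-rhythm task well posed by making label-free records distinguishable
# from sinus rhythm.
other_rhythm_spec <- function() {
  structure(list(label = "other_atrial_rhythm",
                 modify = function(p) { p$waves$P$amp <- p$waves$P$amp * -0.8; p }),
            class = "ecg_class_spec")
}

#' Label compatibility matrix
#'
#' Which pairs of diagnostic labels may co-occur on one record. Mutually
#' exclusive groups: the rhythm classes (sinus rhythm, AF, sinus brady/tachy),
#' right vs left bundle branch block, and low QRS voltage vs LVH. Atrial
#' fibrillation additionally excludes first-degree AV block (no P wave, no PR
#' interval).
#'
#' @return A 9 x 9 logical matrix, TRUE where the pair is compatible.
#' @export
class_compatibility <- function() {
  cls <- ecg_class_names()
  m <- matrix(TRUE, 9, 9, dimnames = list(cls, cls))
  excl <- function(a, b) { m[a, b] <<- FALSE; m[b, a] <<- FALSE }
  rhythm <- cls[1:4]
  for (i in 1:3) for (j in (i + 1):4) excl(rhythm[i], rhythm[j])
  excl("atrial_fibrillation", "first_degree_av_block")
  excl("right_bundle_branch_block", "left_bundle_branch_block")
  excl("low_qrs_voltage", "left_ventricular_hypertrophy")
  diag(m) <- TRUE
  m
}
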