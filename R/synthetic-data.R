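# Synthetic dataset generation: patient-grouped, multi-label median-beat
# records with ground-truth relevance masks.

#' Default class prevalences
#'
#' Training-set label prevalences emulated by the generator (fractions of
#' records carrying each label). They are marginal prevalences of a
#' multi-label scheme and do not sum to one.
#'
#' @return Named numeric vector over the 9 classes.
#' @export
default_prevalences <- function() {
  stats::setNames(
    c(0.629, 0.062, 0.108, 0.072, 0.061, 0.083, 0.042, 0.036, 0.071),
    ecg_class_names())
}

new_ecg_record <- function(patient_id, record_id, signal, sampling_rate,
                           labels, relevance_mask = NULL) {
  structure(list(patient_id = patient_id, record_id = record_id,
                 signal = signal, sampling_rate = sampling_rate,
                 labels = labels, relevance_mask = relevance_mask),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s / %s: %d leads x %d samples @ %g Hz; labels: %s>\n",
              x$patient_id, x$record_id, nrow(x$signal), ncol(x$signal),
              x$sampling_rate,
              paste(names(x$labels)[x$labels == 1], collapse = ", ")))
  invisible(x)
}

#' Sample one synthetic median-beat record
#'
#' Renders the noiseless Gaussian-bump beat for the given class
#' specification(s) (applied cumulatively to the baseline), adds white
#' Gaussian measurement noise, and computes the ground-truth relevance mask as
#' the set of points where the class modifiers changed the noiseless signal
#' relative to the baseline beat rendered with the same patient latent.
#'
#' @param spec One `ecg_class_spec` or a list of compatible specs.
#' @param patient_latent Per-patient parameter offsets from
#'   `sample_patient_latent()`, or NULL.
#' @param noise_sd Additive Gaussian noise SD in millivolts (>= 0).
#' @param rng_seed Integer seed; identical (spec, latent, seed) give a
#'   bit-identical record.
#' @param baseline Baseline `beat_params`.
#' @param sampling_rate Hz. @param duration Record length, seconds.
#' @param patient_id,record_id Identifiers stored on the record.
#' @param mask_tol Millivolt threshold defining the relevance mask.
#' @return An `ecg_record`.
#' @export
#' @examples
#' specs <- make_class_specs()
#' r <- sample_record(specs$atrial_fibrillation, noise_sd = 0, rng_seed = 1)
#' max(abs(r$signal))
sample_record <- function(spec, patient_latent = NULL, noise_sd = 0.03,
                          rng_seed = 1L, baseline = baseline_beat_params(),
                          sampling_rate = 500, duration = 1.2,
                          patient_id = "p1", record_id = "r1",
                          mask_tol = 0.01) {
  stopifnot(noise_sd >= 0)
  specs <- if (inherits(spec, "ecg_class_spec")) list(spec) else spec
  params <- apply_latent(baseline, patient_latent)
  base_params <- params
  for (s in specs) params <- s$modify(params)
  clean <- noiseless_signal(params, sampling_rate, duration)
  base_clean <- noiseless_signal(base_params, sampling_rate, duration)
  mask <- (abs(clean - base_clean) > mask_tol) * 1L
  signal <- withr::with_seed(rng_seed, {
    clean + matrix(stats::rnorm(length(clean), 0, noise_sd),
                   nrow(clean), ncol(clean))
  })
  dimnames(signal) <- dimnames(clean)
  labels <- stats::setNames(integer(9), ecg_class_names())
  for (s in specs) if (s$label %in% names(labels)) labels[s$label] <- 1L
  new_ecg_record(patient_id, record_id, signal, sampling_rate, labels, mask)
}

# Draw one label vector with exact marginal prevalences under the
# compatibility rules. Returns list(labels, spec_labels) where spec_labels is
# the ordered set of morphology modifiers to apply (may include the unlabeled
# other-rhythm proxy).
draw_labels <- function(prev) {
  cls <- ecg_class_names()
  p_rhythm <- prev[cls[1:4]]
  if (sum(p_rhythm) > 1) abort_config("rhythm-class prevalences sum above 1")
  rhythm <- sample(c(cls[1:4], "other_atrial_rhythm"), 1,
                   prob = c(p_rhythm, 1 - sum(p_rhythm)))
  spec_labels <- rhythm
  labels <- stats::setNames(integer(9), cls)
  if (rhythm %in% cls) labels[rhythm] <- 1L
  # AV block requires a (present, upright or inverted) P wave: excluded under
  # AF; conditional probability inflated to keep the marginal exact.
  p_avb <- prev[["first_degree_av_block"]] / (1 - prev[["atrial_fibrillation"]])
  if (p_avb > 1) abort_config("AV-block prevalence incompatible with AF prevalence")
  if (rhythm != "atrial_fibrillation" && stats::runif(1) < p_avb) {
    labels["first_degree_av_block"] <- 1L
    spec_labels <- c(spec_labels, "first_degree_av_block")
  }
  bbb <- sample(c("right_bundle_branch_block", "left_bundle_branch_block", "none"),
                1, prob = c(prev[["right_bundle_branch_block"]],
                            prev[["left_bundle_branch_block"]],
                            1 - prev[["right_bundle_branch_block"]] -
                              prev[["left_bundle_branch_block"]]))
  if (bbb != "none") { labels[bbb] <- 1L; spec_labels <- c(spec_labels, bbb) }
  volt <- sample(c("low_qrs_voltage", "left_ventricular_hypertrophy", "none"),
                 1, prob = c(prev[["low_qrs_voltage"]],
                             prev[["left_ventricular_hypertrophy"]],
                             1 - prev[["low_qrs_voltage"]] -
                               prev[["left_ventricular_hypertrophy"]]))
  if (volt != "none") { labels[volt] <- 1L; spec_labels <- c(spec_labels, volt) }
  list(labels = labels, spec_labels = spec_labels)
}

#' Generate a patient-grouped synthetic dataset
#'
#' Per-patient record counts follow a shifted Poisson, `1 + Poisson(mean - 1)`
#' (strictly positive with the stated mean). Each patient draws one latent
#' offset vector shared by all their records; each record draws a label set
#' whose per-class marginals equal `prevalences` exactly under the
#' compatibility rules of [class_compatibility()].
#'
#' @param n_patients Number of patients (>= 1).
#' @param mean_records_per_patient Mean records per patient (>= 1).
#' @param prevalences Named 9-vector of label prevalences in `[0, 1]`.
#' @param noise_sd Millivolt noise SD.
#' @param seed Integer seed; the dataset is a pure function of the arguments.
#' @param sampling_rate,record_length_s Signal geometry.
#' @param baseline Baseline `beat_params`.
#' @return An `ecg_dataset`: list with `records`, `manifest` (tibble with
#'   patient_id, record_id and one 0/1 column per class), `class_prevalences`,
#'   `generator_seed`, `sampling_rate`, `record_length_s`.
#' @export
#' @examples
#' ds <- generate_dataset(n_patients = 5, seed = 1)
#' nrow(ds$manifest)
generate_dataset <- function(n_patients, mean_records_per_patient = 4.5,
                             prevalences = default_prevalences(),
                             noise_sd = 0.03, seed = 1L,
                             sampling_rate = 500, record_length_s = 1.2,
                             baseline = baseline_beat_params()) {
  if (n_patients < 1) abort_config("n_patients must be >= 1")
  if (mean_records_per_patient < 1) abort_config("mean_records_per_patient must be >= 1")
  if (any(prevalences < 0 | prevalences > 1)) abort_config("prevalences must lie in [0, 1]")
  if (all(prevalences == 0)) abort_config("all-zero prevalences")
  prevalences <- prevalences[ecg_class_names()]
  if (anyNA(prevalences)) abort_config("prevalences must be named by the 9 class names")
  specs <- make_class_specs(baseline)
  specs$other_atrial_rhythm <- other_rhythm_spec()
  records <- vector("list", 0)
  rows <- vector("list", 0)
  withr::with_seed(derive_seed(seed, "generate_dataset"), {
    rec_i <- 0L
    for (pi in seq_len(n_patients)) {
      pid <- sprintf("pt%05d", pi)
      latent <- sample_patient_latent()
      n_rec <- 1L + stats::rpois(1, mean_records_per_patient - 1)
      for (ri in seq_len(n_rec)) {
        rec_i <- rec_i + 1L
        rid <- sprintf("rec%06d", rec_i)
        lab <- draw_labels(prevalences)
        rec_seed <- sample.int(2147483646L, 1)
        rec <- sample_record(specs[lab$spec_labels], latent, noise_sd,
                             rec_seed, baseline, sampling_rate,
                             record_length_s, pid, rid)
        records[[rec_i]] <- rec
        rows[[rec_i]] <- tibble::tibble(patient_id = pid, record_id = rid,
                                        !!!as.list(lab$labels))
      }
    }
  })
  manifest <- dplyr::bind_rows(rows)
  structure(list(records = records, manifest = manifest,
                 class_prevalences = prevalences, generator_seed = seed,
                 sampling_rate = sampling_rate,
                 record_length_s = record_length_s),
            class = "ecg_dataset")
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat(sprintf("<ecg_dataset: %d records, %d patients, 8 x %d samples @ %g Hz>\n",
              length(x$records), dplyr::n_distinct(x$manifest$patient_id),
              round(x$record_length_s * x$sampling_rate), x$sampling_rate))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.ecg_dataset <- function(x, ...) x$manifest

#' Patient index of a dataset
#' @param ds An `ecg_dataset`.
#' @return Named list mapping patient_id to the patient's record_ids.
#' @export
patient_index <- function(ds) {
  split(ds$manifest$record_id, ds$manifest$patient_id)
}

subset_dataset <- function(ds, keep) {
  ds$records <- ds$records[keep]
  ds$manifest <- ds$manifest[keep, , drop = FALSE]
  ds
}

#' Split a dataset at the patient level
#'
#' Validation and test patients are sampled without replacement; all records
#' of a patient stay in one split, so the three patient-id sets are pairwise
#' disjoint and the record sets partition the input.
#'
#' @param ds An `ecg_dataset`.
#' @param n_val_patients,n_test_patients Patient counts for the two held-out
#'   splits; their sum must be below the total patient count.
#' @param seed Integer seed.
#' @return Named list of three `ecg_dataset`s: train, validation, test.
#' @export
split_by_patient <- function(ds, n_val_patients, n_test_patients, seed = 1L) {
  pats <- unique(ds$manifest$patient_id)
  if (n_val_patients + n_test_patients >= length(pats)) {
    stop("too few patients for the requested validation/test sizes")
  }
  held <- withr::with_seed(derive_seed(seed, "split_by_patient"),
                           sample(pats, n_val_patients + n_test_patients))
  val_p <- held[seq_len(n_val_patients)]
  test_p <- setdiff(held, val_p)
  pid <- ds$manifest$patient_id
  list(train = subset_dataset(ds, !(pid %in% held)),
       validation = subset_dataset(ds, pid %in% val_p),
       test = subset_dataset(ds, pid %in% test_p))
}

#' Extract the label vector of a dataset for one class
#' @param ds An `ecg_dataset`. @param class_name One of [ecg_class_names()].
#' @return Integer 0/1 vector over records.
#' @export
dataset_labels <- function(ds, class_name) {
  if (!class_name %in% ecg_class_names()) abort_config(
    sprintf("unknown class '%s'", class_name))
  as.integer(ds$manifest[[class_name]])
}

# Stack dataset signals into an array [8, L, N].
dataset_signals <- function(ds) {
  sigs <- lapply(ds$records, `[[`, "signal")
  arr <- array(unlist(sigs, use.names = FALSE),
               dim = c(dim(sigs[[1]]), length(sigs)))
  arr
}
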