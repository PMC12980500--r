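# Synthetic median-beat generator: class specifications, record sampling,
# dataset composition, and patient-level splitting.

test_that("class specifications plant the stated morphological features", {
  base <- baseline_beat_params()
  specs <- make_class_specs(base)
  expect_named(specs, ecg_class_names())
  expect_length(specs, 9)

  # AV block forces PR above 200 ms for every realized beat
  for (rep in 1:5) {
    lat <- withr::with_seed(rep, ecgxai:::sample_patient_latent())
    p <- specs$first_degree_av_block$modify(ecgxai:::apply_latent(base, lat))
    expect_gt(p$pr_interval, 0.2)
  }
  # AF removes the P component in all leads
  paf <- specs$atrial_fibrillation$modify(base)
  expect_true(all(paf$waves$P$amp == 0))
  # low QRS voltage scales all QRS amplitudes below 0.5 mV
  plo <- specs$low_qrs_voltage$modify(base)
  for (w in c("Q", "R", "S")) expect_lt(max(abs(plo$waves[[w]]$amp)), 0.5)
  # LVH scales QRS up
  plvh <- specs$left_ventricular_hypertrophy$modify(base)
  expect_true(all(abs(plvh$waves$R$amp) > abs(base$waves$R$amp)))
  # bundle branch blocks widen the QRS beyond 120 ms (4 SD span of widened
  # R flanked by shifted Q/S offsets) and differ in V1 polarity
  prb <- specs$right_bundle_branch_block$modify(base)
  plb <- specs$left_bundle_branch_block$modify(base)
  qrs_span <- function(p) (p$waves$S$offset - p$waves$Q$offset) +
    2 * (p$waves$Q$width + p$waves$S$width)
  expect_gt(qrs_span(prb), 0.12)
  expect_gt(qrs_span(plb), 0.12)
  expect_gt(prb$waves$R$amp[["V1"]] + prb$waves$S$amp[["V1"]], 0)
  expect_lt(plb$waves$R$amp[["V1"]] + plb$waves$S$amp[["V1"]], 0)
  # every non-baseline spec changes the noiseless waveform
  ref <- noiseless_signal(base)
  for (nm in setdiff(names(specs), "sinus_rhythm")) {
    expect_gt(max(abs(noiseless_signal(specs[[nm]]$modify(base)) - ref)), 0.01,
              label = nm)
  }
  expect_error(make_class_specs(list()), "P/Q/R/S/T")
})

test_that("noiseless records are exact Gaussian-bump sums with correct masks", {
  specs <- make_class_specs()
  r <- sample_record(specs$atrial_fibrillation, noise_sd = 0, rng_seed = 3)
  # closed form: sum of Q,R,S,T bumps only (no P)
  p <- specs$atrial_fibrillation$modify(baseline_beat_params())
  expect_equal(r$signal, noiseless_signal(p), tolerance = 1e-12)
  # the P bump is absent: signal in the P window is flat
  expect_lt(max(abs(r$signal[, 100:140])), 0.02)
  # mask covers the (removed) P-wave window and nothing near T
  expect_true(any(r$relevance_mask[, 110:150] == 1))
  expect_true(all(r$relevance_mask[, 320:400] == 0))
})

test_that("record sampling is bit-deterministic and has the stated noise power", {
  specs <- make_class_specs()
  lat <- withr::with_seed(2, ecgxai:::sample_patient_latent())
  a <- sample_record(specs$sinus_rhythm, lat, noise_sd = 0.05, rng_seed = 77)
  b <- sample_record(specs$sinus_rhythm, lat, noise_sd = 0.05, rng_seed = 77)
  expect_identical(a$signal, b$signal)
  clean <- sample_record(specs$sinus_rhythm, lat, noise_sd = 0, rng_seed = 77)
  resid <- a$signal - clean$signal
  # Monte-Carlo variance over 4800 points; SE of var ~ sigma^2 sqrt(2/n)
  expect_lt(abs(stats::var(as.vector(resid)) - 0.0025),
            4 * 0.0025 * sqrt(2 / length(resid)))
})

test_that("relevance masks sit where class modifiers changed the signal", {
  ds <- generate_dataset(n_patients = 15, seed = 33)
  base <- baseline_beat_params()
  cls <- ecg_class_names()
  n_checked <- 0
  for (r in ds$records) {
    # sinus rhythm IS the baseline: only records with a non-baseline label
    # must carry a non-empty mask
    if (sum(r$labels) == 0 ||
        (r$labels[["sinus_rhythm"]] == 1 && sum(r$labels) == 1)) next
    n_checked <- n_checked + 1
    expect_gt(sum(r$relevance_mask), 0)
  }
  expect_gt(n_checked, 5)
})

test_that("dataset composition matches the configured prevalences and grouping", {
  ds <- generate_dataset(n_patients = 250, seed = 5)
  expect_length(patient_index(ds), 250)
  expect_false(any(duplicated(ds$manifest$record_id)))
  # identical seed regenerates bit-identical data
  ds2 <- generate_dataset(n_patients = 250, seed = 5)
  expect_identical(ds$records[[17]]$signal, ds2$records[[17]]$signal)
  expect_identical(ds$manifest, ds2$manifest)
  # no record violates the compatibility rules
  compat <- class_compatibility()
  labs <- as.matrix(ds$manifest[, ecg_class_names()])
  for (i in seq_len(nrow(labs))) {
    on <- which(labs[i, ] == 1)
    if (length(on) > 1) {
      pairs <- utils::combn(on, 2)
      for (j in seq_len(ncol(pairs))) {
        expect_true(compat[pairs[1, j], pairs[2, j]])
      }
    }
  }
})

test_that("label marginals and records-per-patient hit their targets at scale", {
  # short records: this checks the label/count machinery, signal length is
  # irrelevant here and short beats keep the test fast
  ds <- generate_dataset(n_patients = 2500, mean_records_per_patient = 4.5,
                         seed = 9, record_length_s = 0.25)
  n <- nrow(ds$manifest)
  prev <- default_prevalences()
  for (cls in c("sinus_rhythm", "atrial_fibrillation", "low_qrs_voltage")) {
    p <- prev[[cls]]
    half <- 2.576 * sqrt(p * (1 - p) / n)   # binomial 99% CI
    expect_lt(abs(mean(ds$manifest[[cls]]) - p), half, label = cls)
  }
  counts <- lengths(patient_index(ds))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 4.5), 2 * se)
  expect_true(all(counts >= 1))
})

test_that("patient-level splits partition records with disjoint patients", {
  ds <- generate_dataset(n_patients = 60, seed = 12, record_length_s = 0.25)
  sp <- split_by_patient(ds, 10, 12, seed = 4)
  pats <- lapply(sp, function(d) unique(d$manifest$patient_id))
  expect_length(intersect(pats$train, pats$validation), 0)
  expect_length(intersect(pats$train, pats$test), 0)
  expect_length(intersect(pats$validation, pats$test), 0)
  expect_length(pats$validation, 10)
  expect_length(pats$test, 12)
  expect_setequal(
    c(sp$train$manifest$record_id, sp$validation$manifest$record_id,
      sp$test$manifest$record_id),
    ds$manifest$record_id)
  expect_equal(nrow(sp$train$manifest) + nrow(sp$validation$manifest) +
                 nrow(sp$test$manifest), nrow(ds$manifest))
  sp2 <- split_by_patient(ds, 10, 12, seed = 4)
  expect_identical(sp$test$manifest$record_id, sp2$test$manifest$record_id)
  expect_error(split_by_patient(ds, 40, 40, seed = 1), "too few patients")
})

test_that("generator rejects invalid configurations", {
  expect_error(generate_dataset(0, seed = 1), "n_patients")
  prev0 <- stats::setNames(rep(0, 9), ecg_class_names())
  expect_error(generate_dataset(5, prevalences = prev0, seed = 1), "all-zero")
  prev_bad <- default_prevalences(); prev_bad[1] <- 1.4
  expect_error(generate_dataset(5, prevalences = prev_bad, seed = 1),
               "\\[0, 1\\]")
})

test_that("dataset and WFDB containers round-trip", {
  ds <- generate_dataset(n_patients = 6, seed = 21)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- read_dataset(dir)
  expect_equal(length(ds2$records), length(ds$records))
  expect_equal(ds2$records[[3]]$signal, ds$records[[3]]$signal,
               tolerance = 1e-6)   # float32 storage
  expect_identical(ds2$records[[3]]$labels, ds$records[[3]]$labels)
  expect_identical(ds2$records[[3]]$relevance_mask,
                   ds$records[[3]]$relevance_mask)

  r <- ds$records[[1]]
  write_wfdb(r, dir, "rec1")
  r2 <- read_wfdb(file.path(dir, "rec1.hea"))
  expect_equal(dim(r2$signal), dim(r$signal))
  expect_identical(rownames(r2$signal), rownames(r$signal))
  expect_lt(max(abs(r2$signal - r$signal)), 0.5 / 200 + 1e-9)  # half LSB at gain 200
  expect_equal(r2$sampling_rate, r$sampling_rate)
})
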