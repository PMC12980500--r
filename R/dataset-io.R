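# On-disk dataset container: one float32 array file (signals, [N x 8 x L],
# written record-major) plus a CSV manifest and a JSON metadata sidecar.
# Individual records can additionally be exported to / read from WFDB
# (format 16) for interchange with standard ECG tooling.

#' Write a dataset to a directory
#'
#' Layout: `signals.f32` (little-endian float32, record-major), `manifest.csv`
#' (patient_id, record_id, 9 label columns), `masks.f32` (0/1 float32, present
#' only when every record carries a relevance mask), and `meta.json`.
#'
#' @param ds An `ecg_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "signals.f32"), "wb")
  on.exit(close(con), add = TRUE)
  for (r in ds$records) {
    writeBin(as.numeric(r$signal), con, size = 4, endian = "little")
  }
  has_masks <- all(vapply(ds$records, function(r) !is.null(r$relevance_mask),
                          logical(1)))
  if (has_masks) {
    mcon <- file(file.path(dir, "masks.f32"), "wb")
    on.exit(close(mcon), add = TRUE)
    for (r in ds$records) {
      writeBin(as.numeric(r$relevance_mask), mcon, size = 4, endian = "little")
    }
  }
  readr::write_csv(ds$manifest, file.path(dir, "manifest.csv"))
  meta <- list(n_records = length(ds$records), n_leads = 8L,
               n_samples = ncol(ds$records[[1]]$signal),
               sampling_rate = ds$sampling_rate,
               record_length_s = ds$record_length_s,
               generator_seed = ds$generator_seed,
               class_prevalences = as.list(ds$class_prevalences),
               has_masks = has_masks)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir Directory containing `signals.f32`, `manifest.csv`, `meta.json`.
#' @return An `ecg_dataset`.
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  n <- meta$n_records; C <- meta$n_leads; L <- meta$n_samples
  sig <- readBin(file.path(dir, "signals.f32"), what = "numeric", size = 4,
                 n = n * C * L, endian = "little")
  masks <- NULL
  if (isTRUE(meta$has_masks)) {
    masks <- readBin(file.path(dir, "masks.f32"), what = "numeric", size = 4,
                     n = n * C * L, endian = "little")
  }
  records <- vector("list", n)
  cls <- ecg_class_names()
  for (i in seq_len(n)) {
    s <- matrix(sig[((i - 1) * C * L + 1):(i * C * L)], C, L,
                dimnames = list(ECG_LEADS, NULL))
    m <- if (!is.null(masks)) {
      matrix(as.integer(masks[((i - 1) * C * L + 1):(i * C * L)]), C, L,
             dimnames = list(ECG_LEADS, NULL))
    }
    labels <- stats::setNames(as.integer(manifest[i, cls]), cls)
    records[[i]] <- new_ecg_record(manifest$patient_id[i],
                                   manifest$record_id[i], s,
                                   meta$sampling_rate, labels, m)
  }
  prev <- unlist(meta$class_prevalences)
  structure(list(records = records, manifest = manifest,
                 class_prevalences = prev,
                 generator_seed = meta$generator_seed,
                 sampling_rate = meta$sampling_rate,
                 record_length_s = meta$record_length_s),
            class = "ecg_dataset")
}

#' Export one record to WFDB format
#'
#' Writes `<name>.hea` and `<name>.dat` (format 16: little-endian 16-bit
#' integers, sample-interleaved across signals) with a fixed gain of 200
#' ADC units per millivolt.
#'
#' @param record An `ecg_record`.
#' @param dir Output directory. @param name Record name (defaults to the
#'   record id). @param gain ADC units per millivolt.
#' @return Path of the header file, invisibly.
#' @export
write_wfdb <- function(record, dir, name = record$record_id, gain = 200) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- record$signal
  n_sig <- nrow(sig); n_samp <- ncol(sig)
  adc <- round(sig * gain)
  adc[adc > 32767] <- 32767; adc[adc < -32768] <- -32768
  dat <- paste0(name, ".dat")
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.integer(adc), con, size = 2, endian = "little")  # column-major
  hdr <- c(sprintf("%s %d %g %d", name, n_sig, record$sampling_rate, n_samp),
           sprintf("%s 16 %g(0)/mV 16 0 %d 0 0 %s",
                   dat, gain, adc[, 1], rownames(sig)))
  hea <- file.path(dir, paste0(name, ".hea"))
  writeLines(hdr, hea)
  invisible(hea)
}

#' Read a WFDB record (format 16)
#'
#' Minimal reader for the subset written by [write_wfdb()]: single .dat file,
#' format 16, per-signal gain in units/mV.
#'
#' @param hea_path Path to the `.hea` header file.
#' @return An `ecg_record` (labels all zero, no relevance mask).
#' @export
read_wfdb <- function(hea_path) {
  lines <- readLines(hea_path)
  head_f <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  name <- head_f[1]; n_sig <- as.integer(head_f[2])
  fs <- as.numeric(head_f[3]); n_samp <- as.integer(head_f[4])
  sig_lines <- lines[2:(1 + n_sig)]
  fields <- strsplit(trimws(sig_lines), "\\s+")
  dat_file <- fields[[1]][1]
  gains <- vapply(fields, function(f) as.numeric(sub("\\(.*$", "", f[3])),
                  numeric(1))
  leads <- vapply(fields, function(f) f[length(f)], character(1))
  raw <- readBin(file.path(dirname(hea_path), dat_file), what = "integer",
                 size = 2, n = n_sig * n_samp, endian = "little", signed = TRUE)
  sig <- matrix(raw, n_sig, n_samp) / gains
  dimnames(sig) <- list(leads, NULL)
  new_ecg_record(patient_id = name, record_id = name, signal = sig,
                 sampling_rate = fs,
                 labels = stats::setNames(integer(9), ecg_class_names()))
}
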