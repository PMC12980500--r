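# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a parent seed and a context key
#'
#' All randomness in the package is funneled through one global seed; stages
#' and sub-tasks derive their own seeds deterministically so that re-running
#' any stage in isolation reproduces the full-pipeline result. Derived seeds
#' stay below 2^31 - 1.
#'
#' @param seed Integer parent seed.
#' @param ... Character or integer context keys (stage name, record index, ...).
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  keys <- list(...)
  h <- as.double(seed) %% 2147483629
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(paste(k, collapse = ""))) else k <- as.double(k)
    # 64-bit doubles hold intermediate products below 2^53 exactly
    h <- (h * 48271 + k + 11) %% 2147483629
  }
  as.integer(h + 1)
}

#' Content hash of an R object (via its canonical JSON form)
#' @keywords internal
#' @noRd
content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

abort_config <- function(msg) stop(structure(
  class = c("ecgxai_config_error", "error", "condition"),
  list(message = msg, call = NULL)))

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what))
  invisible(x)
}

# format a numeric for reports: fixed 6 significant digits so that repeated
# runs yield byte-identical CSV files
signif6 <- function(x) signif(x, 6)
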