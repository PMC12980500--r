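# Attribution-map post-processing: Savitzky-Golay smoothing, per-lead
# correlation scoring, absolute-value point ranking, and mean +/- SD
# aggregation across seeds and classes.

map_values <- function(m) if (inherits(m, "attribution_map")) m$values else m

#' Savitzky-Golay smoothing of an attribution map
#'
#' Least-squares local polynomial smoothing applied independently to each
#' lead row (default 31-sample window, third-order polynomial). Edges are
#' handled by the filter's terminal polynomial fits, so polynomial rows of
#' degree <= `polyorder` are reproduced exactly over the full length.
#'
#' @param map An `attribution_map` or an `[8 x L]` matrix.
#' @param window Odd window length in samples (<= L).
#' @param polyorder Polynomial order (< window).
#' @return Same type as the input, smoothed.
#' @export
savgol_smooth <- function(map, window = 31L, polyorder = 3L) {
  v <- map_values(map)
  if (window %% 2 == 0) abort_config("window must be odd")
  if (polyorder >= window) abort_config("polyorder must be below window")
  if (window > ncol(v)) abort_config("window exceeds map length")
  sm <- t(apply(v, 1, function(row)
    signal::sgolayfilt(row, p = polyorder, n = window)))
  dimnames(sm) <- dimnames(v)
  if (inherits(map, "attribution_map")) { map$values <- sm; map } else sm
}

#' Similarity between two attribution maps
#'
#' Pointwise correlation computed within each lead row, then averaged without
#' weights over the 8 leads. A constant row on either side contributes a
#' correlation of 0 for that lead and raises the degenerate flag (constant
#' maps carry no shape information; scoring them 0 rather than dropping them
#' keeps aggregates unbiased and the flag counts are reported).
#'
#' @param mapA,mapB `attribution_map`s or matrices of identical shape.
#' @param kind `"pearson"` or `"spearman"` (ranks within lead first).
#' @param pooled Correlate the flattened maps across all leads jointly
#'   instead of per lead (sensitivity-analysis variant).
#' @return One-row tibble: `value`, `kind`, `n_points`, `degenerate_flag`.
#' @export
similarity <- function(mapA, mapB, kind = c("pearson", "spearman"),
                       pooled = FALSE) {
  kind <- match.arg(kind)
  a <- map_values(mapA); b <- map_values(mapB)
  if (!all(dim(a) == dim(b))) stop("attribution maps differ in shape")
  cor_safe <- function(u, v) {
    if (stats::sd(u) == 0 || stats::sd(v) == 0) return(NA_real_)
    if (identical(u, v)) return(1)   # exact for identical rows
    stats::cor(u, v, method = kind)
  }
  if (pooled) {
    r <- cor_safe(as.vector(a), as.vector(b))
    degenerate <- is.na(r)
    value <- if (degenerate) 0 else r
  } else {
    rs <- vapply(seq_len(nrow(a)), function(i) cor_safe(a[i, ], b[i, ]),
                 numeric(1))
    degenerate <- anyNA(rs)
    rs[is.na(rs)] <- 0
    value <- mean(rs)
  }
  tibble::tibble(value = value, kind = kind, n_points = length(a),
                 degenerate_flag = degenerate)
}

#' Rank all map points by descending absolute attribution
#'
#' @param map An `attribution_map` or matrix.
#' @return Integer vector of linear indices (column-major over the
#'   `[8 x L]` matrix) in rank order; ties break by ascending (lead, time).
#' @export
rank_points_abs <- function(map) {
  v <- map_values(map)
  stopifnot_finite(v, "attribution map")
  lead <- rep(seq_len(nrow(v)), ncol(v))
  tim <- rep(seq_len(ncol(v)), each = nrow(v))
  order(-abs(as.vector(v)), lead, tim)
}

#' Aggregate similarity scores into mean +/- SD tables
#'
#' @param scores Tibble of scores with a `value` column and arbitrary
#'   grouping keys (e.g. method/pair, class, seed).
#' @param ... Grouping columns (tidy-select), e.g. `method, class`.
#' @return Tibble with per-group `mean`, `sd` (sample SD, n-1; seeds are a
#'   sample of initializations), `n` and `degenerate_count`. Empty input
#'   yields an empty table with a warning rather than silent zeros.
#' @export
aggregate_scores <- function(scores, ...) {
  if (nrow(scores) == 0) {
    warning("no scores to aggregate; returning empty table")
    return(tibble::tibble())
  }
  has_flag <- "degenerate_flag" %in% names(scores)
  scores |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      n = dplyr::n(),
      degenerate_count = if (has_flag) sum(.data$degenerate_flag) else 0L,
      .groups = "drop")
}
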