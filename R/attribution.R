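# Twelve attribution methods behind one dispatch contract. Every method maps
# (model, 8 x L signal) to a relevance matrix of the same shape. The
# attribution target is the pre-sigmoid score of the model's positive class:
# gradients there do not vanish when the output saturates.

#' The twelve attribution method identifiers
#' @return Character vector of method ids accepted by [compute_attribution()].
#' @export
attribution_methods <- function() {
  c("saliency", "smoothgrad", "gradient_input", "guided_backprop", "gradcam",
    "guided_gradcam", "shapley_sampling", "deeplift", "integrated_gradients",
    "ig_smoothgrad", "gradient_shap", "deeplift_shap")
}

new_attribution_map <- function(values, method, model, config = list(),
                                randomization_step = NA_integer_) {
  stopifnot_finite(values, sprintf("%s attribution map", method))
  structure(list(values = values, method = method,
                 target = model$class_label,
                 model_tag = list(class = model$class_label,
                                  init_seed = model$init_seed,
                                  randomization_step = randomization_step),
                 config_hash = content_hash(config)),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("<attribution_map %s: 8 x %d, |max| %.3g>\n", x$method,
              ncol(x$values), max(abs(x$values))))
  invisible(x)
}

#' @export
as_tibble.attribution_map <- function(x, ...) {
  tibble::tibble(lead = rep(rownames(x$values) %||% as.character(1:8),
                            ncol(x$values))[seq_along(x$values)],
                 time = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
                 value = as.vector(x$values), method = x$method)
}

zeros_like <- function(x) array(0, dim(as_batch(x))[1:2])

# First batch slice of a gradient array, with the input's shape and lead names.
slice1 <- function(dx, x) {
  m <- matrix(dx[, , 1], nrow(x), ncol(x))
  dimnames(m) <- dimnames(x)
  m
}

#' Saliency (absolute input gradient)
#'
#' @param model An `ecg_model`. @param x Signal matrix `[8 x L]`.
#' @return An `attribution_map` with values `|d score / d x|`.
#' @export
saliency <- function(model, x) {
  g <- slice1(input_gradient(model, x)$dx, x)
  new_attribution_map(abs(g), "saliency", model)
}

#' Gradient * Input
#' @inheritParams saliency
#' @return Signed map `x * d score / d x`.
#' @export
gradient_input <- function(model, x) {
  g <- slice1(input_gradient(model, x)$dx, x)
  new_attribution_map(x * g, "gradient_input", model)
}

#' Integrated gradients
#'
#' Midpoint-rule Riemann approximation of the path integral from `baseline`
#' to `x`; attributions converge to the completeness identity
#' `sum(map) = score(x) - score(baseline)` as `n_steps` grows.
#'
#' @inheritParams saliency
#' @param baseline Reference signal (default all-zero / flat line).
#' @param n_steps Number of Riemann steps (>= 1).
#' @export
integrated_gradients <- function(model, x, baseline = NULL, n_steps = 64L) {
  if (n_steps < 1) abort_config("n_steps must be >= 1")
  if (is.null(baseline)) baseline <- zeros_like(x)
  stopifnot(all(dim(baseline) == dim(x)))
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  diffs <- x - baseline
  xs <- array(0, c(dim(x), n_steps))
  for (i in seq_len(n_steps)) xs[, , i] <- baseline + alphas[i] * diffs
  g <- input_gradient(model, xs)$dx
  avg <- array(rowMeans(matrix(g, prod(dim(x)), n_steps)), dim(x))
  dimnames(avg) <- dimnames(x)
  new_attribution_map(diffs * avg, "integrated_gradients", model,
                      list(n_steps = n_steps))
}

#' DeepLift (rescale rule)
#'
#' Contribution scores via rescale-rule multipliers chained through the
#' network's convolution, batch-norm, pooling and linear layers (all exactly
#' linear in inference mode) and its ReLU units. Satisfies
#' summation-to-delta exactly: `sum(map) = score(x) - score(baseline)`.
#'
#' @inheritParams integrated_gradients
#' @export
deeplift_rescale <- function(model, x, baseline = NULL) {
  if (is.null(baseline)) baseline <- zeros_like(x)
  stopifnot(all(dim(baseline) == dim(x)))
  r <- input_gradient(model, x, rule = "deeplift", x_ref = baseline)
  new_attribution_map((x - baseline) * slice1(r$dx, x), "deeplift", model)
}

#' Guided backpropagation
#'
#' Backward pass in which every ReLU propagates gradient only where its
#' forward input and the incoming gradient are both positive.
#'
#' @inheritParams saliency
#' @export
guided_backprop <- function(model, x) {
  g <- slice1(input_gradient(model, x, rule = "guided")$dx, x)
  new_attribution_map(g, "guided_backprop", model)
}

#' GradCAM for 1D signals
#'
#' Channel weights are time-averaged gradients at the tap layer; the weighted
#' activation sum is clamped at zero, linearly upsampled to the input length
#' and replicated across the 8 lead rows (post-convolution channels mix
#' leads, so the map carries no per-lead information).
#'
#' @inheritParams saliency
#' @param tap_layer Residual-block activation to tap (`"b<i>"`); default the
#'   last block (deepest convolutional features).
#' @export
gradcam <- function(model, x, tap_layer = NULL) {
  n_blocks <- length(model$blocks)
  if (is.null(tap_layer)) tap_layer <- sprintf("b%d", n_blocks)
  if (!tap_layer %in% sprintf("b%d", seq_len(n_blocks))) {
    abort_config(sprintf("tap layer '%s' not found", tap_layer))
  }
  b <- as.integer(sub("^b", "", tap_layer))
  r <- input_gradient(model, x, collect_block_grads = TRUE)
  act <- r$cache$blocks[[b]]$out
  grd <- r$block_grads[[tap_layer]]
  C <- dim(act)[1]; Lt <- dim(act)[2]
  w <- rowMeans(matrix(grd, C))
  cam <- pmax(colSums(matrix(act, C) * w), 0)
  L <- ncol(x)
  up <- if (Lt == 1) rep(cam, L) else
    stats::approx(seq(0, 1, length.out = Lt), cam,
                  xout = seq(0, 1, length.out = L))$y
  vals <- matrix(rep(up, each = 8), 8, L, dimnames = dimnames(x))
  new_attribution_map(vals, "gradcam", model, list(tap_layer = tap_layer))
}

#' Guided GradCAM
#'
#' Elementwise product of a guided-backpropagation map and an (upsampled)
#' GradCAM map of the same shape.
#'
#' @param gbp_map,gradcam_map `attribution_map`s of identical shape.
#' @export
combine_guided_gradcam <- function(gbp_map, gradcam_map) {
  if (!all(dim(gbp_map$values) == dim(gradcam_map$values))) {
    stop("guided-backprop and GradCAM maps differ in shape")
  }
  structure(list(values = gbp_map$values * gradcam_map$values,
                 method = "guided_gradcam", target = gbp_map$target,
                 model_tag = gbp_map$model_tag,
                 config_hash = gbp_map$config_hash),
            class = "attribution_map")
}

#' SmoothGrad wrapper
#'
#' Averages the base method's maps over `n_samples` Gaussian-perturbed copies
#' of the input; the noise SD is `noise_frac` times the signal range.
#'
#' @param base_method Function `(model, x) -> attribution_map`.
#' @inheritParams saliency
#' @param n_samples Number of noise draws. @param noise_frac Noise SD as a
#'   fraction of `max(x) - min(x)`. @param seed Integer seed.
#' @param method_id Method name recorded on the output.
#' @export
smoothgrad_wrap <- function(base_method, model, x, n_samples = 32L,
                            noise_frac = 0.1, seed = 1L,
                            method_id = "smoothgrad") {
  stopifnot(noise_frac >= 0, n_samples >= 1)
  sd <- noise_frac * (max(x) - min(x))
  acc <- withr::with_seed(derive_seed(seed, "smoothgrad"), {
    total <- array(0, dim(x))
    for (i in seq_len(n_samples)) {
      xi <- x + matrix(stats::rnorm(length(x), 0, sd), nrow(x), ncol(x))
      total <- total + base_method(model, xi)$values
    }
    total / n_samples
  })
  new_attribution_map(acc, method_id, model,
                      list(n_samples = n_samples, noise_frac = noise_frac))
}

#' Shapley value sampling over contiguous time segments
#'
#' The time axis is partitioned into `n_segments` contiguous windows spanning
#' all leads jointly; per-segment Shapley values are estimated by sampling
#' random permutations and accumulating marginal score changes as segments
#' are switched from `baseline` to `x`. The estimator is unbiased; each
#' segment's value is broadcast uniformly to its points.
#'
#' @inheritParams integrated_gradients
#' @param n_segments Number of contiguous segments (<= L).
#' @param n_samples Number of sampled permutations (>= 1).
#' @param seed Integer seed.
#' @export
shapley_sampling <- function(model, x, baseline = NULL, n_segments = 32L,
                             n_samples = 256L, seed = 1L) {
  L <- ncol(x)
  if (n_segments > L) abort_config("n_segments must be <= signal length")
  if (n_samples < 1) abort_config("n_samples must be >= 1")
  if (is.null(baseline)) baseline <- zeros_like(x)
  seg_of <- cut(seq_len(L), n_segments, labels = FALSE)
  base_score <- forward_pass(model, baseline)$logit
  seg_sum <- numeric(n_segments)
  withr::with_seed(derive_seed(seed, "shapley"), {
    for (s in seq_len(n_samples)) {
      perm <- sample.int(n_segments)
      xs <- array(0, c(dim(x), n_segments))
      cur <- baseline
      for (j in seq_len(n_segments)) {
        cols <- seg_of == perm[j]
        cur[, cols] <- x[, cols]
        xs[, , j] <- cur
      }
      scores <- forward_pass(model, xs)$logit
      seg_sum[perm] <- seg_sum[perm] + diff(c(base_score, scores))
    }
  })
  seg_val <- seg_sum / n_samples
  vals <- matrix(seg_val[seg_of], nrow = 8, ncol = L, byrow = TRUE,
                 dimnames = dimnames(x))
  new_attribution_map(vals, "shapley_sampling", model,
                      list(n_segments = n_segments, n_samples = n_samples))
}

#' GradientSHAP
#'
#' Monte-Carlo expectation, over random baselines and uniform path positions,
#' of `(x - baseline) * grad(baseline + a * (x + noise - baseline))`.
#'
#' @inheritParams saliency
#' @param baselines Array `[8 x L x k]` of reference signals (k >= 1).
#' @param n_samples Monte-Carlo samples. @param noise_sd Input noise SD
#'   (absolute, millivolts). @param seed Integer seed.
#' @export
gradient_shap <- function(model, x, baselines, n_samples = 32L,
                          noise_sd = 0, seed = 1L) {
  baselines <- as_batch(baselines)
  k <- dim(baselines)[3]
  if (k < 1) abort_config("empty baseline set")
  withr::with_seed(derive_seed(seed, "gradient_shap"), {
    bi <- sample.int(k, n_samples, replace = TRUE)
    a <- stats::runif(n_samples)
    xs <- array(0, c(dim(x), n_samples))
    for (s in seq_len(n_samples)) {
      xn <- x + matrix(stats::rnorm(length(x), 0, noise_sd), nrow(x), ncol(x))
      xs[, , s] <- baselines[, , bi[s]] + a[s] * (xn - baselines[, , bi[s]])
    }
    g <- input_gradient(model, xs)$dx
    acc <- array(0, dim(x))
    for (s in seq_len(n_samples)) {
      acc <- acc + (x - baselines[, , bi[s]]) * g[, , s]
    }
    acc <- acc / n_samples
    dimnames(acc) <- dimnames(x)
    new_attribution_map(acc, "gradient_shap", model,
                        list(n_samples = n_samples, noise_sd = noise_sd))
  })
}

#' DeepLiftSHAP
#'
#' Mean of DeepLift rescale contributions over a set of baselines; inherits
#' summation-to-delta in expectation over the baseline set.
#'
#' @inheritParams gradient_shap
#' @export
deeplift_shap <- function(model, x, baselines) {
  baselines <- as_batch(baselines)
  k <- dim(baselines)[3]
  if (k < 1) abort_config("empty baseline set")
  xs <- array(x, c(dim(x), k))
  r <- input_gradient(model, xs, rule = "deeplift", x_ref = baselines)
  contrib <- (xs - baselines) * r$dx
  vals <- array(rowMeans(matrix(contrib, length(x), k)), dim(x))
  dimnames(vals) <- dimnames(x)
  new_attribution_map(vals, "deeplift_shap", model, list(k = k))
}

#' Default attribution hyperparameters
#'
#' Settings follow the stabilization heuristic of increasing each budget
#' until further increases no longer visibly change the maps on desk-scale
#' models: IG 64 steps, SmoothGrad 32 draws at 0.1 x signal range, Shapley 32
#' segments x 256 permutations, 16 baseline draws for the SHAP variants.
#'
#' @return Named list of per-method settings.
#' @export
attribution_config <- function() {
  list(ig = list(n_steps = 64L),
       smoothgrad = list(n_samples = 32L, noise_frac = 0.1),
       shapley = list(n_segments = 32L, n_samples = 256L),
       shap = list(n_baselines = 16L, baseline_source = "training-draws",
                   noise_sd = 0),
       gradcam = list(tap_layer = NULL))
}

#' Compute an attribution map by method id
#'
#' Single entry point dispatching to the twelve methods. SHAP-variant
#' baselines default to all-zero signals when no `baselines` array is given.
#'
#' @inheritParams saliency
#' @param method One of [attribution_methods()].
#' @param config Hyperparameters, see [attribution_config()].
#' @param seed Integer seed for the stochastic methods.
#' @param baselines Optional `[8 x L x k]` array of baseline draws for
#'   GradientSHAP / DeepLiftSHAP.
#' @return An `attribution_map`.
#' @export
#' @examples
#' \donttest{
#' m <- build_model(model_config(n_conv_layers = 4, base_channels = 4,
#'                               input_length = 128), init_seed = 1)
#' x <- matrix(rnorm(8 * 128), 8)
#' a <- compute_attribution(m, x, "saliency")
#' dim(a$values)
#' }
compute_attribution <- function(model, x, method,
                                config = attribution_config(), seed = 1L,
                                baselines = NULL) {
  if (!method %in% attribution_methods()) {
    abort_config(sprintf("unknown attribution method '%s'", method))
  }
  if (is.null(baselines)) {
    baselines <- array(0, c(dim(x), config$shap$n_baselines))
  }
  switch(method,
    saliency = saliency(model, x),
    gradient_input = gradient_input(model, x),
    integrated_gradients = integrated_gradients(model, x,
                                                n_steps = config$ig$n_steps),
    deeplift = deeplift_rescale(model, x),
    guided_backprop = guided_backprop(model, x),
    gradcam = gradcam(model, x, config$gradcam$tap_layer),
    guided_gradcam = combine_guided_gradcam(
      guided_backprop(model, x), gradcam(model, x, config$gradcam$tap_layer)),
    smoothgrad = smoothgrad_wrap(saliency, model, x,
                                 config$smoothgrad$n_samples,
                                 config$smoothgrad$noise_frac, seed,
                                 "smoothgrad"),
    ig_smoothgrad = smoothgrad_wrap(
      function(m, xx) integrated_gradients(m, xx, n_steps = config$ig$n_steps),
      model, x, config$smoothgrad$n_samples, config$smoothgrad$noise_frac,
      seed, "ig_smoothgrad"),
    shapley_sampling = shapley_sampling(model, x,
                                        n_segments = config$shapley$n_segments,
                                        n_samples = config$shapley$n_samples,
                                        seed = seed),
    gradient_shap = gradient_shap(model, x, baselines,
                                  n_samples = 2L * dim(as_batch(baselines))[3],
                                  noise_sd = config$shap$noise_sd, seed = seed),
    deeplift_shap = deeplift_shap(model, x, baselines))
}

#' Draw baseline signals from a training dataset
#'
#' @param ds An `ecg_dataset`. @param k Number of draws. @param seed Seed.
#' @return Array `[8 x L x k]`.
#' @export
draw_baselines <- function(ds, k = 16L, seed = 1L) {
  idx <- withr::with_seed(derive_seed(seed, "baselines"),
                          sample.int(length(ds$records), k, replace = k > length(ds$records)))
  array(unlist(lapply(ds$records[idx], `[[`, "signal")),
        c(dim(ds$records[[1]]$signal), k))
}

#' Write / read a stack of attribution maps
#'
#' One float32 array file per (model, method) plus a JSON sidecar recording
#' method, target, model tag and configuration hash.
#'
#' @param maps List of `attribution_map`s sharing method and shape.
#' @param path Output path for the array file (sidecar: `path + ".json"`).
#' @return `path`, invisibly.
#' @export
write_attribution_maps <- function(maps, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  for (m in maps) writeBin(as.numeric(m$values), con, size = 4,
                           endian = "little")
  meta <- list(n_maps = length(maps), n_leads = nrow(maps[[1]]$values),
               n_samples = ncol(maps[[1]]$values),
               method = maps[[1]]$method, target = maps[[1]]$target,
               model_tag = maps[[1]]$model_tag,
               config_hash = maps[[1]]$config_hash)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_attribution_maps
#' @export
read_attribution_maps <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  C <- meta$n_leads; L <- meta$n_samples; n <- meta$n_maps
  raw <- readBin(path, "numeric", size = 4, n = C * L * n, endian = "little")
  lapply(seq_len(n), function(i) {
    structure(list(values = matrix(raw[((i - 1) * C * L + 1):(i * C * L)], C, L,
                                   dimnames = list(ECG_LEADS, NULL)),
                   method = meta$method, target = meta$target,
                   model_tag = meta$model_tag,
                   config_hash = meta$config_hash),
              class = "attribution_map")
  })
}
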