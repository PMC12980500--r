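# Small dense networks behind the same forward/backward contract as the
# convolutional task model. They make the attribution methods checkable
# against closed forms: a 0-hidden-layer network is exactly linear (analytic
# maps for every gradient-based method), and ReLU networks with hand-set
# weights admit hand-worked DeepLift / guided-backpropagation examples.

#' Dense (fully connected) toy model
#'
#' Layers act on the flattened `[8 x L]` input; every hidden layer is
#' followed by a ReLU, the final layer is linear with a single output (the
#' pre-sigmoid score). With no hidden layers the model is linear:
#' `score = <w, x> + b`.
#'
#' @param weights List of weight matrices `[out x in]`, input-first; the last
#'   must have one row.
#' @param biases List of bias vectors matching `weights` (defaults to
#'   zeros).
#' @param input_dim Input shape, `c(leads, samples)`.
#' @return An `mlp_model` usable with [compute_attribution()] and
#'   [forward_pass()].
#' @export
#' @examples
#' w <- matrix(rnorm(16), 1)      # linear model on a 2 x 8 input
#' m <- mlp_model(list(w), input_dim = c(2, 8))
#' forward_pass(m, matrix(1, 2, 8))$logit
mlp_model <- function(weights, biases = NULL, input_dim) {
  stopifnot(length(weights) >= 1, nrow(weights[[length(weights)]]) == 1)
  if (is.null(biases)) biases <- lapply(weights, function(w) numeric(nrow(w)))
  stopifnot(ncol(weights[[1]]) == prod(input_dim))
  structure(list(weights = weights, biases = biases,
                 input_dim = as.integer(input_dim),
                 class_label = "toy", init_seed = 0L, trained = FALSE),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model: %d layer(s) on a %d x %d input>\n",
              length(x$weights), x$input_dim[1], x$input_dim[2]))
  invisible(x)
}

#' @export
forward_pass.mlp_model <- function(model, x, training = FALSE,
                                   keep_cache = FALSE) {
  x <- as_batch(x)
  B <- dim(x)[3]
  a <- matrix(x, prod(model$input_dim), B)
  zs <- vector("list", length(model$weights))
  n <- length(model$weights)
  for (i in seq_len(n)) {
    z <- model$weights[[i]] %*% a + model$biases[[i]]
    zs[[i]] <- z
    a <- if (i < n) pmax(z, 0) else z
  }
  logit <- as.vector(a)
  list(logit = logit, prob = 1 / (1 + exp(-logit)), model = model,
       cache = if (keep_cache) list(zs = zs, x_dim = dim(x)))
}

#' @export
input_gradient.mlp_model <- function(model, x, rule = "grad", x_ref = NULL,
                                     collect_block_grads = FALSE) {
  x <- as_batch(x)
  fw <- forward_pass(model, x, keep_cache = TRUE)
  ref <- NULL
  ref_logit <- NULL
  if (rule == "deeplift") {
    x_ref <- as_batch(x_ref)
    if (dim(x_ref)[3] == 1 && dim(x)[3] > 1) x_ref <- array(x_ref[, , 1], dim(x))
    rf <- forward_pass(model, x_ref, keep_cache = TRUE)
    ref <- rf$cache
    ref_logit <- rf$logit
  }
  n <- length(model$weights)
  B <- dim(x)[3]
  d <- matrix(1, 1, B)
  for (i in rev(seq_len(n))) {
    if (i < n) d <- relu_bwd(d, fw$cache$zs[[i]], rule, ref$zs[[i]])
    d <- crossprod(model$weights[[i]], d)
  }
  dx <- array(d, dim(x))
  list(dx = dx, logit = fw$logit, cache = fw$cache, block_grads = NULL,
       ref_logit = ref_logit)
}
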