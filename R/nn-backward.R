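# Backward passes. One engine serves three semantics:
#  * training: full parameter gradients (batch-norm in batch-statistics mode,
#    dropout masks applied);
#  * attribution gradients (inference mode, batch norm is affine);
#  * guided backpropagation and DeepLift rescale multipliers, which differ
#    from plain gradients only in the ReLU backward rule.

# Spread the pooled gradient back over the time axis.
gap_backward <- function(dfeat, final_dim) {
  C <- final_dim[1]; L <- final_dim[2]; B <- final_dim[3]
  aperm(array(dfeat, c(C, B, L)), c(1, 3, 2)) / L
}

#' Training backward pass
#'
#' @param model Model used in the forward pass.
#' @param cache Cache from `forward_pass(..., training = TRUE, keep_cache = TRUE)`.
#' @param dlogit Gradient of the loss w.r.t. the pre-sigmoid output, length B.
#' @return Named list of parameter gradients (`head.w`, `b1.conv1.w`, ...).
#' @keywords internal
backward_params <- function(model, cache, dlogit) {
  grads <- list()
  grads[["head.w"]] <- drop(cache$feat %*% dlogit)
  grads[["head.b"]] <- sum(dlogit)
  dfeat <- outer(model$head$w, dlogit)
  d <- gap_backward(dfeat, cache$final_dim)
  for (b in rev(seq_along(model$blocks))) {
    blk <- model$blocks[[b]]
    cb <- cache$blocks[[b]]
    if (!is.null(cb$m2)) d <- d * cb$m2
    dz <- d * (cb$zsum > 0)
    bn2 <- bn_bwd_train(blk$bn2, cb$bn2, dz)
    cv2 <- conv1d_bwd(blk$conv2, cb$c2, bn2$dx)
    dh1 <- cv2$dx
    if (!is.null(cb$m1)) dh1 <- dh1 * cb$m1
    dz1 <- dh1 * (cb$z1 > 0)
    bn1 <- bn_bwd_train(blk$bn1, cb$bn1, dz1)
    cv1 <- conv1d_bwd(blk$conv1, cb$c1, bn1$dx)
    if (is.null(blk$proj)) {
      dx <- cv1$dx + dz
    } else {
      pj <- conv1d_bwd(blk$proj, cb$s_cache, dz)
      dx <- cv1$dx + pj$dx
      grads[[sprintf("b%d.proj.w", b)]] <- pj$dw
      grads[[sprintf("b%d.proj.b", b)]] <- pj$db
    }
    grads[[sprintf("b%d.conv1.w", b)]] <- cv1$dw
    grads[[sprintf("b%d.conv1.b", b)]] <- cv1$db
    grads[[sprintf("b%d.conv2.w", b)]] <- cv2$dw
    grads[[sprintf("b%d.conv2.b", b)]] <- cv2$db
    grads[[sprintf("b%d.bn1.gamma", b)]] <- bn1$dgamma
    grads[[sprintf("b%d.bn1.beta", b)]] <- bn1$dbeta
    grads[[sprintf("b%d.bn2.gamma", b)]] <- bn2$dgamma
    grads[[sprintf("b%d.bn2.beta", b)]] <- bn2$dbeta
    d <- dx
  }
  grads
}

#' Input-gradient backward pass (inference mode)
#'
#' Computes d(logit)/dx for every batch element, under one of three backward
#' semantics. For `mode = "deeplift"` the returned values are rescale-rule
#' multipliers; the caller multiplies by (x - baseline) to obtain
#' contributions, and `cache_ref` must hold the forward cache of the
#' reference input.
#'
#' @param model An `ecg_model`.
#' @param cache Forward cache on the input (inference mode).
#' @param mode `"grad"`, `"guided"` or `"deeplift"`.
#' @param cache_ref Forward cache on the reference input (deeplift only).
#' @param collect_block_grads Also return d(logit)/d(activation) at every
#'   block output (needed by GradCAM).
#' @return List with `dx` `[8 x L x B]` and optionally `block_grads`.
#' @keywords internal
backward_input <- function(model, cache, mode = "grad", cache_ref = NULL,
                           collect_block_grads = FALSE) {
  if (mode == "deeplift" && is.null(cache_ref)) {
    stop("deeplift backward requires the reference forward cache")
  }
  B <- cache$final_dim[3]
  dfeat <- outer(model$head$w, rep(1, B))
  d <- gap_backward(dfeat, cache$final_dim)
  block_grads <- if (collect_block_grads) list()
  for (b in rev(seq_along(model$blocks))) {
    blk <- model$blocks[[b]]
    cb <- cache$blocks[[b]]
    rb <- if (!is.null(cache_ref)) cache_ref$blocks[[b]]
    if (collect_block_grads) block_grads[[sprintf("b%d", b)]] <- d
    dz <- relu_bwd(d, cb$zsum, mode, rb$zsum)
    d2 <- bn_bwd_infer(cb$bn2, dz)
    dh1 <- conv1d_bwd_input(blk$conv2, cb$c2, d2)
    dz1 <- relu_bwd(dh1, cb$z1, mode, rb$z1)
    d1 <- bn_bwd_infer(cb$bn1, dz1)
    dx_main <- conv1d_bwd_input(blk$conv1, cb$c1, d1)
    dx <- if (is.null(blk$proj)) dx_main + dz
          else dx_main + conv1d_bwd_input(blk$proj, cb$s_cache, dz)
    d <- dx
  }
  list(dx = d, block_grads = block_grads)
}

# Convenience: gradient of the pre-sigmoid score w.r.t. a batch of inputs.
input_gradient <- function(model, x, rule = "grad", x_ref = NULL,
                           collect_block_grads = FALSE) {
  UseMethod("input_gradient")
}

#' @export
input_gradient.ecg_model <- function(model, x, rule = "grad", x_ref = NULL,
                                     collect_block_grads = FALSE) {
  x <- as_batch(x)
  fw <- forward_pass(model, x, training = FALSE, keep_cache = TRUE)
  cache_ref <- NULL
  ref_logit <- NULL
  if (rule == "deeplift") {
    x_ref <- as_batch(x_ref)
    if (dim(x_ref)[3] == 1 && dim(x)[3] > 1) {
      x_ref <- array(x_ref[, , 1], dim(x))
    }
    rf <- forward_pass(model, x_ref, training = FALSE, keep_cache = TRUE)
    cache_ref <- rf$cache
    ref_logit <- rf$logit
  }
  bk <- backward_input(model, fw$cache, rule, cache_ref, collect_block_grads)
  stopifnot_finite(bk$dx, "input gradient")
  list(dx = bk$dx, logit = fw$logit, cache = fw$cache,
       block_grads = bk$block_grads, ref_logit = ref_logit)
}
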