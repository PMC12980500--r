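# Training: Adam on binary cross-entropy, early stopping on validation AUROC.

param_names <- function(model) {
  out <- c("head.w", "head.b")
  for (b in seq_along(model$blocks)) {
    out <- c(out,
             sprintf("b%d.conv1.w", b), sprintf("b%d.conv1.b", b),
             sprintf("b%d.conv2.w", b), sprintf("b%d.conv2.b", b),
             sprintf("b%d.bn1.gamma", b), sprintf("b%d.bn1.beta", b),
             sprintf("b%d.bn2.gamma", b), sprintf("b%d.bn2.beta", b),
             if (!is.null(model$blocks[[b]]$proj))
               c(sprintf("b%d.proj.w", b), sprintf("b%d.proj.b", b)))
  }
  out
}

get_param <- function(model, name) {
  p <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (p[1] == "head") return(model$head[[p[2]]])
  b <- as.integer(sub("^b", "", p[1]))
  model$blocks[[b]][[p[2]]][[p[3]]]
}

set_param <- function(model, name, value) {
  p <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (p[1] == "head") {
    model$head[[p[2]]] <- value
  } else {
    b <- as.integer(sub("^b", "", p[1]))
    model$blocks[[b]][[p[2]]][[p[3]]] <- value
  }
  model
}

bce_loss <- function(logit, y, pos_weight = 1) {
  sp_pos <- pmax(-logit, 0) + log1p(exp(-abs(logit)))   # softplus(-z)
  sp_neg <- pmax(logit, 0) + log1p(exp(-abs(logit)))    # softplus(z)
  mean(pos_weight * y * sp_pos + (1 - y) * sp_neg)
}

bce_grad <- function(logit, y, pos_weight = 1) {
  s <- 1 / (1 + exp(-logit))
  (-pos_weight * y * (1 - s) + (1 - y) * s) / length(y)
}

#' Train a binary classifier
#'
#' Minimizes binary cross-entropy with Adam; after every epoch the model is
#' scored on the validation split and the parameter snapshot with the best
#' validation AUROC is returned (early stopping after `patience` epochs
#' without improvement). The run is a pure function of (model, data, seed):
#' batch shuffling and dropout draw from one seeded stream.
#'
#' @param model An `ecg_model` from [build_model()].
#' @param train_ds,val_ds Patient-disjoint `ecg_dataset`s (checked).
#' @param class_name Diagnostic class defining the binary labels.
#' @param epochs Maximum epochs (0 returns the initialized model unchanged).
#' @param batch_size,lr,patience Optimization settings.
#' @param seed Integer training seed.
#' @param stop_auroc Optional target validation AUROC; training stops early
#'   once reached (the snapshot at or above the target is kept).
#' @param pos_weight Positive-class weight in the cross-entropy; the default
#'   `"balanced"` uses the negative/positive count ratio, which speeds up
#'   convergence on low-prevalence classes. Use 1 for plain BCE.
#' @return The trained `ecg_model`, with fields `val_auroc`, `threshold`
#'   (Youden's J on the validation split) and `history` (per-epoch tibble).
#' @export
train_model <- function(model, train_ds, val_ds, class_name,
                        epochs = 30L, batch_size = 64L, lr = 1e-3,
                        patience = 5L, seed = 1L, stop_auroc = NULL,
                        pos_weight = "balanced") {
  overlap <- intersect(train_ds$manifest$patient_id, val_ds$manifest$patient_id)
  if (length(overlap) > 0) {
    stop(sprintf("train/validation sets share %d patients", length(overlap)))
  }
  y <- dataset_labels(train_ds, class_name)
  y_val <- dataset_labels(val_ds, class_name)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (length(unique(y_val)) < 2) stop("validation labels contain a single class")
  model$class_label <- class_name
  model$train_seed <- seed
  if (epochs == 0) {
    model$history <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                                    val_auroc = numeric())
    return(model)
  }
  if (identical(pos_weight, "balanced")) {
    pos_weight <- sum(y == 0) / sum(y == 1)
  }
  x <- dataset_signals(train_ds)
  n <- dim(x)[3]
  pn <- param_names(model)
  adam <- list(m = stats::setNames(vector("list", length(pn)), pn),
               v = stats::setNames(vector("list", length(pn)), pn), t = 0)
  for (p in pn) {
    z <- get_param(model, p) * 0
    adam$m[[p]] <- z; adam$v[[p]] <- z
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(auroc = -Inf, model = NULL, epoch = 0L)
  history <- list()
  withr::with_seed(derive_seed(seed, "train"), {
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      losses <- numeric()
      for (i in seq(1, n, by = batch_size)) {
        j <- min(i + batch_size - 1, n)
        bi <- idx[i:j]
        xb <- x[, , bi, drop = FALSE]
        yb <- y[bi]
        fw <- forward_pass(model, xb, training = TRUE, keep_cache = TRUE)
        model <- fw$model
        losses <- c(losses, bce_loss(fw$logit, yb, pos_weight))
        dlogit <- bce_grad(fw$logit, yb, pos_weight)
        grads <- backward_params(model, fw$cache, dlogit)
        adam$t <- adam$t + 1
        bc1 <- 1 - b1^adam$t; bc2 <- 1 - b2^adam$t
        for (p in pn) {
          g <- grads[[p]]
          adam$m[[p]] <- b1 * adam$m[[p]] + (1 - b1) * g
          adam$v[[p]] <- b2 * adam$v[[p]] + (1 - b2) * g * g
          step <- lr * (adam$m[[p]] / bc1) / (sqrt(adam$v[[p]] / bc2) + eps)
          set_param(model, p, get_param(model, p) - step) -> model
        }
      }
      val_scores <- predict_proba(model, val_ds)
      va <- auroc(val_scores, y_val)
      history[[ep]] <- tibble::tibble(epoch = ep,
                                      train_loss = mean(losses),
                                      val_auroc = va)
      if (va > best$auroc) {
        best <- list(auroc = va, model = model, epoch = ep)
      } else if (ep - best$epoch >= patience) {
        break
      }
      if (!is.null(stop_auroc) && va >= stop_auroc) break
    }
  })
  model <- best$model
  model$trained <- TRUE
  model$val_auroc <- best$auroc
  model$history <- dplyr::bind_rows(history)
  val_scores <- predict_proba(model, val_ds)
  model$threshold <- youden_threshold(val_scores, y_val)
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname train_model
#' @param x An `ecg_model`. @param ... Unused.
tidy.ecg_model <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), train_loss = numeric(),
                                val_auroc = numeric())
}

#' @export
#' @rdname train_model
glance.ecg_model <- function(x, ...) {
  tibble::tibble(class = x$class_label, trained = x$trained,
                 n_conv_layers = x$cfg$n_conv_layers,
                 init_seed = x$init_seed,
                 train_seed = x$train_seed %||% NA_integer_,
                 val_auroc = x$val_auroc %||% NA_real_,
                 threshold = x$threshold %||% NA_real_)
}
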