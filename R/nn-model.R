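# 1D residual convolutional classifier. The network is a stack of residual
# blocks of two convolutions (kernel `kernel_size`, batch norm + ReLU +
# dropout after each convolution); every `halve_every` convolutional layers
# the channel dimension doubles and the spatial dimension halves (stride-2
# first convolution, matched by a 1-kernel projection shortcut). Global
# average pooling feeds a single linear unit; the model is a binary
# classifier whose pre-sigmoid output is the attribution target.

#' Model configuration
#'
#' @param n_conv_layers Total number of convolutional layers (even; two per
#'   residual block). The reference-scale architecture uses 22; the desk
#'   profile uses 8.
#' @param kernel_size Odd convolution kernel size (default 7).
#' @param base_channels Channel budget; block `i` carries
#'   `base_channels * 2^i` channels.
#' @param halve_every Number of conv layers between channel doublings /
#'   spatial halvings (must be an even multiple of 2).
#' @param dropout_rate Dropout probability during training.
#' @param input_leads Number of input channels (8 leads).
#' @param input_length Input length in samples.
#' @return A `model_config` list.
#' @export
#' @examples
#' model_config(n_conv_layers = 8, base_channels = 16, input_length = 600)
model_config <- function(n_conv_layers = 8L, kernel_size = 7L,
                         base_channels = 16L, halve_every = 2L,
                         dropout_rate = 0.1, input_leads = 8L,
                         input_length = 600L) {
  if (kernel_size %% 2 == 0) abort_config("kernel_size must be odd")
  if (n_conv_layers %% 2 != 0) abort_config("n_conv_layers must be even (two per residual block)")
  if (halve_every %% 2 != 0) abort_config("halve_every must be even (block granularity)")
  cfg <- list(n_conv_layers = as.integer(n_conv_layers),
              kernel_size = as.integer(kernel_size),
              base_channels = as.integer(base_channels),
              halve_every = as.integer(halve_every),
              dropout_rate = dropout_rate,
              input_leads = as.integer(input_leads),
              input_length = as.integer(input_length))
  # feasibility: the spatial dimension must stay at or above one sample
  # through every halving (input_length / 2^n_halvings >= 1)
  len <- as.numeric(cfg$input_length)
  for (b in seq_len(n_conv_layers %/% 2)) {
    if (block_halves(cfg, b)) {
      len <- len / 2
      if (len < 1) abort_config(sprintf(
        "spatial underflow: length drops below 1 sample at conv layer %d", 2L * b))
    }
  }
  structure(cfg, class = "model_config")
}

block_halves <- function(cfg, b) (2L * b) %% cfg$halve_every == 0L

block_channels <- function(cfg) {
  n_blocks <- cfg$n_conv_layers %/% 2L
  ch <- integer(n_blocks)
  c_cur <- cfg$base_channels
  for (b in seq_len(n_blocks)) {
    if (block_halves(cfg, b)) c_cur <- c_cur * 2L
    ch[b] <- c_cur
  }
  # first doubling is anchored so that base_channels doubles once per stage:
  # with halve_every = 2, block i has base * 2^i channels
  ch
}

init_block <- function(c_in, c_out, k, stride) {
  list(conv1 = conv1d_init(c_in, k, c_out), bn1 = bn_init(c_out),
       conv2 = conv1d_init(c_out, k, c_out), bn2 = bn_init(c_out),
       proj = if (stride != 1L || c_in != c_out) conv1d_init(c_in, 1L, c_out),
       stride = stride)
}

#' Build a randomly initialized task model
#'
#' @param cfg A [model_config()].
#' @param init_seed Integer seed; identical seeds give bit-identical
#'   parameters.
#' @return An `ecg_model` (untrained).
#' @export
build_model <- function(cfg, init_seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  ch <- block_channels(cfg)
  n_blocks <- length(ch)
  withr::with_seed(derive_seed(init_seed, "model_init"), {
    blocks <- vector("list", n_blocks)
    c_in <- cfg$input_leads
    for (b in seq_len(n_blocks)) {
      stride <- if (block_halves(cfg, b)) 2L else 1L
      blocks[[b]] <- init_block(c_in, ch[b], cfg$kernel_size, stride)
      c_in <- ch[b]
    }
    head <- list(w = stats::rnorm(c_in, 0, sqrt(1 / c_in)), b = 0)
    structure(list(cfg = cfg, blocks = blocks, head = head,
                   init_seed = init_seed, class_label = NA_character_,
                   trained = FALSE),
              class = "ecg_model")
  })
}

#' @export
print.ecg_model <- function(x, ...) {
  cat(sprintf("<ecg_model: %d conv layers, base %d channels, input 8 x %d%s%s>\n",
              x$cfg$n_conv_layers, x$cfg$base_channels, x$cfg$input_length,
              if (x$trained) ", trained" else ", untrained",
              if (!is.na(x$class_label)) paste0(", class ", x$class_label) else ""))
  invisible(x)
}

#' Forward pass
#'
#' @param model An `ecg_model` or `mlp_model`.
#' @param x Signal matrix `[8 x L]` or array `[8 x L x B]`.
#' @param training Use batch statistics, dropout and cache updates.
#' @param keep_cache Keep intermediate activations (needed for backward).
#' @return List with `logit` (length-B vector), `prob`, `model` (running
#'   statistics updated when training), and `cache` when requested.
#' @keywords internal
#' @export
forward_pass <- function(model, x, training = FALSE, keep_cache = FALSE) {
  UseMethod("forward_pass")
}

#' @export
forward_pass.ecg_model <- function(model, x, training = FALSE,
                                   keep_cache = FALSE) {
  x <- as_batch(x)
  cache <- if (keep_cache) list(blocks = vector("list", length(model$blocks)))
  h <- x
  drop_p <- if (training) model$cfg$dropout_rate else 0
  for (b in seq_along(model$blocks)) {
    blk <- model$blocks[[b]]
    c1 <- conv1d_fwd(blk$conv1, h, blk$stride)
    n1 <- bn_fwd(blk$bn1, c1$out, training)
    model$blocks[[b]]$bn1 <- n1$layer
    z1 <- n1$out
    h1 <- pmax(z1, 0)
    m1 <- NULL
    if (drop_p > 0) {
      m1 <- array((stats::runif(length(h1)) >= drop_p) / (1 - drop_p), dim(h1))
      h1 <- h1 * m1
    }
    c2 <- conv1d_fwd(blk$conv2, h1, 1L)
    n2 <- bn_fwd(blk$bn2, c2$out, training)
    model$blocks[[b]]$bn2 <- n2$layer
    if (is.null(blk$proj)) {
      s_out <- h; s_cache <- NULL
    } else {
      sp <- conv1d_fwd(blk$proj, h, blk$stride)
      s_out <- sp$out; s_cache <- sp$cache
    }
    zsum <- n2$out + s_out
    out <- pmax(zsum, 0)
    m2 <- NULL
    if (drop_p > 0) {
      m2 <- array((stats::runif(length(out)) >= drop_p) / (1 - drop_p), dim(out))
      out <- out * m2
    }
    if (keep_cache) {
      cache$blocks[[b]] <- list(x_in = h, c1 = c1$cache, z1 = z1, m1 = m1,
                                h1 = h1, c2 = c2$cache, bn1 = n1$cache,
                                bn2 = n2$cache, s_cache = s_cache,
                                zsum = zsum, out = out, m2 = m2)
    }
    h <- out
  }
  d <- dim(h)
  feat <- colSums(aperm(h, c(2, 1, 3))) / d[2]      # [C, B] global average pool
  feat <- matrix(feat, d[1], d[3])
  logit <- colSums(feat * model$head$w) + model$head$b
  if (keep_cache) {
    cache$feat <- feat
    cache$final_dim <- d
    cache$x_dim <- dim(x)
  }
  list(logit = logit, prob = 1 / (1 + exp(-logit)), model = model,
       cache = cache)
}

#' Predict probabilities for a dataset or signal array
#'
#' @param model A trained `ecg_model`.
#' @param data An `ecg_dataset`, a list of `ecg_record`s, or an array
#'   `[8 x L x N]`.
#' @param batch_size Records per forward batch.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict_proba <- function(model, data, batch_size = 256L) {
  x <- if (inherits(data, "ecg_dataset")) dataset_signals(data)
       else if (is.list(data)) {
         array(unlist(lapply(data, `[[`, "signal")),
               c(dim(data[[1]]$signal), length(data)))
       } else as_batch(data)
  n <- dim(x)[3]
  out <- numeric(n)
  for (i in seq(1, n, by = batch_size)) {
    j <- min(i + batch_size - 1, n)
    out[i:j] <- forward_pass(model, x[, , i:j, drop = FALSE])$prob
  }
  out
}

#' Enumerate weight-bearing layers, output-first
#'
#' Returns one entry per convolutional layer plus the linear classification
#' head, ordered from the output layer towards the input. Batch-norm
#' parameters and the projection shortcut are bundled with the convolution
#' they follow (the block's first convolution owns the projection).
#'
#' @param model An `ecg_model`.
#' @return Character vector of layer identifiers, first element `"head"`.
#' @export
enumerate_randomizable_layers <- function(model) {
  n_blocks <- length(model$blocks)
  out <- "head"
  for (b in rev(seq_len(n_blocks))) {
    out <- c(out, sprintf("b%d.conv2", b), sprintf("b%d.conv1", b))
  }
  out
}

#' Re-initialize the top k layers of a model
#'
#' Replaces the parameters of the first `k` entries of
#' [enumerate_randomizable_layers()] (output-first) with fresh
#' training-scheme initializations under `seed`. Batch-norm statistics and
#' affine parameters of a randomized convolution are reset, so no trained
#' information leaks through stale normalization. All other parameters are
#' bit-identical to the input model, which is left unmodified.
#'
#' @param model An `ecg_model`. @param k Number of layers, `0 <= k <= n+1`.
#' @param seed Integer seed.
#' @return A new `ecg_model`.
#' @export
randomize_top_k_layers <- function(model, k, seed = 1L) {
  layers <- enumerate_randomizable_layers(model)
  if (k < 0 || k > length(layers)) stop("k out of range [0, layer count]")
  if (k == 0) return(model)
  withr::with_seed(derive_seed(seed, "randomize", k), {
    for (ly in layers[seq_len(k)]) {
      if (ly == "head") {
        c_in <- length(model$head$w)
        model$head <- list(w = stats::rnorm(c_in, 0, sqrt(1 / c_in)), b = 0)
      } else {
        b <- as.integer(sub("^b(\\d+)\\..*$", "\\1", ly))
        which_conv <- sub("^b\\d+\\.", "", ly)
        blk <- model$blocks[[b]]
        if (which_conv == "conv2") {
          d <- dim(blk$conv2$w)
          model$blocks[[b]]$conv2 <- conv1d_init(d[1], d[2], d[3])
          model$blocks[[b]]$bn2 <- bn_init(d[3])
        } else {
          d <- dim(blk$conv1$w)
          model$blocks[[b]]$conv1 <- conv1d_init(d[1], d[2], d[3])
          model$blocks[[b]]$bn1 <- bn_init(d[3])
          if (!is.null(blk$proj)) {
            dp <- dim(blk$proj$w)
            model$blocks[[b]]$proj <- conv1d_init(dp[1], dp[2], dp[3])
          }
        }
      }
    }
  })
  model
}

#' Enumerate the class x seed training grid
#'
#' @param classes Character vector of class labels.
#' @param n_seeds Number of training repetitions per class.
#' @return Tibble with columns `class`, `seed`, class-major with ascending
#'   seeds; 9 classes x 10 seeds enumerate the full 90-model grid.
#' @export
#' @examples
#' nrow(experiment_grid(ecg_class_names(), 10))
experiment_grid <- function(classes, n_seeds) {
  if (length(classes) == 0) stop("empty class list")
  if (n_seeds < 1) stop("n_seeds must be >= 1")
  tidyr::expand_grid(class = classes, seed = seq_len(n_seeds))
}

#' Save / load a model
#'
#' Writes a single-file parameter archive plus a JSON sidecar describing the
#' configuration, seeds and (when present) validation metrics.
#'
#' @param model An `ecg_model`. @param path Archive path (sidecar gets
#'   `.json` appended).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  meta <- list(cfg = unclass(model$cfg), init_seed = model$init_seed,
               train_seed = model$train_seed %||% NA,
               class_label = model$class_label, trained = model$trained,
               val_auroc = model$val_auroc %||% NA,
               threshold = model$threshold %||% NA)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
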