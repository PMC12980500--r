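# Shared fixtures, memoized across test files. The trained models use the
# desk-depth architecture (8 conv layers: the receptive field must span the
# P-to-T extent for the timing-based classes) with a narrow channel budget so
# each training run stays in the tens of seconds.

fixture_env <- new.env(parent = emptyenv())
fixture_env$models <- list()

desk_model_config <- function(base_channels = 8L) {
  model_config(n_conv_layers = 8L, base_channels = base_channels,
               input_length = 600L)
}

fixture_splits <- function() {
  if (is.null(fixture_env$splits)) {
    ds <- generate_dataset(n_patients = 450, seed = 101)
    fixture_env$splits <- split_by_patient(ds, 60, 60, seed = 7)
  }
  fixture_env$splits
}

fixture_model <- function(class_name = "atrial_fibrillation", seed = 1L,
                          base_channels = 8L) {
  key <- sprintf("%s_%d_%d", class_name, seed, base_channels)
  if (is.null(fixture_env$models[[key]])) {
    sp <- fixture_splits()
    m <- build_model(desk_model_config(base_channels), init_seed = seed)
    fixture_env$models[[key]] <- train_model(
      m, sp$train, sp$validation, class_name,
      epochs = 10L, lr = 3e-3, batch_size = 128L, patience = 8L,
      seed = seed, stop_auroc = 0.93)
  }
  fixture_env$models[[key]]
}

# Balanced record subset of the fixture test split for one class.
fixture_eval_records <- function(class_name, n_pos = 15L, n_neg = 15L,
                                 seed = 11L) {
  sp <- fixture_splits()
  y <- dataset_labels(sp$test, class_name)
  idx <- withr::with_seed(seed, c(
    sample(which(y == 1), min(n_pos, sum(y == 1))),
    sample(which(y == 0), min(n_neg, sum(y == 0)))))
  sp$test$records[idx]
}

# Reduced attribution budgets for experiment-level tests.
fast_attr_config <- function() {
  ac <- attribution_config()
  ac$ig$n_steps <- 16L
  ac$smoothgrad$n_samples <- 8L
  ac$shapley$n_segments <- 10L
  ac$shapley$n_samples <- 16L
  ac$shap$n_baselines <- 4L
  ac
}

# Small untrained conv net for analytic/oracle checks.
toy_conv_model <- function(seed = 5L, L = 64L) {
  build_model(model_config(n_conv_layers = 4L, base_channels = 4L,
                           input_length = L), init_seed = seed)
}

# Linear model as a degenerate dense network: score = <w, x>.
linear_toy <- function(w_matrix) {
  mlp_model(list(matrix(as.vector(w_matrix), nrow = 1)),
            input_dim = dim(w_matrix))
}

random_signal <- function(L = 64L, seed = NULL, sd = 1) {
  gen <- function() matrix(stats::rnorm(8 * L, 0, sd), 8, L,
                           dimnames = list(ecgxai:::ECG_LEADS, NULL))
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Minimal full-pipeline configuration for determinism/orchestration tests.
tiny_config <- function(out_dir, seed = 5L) {
  cfg <- default_run_config()
  cfg$data$n_patients <- 30L
  cfg$data$n_val_patients <- 6L
  cfg$data$n_test_patients <- 6L
  cfg$model$n_conv_layers <- 4L
  cfg$model$base_channels <- 4L
  cfg$training$epochs <- 2L
  cfg$training$batch_size <- 128L
  cfg$grid$classes <- "sinus_rhythm"
  cfg$grid$n_seeds <- 2L
  cfg$methods <- c("saliency", "gradient_input", "deeplift", "gradcam")
  cfg$attribution$ig_steps <- 8L
  cfg$attribution$smoothgrad_samples <- 4L
  cfg$attribution$shapley_segments <- 6L
  cfg$attribution$shapley_samples <- 8L
  cfg$attribution$n_baselines <- 2L
  cfg$experiments$n_records <- 4L
  cfg$experiments$exp3_class <- "sinus_rhythm"
  cfg$experiments$exp4 <- list(n_steps = 4L, step_frac = 0.02,
                               noise_sd = 0.25,
                               noise_mode = "multiplicative",
                               include_controls = TRUE)
  cfg$output_dir <- out_dir
  cfg$seed <- seed
  cfg
}

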