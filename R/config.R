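# Run configuration: one human-editable YAML mapping; all defaults
# materialized at load time; all randomness funneled through a single global
# seed expanded per stage by fixed derivations.

#' Default run configuration
#'
#' @return Nested list with blocks `data`, `model`, `training`, `grid`,
#'   `methods`, `attribution`, `experiments`, plus `output_dir` and `seed`.
#' @export
default_run_config <- function() {
  list(
    data = list(n_patients = 120L, mean_records_per_patient = 4.5,
                prevalences = as.list(default_prevalences()),
                noise_sd = 0.03, record_length_s = 1.2, sampling_rate = 500L,
                n_val_patients = 20L, n_test_patients = 20L,
                wfdb_path = ""),
    model = list(n_conv_layers = 8L, kernel_size = 7L, base_channels = 16L,
                 halve_every = 2L, dropout_rate = 0.1),
    training = list(epochs = 12L, batch_size = 64L, lr = 1e-3, patience = 5L),
    grid = list(classes = "atrial_fibrillation", n_seeds = 2L),
    methods = attribution_methods(),
    attribution = list(ig_steps = 64L, smoothgrad_samples = 32L,
                       noise_frac = 0.1, shapley_segments = 32L,
                       shapley_samples = 256L, n_baselines = 16L),
    experiments = list(which = c("exp1", "exp2", "exp3", "exp4"),
                       n_records = 12L, smooth = TRUE, window = 31L,
                       polyorder = 3L, kind = "pearson", pooled = FALSE,
                       exp3_class = "atrial_fibrillation",
                       exp4 = list(n_steps = 30L, step_frac = 0.01,
                                   noise_sd = 0.25,
                                   noise_mode = "multiplicative",
                                   include_controls = TRUE)),
    output_dir = "ecgxai_runs", seed = 1L)
}

merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    key <- if (path == "") k else paste(path, k, sep = ".")
    if (!k %in% names(defaults)) {
      abort_config(sprintf("unknown configuration key '%s'", key))
    }
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]])) &&
        !k %in% c("prevalences", "classes", "methods", "which", "exp4")) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], key)
    } else if (k == "exp4" && is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], key)
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  methods <- unlist(cfg$methods)
  bad <- setdiff(methods, attribution_methods())
  if (length(bad) > 0) {
    abort_config(sprintf("unknown attribution method '%s'", bad[1]))
  }
  if (length(methods) == 0) abort_config("method list is empty")
  classes <- unlist(cfg$grid$classes)
  bad_cls <- setdiff(classes, ecg_class_names())
  if (length(bad_cls) > 0) {
    abort_config(sprintf("unknown class '%s'", bad_cls[1]))
  }
  if (!cfg$experiments$exp3_class %in% c(classes, ecg_class_names())) {
    abort_config("experiments.exp3_class is not a known class")
  }
  e4 <- cfg$experiments$exp4
  if (e4$n_steps * e4$step_frac > 1 + 1e-12) {
    abort_config("experiments.exp4: n_steps * step_frac exceeds 1")
  }
  model_config(cfg$model$n_conv_layers, cfg$model$kernel_size,
               cfg$model$base_channels, cfg$model$halve_every,
               cfg$model$dropout_rate, 8L,
               as.integer(round(cfg$data$record_length_s *
                                  cfg$data$sampling_rate)))
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a YAML mapping, overlays it on [default_run_config()] (unknown keys
#' are rejected by name), validates cross-field constraints, and echoes the
#' materialized configuration to the log.
#'
#' @param path YAML file path.
#' @param quiet Suppress the configuration echo.
#' @return The validated configuration list.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) abort_config(sprintf("config file '%s' not found", path))
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_run_config(), user %||% list())
  validate_config(cfg)
  if (!quiet) {
    message("configuration (defaults materialized):")
    message(yaml::as.yaml(cfg))
  }
  cfg
}

#' Write a configuration to YAML
#' @param cfg Configuration list. @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

attr_config_from <- function(cfg) {
  ac <- attribution_config()
  ac$ig$n_steps <- cfg$attribution$ig_steps
  ac$smoothgrad$n_samples <- cfg$attribution$smoothgrad_samples
  ac$smoothgrad$noise_frac <- cfg$attribution$noise_frac
  ac$shapley$n_segments <- cfg$attribution$shapley_segments
  ac$shapley$n_samples <- cfg$attribution$shapley_samples
  ac$shap$n_baselines <- cfg$attribution$n_baselines
  ac
}

exp_config_from <- function(cfg) {
  experiment_config(attr = attr_config_from(cfg),
                    smooth = cfg$experiments$smooth,
                    window = cfg$experiments$window,
                    polyorder = cfg$experiments$polyorder,
                    kind = cfg$experiments$kind,
                    pooled = cfg$experiments$pooled)
}
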