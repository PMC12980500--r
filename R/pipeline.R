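# Stage orchestration: simulate -> train -> attribute -> experiments ->
# report. Every stage writes its artifacts plus a JSON manifest holding the
# configuration hash and seeds; re-running an unchanged stage is a no-op.

stage_manifest_path <- function(dir) file.path(dir, "manifest.json")

stage_up_to_date <- function(dir, hash) {
  mp <- stage_manifest_path(dir)
  file.exists(mp) &&
    identical(jsonlite::read_json(mp)$config_hash, unname(hash))
}

write_stage_manifest <- function(dir, hash, cfg, extra = list()) {
  meta <- c(list(config_hash = unname(hash), seed = cfg$seed,
                 r_version = as.character(getRversion()),
                 flags = list(smooth = cfg$experiments$smooth,
                              kind = cfg$experiments$kind,
                              pooled = cfg$experiments$pooled,
                              noise_mode = cfg$experiments$exp4$noise_mode)),
            extra)
  jsonlite::write_json(meta, stage_manifest_path(dir), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

require_stage <- function(dir, producer) {
  if (!dir.exists(dir)) {
    stop(sprintf("missing prerequisite artifacts in '%s'; run the '%s' stage first",
                 dir, producer), call. = FALSE)
  }
}

model_path <- function(out, class, seed) {
  file.path(out, "models", sprintf("%s_s%02d.rds", class, seed))
}

log_msg <- function(level, quiet, ...) if (!quiet) message(sprintf(...))

#' Run pipeline stages
#'
#' Subcommands: `simulate` (synthetic dataset + patient-level split),
#' `train` (the class x seed grid of binary classifiers), `attribute`
#' (map store over the experiment record sample), `exp1`-`exp4` (the four
#' evaluations), `report` (CSV tables), or `all`. Stage outputs land under
#' `config$output_dir`; an unchanged stage (same configuration hash) is
#' skipped.
#'
#' @param config Configuration list from [load_config()] or
#'   [default_run_config()].
#' @param stage One of simulate, train, attribute, exp1, exp2, exp3, exp4,
#'   report, all.
#' @param quiet Suppress progress logging.
#' @return Invisibly, a list of in-memory results for the stages run.
#' @export
run_pipeline <- function(config, stage = "all", quiet = FALSE) {
  stage <- match.arg(stage, c("simulate", "train", "attribute", "exp1",
                              "exp2", "exp3", "exp4", "report", "all"))
  validate_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  stages <- if (stage == "all") {
    c("simulate", "train", "attribute", "exp1", "exp2", "exp3", "exp4", "report")
  } else stage
  if (stage == "report") stages <- c("exp1", "exp2", "exp3", "exp4", "report")
  for (st in stages) {
    results <- switch(st,
      simulate = pipeline_simulate(config, out, results, quiet),
      train = pipeline_train(config, out, results, quiet),
      attribute = pipeline_attribute(config, out, results, quiet),
      exp1 = pipeline_exp(config, out, results, quiet, "exp1"),
      exp2 = pipeline_exp(config, out, results, quiet, "exp2"),
      exp3 = pipeline_exp(config, out, results, quiet, "exp3"),
      exp4 = pipeline_exp(config, out, results, quiet, "exp4"),
      report = { write_report(results, file.path(out, "report")); results })
  }
  invisible(results)
}

pipeline_simulate <- function(cfg, out, results, quiet) {
  dir <- file.path(out, "dataset")
  hash <- content_hash(list(cfg$data, cfg$seed))
  if (!stage_up_to_date(dir, hash)) {
    log_msg("info", quiet, "simulate: generating %d patients", cfg$data$n_patients)
    ds <- generate_dataset(
      n_patients = cfg$data$n_patients,
      mean_records_per_patient = cfg$data$mean_records_per_patient,
      prevalences = unlist(cfg$data$prevalences),
      noise_sd = cfg$data$noise_sd,
      seed = derive_seed(cfg$seed, "simulate"),
      sampling_rate = cfg$data$sampling_rate,
      record_length_s = cfg$data$record_length_s)
    splits <- split_by_patient(ds, cfg$data$n_val_patients,
                               cfg$data$n_test_patients,
                               derive_seed(cfg$seed, "split"))
    split_col <- rep("train", nrow(ds$manifest))
    split_col[ds$manifest$record_id %in% splits$validation$manifest$record_id] <- "validation"
    split_col[ds$manifest$record_id %in% splits$test$manifest$record_id] <- "test"
    ds$manifest$split <- split_col
    write_dataset(ds, dir)
    write_stage_manifest(dir, hash, cfg)
  } else {
    log_msg("info", quiet, "simulate: up to date, skipping")
  }
  results$dataset <- read_dataset(dir)
  results$splits <- list(
    train = subset_dataset(results$dataset, results$dataset$manifest$split == "train"),
    validation = subset_dataset(results$dataset, results$dataset$manifest$split == "validation"),
    test = subset_dataset(results$dataset, results$dataset$manifest$split == "test"))
  results
}

pipeline_train <- function(cfg, out, results, quiet) {
  require_stage(file.path(out, "dataset"), "simulate")
  if (is.null(results$splits)) results <- pipeline_simulate(cfg, out, results, quiet)
  mdir <- file.path(out, "models")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  hash <- content_hash(list(cfg$data, cfg$model, cfg$training, cfg$grid, cfg$seed))
  grid <- experiment_grid(unlist(cfg$grid$classes), cfg$grid$n_seeds)
  mcfg <- model_config(cfg$model$n_conv_layers, cfg$model$kernel_size,
                       cfg$model$base_channels, cfg$model$halve_every,
                       cfg$model$dropout_rate, 8L,
                       as.integer(round(cfg$data$record_length_s *
                                          cfg$data$sampling_rate)))
  models <- list()
  metrics <- list()
  redo <- !stage_up_to_date(mdir, hash)
  for (i in seq_len(nrow(grid))) {
    cls <- grid$class[i]; sd_i <- grid$seed[i]
    mp <- model_path(out, cls, sd_i)
    if (redo || !file.exists(mp)) {
      log_msg("info", quiet, "train: %s seed %d", cls, sd_i)
      m <- build_model(mcfg, init_seed = derive_seed(cfg$seed, "init", cls, sd_i))
      m <- train_model(m, results$splits$train, results$splits$validation, cls,
                       epochs = cfg$training$epochs,
                       batch_size = cfg$training$batch_size,
                       lr = cfg$training$lr, patience = cfg$training$patience,
                       seed = derive_seed(cfg$seed, "train", cls, sd_i))
      save_model(m, mp)
    } else {
      m <- load_model(mp)
    }
    models[[sprintf("%s_s%02d", cls, sd_i)]] <- m
    sc <- predict_proba(m, results$splits$test)
    metrics[[length(metrics) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(class = cls, seed = sd_i),
      compute_metrics(sc, dataset_labels(results$splits$test, cls), m$threshold))
  }
  write_stage_manifest(mdir, hash, cfg)
  results$models <- models
  results$metrics <- dplyr::bind_rows(metrics)
  readr::write_csv(dplyr::mutate(results$metrics,
                                 dplyr::across(dplyr::where(is.numeric), signif6)),
                   file.path(mdir, "metrics.csv"))
  results
}

experiment_records <- function(cfg, results, class) {
  test <- results$splits$test
  y <- dataset_labels(test, class)
  n <- cfg$experiments$n_records
  # balanced draw so AUROC stays defined under perturbation
  pos <- which(y == 1); neg <- which(y == 0)
  k_pos <- max(1L, min(length(pos), n %/% 2L))
  k_neg <- max(1L, min(length(neg), n - k_pos))
  idx <- withr::with_seed(derive_seed(cfg$seed, "records", class), {
    c(sample(pos, k_pos), sample(neg, k_neg))
  })
  test$records[sort(idx)]
}

pipeline_attribute <- function(cfg, out, results, quiet) {
  require_stage(file.path(out, "models"), "train")
  if (is.null(results$models)) results <- pipeline_train(cfg, out, results, quiet)
  adir <- file.path(out, "maps")
  hash <- content_hash(list(cfg$methods, cfg$attribution, cfg$experiments$n_records, cfg$seed))
  ecfg <- exp_config_from(cfg)
  baselines <- draw_baselines(results$splits$train,
                              cfg$attribution$n_baselines,
                              derive_seed(cfg$seed, "baselines"))
  results$baselines <- baselines
  if (!stage_up_to_date(adir, hash)) {
    for (tag in names(results$models)) {
      m <- results$models[[tag]]
      recs <- experiment_records(cfg, results, m$class_label)
      for (meth in unlist(cfg$methods)) {
        log_msg("info", quiet, "attribute: %s / %s", tag, meth)
        maps <- lapply(seq_along(recs), function(i) {
          compute_attribution(m, recs[[i]]$signal, meth, ecfg$attr,
                              seed = derive_seed(cfg$seed, "maps", tag, i),
                              baselines = baselines)
        })
        write_attribution_maps(maps, file.path(adir, tag, paste0(meth, ".f32")))
      }
    }
    write_stage_manifest(adir, hash, cfg)
  } else {
    log_msg("info", quiet, "attribute: up to date, skipping")
  }
  results
}

pipeline_exp <- function(cfg, out, results, quiet, which_exp) {
  if (!which_exp %in% unlist(cfg$experiments$which)) return(results)
  require_stage(file.path(out, "models"), "train")
  if (is.null(results$models)) results <- pipeline_attribute(cfg, out, results, quiet)
  if (is.null(results$baselines)) {
    results$baselines <- draw_baselines(results$splits$train,
                                        cfg$attribution$n_baselines,
                                        derive_seed(cfg$seed, "baselines"))
  }
  ecfg <- exp_config_from(cfg)
  methods <- unlist(cfg$methods)
  log_msg("info", quiet, "running %s", which_exp)
  if (which_exp == "exp1") {
    # per-model matrices, aggregated over every trained (class, seed) model
    per_model <- lapply(names(results$models), function(tag) {
      m <- results$models[[tag]]
      recs <- experiment_records(cfg, results, m$class_label)
      r <- run_inter_method(m, recs, methods, ecfg,
                            seed = derive_seed(cfg$seed, "exp1", tag),
                            baselines = results$baselines)
      r$scores$model_tag <- tag
      r$scores$class <- m$class_label
      r
    })
    scores <- dplyr::bind_rows(lapply(per_model, `[[`, "scores"))
    agg <- aggregate_scores(scores, .data$method_a, .data$method_b)
    k <- length(methods)
    mean_m <- sd_m <- matrix(NA_real_, k, k,
                             dimnames = list(methods, methods))
    for (r in seq_len(nrow(agg))) {
      a <- agg$method_a[r]; b <- agg$method_b[r]
      mean_m[a, b] <- mean_m[b, a] <- agg$mean[r]
      sd_m[a, b] <- sd_m[b, a] <- agg$sd[r]
    }
    diag(mean_m) <- 1; diag(sd_m) <- 0
    results$exp1 <- structure(
      list(scores = scores, mean_matrix = mean_m, sd_matrix = sd_m,
           n_skipped = sum(vapply(per_model, `[[`, 0L, "n_skipped")),
           class = "all", kind = ecfg$kind),
      class = "inter_method_result")
  } else if (which_exp == "exp2") {
    by_class <- split(results$models,
                      vapply(results$models, `[[`, "", "class_label"))
    scores <- list()
    for (cls in names(by_class)) {
      if (length(by_class[[cls]]) < 2) {
        warning(sprintf("class %s has fewer than 2 seed models; skipped", cls))
        next
      }
      recs <- experiment_records(cfg, results, cls)
      r <- run_self_consistency(by_class[[cls]], recs, methods, ecfg,
                                seed = derive_seed(cfg$seed, "exp2", cls),
                                baselines = results$baselines)
      scores[[cls]] <- r$scores
    }
    all_scores <- dplyr::bind_rows(scores)
    results$exp2 <- structure(
      list(scores = all_scores,
           summary = aggregate_scores(all_scores, .data$method),
           by_class = aggregate_scores(all_scores, .data$method, .data$class)),
      class = "self_consistency_result")
  } else if (which_exp == "exp3") {
    cls <- cfg$experiments$exp3_class
    tag <- grep(paste0("^", cls, "_"), names(results$models), value = TRUE)[1]
    if (is.na(tag)) stop(sprintf("no trained model for exp3 class '%s'", cls))
    m <- results$models[[tag]]
    recs <- experiment_records(cfg, results, cls)
    results$exp3 <- run_cascading_randomization(
      m, recs, methods, ecfg, seed = derive_seed(cfg$seed, "exp3"),
      eval_ds = results$splits$test, baselines = results$baselines)
  } else if (which_exp == "exp4") {
    # average trajectories over the available seed models of the first class
    cls <- results$models[[1]]$class_label
    tags <- names(results$models)[vapply(results$models, `[[`, "",
                                         "class_label") == cls]
    recs <- experiment_records(cfg, results, cls)
    e4 <- cfg$experiments$exp4
    meths <- methods
    if (isTRUE(e4$include_controls)) {
      meths <- c(meths, "random_ranking", "oracle_mask")
    }
    per_seed <- lapply(tags, function(tag) {
      tr <- run_perturbation(
        results$models[[tag]], recs, meths, n_steps = e4$n_steps,
        step_frac = e4$step_frac, noise_sd = e4$noise_sd,
        noise_mode = e4$noise_mode, cfg = ecfg,
        seed = derive_seed(cfg$seed, "exp4", tag),
        baselines = results$baselines)
      dplyr::mutate(tibble::as_tibble(tr), model_tag = tag)
    })
    avg <- dplyr::bind_rows(per_seed) |>
      dplyr::group_by(.data$method, .data$step, .data$cumulative_fraction) |>
      dplyr::summarise(auroc = mean(.data$auroc), n_models = dplyr::n(),
                       .groups = "drop")
    results$exp4 <- structure(avg, class = c("perturbation_trajectory",
                                             class(avg)))
  }
  results
}

#' Write experiment reports as CSV
#'
#' Similarity matrices become square CSVs with a method-order header
#' (mirrored, unit diagonal); trajectories become long-format CSVs with
#' columns (step, method, metric, mean, sd, n). Floats are fixed to 6
#' significant digits so identical runs produce byte-identical files.
#'
#' @param results List of experiment results from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  num6 <- function(df) dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                                       signif6))
  if (!is.null(results$exp1)) {
    write_similarity_matrix(results$exp1$mean_matrix,
                            file.path(dir, "exp1_mean_matrix.csv"))
    write_similarity_matrix(results$exp1$sd_matrix,
                            file.path(dir, "exp1_sd_matrix.csv"))
    readr::write_csv(num6(results$exp1$scores),
                     file.path(dir, "exp1_scores.csv"))
  }
  if (!is.null(results$exp2)) {
    readr::write_csv(num6(results$exp2$summary),
                     file.path(dir, "exp2_self_consistency.csv"))
    if (!is.null(results$exp2$by_class)) {
      readr::write_csv(num6(results$exp2$by_class),
                       file.path(dir, "exp2_by_class.csv"))
    }
  }
  if (!is.null(results$exp3)) {
    traj <- dplyr::mutate(results$exp3$trajectory, metric = "pearson_to_step0",
                          .after = "method")
    readr::write_csv(num6(traj), file.path(dir, "exp3_trajectory.csv"))
    readr::write_csv(num6(results$exp3$auroc), file.path(dir, "exp3_auroc.csv"))
  }
  if (!is.null(results$exp4)) {
    readr::write_csv(num6(tibble::as_tibble(results$exp4)),
                     file.path(dir, "exp4_trajectory.csv"))
  }
  if (!is.null(results$metrics)) {
    readr::write_csv(num6(results$metrics), file.path(dir, "model_metrics.csv"))
  }
  invisible(dir)
}

#' Write / read a square similarity matrix CSV
#'
#' @param m Square numeric matrix with method dimnames.
#' @param path CSV path.
#' @return The matrix (read) or `path` invisibly (write).
#' @export
write_similarity_matrix <- function(m, path) {
  df <- tibble::as_tibble(signif6(m), rownames = "method")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$method
  m
}
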