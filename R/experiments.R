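# The four evaluation experiments: inter-method similarity, self-consistency
# across training seeds, cascading layer randomization, and remove-and-debias
# input perturbation.

#' Experiment settings
#'
#' @param attr [attribution_config()] hyperparameters.
#' @param smooth Smooth maps (Savitzky-Golay) before correlation-based
#'   experiments; the perturbation ranking always uses raw maps.
#' @param window,polyorder Savitzky-Golay settings (31-sample window,
#'   third-order polynomial).
#' @param kind Correlation kind, `"pearson"` or `"spearman"`.
#' @param pooled Pooled-flatten correlation instead of per-lead-then-average.
#' @return Named list of experiment settings.
#' @export
experiment_config <- function(attr = attribution_config(), smooth = TRUE,
                              window = 31L, polyorder = 3L,
                              kind = "pearson", pooled = FALSE) {
  list(attr = attr, smooth = smooth, window = window, polyorder = polyorder,
       kind = kind, pooled = pooled)
}

maybe_smooth <- function(map, cfg) {
  if (isTRUE(cfg$smooth)) savgol_smooth(map, cfg$window, cfg$polyorder)
  else map
}

record_signal <- function(r) if (inherits(r, "ecg_record")) r$signal else r
record_id_of <- function(r, i) {
  if (inherits(r, "ecg_record")) r$record_id else sprintf("record%03d", i)
}

compute_method_maps <- function(model, x, methods, cfg, seed, baselines) {
  out <- stats::setNames(vector("list", length(methods)), methods)
  for (m in methods) {
    out[[m]] <- tryCatch(
      compute_attribution(model, x, m, cfg$attr, seed = seed,
                          baselines = baselines),
      error = function(e) {
        warning(sprintf("attribution method '%s' failed: %s", m,
                        conditionMessage(e)))
        NULL
      })
  }
  out
}

#' Experiment 1: inter-method similarity
#'
#' For every record, attribution maps for all methods on the same model are
#' pairwise correlated (after smoothing) and the scores aggregated into a
#' symmetric method x method matrix with unit diagonal.
#'
#' @param model A trained `ecg_model`.
#' @param records List of `ecg_record`s (or `[8 x L]` matrices).
#' @param methods Character vector of >= 2 method ids.
#' @param cfg [experiment_config()].
#' @param seed Integer seed for stochastic methods.
#' @param baselines Optional baseline array for the SHAP variants.
#' @return An `inter_method_result`: `scores` tibble (record, method pair,
#'   value), `mean_matrix`, `sd_matrix`, `n_skipped`.
#' @export
run_inter_method <- function(model, records, methods, cfg = experiment_config(),
                             seed = 1L, baselines = NULL) {
  if (length(methods) < 2) stop("inter-method similarity needs >= 2 methods")
  scores <- list()
  n_skipped <- 0L
  for (i in seq_along(records)) {
    x <- record_signal(records[[i]])
    maps <- compute_method_maps(model, x, methods, cfg,
                                derive_seed(seed, "exp1", i), baselines)
    sm <- lapply(maps, function(m) if (!is.null(m)) maybe_smooth(m, cfg))
    for (a in seq_along(methods)) for (b in seq_len(a)) {
      ma <- sm[[methods[a]]]; mb <- sm[[methods[b]]]
      if (is.null(ma) || is.null(mb)) { n_skipped <- n_skipped + 1L; next }
      s <- similarity(ma, mb, cfg$kind, cfg$pooled)
      scores[[length(scores) + 1L]] <- tibble::tibble(
        record_id = record_id_of(records[[i]], i),
        method_a = methods[a], method_b = methods[b],
        value = if (a == b) 1 else s$value,
        degenerate_flag = s$degenerate_flag)
    }
  }
  scores <- dplyr::bind_rows(scores)
  agg <- aggregate_scores(scores, .data$method_a, .data$method_b)
  k <- length(methods)
  mean_m <- sd_m <- matrix(NA_real_, k, k, dimnames = list(methods, methods))
  for (r in seq_len(nrow(agg))) {
    a <- agg$method_a[r]; b <- agg$method_b[r]
    mean_m[a, b] <- mean_m[b, a] <- agg$mean[r]
    sd_m[a, b] <- sd_m[b, a] <- agg$sd[r]
  }
  diag(mean_m) <- 1; diag(sd_m) <- 0
  structure(list(scores = scores, mean_matrix = mean_m, sd_matrix = sd_m,
                 n_skipped = n_skipped, class = model$class_label,
                 kind = cfg$kind),
            class = "inter_method_result")
}

#' Experiment 2: self-consistency across training seeds
#'
#' Correlates each method's maps across models trained with different random
#' initializations on the same data; all unordered seed pairs contribute.
#'
#' @param models_by_seed List of >= 2 trained `ecg_model`s for one class.
#' @inheritParams run_inter_method
#' @return A `self_consistency_result` with per-pair `scores` and a
#'   per-method aggregate `summary` tibble.
#' @export
run_self_consistency <- function(models_by_seed, records, methods,
                                 cfg = experiment_config(), seed = 1L,
                                 baselines = NULL) {
  s <- length(models_by_seed)
  if (s < 2) {
    warning("self-consistency needs >= 2 seed models; skipping")
    return(NULL)
  }
  cls <- models_by_seed[[1]]$class_label
  scores <- list()
  for (i in seq_along(records)) {
    x <- record_signal(records[[i]])
    maps <- lapply(seq_len(s), function(si) {
      mm <- compute_method_maps(models_by_seed[[si]], x, methods, cfg,
                                derive_seed(seed, "exp2", i), baselines)
      lapply(mm, function(m) if (!is.null(m)) maybe_smooth(m, cfg))
    })
    for (m in methods) for (a in seq_len(s - 1)) for (b in (a + 1):s) {
      ma <- maps[[a]][[m]]; mb <- maps[[b]][[m]]
      if (is.null(ma) || is.null(mb)) next
      sc <- similarity(ma, mb, cfg$kind, cfg$pooled)
      scores[[length(scores) + 1L]] <- tibble::tibble(
        record_id = record_id_of(records[[i]], i), method = m,
        seed_a = a, seed_b = b, class = cls,
        value = sc$value, degenerate_flag = sc$degenerate_flag)
    }
  }
  scores <- dplyr::bind_rows(scores)
  structure(list(scores = scores,
                 summary = aggregate_scores(scores, .data$method),
                 class = cls, n_seed_pairs = s * (s - 1) / 2),
            class = "self_consistency_result")
}

#' Experiment 3: cascading layer randomization
#'
#' Progressively re-initializes layers from the output towards the input;
#' after each step, fresh maps are correlated against the trained-model maps
#' and model AUROC is re-evaluated.
#'
#' @inheritParams run_inter_method
#' @param eval_ds Optional labeled `ecg_dataset` for per-step AUROC.
#' @return A `randomization_trajectory`: `trajectory` tibble (step, method,
#'   mean, sd, n) and `auroc` tibble (step, auroc).
#' @export
run_cascading_randomization <- function(model, records, methods,
                                        cfg = experiment_config(), seed = 1L,
                                        eval_ds = NULL, baselines = NULL) {
  if (length(records) == 0) stop("no records supplied")
  layers <- enumerate_randomizable_layers(model)
  steps <- 0:length(layers)
  y <- if (!is.null(eval_ds)) dataset_labels(eval_ds, model$class_label)
  base_maps <- lapply(seq_along(records), function(i) {
    mm <- compute_method_maps(model, record_signal(records[[i]]), methods,
                              cfg, derive_seed(seed, "exp3", i, 0), baselines)
    lapply(mm, function(m) if (!is.null(m)) maybe_smooth(m, cfg))
  })
  rows <- list()
  auroc_rows <- list()
  for (k in steps) {
    mk <- randomize_top_k_layers(model, k, derive_seed(seed, "exp3rand"))
    if (!is.null(eval_ds)) {
      auroc_rows[[k + 1L]] <- tibble::tibble(
        step = k, auroc = auroc(predict_proba(mk, eval_ds), y))
    }
    for (i in seq_along(records)) {
      mm <- compute_method_maps(mk, record_signal(records[[i]]), methods, cfg,
                                derive_seed(seed, "exp3", i, k), baselines)
      for (m in methods) {
        m0 <- base_maps[[i]][[m]]
        mkmap <- mm[[m]]
        if (is.null(m0) || is.null(mkmap)) next
        sc <- similarity(m0, maybe_smooth(mkmap, cfg), cfg$kind, cfg$pooled)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          step = k, method = m, record_id = record_id_of(records[[i]], i),
          value = sc$value, degenerate_flag = sc$degenerate_flag)
      }
    }
  }
  scores <- dplyr::bind_rows(rows)
  structure(list(scores = scores,
                 trajectory = aggregate_scores(scores, .data$step, .data$method),
                 auroc = dplyr::bind_rows(auroc_rows),
                 class = model$class_label, layers = layers),
            class = "randomization_trajectory")
}

#' One remove-and-debias perturbation step
#'
#' Replaces the highest-ranked `ceiling(step_frac * 8 * L)` not-yet-masked
#' points by a linear interpolation of their nearest unmasked neighbours on
#' the same lead, multiplied by (multiplicative mode) or summed with
#' (additive mode) Gaussian noise. Boundary points extend the nearest
#' unmasked value; a fully masked lead row falls back to zero. Draws from the
#' current RNG stream; callers seed.
#'
#' @param signal `[8 x L]` matrix (current, possibly already perturbed).
#' @param cumulative_mask Logical `[8 x L]` matrix of already-perturbed points.
#' @param ranking Linear-index ranking from [rank_points_abs()].
#' @param step_frac Fraction of all points to add this step, in (0, 1].
#' @param noise_sd Noise SD (multiplicative: around 1; additive: millivolts).
#' @param noise_mode `"multiplicative"` or `"additive"`.
#' @return List with the updated `signal` and `mask`.
#' @export
perturb_step <- function(signal, cumulative_mask, ranking, step_frac,
                         noise_sd = 0.25,
                         noise_mode = c("multiplicative", "additive")) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(step_frac > 0, step_frac <= 1)
  n_total <- length(signal)
  if (all(cumulative_mask)) stop("perturbation mask already covers all points")
  n_new <- ceiling(step_frac * n_total)
  avail <- ranking[!cumulative_mask[ranking]]
  sel <- avail[seq_len(min(n_new, length(avail)))]
  mask <- cumulative_mask
  mask[sel] <- TRUE
  out <- signal
  nl <- nrow(signal)
  leads <- ((sel - 1L) %% nl) + 1L
  times <- ((sel - 1L) %/% nl) + 1L
  noise <- if (noise_mode == "multiplicative") {
    stats::rnorm(length(sel), 1, noise_sd)
  } else {
    stats::rnorm(length(sel), 0, noise_sd)
  }
  for (ld in unique(leads)) {
    ts <- times[leads == ld]
    u <- which(!mask[ld, ])
    if (length(u) == 0) {
      v <- rep(0, length(ts))
    } else {
      li <- findInterval(ts, u)
      v <- numeric(length(ts))
      for (q in seq_along(ts)) {
        l <- if (li[q] >= 1) u[li[q]] else NA
        r <- if (li[q] < length(u)) u[li[q] + 1L] else NA
        v[q] <- if (is.na(l)) signal[ld, r]
                else if (is.na(r)) signal[ld, l]
                else signal[ld, l] +
                  (signal[ld, r] - signal[ld, l]) * (ts[q] - l) / (r - l)
      }
    }
    nz <- noise[leads == ld]
    out[ld, ts] <- if (noise_mode == "multiplicative") v * nz else v + nz
  }
  list(signal = out, mask = mask)
}

#' Experiment 4: remove-and-debias perturbation curves
#'
#' Ranks points once per record from the raw absolute attribution values,
#' then applies `n_steps` cumulative perturbation steps of `step_frac` of all
#' points each, re-running inference after every step. Besides the twelve
#' attribution methods, the controls `"random_ranking"` (uniform random
#' order) and `"oracle_mask"` (ground-truth relevance mask first) are
#' accepted.
#'
#' @inheritParams run_inter_method
#' @param records List of labeled `ecg_record`s containing both classes.
#' @param n_steps,step_frac Schedule (default 1 percent x 30 steps, i.e. 30
#'   percent of points perturbed in total); `n_steps * step_frac <= 1`.
#' @param noise_sd,noise_mode Debias noise (default multiplicative,
#'   sigma 0.25).
#' @return A `perturbation_trajectory` tibble-backed object: columns
#'   `method`, `step`, `cumulative_fraction`, `auroc`.
#' @export
run_perturbation <- function(model, records, methods, n_steps = 30L,
                             step_frac = 0.01, noise_sd = 0.25,
                             noise_mode = "multiplicative",
                             cfg = experiment_config(), seed = 1L,
                             baselines = NULL) {
  if (n_steps * step_frac > 1 + 1e-12) {
    abort_config("n_steps * step_frac must not exceed 1")
  }
  y <- vapply(records, function(r) r$labels[[model$class_label]], integer(1))
  if (length(unique(y)) < 2) stop("perturbation records must contain both classes")
  sig0 <- lapply(records, record_signal)
  n_total <- length(sig0[[1]])
  rows <- list()
  for (m in methods) {
    rankings <- lapply(seq_along(records), function(i) {
      if (m == "random_ranking") {
        withr::with_seed(derive_seed(seed, "rand_rank", i),
                         sample.int(n_total))
      } else if (m == "oracle_mask") {
        mk <- records[[i]]$relevance_mask
        if (is.null(mk)) stop("oracle_mask control needs relevance masks")
        rank_points_abs(mk)
      } else {
        map <- compute_attribution(model, sig0[[i]], m, cfg$attr,
                                   seed = derive_seed(seed, "exp4", i),
                                   baselines = baselines)
        rank_points_abs(map)      # raw absolute values, no smoothing
      }
    })
    sigs <- sig0
    masks <- lapply(sig0, function(s) array(FALSE, dim(s)))
    score0 <- predict_batch(model, sigs)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      method = m, step = 0L, cumulative_fraction = 0,
      auroc = auroc(score0, y))
    for (st in seq_len(n_steps)) {
      withr::with_seed(derive_seed(seed, "exp4step", m, st), {
        for (i in seq_along(records)) {
          ps <- perturb_step(sigs[[i]], masks[[i]], rankings[[i]], step_frac,
                             noise_sd, noise_mode)
          sigs[[i]] <- ps$signal
          masks[[i]] <- ps$mask
        }
      })
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = m, step = st,
        cumulative_fraction = mean(masks[[1]]),
        auroc = auroc(predict_batch(model, sigs), y))
    }
  }
  structure(dplyr::bind_rows(rows), class = c("perturbation_trajectory",
                                              "tbl_df", "tbl", "data.frame"))
}

predict_batch <- function(model, signals) {
  x <- array(unlist(signals), c(dim(signals[[1]]), length(signals)))
  predict_proba(model, x)
}
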