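# The four evaluation experiments on desk-scale fixtures.

fast_cfg <- function(...) {
  experiment_config(attr = fast_attr_config(), ...)
}

test_that("inter-method similarity matrices are symmetric with unit diagonal", {
  m <- fixture_model("atrial_fibrillation", 1)
  recs <- fixture_eval_records("atrial_fibrillation", 2, 2)[1:3]
  methods <- c("saliency", "gradient_input", "integrated_gradients", "gradcam")
  r <- run_inter_method(m, recs, methods, fast_cfg(), seed = 3)
  expect_identical(r$mean_matrix, t(r$mean_matrix))
  expect_equal(unname(diag(r$mean_matrix)), rep(1, 4))
  expect_true(all(abs(r$mean_matrix) <= 1 + 1e-12))
  # duplicated method: off-diagonal self-pair scores exactly 1
  r2 <- run_inter_method(m, recs[1], c("saliency", "saliency"), fast_cfg(),
                         seed = 3)
  expect_equal(unname(r2$mean_matrix["saliency", "saliency"]), 1)
  expect_error(run_inter_method(m, recs, "saliency", fast_cfg()), ">= 2")
})

test_that("IG and zero-noise GradientSHAP converge to the same path integral", {
  m <- fixture_model("atrial_fibrillation", 1)
  x <- fixture_eval_records("atrial_fibrillation", 2, 2)[[1]]$signal
  ig <- integrated_gradients(m, x, n_steps = 128)
  gs <- gradient_shap(m, x, array(0, c(8, 600, 1)), n_samples = 512,
                      noise_sd = 0, seed = 5)
  expect_gt(similarity(ig, gs)$value, 0.97)
})

test_that("self-consistency is exactly 1 for identical models and low for
          random ones", {
  m <- fixture_model("atrial_fibrillation", 1)
  recs <- fixture_eval_records("atrial_fibrillation", 2, 2)[1:2]
  methods <- c("saliency", "gradient_input", "deeplift")
  r <- run_self_consistency(list(m, m), recs, methods, fast_cfg(), seed = 2)
  expect_true(all(r$scores$value == 1))
  expect_equal(nrow(r$scores), length(methods) * length(recs))  # 1 pair each
  # 4 seed models give 6 unordered pairs per method and record
  r4 <- run_self_consistency(list(m, m, m, m), recs[1], "saliency",
                             fast_cfg(), seed = 2)
  expect_equal(nrow(r4$scores), 6)
  # untrained (random) models agree weakly for signed gradient methods
  cfg <- desk_model_config()
  rnd <- lapply(1:2, function(s) {
    mm <- build_model(cfg, init_seed = 100 + s)
    mm$class_label <- "atrial_fibrillation"
    mm
  })
  rr <- run_self_consistency(rnd, fixture_eval_records("atrial_fibrillation",
                                                       3, 3),
                             "gradient_input", fast_cfg(), seed = 4)
  expect_lt(abs(mean(rr$scores$value)), 0.4)
  expect_warning(run_self_consistency(list(m), recs, methods, fast_cfg()),
                 ">= 2 seed")
})

test_that("cascading randomization starts at correlation 1 and degrades to
          chance performance", {
  m <- fixture_model("atrial_fibrillation", 1)
  recs <- fixture_eval_records("atrial_fibrillation", 2, 2)[1:4]
  sp <- fixture_splits()
  y <- dataset_labels(sp$test, "atrial_fibrillation")
  n1 <- min(15L, sum(y == 1)); n0 <- 30L
  eval_idx <- withr::with_seed(9, c(sample(which(y == 1), n1),
                                    sample(which(y == 0), n0)))
  eval_ds <- ecgxai:::subset_dataset(sp$test,
                                     seq_along(sp$test$records) %in% eval_idx)
  methods <- c("saliency", "integrated_gradients", "gradient_input")
  r <- run_cascading_randomization(m, recs, methods, fast_cfg(), seed = 6,
                                   eval_ds = eval_ds)
  step0 <- dplyr::filter(r$trajectory, step == 0)
  expect_true(all(abs(step0$mean - 1) < 1e-12))
  expect_equal(r$auroc$auroc[r$auroc$step == 0], m$val_auroc,
               tolerance = 0.35)  # same model, different (test) records
  # fully randomized model performs at chance
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  final_auroc <- r$auroc$auroc[which.max(r$auroc$step)]
  expect_lt(abs(final_auroc - 0.5), 3 * se)
  # correlation at full randomization is below the first-step value for IG
  ig <- dplyr::filter(r$trajectory, method == "integrated_gradients")
  expect_lt(ig$mean[ig$step == max(ig$step)], ig$mean[ig$step == 1])
})

test_that("perturbation steps interpolate, add noise, and grow the mask by a
          fixed count", {
  sig <- matrix(seq(0, 1.5, length.out = 16), 1, 16)[rep(1, 8), ]
  msk <- array(FALSE, dim(sig))
  target <- 3 + 8 * (8 - 1)          # lead 3, t = 8
  rk <- c(target, setdiff(rank_points_abs(sig), target))
  ps <- withr::with_seed(1, perturb_step(sig, msk, rk, 1 / 128, noise_sd = 0))
  expect_equal(ps$signal[3, 8], (sig[3, 7] + sig[3, 9]) / 2)  # midpoint
  expect_equal(sum(ps$mask), 1)
  expect_equal(ps$signal[-target], sig[-target])   # untouched elsewhere
  # boundary point: one-sided constant extension
  rk2 <- c(3 + 8 * (1 - 1), setdiff(rank_points_abs(sig), 3))
  ps2 <- withr::with_seed(1, perturb_step(sig, msk, rk2, 1 / 128,
                                          noise_sd = 0))
  expect_equal(ps2$signal[3, 1], sig[3, 2])
  # step_frac = 1 masks everything in one step
  ps_all <- withr::with_seed(1, perturb_step(sig, msk, rank_points_abs(sig),
                                             1, noise_sd = 0))
  expect_true(all(ps_all$mask))
  expect_error(perturb_step(sig, ps_all$mask, rank_points_abs(sig), 0.01),
               "already covers")
  # multiplicative noise multiplies the interpolated value
  ps_n <- withr::with_seed(7, perturb_step(sig, msk, rk, 1 / 128,
                                           noise_sd = 0.25))
  fac <- withr::with_seed(7, stats::rnorm(1, 1, 0.25))
  expect_equal(ps_n$signal[3, 8], (sig[3, 7] + sig[3, 9]) / 2 * fac)
  # additive mode adds it
  ps_a <- withr::with_seed(7, perturb_step(sig, msk, rk, 1 / 128,
                                           noise_sd = 0.25,
                                           noise_mode = "additive"))
  nz <- withr::with_seed(7, stats::rnorm(1, 0, 0.25))
  expect_equal(ps_a$signal[3, 8], (sig[3, 7] + sig[3, 9]) / 2 + nz)
})

test_that("the paper perturbation schedule covers exactly 30% of points and
          step-0 AUROC is method-independent", {
  m <- fixture_model("atrial_fibrillation", 1)
  recs <- fixture_eval_records("atrial_fibrillation", 6, 6)
  r <- run_perturbation(m, recs, c("saliency", "random_ranking"),
                        n_steps = 5, step_frac = 0.02, cfg = fast_cfg(),
                        seed = 3)
  t0 <- dplyr::filter(tibble::as_tibble(r), step == 0)
  expect_equal(t0$auroc[1], t0$auroc[2])
  tb <- tibble::as_tibble(r)
  expect_true(all(diff(dplyr::filter(tb, method == "saliency")$cumulative_fraction) > 0))
  expect_error(run_perturbation(m, recs, "saliency", n_steps = 60,
                                step_frac = 0.02), "exceed")
})
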