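# The twelve attribution methods against analytic closed forms,
# finite-difference oracles, hand-worked examples, and their defining axioms.

fd_gradient <- function(model, x, h = 1e-3) {
  g <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    xp <- x; xp[i, j] <- xp[i, j] + h
    xm <- x; xm[i, j] <- xm[i, j] - h
    g[i, j] <- (forward_pass(model, xp)$logit -
                  forward_pass(model, xm)$logit) / (2 * h)
  }
  g
}

test_that("gradient methods reduce to closed forms on a linear model", {
  W <- withr::with_seed(3, matrix(rnorm(8 * 16), 8, 16))
  lm_ <- linear_toy(W)
  x <- random_signal(16, seed = 4)
  expect_equal(unname(saliency(lm_, x)$values), abs(W))
  gi <- gradient_input(lm_, x)
  expect_equal(unname(gi$values), unname(x * W))
  expect_equal(sum(gi$values), forward_pass(lm_, x)$logit)  # zero bias
  expect_true(all(gradient_input(lm_, x * 0)$values == 0))
  # model constant in one lead: its saliency row is zero
  W0 <- W; W0[3, ] <- 0
  expect_true(all(saliency(linear_toy(W0), x)$values[3, ] == 0))
  # IG is exact for any step count on a linear model
  b <- withr::with_seed(5, random_signal(16))
  for (ns in c(1, 7)) {
    expect_equal(unname(integrated_gradients(lm_, x, b, ns)$values),
                 unname((x - b) * W), tolerance = 1e-12)
  }
  expect_true(all(integrated_gradients(lm_, x, x, 8)$values == 0))
  expect_error(integrated_gradients(lm_, x, b, 0), "n_steps")
  # DeepLift rescale is exact on a linear model
  expect_equal(unname(deeplift_rescale(lm_, x, b)$values),
               unname((x - b) * W), tolerance = 1e-12)
})

test_that("gradient methods match a finite-difference oracle on ReLU nets", {
  # tiny 2-layer ReLU net with hand-set weights
  w1 <- withr::with_seed(8, matrix(rnorm(4 * 16, 0, 0.6), 4, 16))
  w2 <- matrix(c(1, -2, 0.5, 1.5), 1, 4)
  net <- mlp_model(list(w1, w2), input_dim = c(2, 8))
  x <- withr::with_seed(9, matrix(rnorm(16), 2, 8))
  g <- ecgxai:::input_gradient(net, x)$dx[, , 1]
  fd <- fd_gradient(net, x)
  expect_lt(max(abs(g - fd)), 1e-4)
  expect_equal(unname(gradient_input(net, x)$values), unname(x * g))
  # and on the small convolutional net
  cm <- toy_conv_model(seed = 2)
  xc <- random_signal(64, seed = 3)
  expect_lt(max(abs(ecgxai:::input_gradient(cm, xc)$dx[, , 1] -
                      fd_gradient(cm, xc))), 1e-4)
})

test_that("DeepLift satisfies summation-to-delta and a hand-worked example", {
  cm <- fixture_model("atrial_fibrillation", 1)
  x <- fixture_eval_records("atrial_fibrillation", 2, 2)[[1]]$signal
  b <- x * 0
  dl <- deeplift_rescale(cm, x, b)
  delta <- forward_pass(cm, x)$logit - forward_pass(cm, b)$logit
  expect_lt(abs(sum(dl$values) - delta), 1e-6)
  # hand-tracked example: y = relu(x1 - x2) + relu(x2), baseline 0
  # x = (3, 1): z1 = 2 (ref 0, m = 1), z2 = 1 (ref 0, m = 1)
  # multipliers back to x: d x1 = 1, d x2 = -1 + 1 = 0
  w1 <- matrix(c(1, 0, -1, 1), 2, 2)   # rows: (x1 - x2), x2
  w2 <- matrix(c(1, 1), 1, 2)
  net <- mlp_model(list(w1, w2), input_dim = c(1, 2))
  dlh <- deeplift_rescale(net, matrix(c(3, 1), 1, 2))
  expect_equal(unname(dlh$values), matrix(c(3 * 1, 1 * 0), 1, 2))
})

test_that("integrated gradients is complete on the trained desk model", {
  cm <- fixture_model("atrial_fibrillation", 1)
  x <- fixture_eval_records("atrial_fibrillation", 2, 2)[[3]]$signal
  ig <- integrated_gradients(cm, x, n_steps = 512)
  delta <- forward_pass(cm, x)$logit - forward_pass(cm, x * 0)$logit
  expect_lt(abs(sum(ig$values) - delta), 0.01 * abs(delta) + 1e-4)
})

test_that("guided backpropagation gates match hand-derived behaviour", {
  # single ReLU y = relu(w . x) with w . x < 0: dead unit, zero map
  w1 <- matrix(rep(1, 4), 1, 4)
  net <- mlp_model(list(w1, matrix(1, 1, 1)), input_dim = c(1, 4))
  x_neg <- matrix(c(-2, -1, 0.5, 0.5), 1, 4)   # sum = -2 < 0
  expect_true(all(guided_backprop(net, x_neg)$values == 0))
  # all-positive activations and gradients: equals the raw gradient
  w_pos <- matrix(abs(withr::with_seed(4, rnorm(12, 1, 0.2))), 3, 4)
  net_pos <- mlp_model(list(w_pos, matrix(1, 1, 3)), input_dim = c(1, 4))
  x_pos <- matrix(abs(rnorm(4)) + 1, 1, 4)
  expect_equal(as.vector(guided_backprop(net_pos, x_pos)$values),
               as.vector(ecgxai:::input_gradient(net_pos, x_pos)$dx[, , 1]))
  # one negative-gradient path is gated off:
  # y = relu(x1) - 2 relu(x2); guided gradient w.r.t. x2 is 0 (incoming
  # gradient -2 < 0), plain gradient is -2
  net_mix <- mlp_model(list(diag(2), matrix(c(1, -2), 1, 2)),
                       input_dim = c(1, 2))
  x_m <- matrix(c(1, 1), 1, 2)
  expect_equal(unname(guided_backprop(net_mix, x_m)$values),
               matrix(c(1, 0), 1, 2))
  expect_equal(as.vector(ecgxai:::input_gradient(net_mix, x_m)$dx[, , 1]),
               c(1, -2))
})

test_that("GradCAM maps are nonnegative, lead-constant, and clamp at zero", {
  cm <- toy_conv_model(seed = 6)
  withr::with_seed(21, {
    for (rep in 1:20) {
      x <- random_signal(64)
      g <- gradcam(cm, x)
      expect_true(all(g$values >= 0))
      expect_equal(max(abs(sweep(g$values, 2, g$values[1, ]))), 0)
    }
  })
  expect_error(gradcam(cm, random_signal(64), "b99"), "not found")
  # negated-head model has non-positive channel weights at the tap when the
  # original map was positive; elementwise ReLU clamp keeps values at >= 0
  x <- random_signal(64, seed = 2)
  g <- gradcam(cm, x)
  cm_neg <- cm
  cm_neg$head$w <- -cm$head$w
  g_neg <- gradcam(cm_neg, x)
  expect_true(all(g_neg$values >= 0))
  # at the tap resolution the two clamped maps have disjoint support
  expect_true(any(g$values > 0) && any(g_neg$values > 0))
})

test_that("Guided GradCAM is the elementwise product of its parts", {
  cm <- toy_conv_model(seed = 7)
  x <- random_signal(64, seed = 5)
  gb <- guided_backprop(cm, x)
  gc <- gradcam(cm, x)
  gg <- combine_guided_gradcam(gb, gc)
  expect_equal(gg$values, gb$values * gc$values)
  zero <- gc; zero$values[] <- 0
  expect_true(all(combine_guided_gradcam(gb, zero)$values == 0))
  one <- gc; one$values[] <- 1
  expect_equal(combine_guided_gradcam(gb, one)$values, gb$values)
  small <- gb; small$values <- gb$values[, 1:10]
  expect_error(combine_guided_gradcam(small, gc), "shape")
})

test_that("SmoothGrad reduces to its base method in degenerate settings and
          its Monte-Carlo variance shrinks like 1/n", {
  cm <- toy_conv_model(seed = 8)
  x <- random_signal(64, seed = 6)
  s0 <- smoothgrad_wrap(saliency, cm, x, n_samples = 4, noise_frac = 0,
                        seed = 3)
  expect_equal(s0$values, saliency(cm, x)$values, tolerance = 1e-12)
  # n = 1 equals the base method on the single perturbed input
  s1 <- smoothgrad_wrap(saliency, cm, x, n_samples = 1, noise_frac = 0.1,
                        seed = 3)
  x1 <- withr::with_seed(ecgxai:::derive_seed(3, "smoothgrad"), {
    x + matrix(rnorm(length(x), 0, 0.1 * (max(x) - min(x))), 8, 64)
  })
  expect_equal(s1$values, saliency(cm, x1)$values, tolerance = 1e-12)
  # variance of the map estimate scales ~ 1/n
  var_at <- function(n, reps = 20) {
    ests <- sapply(seq_len(reps), function(r) {
      smoothgrad_wrap(saliency, cm, x, n_samples = n, noise_frac = 0.15,
                      seed = 1000 + r)$values[1, 1]
    })
    stats::var(ests)
  }
  v1 <- var_at(1); v8 <- var_at(8)
  expect_gt(v1 / v8, 3)      # ideal ratio 8; generous for 20-rep noise
})

test_that("Shapley sampling agrees with the exhaustive permutation oracle", {
  w1 <- withr::with_seed(12, matrix(rnorm(5 * 24, 0, 0.4), 5, 24))
  w2 <- matrix(withr::with_seed(13, rnorm(5)), 1, 5)
  net <- mlp_model(list(w1, w2), input_dim = c(8, 3))
  x <- random_signal(3, seed = 14)
  b <- x * 0
  # exhaustive oracle over all 3! orderings of 3 segments (1 column each)
  seg_cols <- list(1, 2, 3)
  score <- function(cols) {
    xi <- b
    for (cc in cols) xi[, cc] <- x[, cc]
    forward_pass(net, xi)$logit
  }
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  exact <- numeric(3)
  contribs <- vector("list", 3)
  for (s in 1:3) contribs[[s]] <- numeric(0)
  for (p in perms) {
    prev <- score(integer(0))
    done <- integer(0)
    for (s in p) {
      done <- c(done, s)
      cur <- score(done)
      contribs[[s]] <- c(contribs[[s]], cur - prev)
      prev <- cur
    }
  }
  exact <- vapply(contribs, mean, numeric(1))
  est <- shapley_sampling(net, x, n_segments = 3, n_samples = 3000, seed = 2)
  est_vals <- est$values[1, ]
  se <- vapply(contribs, function(cc) stats::sd(cc), numeric(1)) / sqrt(3000)
  for (s in 1:3) expect_lt(abs(est_vals[s] - exact[s]), 3 * se[s] + 1e-9)
  # efficiency: segment values sum to the score difference
  delta <- forward_pass(net, x)$logit - forward_pass(net, b)$logit
  expect_lt(abs(sum(est_vals) - delta), 3 * sqrt(sum(se^2)) + 1e-9)
  # additivity: on a linear (additive) model the value is exact per segment
  W <- withr::with_seed(15, matrix(rnorm(24), 8, 3))
  lin <- linear_toy(W)
  est_lin <- shapley_sampling(lin, x, n_segments = 3, n_samples = 50, seed = 4)
  expect_equal(est_lin$values[1, ], unname(colSums((x - b) * W)),
               tolerance = 1e-10)
  expect_error(shapley_sampling(net, x, n_segments = 99), "n_segments")
})

test_that("SHAP variants reduce correctly and match closed forms", {
  W <- withr::with_seed(16, matrix(rnorm(8 * 12), 8, 12))
  lm_ <- linear_toy(W)
  x <- random_signal(12, seed = 17)
  bset <- withr::with_seed(18, array(rnorm(8 * 12 * 6, 0, 0.5), c(8, 12, 6)))
  # GradientSHAP on a linear model: expectation is (x - mean(baselines)) * W
  gs <- gradient_shap(lm_, x, bset, n_samples = 4000, noise_sd = 0, seed = 3)
  bmean <- apply(bset, c(1, 2), mean)
  # Monte-Carlo SE bound from the baseline spread
  spread <- apply(bset, c(1, 2), stats::sd) * abs(W) / sqrt(4000)
  expect_true(all(abs(gs$values - (x - bmean) * W) <= 3 * spread + 1e-8))
  # DeepLiftSHAP with one baseline equals DeepLift with that baseline
  cm <- toy_conv_model(seed = 9)
  xc <- random_signal(64, seed = 19)
  b1 <- array(random_signal(64, seed = 20), c(8, 64, 1))
  expect_equal(deeplift_shap(cm, xc, b1)$values,
               deeplift_rescale(cm, xc, b1[, , 1])$values, tolerance = 1e-12)
  # summation-to-delta in the mean over baselines
  bk <- array(rnorm(8 * 64 * 5, 0, 0.3), c(8, 64, 5))
  ds_map <- deeplift_shap(cm, xc, bk)
  deltas <- sapply(1:5, function(i) forward_pass(cm, xc)$logit -
                     forward_pass(cm, bk[, , i])$logit)
  expect_lt(abs(sum(ds_map$values) - mean(deltas)), 1e-6)
  expect_error(deeplift_shap(cm, xc, array(0, c(8, 64, 0))), "empty")
})

test_that("every method returns finite maps of the input shape", {
  cm <- toy_conv_model(seed = 11)
  ac <- fast_attr_config()
  withr::with_seed(30, {
    for (rep in 1:8) {
      x <- random_signal(64)
      bl <- array(rnorm(8 * 64 * 2, 0, 0.5), c(8, 64, 2))
      for (meth in attribution_methods()) {
        a <- compute_attribution(cm, x, meth, ac, seed = rep, baselines = bl)
        expect_identical(dim(a$values), dim(x))
        expect_true(all(is.finite(a$values)), label = meth)
        expect_identical(a$method, meth)
      }
    }
  })
  expect_error(compute_attribution(cm, random_signal(64), "lrp"), "unknown")
})

test_that("attribution concentrates inside the planted feature mask", {
  # the bundle-branch-block feature lives on present (nonzero) QRS samples,
  # so baseline-difference methods can localize it; an absent-P feature (AF)
  # is invisible to x-weighted methods wherever x equals the zero baseline
  cm <- fixture_model("left_bundle_branch_block", 1)
  specs <- make_class_specs()
  frac_in_mask <- sapply(c("integrated_gradients", "deeplift",
                           "gradient_input", "smoothgrad"), function(meth) {
    fr <- sapply(1:6, function(i) {
      rec <- sample_record(specs$left_bundle_branch_block, noise_sd = 0,
                           rng_seed = 400 + i,
                           patient_latent = withr::with_seed(500 + i,
                             ecgxai:::sample_patient_latent()))
      a <- compute_attribution(cm, rec$signal, meth, fast_attr_config(),
                               seed = i)
      k <- ceiling(0.05 * length(a$values))
      top <- rank_points_abs(a)[seq_len(k)]
      mean(rec$relevance_mask[top])
    })
    mean(fr)
  })
  for (f in frac_in_mask) expect_gt(f, 0.05)   # above the 5% chance level
})

test_that("attribution map stores round-trip", {
  cm <- toy_conv_model(seed = 12)
  maps <- lapply(1:3, function(i) saliency(cm, random_signal(64, seed = i)))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "sal.f32")
  write_attribution_maps(maps, p)
  back <- read_attribution_maps(p)
  expect_length(back, 3)
  expect_equal(back[[2]]$values, maps[[2]]$values, tolerance = 1e-6)
  expect_identical(back[[2]]$method, "saliency")
})
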