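# train_eval: scheduler, metrics vs pair-counting oracle, aggregation,
# leakage guards, early stopping, seeded training, Grad-CAM.

# one small shared synthetic dataset for the training tests
te_dir <- file.path(tempdir(), "te_synth")
if (!file.exists(file.path(te_dir, "manifest.csv"))) {
  generate_dataset(synthetic_config(n_patients_per_class = 4L,
                                    images_per_patient = 3L,
                                    patch_size = 64L, seed = 303L), te_dir)
}
te_idx <- load_manifest(file.path(te_dir, "manifest.csv"))
te_cfg <- model_config(input_size = 32L, mscfe_branch_channels = 2L,
                       stage_widths = c(4L, 8L), blocks_per_stage = 1L,
                       cbam_reduction_ratio = 2L)

test_that("cosine annealing with warm restarts anchors and restarts correctly", {
  lr0 <- 1e-4
  expect_equal(cosine_restart_lr(0, lr0), lr0)             # published anchor
  expect_equal(cosine_restart_lr(5, lr0, 10, 2), lr0 / 2)  # mid-cycle
  expect_equal(cosine_restart_lr(10, lr0, 10, 2), lr0)     # first restart
  expect_equal(cosine_restart_lr(30, lr0, 10, 2), lr0)     # second restart
  expect_lt(cosine_restart_lr(9, lr0, 10, 2), 0.05 * lr0)  # cycle tail
  # t_mult = 1: plain periodic annealing
  expect_equal(cosine_restart_lr(14, lr0, 7, 1),
               cosine_restart_lr(0, lr0, 7, 1))
  sched <- vapply(0:69, cosine_restart_lr, 1, lr0 = lr0, t0 = 10, t_mult = 2)
  expect_true(all(sched > 0 & sched <= lr0))
})

test_that("metrics: exact cases and trapezoid-vs-pair-counting equivalence", {
  m <- binary_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$accuracy, 100)
  expect_equal(m$f1, 1)
  expect_equal(m$auc, 1)
  # printed pair example: positives {0.8, 0.4}, negatives {0.6, 0.2}
  expect_equal(roc_auc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 3 / 4)
  # oracle equivalence on 50 random score sets (with ties) within 1e-10
  set.seed(71)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(roc_auc(s, y), oracle_auc_pairs(s, y), tolerance = 1e-10)
  }
  # F1 zero-division convention: no positive predictions -> 0
  m0 <- binary_metrics(c(0.1, 0.2), c(1, 0))
  expect_equal(m0$f1, 0)
  # single-class truth: AUC unavailable, accuracy/F1 still returned
  expect_warning(ms <- binary_metrics(c(0.6, 0.7), c(1, 1)), "AUC")
  expect_true(is.na(ms$auc))
  expect_equal(ms$accuracy, 100)
  expect_error(roc_auc(c(0.5, 0.6), c(1, 1)), class = "cellsage_metric_error")
})

test_that("metric bounds hold on fuzzed inputs", {
  set.seed(72)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    m <- binary_metrics(runif(n), y, warn_single_class = FALSE)
    expect_true(m$accuracy >= 0 && m$accuracy <= 100)
    expect_true(m$f1 >= 0 && m$f1 <= 1)
    expect_true(m$auc >= 0 && m$auc <= 1)
  }
})

test_that("aggregate_folds: closed-form mean/sd, degenerate cases", {
  same <- lapply(1:3, function(i) list(accuracy = 91, f1 = 0.9, auc = 0.95))
  ag <- aggregate_folds(same)
  expect_equal(unname(ag$mean), c(91, 0.9, 0.95))
  expect_equal(unname(ag$sd), c(0, 0, 0))
  accs <- c(0.90, 0.92, 0.94, 0.96, 0.98)
  folds <- lapply(accs, function(a) list(accuracy = a, f1 = a, auc = a))
  ag2 <- aggregate_folds(folds)
  expect_equal(unname(ag2$mean["accuracy"]), 0.94)
  expect_equal(unname(ag2$sd["accuracy"]), sd(accs), tolerance = 1e-12)
  expect_equal(unname(ag2$sd["accuracy"]), 0.03162278, tolerance = 1e-6)
  one <- aggregate_folds(folds[1])
  expect_true(all(is.na(one$sd)))
  expect_false(any(is.na(one$mean)))
  expect_error(aggregate_folds(list()), class = "cellsage_config_error")
})

test_that("train refuses patient leakage and anchors the schedule", {
  plan <- patient_stratified_split(te_idx, seed = 1)
  tr <- subset_index(te_idx, plan, "train")
  va <- subset_index(te_idx, plan, "val")
  net <- build_model(te_cfg, seed = 1)
  expect_error(train(net, tr, tr, train_config(max_epochs = 1L),
                     image_dir = te_dir),
               class = "cellsage_leakage_error")
  fit <- train(net, tr, va, train_config(max_epochs = 2L, batch_size = 8L),
               image_dir = te_dir)
  expect_equal(fit$log$lr[1], 1e-4)
  expect_equal(nrow(fit$log), 2L)
  expect_true(all(c("train_loss", "val_loss", "val_accuracy", "val_f1",
                    "val_auc") %in% names(fit$log)))
  # evaluate's own leakage guard
  expect_error(evaluate(fit$model, va, image_dir = te_dir,
                        train_patients = unique(va$patient_id)),
               class = "cellsage_leakage_error")
})

test_that("early stopping halts after `patience` non-improving epochs", {
  plan <- patient_stratified_split(te_idx, seed = 2)
  tr <- subset_index(te_idx, plan, "train")
  va <- subset_index(te_idx, plan, "val")
  net <- build_model(te_cfg, seed = 2)
  # contract: the run ends exactly `patience` epochs after the best
  # validation epoch (or at the cap), and the best epoch is the argmin of
  # the validation-loss column
  cfg <- train_config(learning_rate = 1e-3, max_epochs = 12L,
                      early_stop_patience = 2L, batch_size = 8L,
                      augment = FALSE)
  fit <- train(net, tr, va, cfg, image_dir = te_dir)
  expect_equal(fit$best_epoch, which.min(fit$log$val_loss))
  expect_equal(nrow(fit$log), min(fit$best_epoch + 2L, 12L))
})

test_that("identical seeds reproduce the full epoch log", {
  plan <- patient_stratified_split(te_idx, seed = 3)
  tr <- subset_index(te_idx, plan, "train")
  va <- subset_index(te_idx, plan, "val")
  cfg <- train_config(learning_rate = 1e-3, max_epochs = 3L, batch_size = 8L,
                      seed = 42L)
  f1 <- train(build_model(te_cfg, seed = 7), tr, va, cfg, image_dir = te_dir)
  f2 <- train(build_model(te_cfg, seed = 7), tr, va, cfg, image_dir = te_dir)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("grad_cam_map matches the closed-form toy computation", {
  # toy: 1x1 conv + GAP + linear head. Target activations A (C x H x W);
  # d logit / d A[c, i, j] = w_head[c] / P, so the map is the rectified,
  # min-max-normalized sum_c w_c A_c (the constant 1/P cancels).
  set.seed(81)
  A <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  w_head <- c(0.7, -1.2, 0.4)
  P <- 16
  G <- array(rep(w_head / P, times = 16), c(3, 4, 4))
  got <- grad_cam_map(A, G)
  cam <- pmax(w_head[1] * A[1, , ] + w_head[2] * A[2, , ] +
                w_head[3] * A[3, , ], 0) / P
  want <- (cam - min(cam)) / (max(cam) - min(cam))
  expect_equal(got, want, tolerance = 1e-12)
  # all-zero gradients -> all-zero map (normalization guard)
  expect_equal(grad_cam_map(A, A * 0), matrix(0, 4, 4))
  expect_error(grad_cam_map(A, array(0, c(2, 4, 4))),
               class = "cellsage_shape_error")
  # a layer without spatial extent is a configuration error
  expect_error(grad_cam_map(matrix(0, 3, 3), matrix(0, 3, 3)),
               class = "cellsage_config_error")
})

test_that("grad_cam on a model: bounds, resolution, overlay convention", {
  net <- build_model(te_cfg, seed = 31)
  set.seed(82)
  x <- array(rnorm(3 * 32 * 32), c(3, 32, 32))
  gc_ <- grad_cam(net, x)
  expect_equal(dim(gc_$map), c(32L, 32L))
  expect_true(all(gc_$map >= 0 & gc_$map <= 1))
  # red means high, blue means low
  img <- array(128, c(8, 8, 3))
  map <- matrix(seq(0, 1, length.out = 64), 8, 8)
  ov <- gradcam_overlay(img, map, alpha = 1)
  expect_gt(ov[8, 8, 1], ov[8, 8, 3])  # high -> red dominant
  expect_gt(ov[1, 1, 3], ov[1, 1, 1])  # low -> blue dominant
})

test_that("cross_validate aggregates patient-disjoint folds", {
  cfg <- train_config(learning_rate = 1e-3, max_epochs = 1L, batch_size = 8L,
                      augment = FALSE)
  cv <- cross_validate(te_idx, te_cfg, cfg, k = 2L, image_dir = te_dir,
                       seed = 5L, val_fraction = 0.34)
  expect_s3_class(cv, "fold_metrics")
  expect_equal(nrow(cv$per_fold), 2L)
  expect_false(any(is.na(cv$mean)))
})
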