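# Training recipe and evaluation metrics: Adam with cosine annealing and warm
# restarts, early stopping on validation loss, class-weighted binary
# cross-entropy on logits; accuracy / malignant-class F1 / trapezoidal AUC.

#' Training configuration
#'
#' Defaults are the published recipe: Adam at 1e-4 (beta 0.9/0.999), batch
#' size 32, up to 100 epochs with early stopping (patience 10), cosine
#' annealing with warm restarts, class-weighted BCE-with-logits.
#'
#' @param learning_rate initial learning rate.
#' @param beta1,beta2 Adam moment decays.
#' @param batch_size mini-batch size.
#' @param max_epochs epoch cap.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping.
#' @param t0,t_mult warm-restart schedule: first cycle length (epochs) and
#'   cycle-length multiplier.
#' @param use_class_weights apply inverse-frequency class weights to the
#'   loss.
#' @param augment apply the training-time augmentation policy.
#' @param seed seed covering initial shuffling, dropout and augmentation
#'   draws.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 32L, max_epochs = 100L,
                         early_stop_patience = 10L, t0 = 10L, t_mult = 2L,
                         use_class_weights = TRUE, augment = TRUE,
                         seed = 1L) {
  if (learning_rate <= 0) cs_stop("learning_rate must be > 0",
                                  "cellsage_config_error")
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1)
    cs_stop("beta1/beta2 must lie in [0, 1)", "cellsage_config_error")
  if (early_stop_patience < 1L) cs_stop("patience must be >= 1",
                                        "cellsage_config_error")
  if (batch_size < 1L) cs_stop("batch_size must be >= 1",
                               "cellsage_config_error")
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 t0 = as.integer(t0), t_mult = as.integer(t_mult),
                 use_class_weights = use_class_weights, augment = augment,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate under cosine annealing with warm restarts
#'
#' @param epoch 0-based epoch index.
#' @param lr0 initial learning rate.
#' @param t0 first cycle length in epochs.
#' @param t_mult cycle-length multiplier.
#' @return the scheduled learning rate (equal to `lr0` at every restart).
#' @export
cosine_restart_lr <- function(epoch, lr0, t0 = 10L, t_mult = 2L) {
  if (t_mult == 1L) {
    ti <- t0
    tcur <- epoch %% t0
  } else {
    n <- floor(log(epoch / t0 * (t_mult - 1) + 1, base = t_mult))
    start <- t0 * (t_mult^n - 1) / (t_mult - 1)
    ti <- t0 * t_mult^n
    tcur <- epoch - start
  }
  lr0 * 0.5 * (1 + cos(pi * tcur / ti))
}

bce_with_logits <- function(logit, y, w) {
  # numerically stable: softplus(z) - y*z, softplus via log1p(exp(-|z|))+max(z,0)
  sp <- pmax(logit, 0) + log1p(exp(-abs(logit)))
  loss <- w * (sp - y * logit)
  grad <- w * (sigmoid(logit) - y)
  list(loss = mean(loss), dlogit = grad / length(logit))
}

load_raw_images <- function(index, image_dir, profile) {
  lapply(seq_len(nrow(index)), function(i) {
    img <- read_png(file.path(image_dir, index$image_path[i]))
    if (!is.null(profile)) img <- stain_normalize(img, profile)
    img
  })
}

images_to_batch <- function(imgs, target_size) {
  N <- length(imgs)
  x <- array(0, c(N, 3L, target_size, target_size))
  for (i in seq_len(N)) {
    t <- if (dim(imgs[[i]])[1] == target_size &&
             dim(imgs[[i]])[2] == target_size) imgs[[i]]
         else resize_bilinear(imgs[[i]], target_size)
    x[i, , , ] <- rescale_standardize(clamp(t, 0, 255))
  }
  x
}

adam_step <- function(params, grads, m, v, t, cfg) {
  lr <- cfg$lr_t
  b1 <- cfg$beta1; b2 <- cfg$beta2; eps <- 1e-8
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
    v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g * g
    mhat <- m[[nm]] / (1 - b1^t)
    vhat <- v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, m = m, v = v)
}

#' Train a network
#'
#' Mini-batch optimization with Adam, cosine annealing with warm restarts,
#' class-weighted BCE-with-logits, and early stopping on validation loss
#' (best-epoch weights are restored). The run is fully seeded: weight
#' initialization comes from the model's own seed, and shuffling, dropout and
#' augmentation draws from `config$seed`.
#'
#' @param net a `cellsage_model` (its `config$input_size` sets the training
#'   resolution).
#' @param index_train,index_val disjoint-patient `dataset_index` subsets.
#' @param config a [train_config()].
#' @param profile optional [stain_profile()] applied before everything else.
#' @param image_dir directory that manifest `image_path`s are relative to.
#' @param policy training [augmentation_policy()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (best-epoch weights), `log` (per-epoch
#'   data.frame: train loss, val loss, val metrics, lr), `best_epoch`.
#' @export
train <- function(net, index_train, index_val, config = train_config(),
                  profile = NULL, image_dir = ".",
                  policy = augmentation_policy(), verbose = FALSE) {
  overlap <- intersect(unique(index_train$patient_id),
                       unique(index_val$patient_id))
  if (length(overlap))
    cs_stop("patient leakage between train and validation: %s",
            "cellsage_leakage_error", paste(overlap, collapse = ", "))
  size <- net$config$input_size
  train_imgs <- load_raw_images(index_train, image_dir, profile)
  val_imgs <- load_raw_images(index_val, image_dir, profile)
  xval <- images_to_batch(val_imgs, size)
  yval <- as.numeric(index_val$class_label == "malignant")
  ytr <- as.numeric(index_train$class_label == "malignant")
  cw <- if (config$use_class_weights) compute_class_weights(index_train)
        else c(benign = 1, malignant = 1)
  wtr <- unname(cw[index_train$class_label])
  n <- length(train_imgs)
  m <- lapply(net$params, function(p) p * 0)
  v <- lapply(net$params, function(p) p * 0)
  tstep <- 0L
  best <- list(loss = Inf, params = net$params, state = net$state, epoch = 0L)
  bad <- 0L
  log_rows <- list()
  set.seed(config$seed)
  for (epoch in seq_len(config$max_epochs)) {
    lr_t <- cosine_restart_lr(epoch - 1L, config$learning_rate, config$t0,
                              config$t_mult)
    ord <- sample.int(n)
    tr_loss <- 0; nb <- 0L
    for (bs in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      imgs <- train_imgs[bs]
      if (config$augment) {
        dseeds <- sample.int(.Machine$integer.max - 1L, length(bs))
        imgs <- lapply(seq_along(bs), function(i)
          augment(imgs[[i]], policy, dseeds[i]))
      }
      xb <- images_to_batch(imgs, size)
      X <- bm_from_nchw(xb)
      out <- net_forward(net, X, length(bs), size, size, training = TRUE,
                         keep = TRUE)
      net$state <- out$state
      l <- bce_with_logits(out$logit, ytr[bs], wtr[bs])
      grads <- net_backward(net, out$cache, l$dlogit)
      tstep <- tstep + 1L
      upd <- adam_step(net$params, grads, m, v, tstep,
                       list(lr_t = lr_t, beta1 = config$beta1,
                            beta2 = config$beta2))
      net$params <- upd$params; m <- upd$m; v <- upd$v
      tr_loss <- tr_loss + l$loss; nb <- nb + 1L
    }
    tr_loss <- tr_loss / nb
    vp <- predict_batched(net, xval, config$batch_size)
    vlogit <- stats::qlogis(clamp(vp, 1e-12, 1 - 1e-12))
    vl <- bce_with_logits(vlogit, yval, rep(1, length(yval)))$loss
    vm <- binary_metrics(vp, yval, warn_single_class = FALSE)
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, lr = lr_t, train_loss = tr_loss, val_loss = vl,
      val_accuracy = vm$accuracy, val_f1 = vm$f1, val_auc = vm$auc)
    if (verbose)
      message(sprintf("epoch %3d lr %.2e train %.4f val %.4f acc %.1f",
                      epoch, lr_t, tr_loss, vl, vm$accuracy))
    if (vl < best$loss - 1e-12) {
      best <- list(loss = vl, params = net$params, state = net$state,
                   epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$early_stop_patience) break
    }
  }
  net$params <- best$params
  net$state <- best$state
  list(model = net, log = do.call(rbind, log_rows), best_epoch = best$epoch)
}

predict_batched <- function(net, x, batch_size = 32L) {
  N <- dim(x)[1]
  out <- numeric(N)
  size <- dim(x)[3]
  for (bs in split(seq_len(N), ceiling(seq_len(N) / batch_size))) {
    X <- bm_from_nchw(x[bs, , , , drop = FALSE])
    out[bs] <- net_forward(net, X, length(bs), size, size,
                           training = FALSE, keep = FALSE)$prob
  }
  out
}

# ---- metrics --------------------------------------------------------------

#' Trapezoidal ROC AUC
#'
#' Area under the ROC curve computed by sorting scores, grouping ties (tie
#' groups contribute trapezoids, i.e. ties count one half), and trapezoidal
#' integration. Equals the probability that a random positive outscores a
#' random negative, with ties counted 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) truth, 1 = positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0)
    cs_stop("AUC undefined: test set contains a single class",
            "cellsage_metric_error")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  tp <- cumsum(yy); fp <- cumsum(1 - yy)
  last <- which(diff(s) != 0)
  keep <- c(last, length(s))
  tpr <- c(0, tp[keep] / npos)
  fpr <- c(0, fp[keep] / nneg)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Binary classification metrics
#'
#' Accuracy (percent correct at the threshold), F1 for the malignant
#' (positive) class with the 0-if-no-positive-predictions convention, and
#' trapezoidal [roc_auc()]. A single-class truth vector yields `auc = NA`
#' with a warning; accuracy and F1 are still returned.
#'
#' @param scores predicted malignancy probabilities.
#' @param labels 0/1 truth (1 = malignant).
#' @param threshold decision threshold (default 0.5).
#' @param warn_single_class warn when AUC is undefined.
#' @return list `accuracy` (percent), `f1`, `auc`, `n`.
#' @export
binary_metrics <- function(scores, labels, threshold = 0.5,
                           warn_single_class = TRUE) {
  y <- as.numeric(labels)
  pred <- as.numeric(scores >= threshold)
  acc <- mean(pred == y) * 100
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  auc <- if (length(unique(y)) < 2) {
    if (warn_single_class)
      warning("AUC undefined for a single-class test set", call. = FALSE)
    NA_real_
  } else roc_auc(scores, y)
  list(accuracy = acc, f1 = f1, auc = auc, n = length(y))
}

#' Evaluate a trained network on a held-out index
#'
#' @param net a trained `cellsage_model`.
#' @param index a `dataset_index` of held-out patients.
#' @param profile optional [stain_profile()], as used in training.
#' @param image_dir directory image paths are relative to.
#' @param threshold decision threshold on the sigmoid output.
#' @param train_patients optional character vector of training patient ids;
#'   if given, any overlap with the test patients is a hard error.
#' @return list `accuracy`, `f1`, `auc`, `n`, plus `scores` and `labels`.
#' @export
evaluate <- function(net, index, profile = NULL, image_dir = ".",
                     threshold = 0.5, train_patients = NULL) {
  if (!is.null(train_patients)) {
    overlap <- intersect(unique(index$patient_id), train_patients)
    if (length(overlap))
      cs_stop("patient leakage between train and test: %s",
              "cellsage_leakage_error", paste(overlap, collapse = ", "))
  }
  imgs <- load_raw_images(index, image_dir, profile)
  x <- images_to_batch(imgs, net$config$input_size)
  scores <- predict_batched(net, x)
  labels <- as.numeric(index$class_label == "malignant")
  out <- binary_metrics(scores, labels, threshold)
  out$scores <- scores
  out$labels <- labels
  out
}

#' Aggregate per-fold metrics
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' accuracy, F1 and AUC over folds. With a single fold the sd columns are
#' `NA` (unavailable).
#'
#' @param folds list of per-fold metric lists (each with `accuracy`, `f1`,
#'   `auc`).
#' @return object of class `fold_metrics`: `per_fold` data.frame plus `mean`
#'   and `sd` named vectors.
#' @export
aggregate_folds <- function(folds) {
  if (length(folds) == 0L)
    cs_stop("no folds to aggregate", "cellsage_config_error")
  per <- do.call(rbind, lapply(seq_along(folds), function(i)
    data.frame(fold = i, accuracy = folds[[i]]$accuracy,
               f1 = folds[[i]]$f1, auc = folds[[i]]$auc)))
  mets <- c("accuracy", "f1", "auc")
  mu <- vapply(mets, function(m) mean(per[[m]]), 1)
  sd_ <- if (nrow(per) >= 2L) vapply(mets, function(m) stats::sd(per[[m]]), 1)
         else stats::setNames(rep(NA_real_, 3), mets)
  structure(list(per_fold = per, mean = mu, sd = sd_), class = "fold_metrics")
}

#' @export
print.fold_metrics <- function(x, ...) {
  print(x$per_fold, row.names = FALSE)
  cat(sprintf("mean : acc %.2f%%  F1 %.3f  AUC %.3f\n",
              x$mean["accuracy"], x$mean["f1"], x$mean["auc"]))
  if (!all(is.na(x$sd)))
    cat(sprintf("sd   : acc %.2f   F1 %.3f  AUC %.3f\n",
                x$sd["accuracy"], x$sd["f1"], x$sd["auc"]))
  invisible(x)
}

#' Patient-stratified cross-validation of the full pipeline
#'
#' Convenience driver: for each fold, builds a fresh model, trains on the
#' non-held-out patients (with a patient-wise validation carve-out) and
#' evaluates on the held-out fold.
#'
#' @param index a `dataset_index`.
#' @param model_cfg a [model_config()].
#' @param tr_cfg a [train_config()].
#' @param k folds.
#' @param profile optional stain profile.
#' @param image_dir image root.
#' @param seed fold-assignment seed.
#' @param val_fraction fraction of training patients held for validation.
#' @return a [aggregate_folds()] `fold_metrics`.
#' @export
cross_validate <- function(index, model_cfg, tr_cfg, k = 5L, profile = NULL,
                           image_dir = ".", seed = 1L, val_fraction = 0.2) {
  plans <- kfold_patient_stratified(index, k, seed)
  res <- lapply(seq_along(plans), function(i) {
    plan <- plans[[i]]
    tr_index <- subset_index(index, plan, "train")
    te_index <- subset_index(index, plan, "test")
    inner <- patient_stratified_split(
      tr_index, c(train = 1 - val_fraction, val = val_fraction),
      seed = seed + i)
    net <- build_model(model_cfg, seed = seed + i)
    fit <- train(net, subset_index(tr_index, inner, "train"),
                 subset_index(tr_index, inner, "val"), tr_cfg, profile,
                 image_dir)
    evaluate(fit$model, te_index, profile, image_dir,
             train_patients = unique(tr_index$patient_id))
  })
  aggregate_folds(res)
}
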