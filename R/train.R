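# Hybrid-loss optimization: alpha * BCE + (1 - alpha) * soft Dice, Adam,
# reduce-on-plateau learning-rate scheduling, mini-batches, best-validation
# checkpointing, and an initial pipeline sanity check.

#' Binary cross-entropy loss (mean per pixel)
#'
#' \eqn{-(1/N) \sum_i [y_i \log p_i + (1-y_i) \log(1-p_i)]} with
#' probabilities clipped to `[eps, 1-eps]` for numerical safety.
#'
#' @param p Predicted probabilities in \[0, 1\] (any shape).
#' @param y Ground truth in \{0, 1\}, congruent with `p`.
#' @param eps Clipping constant.
#' @return Scalar loss.
#' @export
bce_loss <- function(p, y, eps = 1e-7) {
  if (length(p) != length(y))
    stop("validation error: p and y must have congruent shapes")
  p <- pmin(pmax(as.vector(p), eps), 1 - eps)
  y <- as.vector(y)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Soft Dice loss
#'
#' \eqn{1 - (2 \sum p y + s) / (\sum p + \sum y + s)} with smoothing `s`
#' guarding empty masks. Zero for a perfect (binary) prediction; 1 for
#' disjoint binary masks as `s -> 0`.
#'
#' @inheritParams bce_loss
#' @param smooth Smoothing constant `s` (default 1).
#' @return Scalar loss in \[0, 1\].
#' @export
dice_loss <- function(p, y, smooth = 1) {
  if (length(p) != length(y))
    stop("validation error: p and y must have congruent shapes")
  p <- as.vector(p); y <- as.vector(y)
  1 - (2 * sum(p * y) + smooth) / (sum(p) + sum(y) + smooth)
}

#' Hybrid total loss
#'
#' `alpha * BCE + (1 - alpha) * Dice`, with `alpha = 0.5` balancing
#' pixel-wise classification against mask overlap.
#'
#' @inheritParams bce_loss
#' @param alpha Weight on the BCE term, in \[0, 1\].
#' @param smooth Dice smoothing constant.
#' @return Scalar loss.
#' @export
total_loss <- function(p, y, alpha = 0.5, smooth = 1) {
  stopifnot(alpha >= 0, alpha <= 1)
  alpha * bce_loss(p, y) + (1 - alpha) * dice_loss(p, y, smooth)
}

# Gradient of the total loss wrt the logits z (p = sigmoid(z)).
total_loss_grad_logits <- function(p, y, alpha = 0.5, smooth = 1, eps = 1e-7) {
  n <- length(p)
  pc <- pmin(pmax(p, eps), 1 - eps)
  # BCE wrt z has the classic form (p - y) / N
  d_bce <- (pc - y) / n
  denom <- sum(p) + sum(y) + smooth
  num <- 2 * sum(p * y) + smooth
  d_dice_p <- -(2 * y * denom - num) / denom^2
  d_dice <- d_dice_p * p * (1 - p)
  g <- alpha * d_bce + (1 - alpha) * d_dice
  array(g, dim = dim(p))
}

#' Training configuration
#'
#' Defaults follow the optimization protocol: Adam at learning rate 0.001,
#' hybrid loss weight alpha = 0.5, mini-batches of 8, an 80/20 split,
#' ReduceLROnPlateau (min mode, factor 0.5, patience 20, relative
#' threshold 1e-4, cooldown 0, min_lr 0) and best-validation-loss
#' checkpointing.
#'
#' @param lr Initial learning rate.
#' @param alpha Hybrid loss weight on BCE.
#' @param batch_size Mini-batch size.
#' @param epochs Number of epochs (any positive; 25/50/100/125 by
#'   convention at full scale).
#' @param split_fraction Training fraction for [split_dataset()].
#' @param scheduler Named list of plateau-scheduler settings.
#' @param seed Seed for shuffling and augmentation.
#' @param flip_prob Train-time flip augmentation probability (0 disables).
#' @param early_stop_patience Optional hard stop after this many
#'   non-improving epochs (default `Inf` = off; the scheduler already
#'   provides implicit early stopping).
#' @param smooth Dice smoothing constant.
#' @return List of class `train_config`.
#' @export
train_config <- function(lr = 0.001, alpha = 0.5, batch_size = 8L,
                         epochs = 25L, split_fraction = 0.8,
                         scheduler = list(mode = "min", factor = 0.5,
                                          patience = 20L, threshold = 1e-4,
                                          threshold_mode = "rel",
                                          cooldown = 0L, min_lr = 0,
                                          eps = 1e-8),
                         seed = 1L, flip_prob = 0.5,
                         early_stop_patience = Inf, smooth = 1) {
  stopifnot(lr > 0, alpha >= 0, alpha <= 1, batch_size >= 1, epochs >= 1)
  structure(as.list(environment()), class = "train_config")
}

#' Reduce-on-plateau learning-rate scheduler
#'
#' Tracks the best validation loss; an epoch counts as improving when the
#' loss drops below `best * (1 - threshold)` (relative mode) or
#' `best - threshold` (absolute mode). Once the count of consecutive
#' non-improving epochs reaches `patience`, the learning rate is multiplied
#' by `factor` (never below `min_lr`; updates smaller than `eps` are
#' skipped) and the counter resets.
#'
#' @param lr0 Initial learning rate.
#' @param factor,patience,threshold,threshold_mode,cooldown,min_lr,eps
#'   Scheduler settings (see [train_config()] defaults).
#' @return List of class `plateau_scheduler`; advance it with
#'   [scheduler_step()].
#' @export
plateau_scheduler <- function(lr0, factor = 0.5, patience = 20L,
                              threshold = 1e-4, threshold_mode = "rel",
                              cooldown = 0L, min_lr = 0, eps = 1e-8) {
  stopifnot(factor > 0, factor < 1, patience >= 0)
  structure(list(lr = lr0, factor = factor, patience = patience,
                 threshold = threshold, threshold_mode = threshold_mode,
                 cooldown = cooldown, min_lr = min_lr, eps = eps,
                 best = Inf, num_bad = 0L, cooldown_counter = 0L,
                 n_reductions = 0L),
            class = "plateau_scheduler")
}

#' Advance a plateau scheduler by one epoch
#'
#' @param sched A [plateau_scheduler()].
#' @param value This epoch's validation loss.
#' @return Updated scheduler (fields `lr`, `best`, `num_bad`,
#'   `n_reductions`).
#' @export
scheduler_step <- function(sched, value) {
  improved <- if (sched$threshold_mode == "rel")
    value < sched$best * (1 - sched$threshold)
  else value < sched$best - sched$threshold
  if (improved) {
    sched$best <- value
    sched$num_bad <- 0L
  } else if (sched$cooldown_counter > 0L) {
    sched$cooldown_counter <- sched$cooldown_counter - 1L
    sched$num_bad <- 0L
  } else {
    sched$num_bad <- sched$num_bad + 1L
  }
  if (sched$num_bad >= sched$patience) {
    new_lr <- max(sched$lr * sched$factor, sched$min_lr)
    if (sched$lr - new_lr > sched$eps) {
      sched$lr <- new_lr
      sched$n_reductions <- sched$n_reductions + 1L
    }
    sched$num_bad <- 0L
    sched$cooldown_counter <- sched$cooldown
  }
  sched
}

#' Split a manifest into training and validation sets
#'
#' Shuffled, disjoint and exhaustive; stratified by `label_true` when that
#' column is present, with largest-remainder rounding so the overall train
#' count is exactly `round(fraction * n)`.
#'
#' @param manifest Data.frame with `image_id` (and optionally
#'   `label_true`), or an integer count of unlabelled records.
#' @param fraction Training fraction.
#' @param seed Shuffle seed.
#' @return List with character vectors `train_ids` and `val_ids` (or
#'   integer indices when `manifest` has no `image_id`).
#' @export
split_dataset <- function(manifest, fraction = 0.8, seed = 1L) {
  if (is.numeric(manifest) && length(manifest) == 1)
    manifest <- data.frame(image_id = seq_len(manifest))
  n <- nrow(manifest)
  if (n < 5) stop("split error: need at least 5 records")
  stopifnot(fraction > 0, fraction < 1)
  ids <- manifest$image_id
  if (is.null(ids)) ids <- seq_len(n)
  labels <- if ("label_true" %in% names(manifest))
    as.character(manifest$label_true) else rep("all", n)

  with_local_seed(seed, {
    n_train_total <- round(fraction * n)
    strata <- split(seq_len(n), labels)
    raw <- vapply(strata, length, numeric(1)) * fraction
    take <- floor(raw)
    short <- n_train_total - sum(take)
    if (short > 0) {
      ord <- order(raw - take, decreasing = TRUE)
      take[ord[seq_len(short)]] <- take[ord[seq_len(short)]] + 1
    } else if (short < 0) {
      ord <- order(raw - take)
      k <- seq_len(-short)
      take[ord[k]] <- take[ord[k]] - 1
    }
    train_idx <- unlist(lapply(seq_along(strata), function(s) {
      idx <- sample(strata[[s]])
      idx[seq_len(take[s])]
    }), use.names = FALSE)
    train_idx <- sample(train_idx)
    val_idx <- sample(setdiff(seq_len(n), train_idx))
    list(train_ids = ids[train_idx], val_ids = ids[val_idx])
  })
}

# Adam update for one flat parameter vector; state carries m, v, t.
adam_init <- function(layers) {
  lapply(layers, function(l) lapply(l[intersect(names(l),
    c("W", "b", "gamma", "beta"))], function(p)
      list(m = array(0, dim = dim(p) %||% length(p)),
           v = array(0, dim = dim(p) %||% length(p)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_update <- function(layers, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      st <- state[[nm]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[nm]][[pn]] <- layers[[nm]][[pn]] - lr * mhat / (sqrt(vhat) + eps)
      state[[nm]][[pn]] <- st
    }
  }
  list(layers = layers, state = state)
}

batch_dice_hard <- function(prob, y, threshold = 0.5) {
  dice_coefficient(array(as.integer(prob >= threshold), dim = dim(prob)),
                   array(as.integer(y > 0.5), dim = dim(y)))
}

#' Train a SegNet model
#'
#' Mini-batch Adam on the hybrid BCE + Dice loss with per-epoch validation,
#' reduce-on-plateau scheduling on the validation loss, and checkpointing
#' of the best-validation-loss weights. A sanity check (one
#' forward/backward pass on the first batch: finite loss, nonzero
#' gradients) runs before the first epoch. Training aborts with
#' diagnostics if the loss becomes non-finite.
#'
#' @param model A `segnet_model` from [build_segnet()], or a `segnet_fit`
#'   to resume from (history continues contiguously).
#' @param train_x,train_y Arrays `(H, W, 3, N)` and `(H, W, 1, N)`.
#' @param val_x,val_y Validation arrays, same layout.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List of class `segnet_fit`: `model` (best checkpoint),
#'   `final_model`, `history` (data.frame epoch/train_loss/val_loss/
#'   train_dice/val_dice/train_dice_soft/lr), `best_epoch`,
#'   `best_val_loss`, `scheduler`, `adam`, `cfg`.
#' @export
fit_segnet <- function(model, train_x, train_y, val_x, val_y,
                       cfg = train_config(), verbose = TRUE) {
  resume <- inherits(model, "segnet_fit")
  if (resume) {
    fit0 <- model
    model <- fit0$final_model
    sched <- fit0$scheduler
    adam <- fit0$adam
    history <- fit0$history
    epoch0 <- max(history$epoch)
    t_step <- fit0$t_step
    best <- list(model = fit0$model, val_loss = fit0$best_val_loss,
                 epoch = fit0$best_epoch)
  } else {
    sc <- cfg$scheduler
    sched <- plateau_scheduler(cfg$lr, sc$factor, sc$patience, sc$threshold,
                               sc$threshold_mode, sc$cooldown, sc$min_lr,
                               sc$eps)
    adam <- adam_init(model$layers)
    history <- NULL
    epoch0 <- 0L
    t_step <- 0L
    best <- list(model = model, val_loss = Inf, epoch = 0L)
  }
  n_train <- dim(train_x)[4]
  stopifnot(dim(train_y)[4] == n_train, dim(val_x)[4] == dim(val_y)[4])

  sanity_check_batch(model, train_x, train_y, cfg)

  with_local_seed(cfg$seed + epoch0, {
    for (epoch in (epoch0 + 1L):(epoch0 + cfg$epochs)) {
      ord <- sample(n_train)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      tr_loss <- 0; tr_dice <- 0; tr_dice_soft <- 0; n_seen <- 0
      for (bi in batches) {
        xb <- train_x[, , , bi, drop = FALSE]
        yb <- train_y[, , , bi, drop = FALSE]
        if (cfg$flip_prob > 0) {
          for (k in seq_along(bi)) {
            fl <- random_flip_pair(xb[, , , k], yb[, , 1, k], cfg$flip_prob)
            xb[, , , k] <- fl$image
            yb[, , 1, k] <- fl$mask
          }
        }
        fw <- segnet_forward(model, xb, training = TRUE, keep_cache = TRUE)
        model <- fw$model
        prob <- 1 / (1 + exp(-fw$logits))
        loss <- total_loss(prob, yb, cfg$alpha, cfg$smooth)
        if (!is.finite(loss))
          stop(sprintf(paste0("training aborted: non-finite loss at epoch ",
                              "%d (lr %.2e, batch of %d)"),
                       epoch, sched$lr, length(bi)))
        dl <- total_loss_grad_logits(prob, yb, cfg$alpha, cfg$smooth)
        grads <- segnet_backward(model, fw$cache, dl)
        t_step <- t_step + 1L
        up <- adam_update(model$layers, grads, adam, sched$lr, t_step)
        model$layers <- up$layers
        adam <- up$state
        w <- length(bi)
        tr_loss <- tr_loss + loss * w
        tr_dice <- tr_dice + batch_dice_hard(prob, yb) * w
        tr_dice_soft <- tr_dice_soft + (1 - dice_loss(prob, yb, cfg$smooth)) * w
        n_seen <- n_seen + w
      }
      val <- evaluate_loss(model, val_x, val_y, cfg)
      sched_prev_lr <- sched$lr
      sched <- scheduler_step(sched, val$loss)
      if (val$loss < best$val_loss) {
        best <- list(model = model, val_loss = val$loss, epoch = epoch)
      }
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = tr_loss / n_seen, val_loss = val$loss,
        train_dice = tr_dice / n_seen, val_dice = val$dice,
        train_dice_soft = tr_dice_soft / n_seen, lr = sched_prev_lr))
      if (verbose)
        message(sprintf(
          "epoch %3d | train loss %.4f dice %.4f | val loss %.4f dice %.4f | lr %.2e%s",
          epoch, tr_loss / n_seen, tr_dice / n_seen, val$loss, val$dice,
          sched_prev_lr,
          if (sched$lr != sched_prev_lr)
            sprintf(" -> %.2e", sched$lr) else ""))
      if (is.finite(cfg$early_stop_patience) &&
          epoch - best$epoch >= cfg$early_stop_patience) {
        if (verbose) message("early stop: no improvement for ",
                             cfg$early_stop_patience, " epochs")
        break
      }
    }
  })
  structure(list(model = best$model, final_model = model, history = history,
                 best_epoch = best$epoch, best_val_loss = best$val_loss,
                 scheduler = sched, adam = adam, t_step = t_step, cfg = cfg),
            class = "segnet_fit")
}

# One forward/backward on the first batch: finite loss and nonzero
# gradients, before any weight is touched.
sanity_check_batch <- function(model, train_x, train_y, cfg) {
  n <- min(cfg$batch_size, dim(train_x)[4])
  xb <- train_x[, , , seq_len(n), drop = FALSE]
  yb <- train_y[, , , seq_len(n), drop = FALSE]
  fw <- segnet_forward(model, xb, training = TRUE, keep_cache = TRUE)
  prob <- 1 / (1 + exp(-fw$logits))
  loss <- total_loss(prob, yb, cfg$alpha, cfg$smooth)
  if (!is.finite(loss))
    stop("sanity check failed: non-finite loss on the first batch")
  grads <- segnet_backward(model, fw$cache,
                           total_loss_grad_logits(prob, yb, cfg$alpha,
                                                  cfg$smooth))
  gmax <- max(vapply(grads, function(g) max(abs(g$W)), numeric(1)))
  if (gmax == 0)
    stop("sanity check failed: all-zero gradients on the first batch")
  invisible(TRUE)
}

# Validation loss and mean per-batch thresholded Dice in eval mode.
evaluate_loss <- function(model, x, y, cfg, batch_size = cfg$batch_size) {
  n <- dim(x)[4]
  batches <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  loss <- 0; dice <- 0
  for (bi in batches) {
    fw <- segnet_forward(model, x[, , , bi, drop = FALSE], training = FALSE)
    prob <- 1 / (1 + exp(-fw$logits))
    yb <- y[, , , bi, drop = FALSE]
    loss <- loss + total_loss(prob, yb, cfg$alpha, cfg$smooth) * length(bi)
    dice <- dice + batch_dice_hard(prob, yb) * length(bi)
  }
  list(loss = loss / n, dice = dice / n)
}

#' Per-image evaluation of a trained segmenter
#'
#' @param model A `segnet_model`.
#' @param x,y Arrays `(H, W, 3, N)` / `(H, W, 1, N)`.
#' @param threshold Probability threshold.
#' @return List with `per_image` (data.frame of per-image Dice), `panel`
#'   (pooled pixel [metric_panel()]) and `mean_dice`.
#' @export
evaluate_segmenter <- function(model, x, y, threshold = 0.5) {
  n <- dim(x)[4]
  dices <- numeric(n)
  counts <- list(tp = 0, tn = 0, fp = 0, fn = 0)
  batches <- split(seq_len(n), ceiling(seq_len(n) / 8))
  for (bi in batches) {
    fw <- segnet_forward(model, x[, , , bi, drop = FALSE], training = FALSE)
    prob <- 1 / (1 + exp(-fw$logits))
    for (k in seq_along(bi)) {
      pm <- matrix(as.integer(prob[, , 1, k] >= threshold),
                   dim(prob)[1], dim(prob)[2])
      tm <- matrix(as.integer(y[, , 1, bi[k]] > 0.5),
                   dim(y)[1], dim(y)[2])
      dices[bi[k]] <- dice_coefficient(pm, tm)
      cc <- confusion_counts(pm, tm)
      for (f in names(counts)) counts[[f]] <- counts[[f]] + cc[[f]]
    }
  }
  list(per_image = data.frame(index = seq_len(n), dice = dices),
       panel = metric_panel(counts), mean_dice = mean(dices))
}

#' Save / load a training checkpoint
#'
#' The checkpoint bundles the best-validation weights, the model and
#' training configurations, the history, and scheduler/optimizer state, so
#' training can resume and inference can reload the segmenter.
#'
#' @param fit A `segnet_fit`.
#' @param path Destination file.
#' @return `path` (save) / the `segnet_fit` (load).
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "segnet_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  fit <- readRDS(path)
  if (!inherits(fit, "segnet_fit")) stop("not a fetalbiom checkpoint: ", path)
  fit
}
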