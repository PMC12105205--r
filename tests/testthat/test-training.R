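# Brute-force scalar-loop oracles for the loss functions.
bce_oracle <- function(p, y, eps = 1e-7) {
  tot <- 0
  for (i in seq_along(p)) {
    pi <- min(max(p[i], eps), 1 - eps)
    tot <- tot + y[i] * log(pi) + (1 - y[i]) * log(1 - pi)
  }
  -tot / length(p)
}
dice_oracle <- function(p, y, s = 1) {
  inter <- 0; sp <- 0; sy <- 0
  for (i in seq_along(p)) {
    inter <- inter + p[i] * y[i]; sp <- sp + p[i]; sy <- sy + y[i]
  }
  1 - (2 * inter + s) / (sp + sy + s)
}

test_that("losses match scalar brute-force oracles to 1e-9 relative", {
  set.seed(11)
  for (i in 1:50) {
    p <- matrix(runif(64), 8, 8)
    y <- matrix(rbinom(64, 1, 0.4), 8, 8)
    expect_equal(bce_loss(p, y), bce_oracle(p, y), tolerance = 1e-9)
    expect_equal(dice_loss(p, y), dice_oracle(p, y), tolerance = 1e-9)
    expect_equal(total_loss(p, y, alpha = 0.5),
                 (bce_oracle(p, y) + dice_oracle(p, y)) / 2,
                 tolerance = 1e-9)
  }
})

test_that("loss closed forms and degenerate weights behave", {
  y <- matrix(rbinom(100, 1, 0.5), 10, 10)
  expect_lt(bce_loss(y, y), 1e-6)                    # perfect prediction
  p_half <- matrix(0.5, 10, 10)
  expect_equal(bce_loss(p_half, y), log(2), tolerance = 1e-12)
  expect_lt(dice_loss(y, y), 0.01)
  # disjoint binary masks, vanishing smoothing -> dice loss 1
  a <- matrix(0, 5, 5); a[1:10] <- 1
  b <- matrix(0, 5, 5); b[11:20] <- 1
  expect_equal(dice_loss(a, b, smooth = 1e-12), 1, tolerance = 1e-9)
  # 25/25 pixels with overlap 5 -> 1 - 10/50
  a2 <- matrix(0, 10, 10); a2[1:25] <- 1
  b2 <- matrix(0, 10, 10); b2[21:45] <- 1
  expect_equal(dice_loss(a2, b2, smooth = 0), 0.8)
  p <- matrix(runif(100), 10, 10)
  expect_equal(total_loss(p, y, alpha = 1), bce_loss(p, y))
  expect_equal(total_loss(p, y, alpha = 0), dice_loss(p, y))
  expect_error(bce_loss(p, y[1:50]), "congruent")
})

test_that("loss bounds hold on random inputs", {
  set.seed(12)
  for (i in 1:20) {
    p <- matrix(runif(64), 8, 8); y <- matrix(rbinom(64, 1, 0.5), 8, 8)
    d <- dice_loss(p, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_gte(total_loss(p, y), 0)
  }
})

test_that("loss gradient wrt logits matches finite differences", {
  set.seed(13)
  z <- matrix(rnorm(36), 6, 6)
  y <- matrix(rbinom(36, 1, 0.5), 6, 6)
  p <- 1 / (1 + exp(-z))
  g <- fetalbiom:::total_loss_grad_logits(p, y)
  h <- 1e-6
  for (i in c(1, 17, 36)) {
    zp <- z; zp[i] <- zp[i] + h
    zm <- z; zm[i] <- zm[i] - h
    fd <- (total_loss(1 / (1 + exp(-zp)), y) -
             total_loss(1 / (1 + exp(-zm)), y)) / (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-5)
  }
})

test_that("a 21-epoch plateau triggers exactly one halving at patience 20", {
  sched <- plateau_scheduler(0.001, factor = 0.5, patience = 20L,
                             threshold = 1e-4)
  lrs <- numeric(21)
  for (e in 1:21) {
    sched <- scheduler_step(sched, 1.0)  # never improves after epoch 1
    lrs[e] <- sched$lr
  }
  expect_equal(lrs[1:20], rep(0.001, 20))
  expect_equal(lrs[21], 0.0005)
  expect_identical(sched$n_reductions, 1L)
})

test_that("scheduler ignores sub-threshold improvements and obeys min_lr", {
  sched <- plateau_scheduler(0.001, patience = 2L, threshold = 1e-4)
  # relative threshold: 0.99995 is NOT an improvement over 1.0
  for (v in c(1.0, 0.99995, 0.99996, 0.99997))
    sched <- scheduler_step(sched, v)
  expect_equal(sched$lr, 0.0005)
  # a real improvement resets the counter
  sched <- scheduler_step(sched, 0.5)
  expect_identical(sched$num_bad, 0L)
  sched2 <- plateau_scheduler(0.001, patience = 1L, min_lr = 4e-4)
  for (i in 1:10) sched2 <- scheduler_step(sched2, 1.0)
  expect_equal(sched2$lr, 4e-4)  # floor respected
})

test_that("learning rate is non-increasing and halves exactly", {
  set.seed(14)
  sched <- plateau_scheduler(0.001, patience = 3L)
  lrs <- numeric(60)
  for (e in 1:60) {
    sched <- scheduler_step(sched, runif(1, 0.4, 0.6))
    lrs[e] <- sched$lr
  }
  expect_true(all(diff(lrs) <= 0))
  uniq <- unique(lrs)
  expect_true(all(abs(uniq / 0.001 - 2^-(seq_along(uniq) - 1)) < 1e-12))
})

test_that("an improving stream never reduces the learning rate", {
  sched <- plateau_scheduler(0.001, patience = 2L)
  for (v in seq(1, 0.1, length.out = 30)) sched <- scheduler_step(sched, v)
  expect_equal(sched$lr, 0.001)
  expect_identical(sched$n_reductions, 0L)
})

test_that("the 80/20 split is exact, disjoint, exhaustive and seeded", {
  man <- data.frame(image_id = sprintf("im%03d", 1:700),
                    label_true = rep(c("normal", "microcephaly",
                                       "macrocephaly"), c(500, 100, 100)))
  sp <- split_dataset(man, 0.8, seed = 3)
  expect_length(sp$train_ids, 560)
  expect_length(sp$val_ids, 140)
  expect_length(intersect(sp$train_ids, sp$val_ids), 0)
  expect_setequal(c(sp$train_ids, sp$val_ids), man$image_id)
  sp2 <- split_dataset(man, 0.8, seed = 3)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(man, 0.8, seed = 4)
  expect_false(identical(sp$train_ids, sp3$train_ids))
  # stratification: 80% within each label stratum
  lab <- man$label_true[match(sp$train_ids, man$image_id)]
  expect_identical(as.integer(table(factor(lab, unique(man$label_true)))),
                   c(400L, 80L, 80L))
  expect_error(split_dataset(man[1:4, ], 0.8, 1), "at least 5")
})

test_that("training overfits a single phantom batch", {
  tb <- tiny_batch(n = 4, seed = 51, a_px_range = c(18, 26))
  cfg <- segnet_config(c(64, 96, 3), width_multiplier = 0.125)
  m <- build_segnet(cfg, init_seed = 3)
  st <- fetalbiom:::adam_init(m$layers)
  loss <- NA
  # aggressive single-batch fitting: higher rate than the cohort protocol
  for (step in 1:200) {
    fw <- fetalbiom:::segnet_forward(m, tb$x, TRUE, keep_cache = TRUE)
    p <- 1 / (1 + exp(-fw$logits))
    loss <- total_loss(p, tb$y)
    if (loss < 0.04) break  # early exit once clearly below target
    g <- fetalbiom:::segnet_backward(m, fw$cache,
                                     fetalbiom:::total_loss_grad_logits(p, tb$y))
    up <- fetalbiom:::adam_update(m$layers, g, st, lr = 3e-3, t = step)
    m$layers <- up$layers; st <- up$state
  }
  expect_lt(loss, 0.05)
})

test_that("fit produces history, best checkpoint and contiguous resume", {
  tb <- tiny_batch(n = 8, seed = 61)
  vb <- tiny_batch(n = 4, seed = 71)
  cfg <- segnet_config(c(64, 96, 3), width_multiplier = 0.0625)
  m <- build_segnet(cfg, init_seed = 5)
  tc <- train_config(epochs = 2L, batch_size = 4L, seed = 9, flip_prob = 0.5)
  fit <- fit_segnet(m, tb$x, tb$y, vb$x, vb$y, tc, verbose = FALSE)
  expect_s3_class(fit, "segnet_fit")
  expect_identical(fit$history$epoch, 1:2)
  expect_identical(names(fit$history),
                   c("epoch", "train_loss", "val_loss", "train_dice",
                     "val_dice", "train_dice_soft", "lr"))
  expect_true(all(fit$history$lr == 0.001))  # scheduler silent at patience 20
  expect_equal(fit$best_val_loss, min(fit$history$val_loss))
  expect_identical(fit$best_epoch,
                   fit$history$epoch[which.min(fit$history$val_loss)])
  # resume continues the epoch numbering without gaps
  fit2 <- fit_segnet(fit, tb$x, tb$y, vb$x, vb$y, tc, verbose = FALSE)
  expect_identical(fit2$history$epoch, 1:4)
  # checkpoint round trip
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit2, path)
  back <- load_checkpoint(path)
  expect_equal(back$history, fit2$history)
  expect_error(load_checkpoint(tempfile()), "not found")
  unlink(path)
})
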