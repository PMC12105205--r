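expected_plan <- data.frame(
  block = c("input",
            "encoder1_conv", "encoder1_pool", "encoder2_conv", "encoder2_pool",
            "encoder3_conv", "encoder3_pool", "encoder4_conv", "encoder4_pool",
            "encoder5_conv", "encoder5_pool",
            "decoder5_upsample", "decoder5_conv", "decoder4_upsample",
            "decoder4_conv", "decoder3_upsample", "decoder3_conv",
            "decoder2_upsample", "decoder2_conv", "decoder1_upsample",
            "decoder1_conv", "output"),
  height = c(128, 128, 64, 64, 32, 32, 16, 16, 8, 8, 4,
             8, 8, 16, 16, 32, 32, 64, 64, 128, 128, 128),
  width = c(192, 192, 96, 96, 48, 48, 24, 24, 12, 12, 6,
            12, 12, 24, 24, 48, 48, 96, 96, 192, 192, 192),
  channels = c(3, 64, 64, 128, 128, 256, 256, 512, 512, 512, 512,
               512, 512, 512, 512, 512, 256, 256, 128, 128, 64, 1),
  stringsAsFactors = FALSE)

test_that("configuration derives the channel plan and rejects bad grids", {
  cfg <- segnet_config()
  expect_identical(cfg$encoder_channels, c(64L, 128L, 256L, 512L, 512L))
  expect_identical(cfg$encoder_convs, c(2L, 2L, 3L, 3L, 3L))
  expect_identical(cfg$decoder_channels, rev(cfg$encoder_channels))
  expect_identical(cfg$decoder_convs, c(3L, 3L, 3L, 2L, 2L))
  q <- segnet_config(width_multiplier = 0.25)
  expect_identical(q$encoder_channels, c(16L, 32L, 64L, 128L, 128L))
  expect_error(segnet_config(input_shape = c(100, 192, 3)), "divisible")
})

test_that("block output shapes follow the architecture plan exactly", {
  shapes <- segnet_shape_audit(segnet_config())
  expect_identical(shapes$block, expected_plan$block)
  expect_equal(shapes$height, expected_plan$height)
  expect_equal(shapes$width, expected_plan$width)
  expect_equal(shapes$channels, expected_plan$channels)
  # bottleneck is 4 x 6 x 512 and the head restores 128 x 192 x K
  expect_identical(unlist(shapes[shapes$block == "encoder5_pool", 2:4],
                          use.names = FALSE), c(4L, 6L, 512L) * 1L)
})

test_that("prediction thresholds sigmoid probabilities with >= semantics", {
  cfg <- segnet_config(c(64, 96, 3), width_multiplier = 0.125)
  m <- build_segnet(cfg, init_seed = 1)
  img <- array(runif(64 * 96 * 3), dim = c(64, 96, 3))
  # zero output head -> logits 0 -> sigmoid 0.5 -> all foreground at 0.5
  m$layers$out_conv$W[] <- 0; m$layers$out_conv$b[] <- 0
  expect_true(all(predict_mask(m, img) == 1L))
  m$layers$out_conv$b[] <- -10
  expect_true(all(predict_mask(m, img) == 0L))
  m2 <- build_segnet(cfg, init_seed = 2)
  out <- predict_mask(m2, img, return_prob = TRUE)
  expect_identical(dim(out$mask), c(64L, 96L))
  expect_true(all(out$mask %in% c(0L, 1L)))
  expect_true(all(out$prob >= 0 & out$prob <= 1))
  expect_error(predict_mask(m2, array(0, c(32, 32, 3))), "shape")
})

test_that("max-unpooling places values only at stored indices", {
  set.seed(4)
  x <- array(rnorm(16 * 24 * 5 * 2), dim = c(16, 24, 5, 2))
  pl <- fetalbiom:::cpp_maxpool2_fwd(x)
  up <- fetalbiom:::cpp_unpool2_fwd(pl$y, pl$idx, 16L, 24L)
  for (n in 1:2) for (c in 1:5) {
    plane <- up[, , c, n]
    nz <- which(plane != 0) - 1L
    stored <- sort(pl$idx[, , c, n][pl$y[, , c, n] != 0])
    expect_true(all(nz %in% pl$idx[, , c, n]))
    expect_identical(sum(plane != 0), length(unique(stored)))
  }
  # round trip: pooling the unpooled tensor recovers the pooled values
  pl2 <- fetalbiom:::cpp_maxpool2_fwd(up)
  expect_equal(pl2$y[pl$y > 0], pl$y[pl$y > 0])
})

test_that("factor-2 bilinear upsampling uses half-pixel interpolation", {
  x <- array(c(1, 3, 5, 7), dim = c(2, 2, 1, 1))
  y <- fetalbiom:::cpp_upsample_bilinear2_fwd(x)
  expect_identical(dim(y), c(4L, 4L, 1L, 1L))
  expect_equal(y[, 1, 1, 1], c(1, 1.5, 2.5, 3))   # edge clamp + 1/4-3/4 mix
  expect_equal(y[1, , 1, 1], c(1, 2, 4, 5))
  # adjoint identity <A x, u> = <x, A^T u>
  set.seed(2)
  x2 <- array(rnorm(8 * 12 * 3 * 2), dim = c(8, 12, 3, 2))
  u <- array(rnorm(16 * 24 * 3 * 2), dim = c(16, 24, 3, 2))
  lhs <- sum(fetalbiom:::cpp_upsample_bilinear2_fwd(x2) * u)
  rhs <- sum(x2 * fetalbiom:::cpp_upsample_bilinear2_bwd(u, 8L, 12L))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("backpropagation matches the loss along its own gradient", {
  set.seed(3)
  cfg <- segnet_config(c(32, 32, 3), width_multiplier = 0.0625)
  m <- build_segnet(cfg, init_seed = 2)
  x <- array(runif(32 * 32 * 3 * 2), dim = c(32, 32, 3, 2))
  y <- array(rbinom(32 * 32 * 2, 1, 0.3), dim = c(32, 32, 1, 2))
  lossof <- function(mm) {
    f <- fetalbiom:::segnet_forward(mm, x, training = TRUE)
    total_loss(1 / (1 + exp(-f$logits)), y)
  }
  fw <- fetalbiom:::segnet_forward(m, x, training = TRUE, keep_cache = TRUE)
  p <- 1 / (1 + exp(-fw$logits))
  g <- fetalbiom:::segnet_backward(m, fw$cache,
                                   fetalbiom:::total_loss_grad_logits(p, y))
  gn2 <- 0
  for (nm in names(g)) for (pn in names(g[[nm]]))
    gn2 <- gn2 + sum(g[[nm]][[pn]]^2)
  h <- 1e-6
  mp <- m; mm2 <- m
  for (nm in names(g)) for (pn in names(g[[nm]])) {
    mp$layers[[nm]][[pn]] <- mp$layers[[nm]][[pn]] + h * g[[nm]][[pn]]
    mm2$layers[[nm]][[pn]] <- mm2$layers[[nm]][[pn]] - h * g[[nm]][[pn]]
  }
  fd <- (lossof(mp) - lossof(mm2)) / (2 * h)
  expect_equal(fd / gn2, 1, tolerance = 0.02)
})

test_that("one optimization step decreases the loss in seeded trials", {
  tb <- tiny_batch(n = 2, seed = 41)
  cfg <- segnet_config(c(64, 96, 3), width_multiplier = 0.0625)
  wins <- 0L
  for (seed in 1:10) {
    m <- build_segnet(cfg, init_seed = seed)
    fw <- fetalbiom:::segnet_forward(m, tb$x, TRUE, keep_cache = TRUE)
    p <- 1 / (1 + exp(-fw$logits))
    l0 <- total_loss(p, tb$y)
    g <- fetalbiom:::segnet_backward(m, fw$cache,
                                     fetalbiom:::total_loss_grad_logits(p, tb$y))
    st <- fetalbiom:::adam_init(m$layers)
    up <- fetalbiom:::adam_update(m$layers, g, st, lr = 1e-3, t = 1)
    m$layers <- up$layers
    fw1 <- fetalbiom:::segnet_forward(m, tb$x, TRUE)
    l1 <- total_loss(1 / (1 + exp(-fw1$logits)), tb$y)
    if (l1 < l0) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("both upsampling modes run end to end", {
  tb <- tiny_batch(n = 2, seed = 43)
  for (mode in c("bilinear", "unpool_indices")) {
    cfg <- segnet_config(c(64, 96, 3), width_multiplier = 0.0625,
                         upsample_mode = mode)
    m <- build_segnet(cfg, init_seed = 7)
    fw <- fetalbiom:::segnet_forward(m, tb$x, training = TRUE,
                                     keep_cache = TRUE)
    expect_identical(dim(fw$logits), c(64L, 96L, 1L, 2L))
    p <- 1 / (1 + exp(-fw$logits))
    g <- fetalbiom:::segnet_backward(m, fw$cache,
                                     fetalbiom:::total_loss_grad_logits(p, tb$y))
    expect_true(all(is.finite(unlist(g$enc1_conv1))))
  }
})
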