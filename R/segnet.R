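# The optimized SegNet encoder-decoder, parameterized by width multiplier
# and class count. Five encoder blocks of [conv -> batch-norm -> ReLU]
# repeated 2/2/3/3/3 times, each followed by 2x2 max pooling; the decoder
# mirrors the encoder, up-sampling by 2 (bilinear by default, or
# max-unpooling with the stored encoder indices) before its convolutions,
# with channel reduction carried by the first convolution of each decoder
# block; a final 1x1 convolution maps to K class channels of logits.

BASE_ENCODER_CHANNELS <- c(64L, 128L, 256L, 512L, 512L)
ENCODER_CONVS <- c(2L, 2L, 3L, 3L, 3L)

#' SegNet configuration
#'
#' @param input_shape Integer `(H, W, C)`; H and W must be divisible by
#'   2^5 = 32 so that five pooling stages are exact.
#' @param width_multiplier Scales every channel count (default 1; use e.g.
#'   0.25 for desk-scale training, giving channels 16/32/64/128/128).
#' @param k_classes Output channels K (1 for binary segmentation).
#' @param upsample_mode `"bilinear"` (default) or `"unpool_indices"`
#'   (classic max-unpooling with stored encoder indices).
#' @param dropout_rate Optional dropout after encoder blocks 4 and 5
#'   (default 0 = off).
#' @return List of class `segnet_config` including the derived encoder and
#'   decoder channel/conv plans.
#' @export
segnet_config <- function(input_shape = c(128L, 192L, 3L),
                          width_multiplier = 1,
                          k_classes = 1L,
                          upsample_mode = c("bilinear", "unpool_indices"),
                          dropout_rate = 0) {
  upsample_mode <- match.arg(upsample_mode)
  if (any(input_shape[1:2] %% 32L != 0))
    stop("configuration error: input dims must be divisible by 32 (five 2x2 pools)")
  stopifnot(width_multiplier > 0, k_classes >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  enc <- pmax(1L, as.integer(round(BASE_ENCODER_CHANNELS * width_multiplier)))
  structure(list(
    input_shape = as.integer(input_shape),
    width_multiplier = width_multiplier,
    k_classes = as.integer(k_classes),
    upsample_mode = upsample_mode,
    dropout_rate = dropout_rate,
    encoder_channels = enc,
    encoder_convs = ENCODER_CONVS,
    decoder_channels = rev(enc),
    decoder_convs = rev(ENCODER_CONVS)
  ), class = "segnet_config")
}

# He-normal initialized conv layer with batch-norm parameters.
new_conv_layer <- function(k, cin, cout) {
  list(
    W = array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
              dim = c(k, k, cin, cout)),
    b = numeric(cout),
    gamma = rep(1, cout), beta = numeric(cout),
    rmean = numeric(cout), rvar = rep(1, cout)
  )
}

#' Build a SegNet model
#'
#' Allocates He-normal initialized weights for every convolution plus
#' batch-norm scale/shift and running statistics.
#'
#' @param cfg A [segnet_config()].
#' @param init_seed Integer seed for weight initialization.
#' @return List of class `segnet_model` with `cfg` and `layers` (named
#'   list: `enc<i>_conv<j>`, `dec<i>_conv<j>`, `out_conv`).
#' @export
build_segnet <- function(cfg = segnet_config(), init_seed = 1L) {
  with_local_seed(init_seed, {
    layers <- list()
    cin <- cfg$input_shape[3]
    for (i in seq_along(cfg$encoder_channels)) {
      cout <- cfg$encoder_channels[i]
      for (j in seq_len(cfg$encoder_convs[i])) {
        layers[[sprintf("enc%d_conv%d", i, j)]] <- new_conv_layer(3L, cin, cout)
        cin <- cout
      }
    }
    for (i in rev(seq_along(cfg$decoder_channels))) {
      # dec5 processes the bottleneck first; dec1 restores full resolution
      cout <- cfg$decoder_channels[6 - i]
      for (j in seq_len(cfg$decoder_convs[6 - i])) {
        layers[[sprintf("dec%d_conv%d", i, j)]] <- new_conv_layer(3L, cin, cout)
        cin <- cout
      }
    }
    layers[["out_conv"]] <- list(
      W = array(rnorm(cin * cfg$k_classes, sd = sqrt(2 / cin)),
                dim = c(1, 1, cin, cfg$k_classes)),
      b = numeric(cfg$k_classes))
    structure(list(cfg = cfg, layers = layers), class = "segnet_model")
  })
}

#' @export
print.segnet_model <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l)
    length(l$W) + length(l$b) + length(l$gamma) + length(l$beta), numeric(1)))
  cat(sprintf(paste0("SegNet: input %s, channels [%s], upsample %s, K=%d, ",
                     "%.2fM parameters\n"),
              paste(x$cfg$input_shape, collapse = "x"),
              paste(x$cfg$encoder_channels, collapse = ", "),
              x$cfg$upsample_mode, x$cfg$k_classes, np / 1e6))
  invisible(x)
}

# Conv -> BN -> ReLU with caches for backprop (x, xhat, invstd and the
# post-activation a suffice for the fused backward kernel).
conv_bn_relu_fwd <- function(layer, x, training) {
  fw <- cpp_convbnrelu_fwd(x, layer$W, layer$b, layer$gamma, layer$beta,
                           layer$rmean, layer$rvar, 1e-5, training,
                           TRUE, TRUE)
  list(a = fw$a, cache = list(x = x, xhat = fw$xhat, invstd = fw$invstd),
       batch_mean = fw$batch_mean, batch_var = fw$batch_var)
}

conv_bn_relu_bwd <- function(layer, cache, da) {
  bw <- cpp_convbnrelu_bwd(da, cache$a, cache$xhat, layer$gamma,
                           cache$invstd, cache$x, layer$W, TRUE, TRUE)
  list(dx = bw$dx,
       grads = list(W = bw$dw, b = bw$db, gamma = bw$dgamma, beta = bw$dbeta))
}

# Plain convolution (the 1x1 output head): no batch-norm, no ReLU.
conv_plain_fwd <- function(layer, x) {
  z <- numeric(0)
  cpp_convbnrelu_fwd(x, layer$W, layer$b, z, z, z, z, 1e-5, FALSE,
                     FALSE, FALSE)$a
}

conv_plain_bwd <- function(layer, x, dy) {
  z <- numeric(0)
  bw <- cpp_convbnrelu_bwd(dy, dy, dy, z, z, x, layer$W, FALSE, FALSE)
  list(dx = bw$dx, grads = list(W = bw$dw, b = bw$db))
}

#' Forward pass of a SegNet model
#'
#' @param model A `segnet_model`.
#' @param x Input array `(H, W, C)` for one image or `(H, W, C, N)` batch.
#' @param training Use batch statistics (and update running statistics in
#'   the returned model) and dropout; `FALSE` for evaluation.
#' @param keep_cache Retain per-layer caches for [segnet_backward()].
#' @param record_shapes Record the output shape of every block.
#' @return List with `logits` `(H, W, K, N)`, `model` (running statistics
#'   updated when training), `cache`, and `shapes` (data.frame when
#'   recorded).
#' @export
segnet_forward <- function(model, x, training = FALSE, keep_cache = FALSE,
                           record_shapes = FALSE) {
  cfg <- model$cfg
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  if (!all(dim(x)[1:3] == cfg$input_shape))
    stop("inference error: input shape ", paste(dim(x)[1:3], collapse = "x"),
         " does not match model input ",
         paste(cfg$input_shape, collapse = "x"))
  caches <- list(); pools <- list(); shapes <- list()
  note_shape <- function(name, a) {
    if (record_shapes)
      shapes[[length(shapes) + 1]] <<- data.frame(
        block = name, height = dim(a)[1], width = dim(a)[2],
        channels = dim(a)[3])
  }
  note_shape("input", x)
  a <- x
  for (i in 1:5) {
    for (j in seq_len(cfg$encoder_convs[i])) {
      nm <- sprintf("enc%d_conv%d", i, j)
      fw <- conv_bn_relu_fwd(model$layers[[nm]], a, training)
      if (training) {
        model$layers[[nm]]$rmean <- 0.9 * model$layers[[nm]]$rmean + 0.1 * fw$batch_mean
        model$layers[[nm]]$rvar  <- 0.9 * model$layers[[nm]]$rvar + 0.1 * fw$batch_var
      }
      if (keep_cache) { fw$cache$a <- fw$a; caches[[nm]] <- fw$cache }
      a <- fw$a
    }
    note_shape(sprintf("encoder%d_conv", i), a)
    pl <- cpp_maxpool2_fwd(a)
    pools[[i]] <- list(idx = pl$idx, h = dim(a)[1], w = dim(a)[2])
    a <- pl$y
    note_shape(sprintf("encoder%d_pool", i), a)
    if (training && cfg$dropout_rate > 0 && i >= 4) {
      keep <- array(runif(length(a)) >= cfg$dropout_rate, dim = dim(a))
      a <- a * keep / (1 - cfg$dropout_rate)
      if (keep_cache) caches[[sprintf("drop%d", i)]] <- keep
    }
  }
  for (i in 5:1) {
    pool <- pools[[i]]
    if (cfg$upsample_mode == "unpool_indices") {
      # channel reduction sits in the first conv after up-sampling, so the
      # arriving activation can carry a multiple of the encoder's channel
      # count here; pooling switches are shared across channel groups
      a <- cpp_unpool2_fwd(a, tile_idx(pool$idx, dim(a)[3]), pool$h, pool$w)
    } else {
      a <- cpp_upsample_bilinear2_fwd(a)
    }
    note_shape(sprintf("decoder%d_upsample", i), a)
    for (j in seq_len(cfg$decoder_convs[6 - i])) {
      nm <- sprintf("dec%d_conv%d", i, j)
      fw <- conv_bn_relu_fwd(model$layers[[nm]], a, training)
      if (training) {
        model$layers[[nm]]$rmean <- 0.9 * model$layers[[nm]]$rmean + 0.1 * fw$batch_mean
        model$layers[[nm]]$rvar  <- 0.9 * model$layers[[nm]]$rvar + 0.1 * fw$batch_var
      }
      if (keep_cache) { fw$cache$a <- fw$a; caches[[nm]] <- fw$cache }
      a <- fw$a
    }
    note_shape(sprintf("decoder%d_conv", i), a)
  }
  logits <- conv_plain_fwd(model$layers$out_conv, a)
  note_shape("output", logits)
  if (keep_cache) caches[["out_in"]] <- a
  list(logits = logits, model = model,
       cache = if (keep_cache) list(layers = caches, pools = pools) else NULL,
       shapes = if (record_shapes) do.call(rbind, shapes) else NULL)
}

# Replicate stored pooling indices across channel groups when the decoder
# carries more channels than the encoder did at the same resolution.
tile_idx <- function(idx, channels) {
  d <- dim(idx)
  if (d[3] == channels) return(idx)
  if (channels %% d[3] != 0)
    stop("inference error: decoder channels not a multiple of stored indices")
  idx[, , rep(seq_len(d[3]), length.out = channels), , drop = FALSE]
}

# Backward pass: gradient of the scalar loss wrt every parameter.
# dlogits has the shape of the logits.
segnet_backward <- function(model, cache, dlogits) {
  cfg <- model$cfg
  grads <- list()
  bw <- conv_plain_bwd(model$layers$out_conv, cache$layers$out_in, dlogits)
  grads$out_conv <- bw$grads
  da <- bw$dx
  for (i in 1:5) {
    for (j in rev(seq_len(cfg$decoder_convs[6 - i]))) {
      nm <- sprintf("dec%d_conv%d", i, j)
      bw <- conv_bn_relu_bwd(model$layers[[nm]], cache$layers[[nm]], da)
      grads[[nm]] <- bw$grads
      da <- bw$dx
    }
    pool <- cache$pools[[i]]
    if (cfg$upsample_mode == "unpool_indices") {
      da <- cpp_unpool2_bwd(da, tile_idx(pool$idx, dim(da)[3]),
                            pool$h / 2L, pool$w / 2L)
    } else {
      da <- cpp_upsample_bilinear2_bwd(da, pool$h / 2L, pool$w / 2L)
    }
  }
  for (i in 5:1) {
    dr <- cache$layers[[sprintf("drop%d", i)]]
    if (!is.null(dr)) da <- da * dr / (1 - cfg$dropout_rate)
    pool <- cache$pools[[i]]
    da <- cpp_maxpool2_bwd(pool$idx, da, pool$h, pool$w)
    for (j in rev(seq_len(cfg$encoder_convs[i]))) {
      nm <- sprintf("enc%d_conv%d", i, j)
      bw <- conv_bn_relu_bwd(model$layers[[nm]], cache$layers[[nm]], da)
      grads[[nm]] <- bw$grads
      da <- bw$dx
    }
  }
  grads
}

#' Predict a binary mask for one image
#'
#' Applies the sigmoid to the logits and thresholds. The boundary
#' convention is `>=`: a probability exactly at the threshold is
#' foreground (so an all-zero-logit model at threshold 0.5 predicts all
#' ones).
#'
#' @param model A `segnet_model` (typically the best checkpoint from
#'   [fit_segnet()]).
#' @param image `(H, W, 3)` array (preprocessed) or `(H, W, 3, N)` batch.
#' @param threshold Probability threshold in (0, 1).
#' @param return_prob Also return the probability map.
#' @return Integer 0/1 mask `(H, W)` (or `(H, W, N)` for a batch); with
#'   `return_prob`, a list with `mask` and `prob`.
#' @export
predict_mask <- function(model, image, threshold = 0.5, return_prob = FALSE) {
  single <- length(dim(image)) == 3
  fw <- segnet_forward(model, image, training = FALSE)
  prob <- 1 / (1 + exp(-fw$logits))
  mask <- array(as.integer(prob >= threshold), dim = dim(prob))
  # drop the K=1 class axis
  d <- dim(mask)
  mask <- array(mask[, , 1, ], dim = c(d[1], d[2], d[4]))
  prob <- array(prob[, , 1, ], dim = c(d[1], d[2], d[4]))
  if (single) { mask <- mask[, , 1]; prob <- prob[, , 1] }
  if (return_prob) list(mask = mask, prob = prob) else mask
}

#' Audit the per-block output shapes of a configuration
#'
#' Runs one zero image through the network and records every block's
#' output dimensions; on the default configuration this reproduces the
#' architecture plan exactly (encoder pools 64x96x64 ... 4x6x512, decoder
#' mirror, 128x192xK output).
#'
#' @param cfg A [segnet_config()].
#' @return Data.frame with `block`, `height`, `width`, `channels`.
#' @export
segnet_shape_audit <- function(cfg = segnet_config()) {
  model <- build_segnet(cfg, init_seed = 0L)
  x <- array(0, dim = c(cfg$input_shape, 1))
  segnet_forward(model, x, training = FALSE, record_shapes = TRUE)$shapes
}
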