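# Shared fixtures: reference tables and quickly rendered phantoms.

ref_default <- default_reference_table()

# Small hand-checkable table: at week 20 the HC mean is 175 mm, SD 8 mm.
ref_hand <- data.frame(
  ga_weeks    = 18:22,
  hc_mean_mm  = c(155, 165, 175, 185, 195),
  hc_sd_mm    = c(7.2, 7.6, 8.0, 8.4, 8.8),
  bpd_mean_mm = c(43, 46, 49, 52, 55),
  bpd_sd_mm   = c(1.7, 1.8, 1.9, 2.0, 2.1)
)

# A rendered phantom pair with known ground truth.
quick_phantom <- function(seed = 1, ga = 26, class_mode = "force_normal",
                          noise = noise_params()) {
  spec <- sample_phantom_spec(ref_default, ga, class_mode, rng_seed = seed)
  render_phantom(spec, noise = noise)
}

# Exact filled-ellipse mask built directly from geometry (no rendering).
ellipse_mask <- function(h, w, cx, cy, a_px, b_px, rot_deg = 0) {
  th <- rot_deg * pi / 180
  x <- matrix(rep(0:(w - 1), each = h), h, w) - cx
  y <- matrix(rep(0:(h - 1), times = w), h, w) - cy
  xr <- x * cos(th) + y * sin(th)
  yr <- -x * sin(th) + y * cos(th)
  matrix(as.integer((xr / a_px)^2 + (yr / b_px)^2 <= 1), h, w)
}

# Tiny model-ready phantom batch for training tests: small frame, small
# heads (scaled reference), width-0.125 scale.
tiny_batch <- function(n = 4, seed = 5, h = 64, w = 96,
                       a_px_range = c(14, 20)) {
  x <- array(0, dim = c(h, w, 3, n))
  y <- array(0, dim = c(h, w, 1, n))
  for (i in seq_len(n)) {
    spec <- sample_phantom_spec(ref_default, 15 + (i %% 4), "force_normal",
                                rng_seed = seed + i, height = h, width = w,
                                a_px_range = a_px_range)
    pair <- render_phantom(spec)
    x[, , , i] <- normalize_image(pair$image)
    y[, , 1, i] <- pair$mask
  }
  list(x = x, y = y)
}
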