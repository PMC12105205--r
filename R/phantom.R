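# Synthetic fetal-head ultrasound phantoms with analytic ground truth.
# Every phantom carries its exact head-circumference (HC), biparietal
# diameter (BPD) and growth-class label, so segmentation, biometry and
# classification can all be scored against closed-form truth.

#' Noise and appearance parameters for phantom rendering
#'
#' Speckle is modelled as a multiplicative mean-one gamma field (shape
#' `speckle_shape`, so variance `1/speckle_shape`), smoothed with a Gaussian
#' kernel of `speckle_blur_sigma` pixels to give it the lateral correlation
#' of real speckle, and mixed in with weight `speckle_weight` (0 disables
#' noise entirely). The skull rim is a bright band of roughly
#' `rim_thickness_px` pixels straddling the ellipse outline. Optional
#' angular shadow sectors attenuate wedges below the head the way bone
#' shadows do.
#'
#' @param background,interior,rim_brightness Intensities in \[0, 1\].
#' @param rim_thickness_px Rim band thickness in pixels.
#' @param speckle_shape Gamma shape of the multiplicative field.
#' @param speckle_weight Mixing weight in \[0, 1\]; 0 = noiseless.
#' @param speckle_blur_sigma Gaussian smoothing sigma in pixels.
#' @param n_shadow_sectors Number of attenuated angular wedges (default 0).
#' @param shadow_strength Multiplicative attenuation inside a wedge.
#' @param shadow_width_deg Angular width of each wedge, degrees.
#' @return List of class `noise_params`.
#' @export
noise_params <- function(background = 0.10, interior = 0.40,
                         rim_brightness = 0.95, rim_thickness_px = 3,
                         speckle_shape = 3, speckle_weight = 0.7,
                         speckle_blur_sigma = 1.0,
                         n_shadow_sectors = 0, shadow_strength = 0.5,
                         shadow_width_deg = 20) {
  stopifnot(speckle_weight >= 0, speckle_weight <= 1, speckle_shape > 0,
            rim_thickness_px > 0, n_shadow_sectors >= 0)
  structure(as.list(environment()), class = "noise_params")
}

#' Sample a phantom head specification at a gestational age
#'
#' Draws an HC z-score from a standard normal truncated to the requested
#' class band (`force_micro`: z < -2, `force_macro`: z > +2, `force_normal`:
#' |z| <= 2; `random`: the untruncated distribution, clipped to |z| <= 3.5
#' so every head is renderable), converts it to an HC in mm using the
#' reference mean/SD at `ga_weeks`, and derives the ellipse semi-axes from
#' the cephalic index by inverting the Ramanujan perimeter (closed form at
#' fixed axis ratio). Pixel spacing is drawn so the head occupies a
#' realistic fraction of the frame, then clamped to `spacing_range`.
#' The stored class label is recomputed from `hc_true` with the strict
#' +/-2 SD rule, so label and measurement can never disagree.
#'
#' @param ref Reference table (see [default_reference_table()]).
#' @param ga_weeks Gestational age in weeks; must lie inside the table.
#' @param class_mode One of `"random"`, `"force_micro"`, `"force_normal"`,
#'   `"force_macro"`.
#' @param rng_seed Integer seed making the draw reproducible.
#' @param cephalic_index Minor/major semi-axis ratio (default 0.78).
#' @param height,width Frame size in pixels the phantom must fit.
#' @param spacing_range Admissible pixel spacing in mm/px, within (0.05, 1].
#' @param a_px_range Range the semi-major axis should span in pixels; the
#'   spacing is drawn to land in it (then clamped to `spacing_range`).
#' @param z Optional fixed z-score overriding the random draw (used for
#'   deterministic constructions).
#' @param image_id Identifier stored in the spec.
#' @return List of class `phantom_spec` with fields `image_id`, `ga_weeks`,
#'   `center_xy` (x, y pixels), `semi_axis_a`, `semi_axis_b` (mm),
#'   `rotation_deg`, `pixel_spacing` (mm/px), `hc_true`, `bpd_true` (mm),
#'   `label_true`, `noise_seed`, `height`, `width`.
#' @export
sample_phantom_spec <- function(ref, ga_weeks,
                                class_mode = c("random", "force_micro",
                                               "force_normal", "force_macro"),
                                rng_seed = NULL,
                                cephalic_index = 0.78,
                                height = 128L, width = 192L,
                                spacing_range = c(0.05, 1.0),
                                a_px_range = c(32, 50),
                                z = NULL, image_id = "phantom_0001") {
  class_mode <- match.arg(class_mode)
  stopifnot(spacing_range[1] > 0.0, spacing_range[2] <= 1.0,
            spacing_range[1] < spacing_range[2])
  r <- ref_lookup(ref, ga_weeks, "hc")  # errors if ga outside table

  with_local_seed(rng_seed, {
    if (is.null(z)) {
      band <- switch(class_mode,
        random       = c(-3.5, 3.5),
        force_micro  = c(-3.5, -2),
        force_normal = c(-2, 2),
        force_macro  = c(2, 3.5))
      u <- runif(1, pnorm(band[1]), pnorm(band[2]))
      z <- qnorm(u)
    }
    hc_true <- r$mean + z * r$sd
    if (hc_true <= 0)
      stop("phantom generation error: non-positive HC at ga ", ga_weeks)
    ax <- hc_to_semi_axes(hc_true, cephalic_index)
    label_true <- label_from_z((hc_true - r$mean) / r$sd)

    # spacing so the semi-major axis spans a plausible pixel extent
    margin <- 3
    a_px_target <- runif(1, a_px_range[1], a_px_range[2])
    spacing <- min(max(ax$a / a_px_target, spacing_range[1]), spacing_range[2])
    a_px <- ax$a / spacing
    lim <- (min(height, width) - 1) / 2 - margin
    if (a_px > lim)
      stop(sprintf(paste0("phantom generation error: head semi-axis %.1f px ",
                          "exceeds frame limit %.1f px at spacing %.3f mm/px"),
                   a_px, lim, spacing))
    cx <- runif(1, a_px + margin, width - 1 - a_px - margin)
    cy <- runif(1, a_px + margin, height - 1 - a_px - margin)
    rotation <- runif(1, 0, 180)
    noise_seed <- sample.int(.Machine$integer.max, 1)

    structure(list(
      image_id = image_id, ga_weeks = ga_weeks,
      center_xy = c(x = cx, y = cy),
      semi_axis_a = ax$a, semi_axis_b = ax$b,
      rotation_deg = rotation, pixel_spacing = spacing,
      hc_true = hc_true, bpd_true = 2 * ax$b,
      label_true = label_true, noise_seed = noise_seed,
      height = as.integer(height), width = as.integer(width)
    ), class = "phantom_spec")
  })
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("phantom %s: GA %.1f wk, HC %.1f mm, BPD %.1f mm (%s), ",
                     "%.3f mm/px, %dx%d px\n"),
              x$image_id, x$ga_weeks, x$hc_true, x$bpd_true, x$label_true,
              x$pixel_spacing, x$height, x$width))
  invisible(x)
}

#' Render a phantom image and its exact ground-truth mask
#'
#' The mask is the exact filled ellipse: a pixel is foreground iff its
#' center (integer coordinates, x = column, y = row, 0-based) lies inside
#' the rotated ellipse. The image shows a dark speckled background, a
#' mid-intensity head interior and a bright skull rim straddling the
#' outline; speckle is multiplicative and deterministic given
#' `spec$noise_seed`.
#'
#' @param spec A `phantom_spec`.
#' @param height,width Frame size; defaults to the spec's own frame.
#' @param noise A [noise_params()] list.
#' @return List of class `phantom_pair` with `image` (H x W matrix in
#'   \[0, 1\]), `mask` (H x W integer 0/1 matrix) and `spec`.
#' @export
render_phantom <- function(spec, height = spec$height, width = spec$width,
                           noise = noise_params()) {
  stopifnot(inherits(spec, "phantom_spec"))
  a_px <- spec$semi_axis_a / spec$pixel_spacing
  b_px <- spec$semi_axis_b / spec$pixel_spacing
  cx <- spec$center_xy[["x"]]; cy <- spec$center_xy[["y"]]
  if (cx - a_px < -0.5 || cx + a_px > width - 0.5 ||
      cy - a_px < -0.5 || cy + a_px > height - 0.5)
    stop(sprintf(paste0("render error: ellipse (center %.1f,%.1f, semi-axis ",
                        "%.1f px) overflows the %dx%d frame"),
                 cx, cy, a_px, height, width))

  th <- spec$rotation_deg * pi / 180
  x <- matrix(rep(0:(width - 1), each = height), height, width) - cx
  y <- matrix(rep(0:(height - 1), times = width), height, width) - cy
  xr <- x * cos(th) + y * sin(th)
  yr <- -x * sin(th) + y * cos(th)
  rho <- sqrt((xr / a_px)^2 + (yr / b_px)^2)

  mask <- matrix(as.integer(rho <= 1), height, width)
  clean <- matrix(noise$background, height, width)
  clean[rho <= 1] <- noise$interior
  rim_half <- noise$rim_thickness_px / (2 * b_px)
  clean[abs(rho - 1) <= rim_half] <- noise$rim_brightness

  if (noise$n_shadow_sectors > 0) {
    phi <- atan2(y, x) * 180 / pi  # angle from center, degrees
    centers <- with_local_seed(spec$noise_seed + 1L,
                               runif(noise$n_shadow_sectors, -180, 180))
    shadowed <- Reduce(`|`, lapply(centers, function(c0) {
      d <- abs(((phi - c0 + 180) %% 360) - 180)
      d <= noise$shadow_width_deg / 2 & rho > 1
    }))
    clean[shadowed] <- clean[shadowed] * noise$shadow_strength
  }

  img <- clean
  if (noise$speckle_weight > 0) {
    field <- with_local_seed(spec$noise_seed, {
      f <- matrix(rgamma(height * width, shape = noise$speckle_shape,
                         scale = 1 / noise$speckle_shape), height, width)
      if (noise$speckle_blur_sigma > 0)
        f <- EBImage::gblur(f, sigma = noise$speckle_blur_sigma)
      f
    })
    img <- clean * (1 + noise$speckle_weight * (field - 1))
  }
  img[img < 0] <- 0; img[img > 1] <- 1

  structure(list(image = img, mask = mask, spec = spec),
            class = "phantom_pair")
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image PNGs (`<id>.png`, 8-bit grayscale), `n` mask PNGs
#' (`<id>_mask.png`, values 0/255) and `manifest.csv` with header
#' `image_id,ga_weeks,pixel_spacing_mm,hc_true_mm,bpd_true_mm,label_true`.
#' Trimester balance is enforced by sampling gestational age uniformly from
#' the second-trimester range for half the images and from the
#' third-trimester range for the other half; class counts follow
#' `class_fractions` exactly (largest-remainder rounding), shuffled across
#' the cohort. Fully deterministic given `seed`.
#'
#' @param n Number of phantoms.
#' @param out_dir Output directory (created if missing).
#' @param ref Reference table.
#' @param class_fractions Length-3 numeric (micro, normal, macro) summing
#'   to 1.
#' @param seed Integer seed for the whole dataset.
#' @param height,width Frame size in pixels.
#' @param noise A [noise_params()] list.
#' @param trimester_ranges List with `second` and `third` GA ranges
#'   (weeks).
#' @param a_px_range Passed to [sample_phantom_spec()].
#' @param write_images Set `FALSE` to produce only the manifest (fast path
#'   for cohort-level checks).
#' @return The manifest data.frame (invisibly), with an extra
#'   `image_path` / `mask_path` column pair when images are written.
#' @export
generate_phantom_dataset <- function(n, out_dir, ref,
                                     class_fractions = c(0.15, 0.70, 0.15),
                                     seed = 1L,
                                     height = 128L, width = 192L,
                                     noise = noise_params(),
                                     trimester_ranges = list(second = c(14, 27),
                                                             third = c(27, 40)),
                                     a_px_range = c(32, 50),
                                     write_images = TRUE) {
  stopifnot(n >= 1, length(class_fractions) == 3,
            abs(sum(class_fractions) - 1) < 1e-8)
  if (write_images && !dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)

  ga_lo <- max(min(ref$ga_weeks), trimester_ranges$second[1])
  ga_hi <- min(max(ref$ga_weeks), trimester_ranges$third[2])

  manifest <- with_local_seed(seed, {
    n2 <- floor(n / 2); n3 <- n - n2
    ga <- c(runif(n2, ga_lo, min(trimester_ranges$second[2], ga_hi)),
            runif(n3, max(trimester_ranges$third[1], ga_lo), ga_hi))
    modes <- sample(rep(c("force_micro", "force_normal", "force_macro"),
                        largest_remainder(n, class_fractions)))
    spec_seeds <- sample.int(.Machine$integer.max, n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("phantom_%04d", i)
      spec <- sample_phantom_spec(ref, ga[i], class_mode = modes[i],
                                  rng_seed = spec_seeds[i],
                                  height = height, width = width,
                                  a_px_range = a_px_range,
                                  image_id = id)
      row <- data.frame(image_id = id, ga_weeks = ga[i],
                        pixel_spacing_mm = spec$pixel_spacing,
                        hc_true_mm = spec$hc_true, bpd_true_mm = spec$bpd_true,
                        label_true = spec$label_true,
                        stringsAsFactors = FALSE)
      if (write_images) {
        pair <- render_phantom(spec, noise = noise)
        img_path <- file.path(out_dir, paste0(id, ".png"))
        msk_path <- file.path(out_dir, paste0(id, "_mask.png"))
        png::writePNG(pair$image, img_path)
        png::writePNG(pair$mask * 1.0, msk_path)
        row$image_path <- img_path
        row$mask_path <- msk_path
      }
      rows[[i]] <- row
    }
    do.call(rbind, rows)
  })

  if (write_images)
    utils::write.csv(manifest[, c("image_id", "ga_weeks", "pixel_spacing_mm",
                                  "hc_true_mm", "bpd_true_mm", "label_true")],
                     file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# Integer class counts matching fractions exactly via largest remainders.
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    order_by_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_by_rem[seq_len(short)]] <- counts[order_by_rem[seq_len(short)]] + 1
  }
  as.integer(counts)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG
# state afterwards; with a NULL seed the current stream is used directly.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
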