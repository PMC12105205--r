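test_that("class bands truncate the HC draw and set the matching label", {
  # week 20 of the hand table: mean 175, sd 8 -> normal band [159, 191]
  for (seed in 1:20) {
    s <- sample_phantom_spec(ref_hand, 20, "force_normal", rng_seed = seed)
    expect_gte(s$hc_true, 159); expect_lte(s$hc_true, 191)
    expect_identical(s$label_true, "normal")
  }
  for (seed in 1:20) {
    s <- sample_phantom_spec(ref_hand, 20, "force_micro", rng_seed = seed)
    expect_lt(s$hc_true, 159)
    expect_identical(s$label_true, "microcephaly")
    s <- sample_phantom_spec(ref_hand, 20, "force_macro", rng_seed = seed)
    expect_gt(s$hc_true, 191)
    expect_identical(s$label_true, "macrocephaly")
  }
})

test_that("a fixed z-score maps exactly onto the reference scale", {
  s <- sample_phantom_spec(ref_hand, 20, "random", rng_seed = 1, z = -2.5)
  expect_equal(s$hc_true, 175 - 2.5 * 8)  # 155 mm
  expect_identical(s$label_true, "microcephaly")
})

test_that("spec geometry is internally consistent", {
  s <- sample_phantom_spec(ref_default, 30, "random", rng_seed = 3)
  expect_gte(s$semi_axis_a, s$semi_axis_b)
  expect_equal(s$bpd_true, 2 * s$semi_axis_b)
  # stored HC is the Ramanujan perimeter, itself within 0.1% of exact
  expect_equal(ramanujan_perimeter(s$semi_axis_a, s$semi_axis_b), s$hc_true,
               tolerance = 1e-9)
  expect_equal(ellipse_perimeter_exact(s$semi_axis_a, s$semi_axis_b),
               s$hc_true, tolerance = 1e-3)
  expect_true(s$pixel_spacing > 0.05 && s$pixel_spacing <= 1)
  expect_error(sample_phantom_spec(ref_default, 50, "random", rng_seed = 1),
               "outside")
})

test_that("rendered mask is the exact filled ellipse", {
  # circle: mask pixel count within 1% of pi * r^2
  s <- sample_phantom_spec(ref_hand, 20, "force_normal", rng_seed = 2,
                           cephalic_index = 0.999999)
  pair <- render_phantom(s)
  r_px <- s$semi_axis_a / s$pixel_spacing
  expect_lt(abs(sum(pair$mask) - pi * r_px^2) / (pi * r_px^2), 0.01)
  expect_identical(dim(pair$image), dim(pair$mask))
  expect_true(all(pair$mask %in% c(0L, 1L)))
  expect_true(all(pair$image >= 0 & pair$image <= 1))
})

test_that("rendering is deterministic given the noise seed", {
  s <- sample_phantom_spec(ref_default, 24, "random", rng_seed = 4)
  p1 <- render_phantom(s); p2 <- render_phantom(s)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$mask, p2$mask)
})

# normalized elliptical radius of every pixel for a rendered pair
sqrt_rho <- function(pair, s) {
  h <- nrow(pair$image); w <- ncol(pair$image)
  th <- s$rotation_deg * pi / 180
  x <- matrix(rep(0:(w - 1), each = h), h, w) - s$center_xy[["x"]]
  y <- matrix(rep(0:(h - 1), times = w), h, w) - s$center_xy[["y"]]
  xr <- x * cos(th) + y * sin(th)
  yr <- -x * sin(th) + y * cos(th)
  sqrt((xr / (s$semi_axis_a / s$pixel_spacing))^2 +
         (yr / (s$semi_axis_b / s$pixel_spacing))^2)
}

test_that("zero speckle weight gives the exact clean intensities", {
  s <- sample_phantom_spec(ref_default, 24, "random", rng_seed = 4)
  np <- noise_params(speckle_weight = 0, interior = 0.37, background = 0.11)
  pair <- render_phantom(s, noise = np)
  rim <- abs(sqrt_rho(pair, s) - 1) <= np$rim_thickness_px /
    (2 * s$semi_axis_b / s$pixel_spacing)
  inside <- pair$mask == 1 & !rim
  outside <- pair$mask == 0 & !rim
  expect_true(all(pair$image[inside] == 0.37))
  expect_true(all(pair$image[outside] == 0.11))
})

test_that("a phantom too large for its frame is refused", {
  s <- sample_phantom_spec(ref_default, 35, "random", rng_seed = 6)
  expect_error(render_phantom(s, height = 64L, width = 96L), "overflow")
})

test_that("dataset generation writes a coherent, reproducible manifest", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  m1 <- generate_phantom_dataset(10, d1, ref_default,
                                 class_fractions = c(0, 1, 0), seed = 21)
  expect_identical(nrow(m1), 10L)
  expect_true(all(m1$label_true == "normal"))
  expect_true(all(file.exists(file.path(d1, paste0(m1$image_id, ".png")))))
  expect_true(all(file.exists(file.path(d1, paste0(m1$image_id, "_mask.png")))))
  man_csv <- utils::read.csv(file.path(d1, "manifest.csv"))
  expect_identical(names(man_csv),
                   c("image_id", "ga_weeks", "pixel_spacing_mm", "hc_true_mm",
                     "bpd_true_mm", "label_true"))
  m2 <- generate_phantom_dataset(10, d2, ref_default,
                                 class_fractions = c(0, 1, 0), seed = 21)
  expect_equal(m1[names(man_csv)], m2[names(man_csv)])
  # masks written as strict 0/255 PNG
  msk <- png::readPNG(file.path(d1, paste0(m1$image_id[1], "_mask.png")))
  expect_true(all(msk %in% c(0, 1)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("trimesters are balanced in a large cohort", {
  man <- generate_phantom_dataset(700, tempdir(), ref_default, seed = 31,
                                  write_images = FALSE)
  expect_identical(sum(man$ga_weeks < 27), 350L)
  expect_identical(sum(man$ga_weeks >= 27), 350L)
  # class mix follows the requested fractions exactly
  expect_identical(as.integer(table(factor(man$label_true,
    c("microcephaly", "normal", "macrocephaly")))), c(105L, 490L, 105L))
  # every stored label agrees with reclassification from hc_true
  relab <- vapply(seq_len(nrow(man)), function(i)
    classify_case(man$hc_true_mm[i], man$ga_weeks[i], ref_default)$label,
    character(1))
  expect_identical(relab, man$label_true)
})

test_that("biometry on the noiseless ground-truth mask recovers the spec", {
  for (seed in c(11, 12, 13)) {
    s <- sample_phantom_spec(ref_default, 22 + seed %% 10, "random",
                             rng_seed = seed)
    pair <- render_phantom(s, noise = noise_params(speckle_weight = 0))
    res <- measure_biometry(pair$mask, s$pixel_spacing)
    expect_lt(abs(res$hc_mm - s$hc_true) / s$hc_true, 0.02)
    expect_lt(abs(res$bpd_mm - s$bpd_true) / s$bpd_true, 0.02)
  }
})
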