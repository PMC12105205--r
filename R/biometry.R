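# HC and BPD extraction from a predicted binary mask: keep the largest
# 8-connected component, trace its outer contour, fit an ellipse by direct
# least squares, and convert the fitted axes to millimetres.
#
# Coordinate convention: pixel centers at integer coordinates, x = column,
# y = row (both 0-based); rotation measured from the x-axis, degrees in
# [0, 180).

#' Keep the largest 8-connected foreground component
#'
#' Guards biometry against satellite specks produced by segmentation noise.
#' Ties between equal-sized components are broken deterministically by scan
#' order (column-major) and flagged.
#'
#' @param mask Binary 0/1 matrix.
#' @return List with `mask` (largest component only), `removed_px` and
#'   `flags` (character vector; may contain `"ambiguous_component"`).
#' @export
largest_component <- function(mask) {
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1))) stop("validation error: mask must be binary 0/1")
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (sum(m) == 0) stop("measurement error: no head region in mask")
  lab <- cpp_label_components8(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)  # first label in scan order wins ties
  flags <- character(0)
  if (sum(sizes == max(sizes)) > 1) flags <- "ambiguous_component"
  out <- matrix(as.integer(lab == keep), nrow(m), ncol(m))
  list(mask = out, removed_px = sum(m) - sum(out), flags = flags)
}

#' Least-squares ellipse fit to the outer contour of a mask
#'
#' Traces the outer boundary of the (single-component) mask and fits an
#' ellipse by the direct least-squares conic method, then converts the
#' conic to center, axes and rotation. Because mask pixels are "center
#' inside the curve", boundary-pixel centers sit about half a pixel inside
#' the continuous outline; `outer_offset_px` (default 0.5) is added to each
#' semi-axis to recover the outer caliper convention.
#'
#' @param mask Binary matrix containing one foreground component with at
#'   least `min_px` pixels.
#' @param min_px Minimum foreground pixel count (default 50).
#' @param outer_offset_px Half-pixel outer-boundary correction.
#' @return List of class `fitted_ellipse` with `center_xy` (x, y px),
#'   `major_axis`, `minor_axis` (full lengths, px), `rotation_deg` in
#'   \[0, 180), and `fit_residual` (mean absolute normalized radial
#'   deviation of contour points).
#' @export
fit_head_ellipse <- function(mask, min_px = 50, outer_offset_px = 0.5) {
  if (sum(mask) < min_px)
    stop("measurement error: fewer than ", min_px, " foreground pixels")
  ct <- mask_contour(mask)
  fit <- fit_ellipse_lsq(ct[, 1], ct[, 2])
  a <- fit$a + outer_offset_px
  b <- fit$b + outer_offset_px
  rho <- sqrt(((cos(fit$theta) * (ct[, 1] - fit$cx) +
                  sin(fit$theta) * (ct[, 2] - fit$cy)) / fit$a)^2 +
                ((-sin(fit$theta) * (ct[, 1] - fit$cx) +
                    cos(fit$theta) * (ct[, 2] - fit$cy)) / fit$b)^2)
  structure(list(
    center_xy = c(x = fit$cx, y = fit$cy),
    major_axis = 2 * a, minor_axis = 2 * b,
    rotation_deg = (fit$theta * 180 / pi) %% 180,
    fit_residual = mean(abs(rho - 1))
  ), class = "fitted_ellipse")
}

#' @export
print.fitted_ellipse <- function(x, ...) {
  cat(sprintf("ellipse: center (%.1f, %.1f) px, axes %.1f x %.1f px, %.1f deg\n",
              x$center_xy[["x"]], x$center_xy[["y"]],
              x$major_axis, x$minor_axis, x$rotation_deg))
  invisible(x)
}

#' Perimeter of a fitted ellipse in millimetres
#'
#' Ramanujan approximation applied to the semi-axes converted to mm.
#'
#' @param e A `fitted_ellipse` (axes in px).
#' @param spacing Pixel spacing in mm/px (> 0).
#' @return Perimeter in mm.
#' @export
ellipse_perimeter_mm <- function(e, spacing) {
  stopifnot(spacing > 0)
  ramanujan_perimeter(e$major_axis / 2 * spacing, e$minor_axis / 2 * spacing)
}

#' Measure HC and BPD from a binary mask
#'
#' Pipeline: fill holes, keep the largest 8-connected component, trace the
#' outer contour, scale contour coordinates to millimetres (supporting
#' anisotropic spacing), fit the ellipse, and report
#' HC = Ramanujan perimeter of the fitted ellipse and
#' BPD = full minor axis (outer-to-outer; `bpd_scale` rescales for other
#' caliper conventions). The raw contour arc length is included as a
#' diagnostic (`contour_mm`): it runs slightly above the fitted perimeter
#' on noisy masks, which is why the fitted ellipse is the primary HC.
#'
#' @param mask Binary 0/1 matrix.
#' @param spacing Isotropic pixel spacing, mm/px; ignored when `anisotropy`
#'   is given.
#' @param anisotropy Optional per-axis spacing `c(sy, sx)` in mm/px.
#' @param bpd_scale Multiplier on the minor axis for alternative caliper
#'   conventions (default 1, outer-to-outer).
#' @return List of class `biometry_result` with `hc_mm`, `bpd_mm`,
#'   `ellipse` (pixel-unit fit), `pixel_spacing`, `n_foreground_px`,
#'   `contour_mm` and `quality_flags`.
#' @export
measure_biometry <- function(mask, spacing, anisotropy = NULL, bpd_scale = 1) {
  sp <- if (is.null(anisotropy)) c(spacing, spacing) else rep_len(anisotropy, 2)
  stopifnot(all(sp > 0))
  filled <- fill_mask_holes(mask)
  lc <- largest_component(filled)
  flags <- lc$flags
  if (lc$removed_px > 0)
    flags <- c(flags, sprintf("removed_%d_px", lc$removed_px))

  ct <- mask_contour(lc$mask)
  # contour in mm (x = col * sx, y = row * sy), fit there so anisotropic
  # spacing is handled before any axis is read off
  x_mm <- ct[, 1] * sp[2]; y_mm <- ct[, 2] * sp[1]
  fit <- fit_ellipse_lsq(x_mm, y_mm)
  off <- 0.5 * mean(sp)  # half-pixel outer correction, mm
  a_mm <- fit$a + off; b_mm <- fit$b + off
  if (!is.finite(a_mm) || !is.finite(b_mm) || b_mm <= 0)
    stop("fit error: degenerate contour")

  hc_mm <- ramanujan_perimeter(a_mm, b_mm)
  bpd_mm <- 2 * b_mm * bpd_scale
  seg <- sqrt(diff(c(x_mm, x_mm[1]))^2 + diff(c(y_mm, y_mm[1]))^2)
  px_mean <- mean(sp)
  rho <- sqrt(((cos(fit$theta) * (x_mm - fit$cx) +
                  sin(fit$theta) * (y_mm - fit$cy)) / fit$a)^2 +
                ((-sin(fit$theta) * (x_mm - fit$cx) +
                    cos(fit$theta) * (y_mm - fit$cy)) / fit$b)^2)
  ellipse <- structure(list(
    center_xy = c(x = fit$cx / sp[2], y = fit$cy / sp[1]),
    major_axis = 2 * a_mm / px_mean, minor_axis = 2 * b_mm / px_mean,
    rotation_deg = (fit$theta * 180 / pi) %% 180,
    fit_residual = mean(abs(rho - 1))
  ), class = "fitted_ellipse")
  if (abs(sp[1] - sp[2]) > 1e-12) flags <- c(flags, "anisotropic_spacing")

  structure(list(
    hc_mm = hc_mm, bpd_mm = bpd_mm, ellipse = ellipse,
    pixel_spacing = if (is.null(anisotropy)) spacing else sp,
    n_foreground_px = sum(lc$mask), contour_mm = sum(seg),
    quality_flags = flags
  ), class = "biometry_result")
}

#' @export
print.biometry_result <- function(x, ...) {
  cat(sprintf("biometry: HC %.1f mm, BPD %.1f mm (%d px head%s)\n",
              x$hc_mm, x$bpd_mm, x$n_foreground_px,
              if (length(x$quality_flags))
                paste0("; flags: ", paste(x$quality_flags, collapse = ","))
              else ""))
  invisible(x)
}

# Outer contour of the largest object as (x, y) 0-based pixel-center
# coordinates (x = column, y = row).
mask_contour <- function(mask) {
  lab <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  oc <- EBImage::ocontour(lab)
  if (length(oc) == 0) stop("measurement error: no contour found")
  ct <- oc[[1]]
  if (nrow(ct) < 6) stop("fit error: degenerate contour")
  # EBImage coordinates follow (dim1, dim2) = (row, col); reorder to (x, y)
  cbind(x = ct[, 2], y = ct[, 1])
}

# Direct least-squares ellipse fit (Fitzgibbon; numerically stabilized
# Halir-Flusser partitioning). Returns center, semi-axes and rotation.
fit_ellipse_lsq <- function(x, y) {
  if (length(x) < 6) stop("fit error: need at least 6 contour points")
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my  # center the data for conditioning
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("fit error: degenerate (collinear) contour"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M)
  # admissible solution satisfies 4ac - b^2 > 0
  cond <- 4 * eg$vectors[1, ] * eg$vectors[3, ] - eg$vectors[2, ]^2
  k <- which(Re(cond) > 0 & abs(Im(eg$values)) < 1e-8)
  if (length(k) == 0) stop("fit error: no elliptical solution")
  a1 <- Re(eg$vectors[, k[1]])
  coef <- c(a1, as.vector(Tm %*% a1))  # A B C D E F in centered frame
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F0 <- coef[6]

  den <- 4 * A * C - B^2
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F0
  Mq <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(Mq, symmetric = TRUE)
  ax2 <- -Fc / eq$values
  if (any(!is.finite(ax2)) || any(ax2 <= 0))
    stop("fit error: degenerate conic")
  semis <- sqrt(ax2)
  major_i <- which.max(semis)
  v <- eq$vectors[, major_i]
  list(cx = cx + mx, cy = cy + my,
       a = max(semis), b = min(semis),
       theta = atan2(v[2], v[1]) %% pi)
}
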