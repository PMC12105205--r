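#' Z-score of a measurement against the gestational-age reference
#'
#' `(value - mean(ga)) / sd(ga)` with mean and SD linearly interpolated
#' between integer weeks.
#'
#' @param value_mm Measured HC or BPD in mm.
#' @param ga_weeks Gestational age in weeks.
#' @param ref Reference table (see [default_reference_table()]).
#' @param which `"hc"` or `"bpd"`.
#' @return The z-score (dimensionless).
#' @export
zscore <- function(value_mm, ga_weeks, ref, which = c("hc", "bpd")) {
  which <- match.arg(which)
  stopifnot(is.numeric(value_mm), length(value_mm) == 1)
  r <- ref_lookup(ref, ga_weeks, which)
  (value_mm - r$mean) / r$sd
}

#' Classify a head measurement as microcephaly, normal or macrocephaly
#'
#' HC-driven rule: microcephaly iff the HC z-score is strictly below
#' `-threshold`, macrocephaly iff strictly above `+threshold`, otherwise
#' normal. The boundary (z exactly at the threshold) is classified normal:
#' "more than 2 SD" is read as a strict inequality. The BPD z-score is
#' reported for context but does not change the label unless
#' `strict_concordance = TRUE`, in which case an abnormal label is kept only
#' when the BPD z-score falls in the same abnormal band.
#'
#' @param hc_mm Measured head circumference, mm (> 0).
#' @param ga_weeks Gestational age, weeks.
#' @param ref Reference table.
#' @param bpd_mm Optional measured biparietal diameter, mm.
#' @param threshold SD threshold (default 2; the 98th-percentile reading of
#'   the macrocephaly rule would correspond to about 2.054).
#' @param strict_concordance Require HC and BPD to agree before labelling
#'   a case abnormal. Default `FALSE` (HC-primary).
#' @return List of class `fetalbiom_classification` with `label` (factor
#'   level among microcephaly/normal/macrocephaly), `z_hc`, `z_bpd` (NA when
#'   no BPD given), `ga_weeks` and `rule_fired`.
#' @export
#' @examples
#' ref <- default_reference_table()
#' classify_case(hc_mm = 175, ga_weeks = 24, ref = ref)
classify_case <- function(hc_mm, ga_weeks, ref, bpd_mm = NULL,
                          threshold = 2, strict_concordance = FALSE) {
  stopifnot(hc_mm > 0, threshold > 0)
  z_hc <- zscore(hc_mm, ga_weeks, ref, "hc")
  z_bpd <- if (is.null(bpd_mm)) NA_real_ else zscore(bpd_mm, ga_weeks, ref, "bpd")
  label <- label_from_z(z_hc, threshold)
  rule <- sprintf("hc z=%.3f vs +/-%.3g", z_hc, threshold)
  if (strict_concordance && label != "normal") {
    if (is.na(z_bpd)) stop("strict_concordance requires bpd_mm")
    if (label_from_z(z_bpd, threshold) != label) {
      rule <- paste0(rule, "; bpd z=", sprintf("%.3f", z_bpd), " discordant -> normal")
      label <- "normal"
    } else {
      rule <- paste0(rule, "; bpd concordant")
    }
  }
  structure(
    list(label = label, z_hc = z_hc, z_bpd = z_bpd,
         ga_weeks = ga_weeks, rule_fired = rule),
    class = "fetalbiom_classification"
  )
}

label_from_z <- function(z, threshold = 2) {
  if (z < -threshold) "microcephaly"
  else if (z > threshold) "macrocephaly"
  else "normal"
}

#' @export
print.fetalbiom_classification <- function(x, ...) {
  cat(sprintf("fetal head classification: %s (HC z = %+.2f%s, GA %.1f wk)\n",
              x$label, x$z_hc,
              if (is.na(x$z_bpd)) "" else sprintf(", BPD z = %+.2f", x$z_bpd),
              x$ga_weeks))
  invisible(x)
}

#' Classify a batch of biometry measurements
#'
#' @param biometry Data.frame with columns `image_id`, `hc_mm`, `ga_weeks`
#'   and optionally `bpd_mm`.
#' @param ref Reference table.
#' @param threshold SD threshold passed to [classify_case()].
#' @return Data.frame with `image_id`, `ga_weeks`, `hc_mm`, `bpd_mm`,
#'   `z_hc`, `z_bpd`, `label`.
#' @export
classify_batch <- function(biometry, ref, threshold = 2) {
  stopifnot(all(c("image_id", "hc_mm", "ga_weeks") %in% names(biometry)))
  has_bpd <- "bpd_mm" %in% names(biometry)
  rows <- lapply(seq_len(nrow(biometry)), function(i) {
    cl <- classify_case(biometry$hc_mm[i], biometry$ga_weeks[i], ref,
                        bpd_mm = if (has_bpd) biometry$bpd_mm[i] else NULL,
                        threshold = threshold)
    data.frame(image_id = biometry$image_id[i], ga_weeks = cl$ga_weeks,
               hc_mm = biometry$hc_mm[i],
               bpd_mm = if (has_bpd) biometry$bpd_mm[i] else NA_real_,
               z_hc = cl$z_hc, z_bpd = cl$z_bpd, label = cl$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
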