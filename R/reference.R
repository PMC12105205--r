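#' Gestational-age reference table for HC and BPD
#'
#' A reference table holds, per gestational week, the population mean and
#' standard deviation of head circumference (HC) and biparietal diameter
#' (BPD) in millimetres. It defines the normal band used for z-scores and
#' for microcephaly / macrocephaly classification. The default table is
#' also shipped as a CSV at `system.file("extdata",
#' "reference_table_synthetic.csv", package = "fetalbiom")` for
#' command-line use.
#'
#' @details
#' The default table shipped by [default_reference_table()] is *synthetic
#' and illustrative, not clinical*: means grow linearly from 98 mm (week 14)
#' to about 296 mm (week 40), the SD is 3% of the mean, and BPD columns are
#' derived from HC assuming a cephalic index of 0.78 so that HC and BPD
#' z-scores agree for a phantom head. Substitute a published growth standard
#' for any real analysis.
#'
#' @param ga_min,ga_max Integer week range covered by the default table.
#' @return A data.frame with columns `ga_weeks`, `hc_mean_mm`, `hc_sd_mm`,
#'   `bpd_mean_mm`, `bpd_sd_mm`.
#' @export
default_reference_table <- function(ga_min = 14L, ga_max = 40L) {
  stopifnot(ga_min >= 1, ga_max > ga_min)
  ga <- seq.int(ga_min, ga_max)
  hc_mean <- 98 + (ga - 14) * 7.6
  # BPD consistent with a 0.78 cephalic index: bpd = 2*0.78*a, hc = P(a, 0.78a)
  bpd_per_hc <- 2 * 0.78 / ramanujan_perimeter(1, 0.78)
  ref <- data.frame(
    ga_weeks    = ga,
    hc_mean_mm  = hc_mean,
    hc_sd_mm    = 0.03 * hc_mean,
    bpd_mean_mm = bpd_per_hc * hc_mean,
    bpd_sd_mm   = 0.03 * bpd_per_hc * hc_mean
  )
  validate_reference_table(ref)
  ref
}

#' Validate a reference table
#'
#' Checks the schema (five numeric columns), contiguous integer GA coverage,
#' strictly increasing means, and positive SDs.
#'
#' @param ref Data.frame as returned by [default_reference_table()] or
#'   [read_reference_table()].
#' @return `ref`, invisibly, if valid; otherwise an error.
#' @export
validate_reference_table <- function(ref) {
  need <- c("ga_weeks", "hc_mean_mm", "hc_sd_mm", "bpd_mean_mm", "bpd_sd_mm")
  if (!is.data.frame(ref) || !all(need %in% names(ref)))
    stop("reference table must have columns: ", paste(need, collapse = ", "))
  ga <- ref$ga_weeks
  if (any(diff(ga) != 1))
    stop("reference table gestational ages must be contiguous integer weeks")
  if (any(diff(ref$hc_mean_mm) <= 0) || any(diff(ref$bpd_mean_mm) <= 0))
    stop("reference means must be strictly increasing in gestational age")
  if (any(ref$hc_sd_mm <= 0) || any(ref$bpd_sd_mm <= 0))
    stop("reference SDs must be positive")
  invisible(ref)
}

#' Read a reference table from CSV
#'
#' Expected header: `ga_weeks,hc_mean_mm,hc_sd_mm,bpd_mean_mm,bpd_sd_mm`.
#'
#' @param path Path to the CSV file.
#' @return Validated reference data.frame.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path))
    stop("reference table CSV not found: ", path)
  ref <- utils::read.csv(path)
  validate_reference_table(ref)
  ref
}

#' Interpolated reference mean and SD at a gestational age
#'
#' Linear interpolation between integer weeks for both mean and SD.
#'
#' @param ref Reference table.
#' @param ga_weeks Gestational age in weeks (may be fractional).
#' @param which `"hc"` or `"bpd"`.
#' @return List with `mean` and `sd` in mm.
#' @export
ref_lookup <- function(ref, ga_weeks, which = c("hc", "bpd")) {
  which <- match.arg(which)
  validate_reference_table(ref)
  if (ga_weeks < min(ref$ga_weeks) || ga_weeks > max(ref$ga_weeks))
    stop(sprintf("gestational age %.2f outside reference table range [%d, %d]",
                 ga_weeks, min(ref$ga_weeks), max(ref$ga_weeks)))
  mcol <- paste0(which, "_mean_mm"); scol <- paste0(which, "_sd_mm")
  list(
    mean = stats::approx(ref$ga_weeks, ref[[mcol]], xout = ga_weeks)$y,
    sd   = stats::approx(ref$ga_weeks, ref[[scol]], xout = ga_weeks)$y
  )
}
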