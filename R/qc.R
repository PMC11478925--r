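#' Quality-control criteria
#'
#' Feature selection keeps a variable when its CRLB is below
#' `crlb_threshold` percent in at least `min_subjects` subjects. Spectrum
#' gates (minimum SNR, maximum linewidth) are conventional defaults exposed
#' as configuration.
#'
#' @param crlb_threshold CRLB percentage threshold (strict `<`, default 30).
#' @param min_subjects Minimum number of subjects meeting the threshold
#'   (default 2).
#' @param min_snr Spectrum-level minimum SNR (default 4).
#' @param max_fwhm_ppm Spectrum-level maximum linewidth in ppm (default 0.1).
#' @return A `mrs_qc_criteria` list.
#' @export
qc_criteria <- function(crlb_threshold = 30, min_subjects = 2,
                        min_snr = 4, max_fwhm_ppm = 0.1) {
  stopifnot(crlb_threshold > 0, min_subjects >= 1)
  structure(list(
    crlb_threshold = crlb_threshold, min_subjects = min_subjects,
    min_snr = min_snr, max_fwhm_ppm = max_fwhm_ppm
  ), class = "mrs_qc_criteria")
}

#' Select reliable features across a cohort
#'
#' A feature is included if and only if the number of subjects in which its
#' CRLB is strictly below the threshold is at least `min_subjects`. MMLip
#' group variables are evaluated on their grouped CRLBs (minimum over
#' members), which [group_mmlip()] has already produced.
#'
#' @param feature_table Long tibble with columns `subject`, `feature`,
#'   `crlb_pct` (one row per subject x feature), e.g. stacked outputs of
#'   [group_mmlip()].
#' @param criteria A [qc_criteria()].
#' @return Character vector of included feature names (in first-appearance
#'   order).
#' @export
select_features <- function(feature_table, criteria = qc_criteria()) {
  stopifnot(all(c("subject", "feature", "crlb_pct") %in% names(feature_table)))
  if (nrow(feature_table) == 0) abort("empty cohort")
  counts <- feature_table |>
    group_by(.data$feature) |>
    summarise(n_ok = sum(.data$crlb_pct < criteria$crlb_threshold),
              .groups = "drop")
  keep <- counts$feature[counts$n_ok >= criteria$min_subjects]
  intersect(unique(feature_table$feature), keep)
}

#' Spectrum-level quality control
#'
#' A spectrum fails if its SNR is below the minimum, its linewidth exceeds
#' the maximum, or the fit did not converge. Reasons are enumerated.
#'
#' @param result An `mrs_quant`.
#' @param criteria A [qc_criteria()].
#' @return One-row tibble: `pass` (logical), `reasons` (comma-separated
#'   string, empty when passing), `snr`, `fwhm_ppm`, `converged`.
#' @export
spectrum_qc <- function(result, criteria = qc_criteria()) {
  reasons <- character()
  if (is.na(result$snr) || result$snr < criteria$min_snr) reasons <- c(reasons, "SNR")
  if (is.na(result$fwhm_ppm) || result$fwhm_ppm > criteria$max_fwhm_ppm) {
    reasons <- c(reasons, "FWHM")
  }
  if (!isTRUE(result$converged)) reasons <- c(reasons, "NON_CONVERGED")
  tibble(
    pass = length(reasons) == 0,
    reasons = paste(reasons, collapse = ","),
    snr = result$snr,
    fwhm_ppm = result$fwhm_ppm,
    converged = isTRUE(result$converged)
  )
}

#' Cohort-level QC report
#'
#' @param quants Named list of `mrs_quant` objects (names = subject ids).
#' @param criteria A [qc_criteria()].
#' @return Tibble: `subject`, `pass`, `reasons`, `snr`, `fwhm_ppm`,
#'   `converged`.
#' @export
cohort_qc <- function(quants, criteria = qc_criteria()) {
  purrr::imap_dfr(quants, function(q, nm) {
    mutate(spectrum_qc(q, criteria), subject = nm, .before = 1)
  })
}
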