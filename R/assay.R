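#' Telomere-content delta-Ct from duplicate qPCR reactions
#'
#' The average cycle threshold of the telomeric reaction is subtracted
#' from that of the single-copy internal-control locus (RPL0), so a higher
#' delta corresponds to more telomeric template.
#'
#' @param telomere_cts numeric vector of telomere-reaction Ct values.
#' @param control_cts numeric vector of control-locus Ct values.
#' @return `mean(control_cts) - mean(telomere_cts)`.
#' @export
telomere_delta_ct <- function(telomere_cts, control_cts) {
  if (!length(telomere_cts) || !length(control_cts))
    stop("both Ct vectors must be non-empty")
  stopifnot(all(is.finite(telomere_cts)), all(is.finite(control_cts)))
  mean(control_cts) - mean(telomere_cts)
}

#' Relative peak area of a metabolite measurement
#'
#' `metabolite_area / (is_area * sample_amount)`, the internal-standard-
#' and amount-normalized peak area used for cross-sample comparison of
#' CE-TOFMS metabolite signals.
#'
#' @param metabolite_area metabolite peak area (>= 0).
#' @param is_area internal-standard peak area (> 0).
#' @param sample_amount sample amount (> 0).
#' @return The normalized relative peak area.
#' @export
relative_peak_area <- function(metabolite_area, is_area, sample_amount) {
  if (is_area <= 0 || sample_amount <= 0)
    stop("internal-standard area and sample amount must be positive")
  metabolite_area / (is_area * sample_amount)
}
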