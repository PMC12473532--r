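# Agreement machinery between an estimated and a reference vitals series:
# MAE, Pearson correlation, Bland-Altman bias and 95% limits of agreement.

#' Align two timestamped series by nearest neighbour
#'
#' Pairs each estimate sample with the closest reference sample within
#' `max_gap_s`; samples with no partner in range are dropped and counted.
#'
#' @param estimate,reference data frames with columns `time_s` and a value
#'   column (`bpm` or the first non-time column), sorted by time.
#' @param max_gap_s maximum pairing distance in seconds.
#' @return object of class `paired_series`: `time_s`, `estimate`,
#'   `reference`, `n_dropped`.
#' @export
align_series <- function(estimate, reference, max_gap_s = 0.5) {
  val_col <- function(df) {
    nm <- setdiff(names(df), "time_s")
    if (!"time_s" %in% names(df) || length(nm) < 1L)
      abort_config("series need a `time_s` column and a value column")
    df[[nm[1]]]
  }
  te <- estimate$time_s;  ve <- val_col(estimate)
  tr <- reference$time_s; vr <- val_col(reference)
  if (length(te) == 0L || length(tr) == 0L)
    abort_alignment("empty input series")
  j <- vapply(te, function(t) which.min(abs(tr - t)), 0L)
  gap <- abs(tr[j] - te)
  keep <- gap <= max_gap_s
  if (!any(keep)) abort_alignment("no sample pairs within max_gap_s")
  structure(list(time_s = te[keep], estimate = ve[keep],
                 reference = vr[j][keep], n_dropped = sum(!keep)),
            class = "paired_series")
}

#' Agreement report: MAE, Pearson r, Bland-Altman bias and 95% LoA
#'
#' Differences are taken estimate minus reference, so a negative bias means
#' the contactless estimate under-reads. The limits of agreement use the
#' sample (n-1) standard deviation of the differences and the conventional
#' 1.96 multiplier. Pearson r is flagged undefined (NA) when either series
#' is constant; the remaining metrics are still computed.
#'
#' @param pairs a [align_series()] result, or a list/data.frame with
#'   `estimate` and `reference` vectors of equal length >= 2.
#' @return object of class `agreement_report`: `n`, `mae`, `pearson_r`,
#'   `pearson_defined`, `bias`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
agreement <- function(pairs) {
  e <- pairs$estimate; r <- pairs$reference
  n <- length(e)
  if (n != length(r)) abort_config("estimate/reference length mismatch")
  if (n < 2L) abort_config("agreement needs at least 2 pairs")
  if (!all(is.finite(e)) || !all(is.finite(r)))
    abort_config("non-finite values in paired series")
  d <- e - r
  bias <- mean(d)
  sd_diff <- stats::sd(d)                 # sample (n-1) SD
  defined <- stats::sd(e) > 0 && stats::sd(r) > 0
  structure(list(
    n = n,
    mae = mean(abs(d)),
    pearson_r = if (defined) stats::cor(e, r) else NA_real_,
    pearson_defined = defined,
    bias = bias,
    sd_diff = sd_diff,
    loa_low = bias - 1.96 * sd_diff,
    loa_high = bias + 1.96 * sd_diff
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("<agreement_report> n=%d  MAE=%.3f  r=%s  ",
                     "bias=%.3f  LoA=[%.3f, %.3f]\n"),
              x$n, x$mae,
              if (x$pearson_defined) sprintf("%.3f", x$pearson_r) else "undefined",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}
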