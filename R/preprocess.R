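# SNR preprocessing: a matched temporal filter built from labeled transients,
# followed by pixel-wise median subtraction and quantile-based noise
# normalization.

NOISE_FLOOR <- 1e-6

#' Build the matched calcium-transient kernel
#'
#' Transients whose peak lies in `[snr_lo, snr_hi]` (SNR units) are aligned by
#' their peaks, averaged, truncated where the average falls below 5% of its
#' peak at either end, peak-normalized to 1 and finally time-reversed, giving
#' the taps of a matched filter. If no transient qualifies the full set is
#' averaged instead and a warning is emitted (kernel quality is degraded).
#'
#' @param transients List of numeric vectors: transient snippets in SNR units.
#' @param snr_lo,snr_hi Peak-SNR selection band.
#' @return A `calcium_kernel`: list with `taps` (time-reversed, peak value 1)
#'   and `peak_index` (position of the peak within `taps`).
#' @export
build_matched_kernel <- function(transients, snr_lo = 5, snr_hi = 8) {
  if (length(transients) == 0L)
    sandseg_error("no transients supplied", "sandseg_kernel_error")
  peaks <- vapply(transients, max, numeric(1))
  keep <- peaks >= snr_lo & peaks <= snr_hi
  if (!any(keep)) {
    warning("no transient with peak SNR in [", snr_lo, ", ", snr_hi,
            "]; averaging all ", length(transients),
            " transients (kernel quality degraded)")
    keep <- rep(TRUE, length(transients))
  }
  sel <- transients[keep]
  pk <- vapply(sel, which.max, integer(1))
  pre <- max(pk) ; post <- max(vapply(sel, length, integer(1)) - pk)
  aligned <- vapply(seq_along(sel), function(i) {
    v <- rep(NA_real_, pre + post)
    v[(pre - pk[i] + 1):(pre - pk[i] + length(sel[[i]]))] <- sel[[i]]
    v
  }, numeric(pre + post))
  avg <- rowMeans(matrix(aligned, pre + post), na.rm = TRUE)
  avg[is.nan(avg)] <- 0
  peak_val <- max(avg)
  above <- which(avg >= 0.05 * peak_val)
  avg <- avg[above[1]:above[length(above)]]
  avg <- avg / max(avg)
  taps <- rev(avg)
  structure(list(taps = taps,
                 peak_index = length(taps) - which.max(avg) + 1L),
            class = "calcium_kernel")
}

#' Matched temporal filtering of a video
#'
#' Correlates every pixel trace with the (un-reversed) transient template, so
#' a transient matching the template attains its filter-response maximum at
#' the transient's peak frame. Boundaries are handled by temporal reflection;
#' the output has the same length as the input.
#'
#' @param video `H x W x T` array.
#' @param kernel A `calcium_kernel` from [build_matched_kernel()] (or a plain
#'   numeric vector of taps, taken as already time-reversed).
#' @return Filtered `H x W x T` array.
#' @export
temporal_filter <- function(video, kernel) {
  video <- as_frames(video)
  taps <- if (inherits(kernel, "calcium_kernel")) kernel$taps else as.numeric(kernel)
  if (length(taps) > dim(video)[3])
    sandseg_error("kernel longer than the video", "sandseg_shape_error")
  template <- rev(taps)
  cpp_temporal_filter(video, template, which.max(template))
}

#' Convert a (filtered) video to its SNR representation
#'
#' Per pixel, subtracts the temporal median and divides by a quantile-based
#' noise estimate `(Q(q2) - Q(q1)) / 0.6745` (the lower-sided quartile spread
#' by default, robust to positive-going transients), floored at `1e-6`.
#' Quantiles use linear interpolation between order statistics (R type 7).
#'
#' @param filtered `H x W x T` array (typically the [temporal_filter()] output).
#' @param noise_quantiles Pair of quantile levels used for the noise image.
#' @return An `snr_video`: list with `frames` (`H x W x T`, noise units),
#'   `median_image` and `noise_image` (both `H x W`, the latter strictly
#'   positive).
#' @export
snr_normalize <- function(filtered, noise_quantiles = c(0.25, 0.5)) {
  filtered <- as_frames(filtered)
  d <- dim(filtered)
  if (d[3] < 2)
    sandseg_error("need at least 2 frames", "sandseg_shape_error")
  m <- matrix(filtered, d[1] * d[2], d[3])
  q <- cpp_row_quantiles(m, c(noise_quantiles[1], noise_quantiles[2], 0.5))
  med <- q[, 3]
  noise <- pmax((q[, 2] - q[, 1]) / 0.6745, NOISE_FLOOR)
  frames <- (m - med) / noise
  dim(frames) <- d
  structure(list(frames = frames,
                 median_image = matrix(med, d[1], d[2]),
                 noise_image = matrix(noise, d[1], d[2])),
            class = "snr_video")
}

#' Mean SNR trace of a mask
#'
#' @param snr_video An `snr_video` or `H x W x T` array.
#' @param mask Logical/0-1 `H x W` matrix or vector of linear pixel indices.
#' @return Numeric vector: per-frame mean SNR inside the mask.
#' @export
snr_trace <- function(snr_video, mask) mask_trace(snr_video, mask)

# Extract peak-aligned transient snippets with peak SNR inside [snr_lo,
# snr_hi] from a set of SNR traces. A snippet spans `pre` frames before to
# `post` frames after a local maximum; only isolated transients qualify (the
# peak must dominate its whole window, which rejects secondary bumps riding
# on larger compound events).
collect_transients <- function(traces, snr_lo = 5, snr_hi = 8,
                               pre = 5L, post = 25L) {
  if (is.numeric(traces) && is.null(dim(traces))) traces <- list(traces)
  if (is.matrix(traces)) traces <- asplit(traces, 1)
  out <- list()
  for (tr in traces) {
    T_ <- length(tr)
    is_peak <- c(FALSE, diff(tr) > 0) & c(diff(tr) < 0, FALSE)
    for (p in which(is_peak & tr >= snr_lo & tr <= snr_hi)) {
      span <- max(1, p - pre):min(T_, p + post)
      if (max(tr[span]) > tr[p]) next
      out[[length(out) + 1L]] <- tr[span]
    }
  }
  out
}
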