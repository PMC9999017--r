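#' First-order (intensity-distribution) features
#'
#' The 25 first-order features of the catalog, computed on raw ROI
#' intensities except for the entropies and uniformity, which use the
#' quantized-histogram probabilities, and the histogram mode, which is the
#' center of the fullest quantized bin (ties to the lowest bin).
#'
#' Conventions: population (n) variance and standard deviation; quantiles by
#' linear interpolation (type 7); skewness `m3/m2^1.5` and kurtosis `m4/m2^2`
#' (excess = kurtosis - 3), both defined as 0 on zero-variance ROIs;
#' coefficient of variation std/mean (0 when the mean is 0); MAD = mean
#' absolute deviation from the mean; robust MAD = the same restricted to the
#' central P10--P90 intensity band; RMS = root mean square; energy = sum of
#' squared intensities.
#'
#' @param q a [quantize_roi()] result (carries both raw values and levels).
#' @return Named numeric vector of length 25 (`CONVENTIONAL_*`).
#' @export
first_order_features <- function(q) {
  x <- q$values
  n <- length(x)
  if (n < 2) {
    abort("first-order features need an ROI of >= 2 pixels",
          class = "stirq_radiomics_error")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  s <- sqrt(m2)
  qs <- quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7, names = FALSE)
  p10 <- qs[1]; q1 <- qs[2]; med <- qs[3]; q3 <- qs[4]; p90 <- qs[5]
  band <- x[x >= p10 & x <= p90]
  skew <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - m)^4) / m2^2 else 0

  counts <- tabulate(q$levels, nbins = q$G)
  p <- counts / n
  pp <- p[p > 0]
  mode_bin <- which.max(counts)  # which.max takes the lowest on ties
  hist_mode <- if (q$bin_edges[1] == q$bin_edges[q$G + 1]) {
    q$bin_edges[1]
  } else {
    (q$bin_edges[mode_bin] + q$bin_edges[mode_bin + 1]) / 2
  }

  c(
    CONVENTIONAL_min = min(x),
    CONVENTIONAL_max = max(x),
    CONVENTIONAL_range = max(x) - min(x),
    CONVENTIONAL_mean = m,
    CONVENTIONAL_std = s,
    CONVENTIONAL_variance = m2,
    CONVENTIONAL_CV = if (m != 0) s / m else 0,
    CONVENTIONAL_skewness = skew,
    CONVENTIONAL_kurtosis = kurt,
    CONVENTIONAL_excess_kurtosis = if (m2 > 0) kurt - 3 else 0,
    CONVENTIONAL_Q1 = q1,
    CONVENTIONAL_median = med,
    CONVENTIONAL_Q3 = q3,
    CONVENTIONAL_IQR = q3 - q1,
    CONVENTIONAL_P10 = p10,
    CONVENTIONAL_P90 = p90,
    CONVENTIONAL_hist_mode = hist_mode,
    CONVENTIONAL_sum = sum(x),
    CONVENTIONAL_RMS = sqrt(mean(x^2)),
    CONVENTIONAL_MAD = mean(abs(x - m)),
    CONVENTIONAL_robust_MAD = mean(abs(band - mean(band))),
    CONVENTIONAL_entropy_log2 = -sum(pp * log2(pp)),
    CONVENTIONAL_entropy_log10 = -sum(pp * log10(pp)),
    CONVENTIONAL_uniformity = sum(p^2),
    CONVENTIONAL_energy = sum(x^2)
  )
}
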