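#' First-order (histogram) features of an ROI's intensity distribution
#'
#' Computes the 19 first-order features of the extractor's registry from the
#' raw in-ROI Hounsfield-unit values. Binned quantities (entropy, uniformity,
#' energy, total energy) use `n_bins` equal-width bins spanning the ROI's own
#' \[min, max\], so they are invariant to adding a constant to all intensities.
#'
#' Definitions fixed by the registry:
#' * entropy: \eqn{-\sum_i p_i \log_2 p_i} over normalized bin probabilities;
#' * uniformity: \eqn{\sum_i p_i^2};
#' * energy: \eqn{\sum_i n_i^2} over raw bin counts (distinct from uniformity);
#' * total energy: energy times the voxel volume in mm^3;
#' * skewness/kurtosis: population moment ratios \eqn{m_3/m_2^{3/2}} and
#'   \eqn{m_4/m_2^2}, defined as 0 for a constant input;
#' * robust MAD: mean absolute deviation of the values inside the
#'   \[10th, 90th\] percentile interval, about their own mean.
#'
#' @param values numeric vector of in-ROI intensities (HU); at least 1 voxel.
#' @param n_bins number of histogram bins (default 128).
#' @param voxel_volume voxel volume in mm^3 used by total energy (default 1).
#' @return Named numeric vector of the 19 first-order features.
#' @export
histogram_features <- function(values, n_bins = 128L, voxel_volume = 1) {
  if (length(values) < 1L) {
    stop("histogram features need at least one in-ROI voxel", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("intensities must be finite", call. = FALSE)
  }

  n <- length(values)
  mu <- mean(values)
  q <- unname(stats::quantile(values, c(0.1, 0.25, 0.75, 0.9)))
  p10 <- q[1]; p90 <- q[4]
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)

  trimmed <- values[values >= p10 & values <= p90]
  rmad <- if (length(trimmed)) mean(abs(trimmed - mean(trimmed))) else 0

  counts <- tabulate(discretize_bins(values, n_bins), nbins = n_bins)
  p <- counts / n
  p <- p[p > 0]

  energy <- sum(as.numeric(counts)^2)

  c(
    Min = min(values),
    Max = max(values),
    Mean = mu,
    Median = stats::median(values),
    P10 = p10,
    P90 = p90,
    IQR = q[3] - q[2],
    Range = max(values) - min(values),
    MAD = mean(abs(values - mu)),
    rMAD = rmad,
    RMS = sqrt(mean(values^2)),
    SD = sqrt(m2),
    Variance = m2,
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Entropy = -sum(p * log2(p)),
    Uniformity = sum(p^2),
    Energy = energy,
    TotalEnergy = energy * voxel_volume
  )
}
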