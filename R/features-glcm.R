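#' Gray-level co-occurrence matrix (GLCM) features
#'
#' Second-order texture features quantifying intratumoral heterogeneity.
#' In-ROI intensities are discretized into `n_bins` equal-width gray levels
#' over the ROI's own \[min, max\]. Co-occurrences are counted symmetrically
#' over the 13 unique 3D unit offsets (distance 1), restricted to voxel pairs
#' lying inside the mask; each offset's matrix is normalized to sum 1, the 16
#' registry features are computed per offset and averaged across offsets that
#' produced at least one pair. All entropies use log base 2.
#'
#' Degenerate conventions: a constant region has a single nonzero GLCM cell
#' (maximum probability 1, contrast 0); correlation is defined as 1 and the
#' first informational measure of correlation as 0 when the marginal variance
#' or entropy vanishes.
#'
#' @param intensities numeric 3D array of HU values.
#' @param mask logical 3D array, same shape.
#' @param n_bins gray levels for discretization (default 128).
#' @param offsets integer matrix of voxel offsets, one per row; defaults to
#'   the 13 unique 3D unit directions.
#' @return Named numeric vector of 16 GLCM features.
#' @export
glcm_features <- function(intensities, mask, n_bins = 128L,
                          offsets = unit_offsets_3d()) {
  check_mask(mask)
  mask <- array(as.logical(mask), dim(mask))
  stopifnot(identical(dim(intensities), dim(mask)))
  if (any(!is.finite(intensities[mask]))) {
    stop("in-mask intensities must be finite", call. = FALSE)
  }

  lev <- array(0L, dim(mask))
  lev[mask] <- discretize_bins(intensities[mask], n_bins)

  per_offset <- list()
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    both <- mask & shift3d(mask, -o, fill = FALSE)
    if (!any(both)) next
    i <- lev[both]
    j <- shift3d(lev, -o, fill = 0L)[both]
    # symmetric counts over n_bins^2 cells, kept sparse
    code <- c((i - 1) * n_bins + j, (j - 1) * n_bins + i)
    tab <- table(code)
    cells <- as.integer(names(tab))
    cnt <- as.numeric(tab)
    per_offset[[length(per_offset) + 1L]] <- list(
      i = (cells - 1L) %/% n_bins + 1L,
      j = (cells - 1L) %% n_bins + 1L,
      p = cnt / sum(cnt)
    )
  }
  if (!length(per_offset)) {
    stop("no valid in-mask voxel pair for any offset", call. = FALSE)
  }

  feats <- vapply(per_offset, glcm_features_one, numeric(16L))
  rowMeans(feats)
}

# Features of one normalized sparse symmetric GLCM {i, j, p}.
glcm_features_one <- function(g) {
  i <- g$i; j <- g$j; p <- g$p

  # marginal p_x(i) (= p_y by symmetry)
  lv <- sort(unique(c(i, j)))
  px <- vapply(lv, function(l) sum(p[i == l]), numeric(1))
  mu <- sum(lv * px)
  sig2 <- sum((lv - mu)^2 * px)

  contrast <- sum((i - j)^2 * p)
  dissim <- sum(abs(i - j) * p)
  autoc <- sum(i * j * p)
  correlation <- if (sig2 > 0) (autoc - mu^2) / sig2 else 1

  cl <- i + j - 2 * mu
  cluster_tend <- sum(cl^2 * p)
  cluster_shade <- sum(cl^3 * p)
  cluster_prom <- sum(cl^4 * p)

  asm <- sum(p^2)
  ent <- -sum(p * log2(p))

  # difference and sum distributions
  pd <- tapply(p, abs(i - j), sum)
  ps <- tapply(p, i + j, sum)
  diff_ent <- -sum(pd * log2(pd))
  sum_avg <- sum(as.numeric(names(ps)) * ps)
  sum_ent <- -sum(ps * log2(ps))

  idm <- sum(p / (1 + (i - j)^2))

  hx <- -sum(px * log2(px))
  pxi <- px[match(i, lv)]
  pyj <- px[match(j, lv)]
  hxy1 <- -sum(p * log2(pxi * pyj))
  outer_p <- outer(px, px)
  hxy2 <- -sum(outer_p * log2(outer_p))
  imc1 <- if (hx > 0) (ent - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))

  c(
    Autocorrelation = autoc,
    ClusterProminence = cluster_prom,
    ClusterShade = cluster_shade,
    ClusterTendency = cluster_tend,
    Contrast = contrast,
    Correlation = correlation,
    DifferenceEntropy = diff_ent,
    Dissimilarity = dissim,
    ASM = asm,
    Entropy = ent,
    IDM = idm,
    IMC1 = imc1,
    IMC2 = imc2,
    MaxProbability = max(p),
    SumAverage = sum_avg,
    SumEntropy = sum_ent
  )
}
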