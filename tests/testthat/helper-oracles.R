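# Independent brute-force oracles. These re-derive every feature directly
# from its textbook definition (dense matrices, explicit loops, flood fill)
# and deliberately share no code with the package internals.

oracle_discretize <- function(vals, n_bins) {
  rng <- range(vals)
  if (rng[1] == rng[2]) {
    return(rep(1L, length(vals)))
  }
  b <- floor((vals - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1
  b[b > n_bins] <- n_bins
  as.integer(b)
}

oracle_histogram <- function(values, n_bins = 128, voxel_volume = 1) {
  n <- length(values)
  s <- sort(values)
  mu <- sum(values) / n
  q <- quantile(values, c(0.1, 0.25, 0.75, 0.9))
  cm <- function(k) sum((values - mu)^k) / n
  inr <- values[values >= q[1] & values <= q[4]]
  cnt <- tabulate(oracle_discretize(values, n_bins), n_bins)
  p <- cnt[cnt > 0] / n
  en <- sum(as.numeric(cnt[cnt > 0])^2)
  c(Min = s[1], Max = s[n], Mean = mu, Median = median(values),
    P10 = unname(q[1]), P90 = unname(q[4]), IQR = unname(q[3] - q[2]),
    Range = s[n] - s[1], MAD = sum(abs(values - mu)) / n,
    rMAD = sum(abs(inr - mean(inr))) / length(inr),
    RMS = sqrt(sum(values^2) / n), SD = sqrt(cm(2)), Variance = cm(2),
    Skewness = if (cm(2) > 0) cm(3) / cm(2)^1.5 else 0,
    Kurtosis = if (cm(2) > 0) cm(4) / cm(2)^2 else 0,
    Entropy = -sum(p * log2(p)), Uniformity = sum(p^2),
    Energy = en, TotalEnergy = en * voxel_volume)
}

oracle_glcm_matrix_feats <- function(P) {
  nb <- nrow(P)
  i <- row(P)
  j <- col(P)
  px <- rowSums(P)
  mu <- sum((1:nb) * px)
  sig2 <- sum(((1:nb) - mu)^2 * px)
  lg <- function(x) ifelse(x > 0, log2(x), 0)
  autoc <- sum(i * j * P)
  pd <- sapply(0:(nb - 1), function(k) sum(P[abs(i - j) == k]))
  ps <- sapply(2:(2 * nb), function(k) sum(P[(i + j) == k]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  PXY <- outer(px, px)
  ent <- -sum(P * lg(P))
  hxy1 <- -sum(P * lg(PXY))
  hxy2 <- -sum(PXY * lg(PXY))
  c(Autocorrelation = autoc,
    ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = if (sig2 > 0) (autoc - mu^2) / sig2 else 1,
    DifferenceEntropy = -sum(pd[pd > 0] * log2(pd[pd > 0])),
    Dissimilarity = sum(abs(i - j) * P),
    ASM = sum(P^2),
    Entropy = ent,
    IDM = sum(P / (1 + (i - j)^2)),
    IMC1 = if (hx > 0) (ent - hxy1) / hx else 0,
    IMC2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - ent)))),
    MaxProbability = max(P),
    SumAverage = sum((2:(2 * nb)) * ps),
    SumEntropy = -sum(ps[ps > 0] * log2(ps[ps > 0])))
}

oracle_glcm <- function(intens, mask, n_bins = 128,
                        offsets = radrcc:::unit_offsets_3d()) {
  lev <- array(NA_integer_, dim(mask))
  lev[mask] <- oracle_discretize(intens[mask], n_bins)
  dm <- dim(mask)
  acc <- NULL
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    P <- matrix(0, n_bins, n_bins)
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
      if (!mask[x, y, z]) next
      x2 <- x + o[1]; y2 <- y + o[2]; z2 <- z + o[3]
      if (x2 < 1 || x2 > dm[1] || y2 < 1 || y2 > dm[2] ||
          z2 < 1 || z2 > dm[3]) next
      if (!mask[x2, y2, z2]) next
      i <- lev[x, y, z]; j <- lev[x2, y2, z2]
      P[i, j] <- P[i, j] + 1
      P[j, i] <- P[j, i] + 1
    }
    if (sum(P) == 0) next
    acc <- cbind(acc, oracle_glcm_matrix_feats(P / sum(P)))
  }
  rowMeans(acc)
}

# 26-connected zone sizes by explicit flood fill
oracle_zone_sizes <- function(intens, mask, n_bins = 32) {
  lev <- array(NA_integer_, dim(mask))
  lev[mask] <- oracle_discretize(intens[mask], n_bins)
  dm <- dim(mask)
  visited <- array(FALSE, dm)
  neigh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  neigh <- neigh[rowSums(abs(neigh)) > 0, ]
  sizes <- integer(0)
  for (lin in which(mask)) {
    if (visited[lin]) next
    start <- arrayInd(lin, dm)
    stack <- list(start)
    visited[lin] <- TRUE
    sz <- 0L
    target <- lev[lin]
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      sz <- sz + 1L
      for (r in seq_len(nrow(neigh))) {
        nb <- cur + neigh[r, ]
        if (any(nb < 1) || any(nb > dm)) next
        if (!mask[nb[1], nb[2], nb[3]] || visited[nb[1], nb[2], nb[3]]) next
        if (lev[nb[1], nb[2], nb[3]] != target) next
        visited[nb[1], nb[2], nb[3]] <- TRUE
        stack[[length(stack) + 1L]] <- nb
      }
    }
    sizes <- c(sizes, sz)
  }
  sizes
}

oracle_iszm <- function(intens, mask, n_bins = 32) {
  sizes <- oracle_zone_sizes(intens, mask, n_bins)
  nz <- length(sizes)
  c(ZonePercentage = nz / sum(mask),
    SizeZoneNonUniformityNormalized = sum(as.numeric(table(sizes))^2) / nz^2)
}

# voxelwise spherical erosion: keep voxels whose whole r-ball stays in-mask
oracle_erode <- function(mask, spacing, r) {
  dm <- dim(mask)
  reach <- floor(r / spacing)
  offs <- as.matrix(expand.grid(-reach[1]:reach[1], -reach[2]:reach[2],
                                -reach[3]:reach[3]))
  d2 <- (offs[, 1] * spacing[1])^2 + (offs[, 2] * spacing[2])^2 +
    (offs[, 3] * spacing[3])^2
  offs <- offs[d2 <= r^2, , drop = FALSE]
  out <- array(FALSE, dm)
  for (lin in which(mask)) {
    v <- arrayInd(lin, dm)
    nb <- sweep(offs, 2, as.integer(v), `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!all(ok)) next
    if (all(mask[nb])) out[lin] <- TRUE
  }
  out
}
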