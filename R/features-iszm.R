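#' Intensity size-zone matrix (ISZM) features
#'
#' Regional texture descriptors built from the zones of the discretized ROI:
#' after equal-width discretization into `n_bins` gray levels, a zone is a
#' maximal 26-connected set of in-mask voxels sharing one gray level. Two
#' registry features summarize the zone structure:
#' * zone percentage: number of zones divided by number of in-ROI voxels
#'   (1 when every voxel is its own zone, 1/V for a single homogeneous zone);
#' * size-zone non-uniformity (normalized): \eqn{\sum_s (\sum_l M(l,s))^2 / N_z^2}
#'   over the size-zone matrix M, equal to 1 when all zones have the same size.
#'
#' @inheritParams glcm_features
#' @param n_bins gray levels for discretization (default 32).
#' @return Named numeric vector with `ZonePercentage` and
#'   `SizeZoneNonUniformityNormalized`.
#' @export
iszm_features <- function(intensities, mask, n_bins = 32L) {
  check_mask(mask)
  mask <- array(as.logical(mask), dim(mask))
  stopifnot(identical(dim(intensities), dim(mask)))
  if (any(!is.finite(intensities[mask]))) {
    stop("in-mask intensities must be finite", call. = FALSE)
  }

  sizes <- zone_sizes(intensities, mask, n_bins)
  nz <- length(sizes)
  c(
    ZonePercentage = nz / sum(mask),
    SizeZoneNonUniformityNormalized = sum(as.numeric(table(sizes))^2) / nz^2
  )
}

# Sizes of all 26-connected constant-gray-level zones inside the mask.
zone_sizes <- function(intensities, mask, n_bins) {
  lev <- array(0L, dim(mask))
  lev[mask] <- discretize_bins(intensities[mask], n_bins)

  vox <- which(mask) # linear indices of in-mask voxels
  id <- array(0L, dim(mask))
  id[vox] <- seq_along(vox) # vertex ids 1..N

  edges <- vector("list", 13L)
  offs <- unit_offsets_3d()
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    both <- mask & shift3d(mask, -o, fill = FALSE) &
      (lev == shift3d(lev, -o, fill = -1L))
    if (!any(both)) next
    a <- id[both]
    b <- shift3d(id, -o, fill = 0L)[both]
    edges[[r]] <- rbind(a, b)
  }
  e <- unlist(edges, use.names = FALSE)
  if (is.null(e)) {
    return(rep.int(1L, length(vox)))
  }
  g <- igraph::make_graph(e, n = length(vox), directed = FALSE)
  igraph::components(g)$csize
}
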