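#' @keywords internal
"_PACKAGE"

# Shift a 3D array by an integer voxel offset: out[v + d] = a[v].
# Voxels shifted in from outside the grid take `fill`.
shift3d <- function(a, d, fill = FALSE) {
  dm <- dim(a)
  stopifnot(length(dm) == 3L, length(d) == 3L)
  out <- array(fill, dm)
  if (any(abs(d) >= dm)) {
    return(out)
  }
  src <- vector("list", 3L)
  dst <- vector("list", 3L)
  for (k in 1:3) {
    if (d[k] >= 0) {
      src[[k]] <- seq_len(dm[k] - d[k])
    } else {
      src[[k]] <- seq.int(1L - d[k], dm[k])
    }
    dst[[k]] <- src[[k]] + d[k]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# The 13 unique 3D unit offsets (one per symmetric direction pair).
unit_offsets_3d <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0),
    c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
}

# Equal-width discretization of values into 1..n_bins over [min, max].
# A constant input maps every voxel to bin 1.
discretize_bins <- function(x, n_bins) {
  stopifnot(n_bins >= 1L)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(rep.int(1L, length(x)))
  }
  b <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
  b[b > n_bins] <- n_bins
  as.integer(b)
}

check_mask <- function(mask, what = "mask") {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stop(sprintf("`%s` must be a 3D array", what), call. = FALSE)
  }
  if (!any(mask)) {
    stop(sprintf("`%s` is empty: no in-mask voxels", what), call. = FALSE)
  }
  invisible(TRUE)
}

check_spacing <- function(spacing) {
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive finite voxel dimensions (mm)", call. = FALSE)
  }
  invisible(TRUE)
}

# Deterministic per-stage seed derived from one global seed by hashing the
# stage name; keeps every stage independently re-runnable. Result < 2^31.
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) {
    h <- (h * 131 + ch) %% 2147480951 # large prime below 2^31
  }
  as.integer((h + as.numeric(seed)) %% 2147480951)
}
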