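#' Specify a synthetic pT1 renal-tumor cohort
#'
#' Bundles the generator's study conditions: cohort size and class balance,
#' image geometry, the Hounsfield-unit structure of the tumor (enhancing
#' textured rim around a hypodense necrotic core), and the survival model
#' whose log-hazard is linear in the four standardized signature features.
#' Defaults emulate the discovery-cohort structure: 58 patients of whom 12
#' metastasize, nephrographic-phase HU levels (rim ~110 HU, necrotic core
#' ~25 HU), a larger necrotic fraction and stronger rim texture contrast in
#' the metastasis class, and exponential event/censoring times on a monthly
#' scale.
#'
#' @param n_patients cohort size (>= 4). Default 58.
#' @param metastasis_fraction proportion of metastasis-class patients.
#'   Default 12/58.
#' @param grid_size voxels per axis of the cubic image grid (>= 16).
#' @param voxel_spacing mm per axis; the default anisotropic z matches
#'   thick-slice abdominal CT reconstructions.
#' @param rim_hu_mean,rim_hu_sd HU mean / texture sd of the enhancing rim.
#' @param core_hu_mean,core_hu_sd HU mean / sd of the necrotic core.
#' @param necrotic_fraction_by_class length-2 proportions (non-metastasis,
#'   metastasis) of tumor volume occupied by the hypodense core.
#' @param texture_correlation_length spatial correlation length of the
#'   intensity noise, in voxels (Gaussian-smoothed white noise).
#' @param hazard_coefficients true log-hazard weights on the four
#'   standardized signature features, in [signature_features()] order.
#' @param baseline_hazard_rate baseline event rate per month.
#' @param censoring_rate independent exponential censoring rate per month.
#' @param seed integer RNG seed; fixed seed gives bit-identical cohorts.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 58L,
                        metastasis_fraction = 12 / 58,
                        grid_size = 32L,
                        voxel_spacing = c(1, 1, 2.5),
                        rim_hu_mean = 110, rim_hu_sd = 12,
                        core_hu_mean = 25, core_hu_sd = 8,
                        necrotic_fraction_by_class = c(0.10, 0.40),
                        texture_correlation_length = 1.5,
                        hazard_coefficients = c(-0.10, 0.03, 0.43, 0.64),
                        baseline_hazard_rate = 0.012,
                        censoring_rate = 0.010,
                        seed = 1L) {
  spec <- list(
    n_patients = as.integer(n_patients),
    metastasis_fraction = metastasis_fraction,
    grid_size = as.integer(grid_size),
    voxel_spacing = as.numeric(voxel_spacing),
    rim_hu_mean = rim_hu_mean, rim_hu_sd = rim_hu_sd,
    core_hu_mean = core_hu_mean, core_hu_sd = core_hu_sd,
    necrotic_fraction_by_class = necrotic_fraction_by_class,
    texture_correlation_length = texture_correlation_length,
    hazard_coefficients = hazard_coefficients,
    baseline_hazard_rate = baseline_hazard_rate,
    censoring_rate = censoring_rate,
    seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  stopifnot(
    spec$n_patients >= 4L,
    spec$grid_size >= 16L,
    spec$metastasis_fraction >= 0, spec$metastasis_fraction <= 1,
    length(spec$necrotic_fraction_by_class) == 2L,
    all(spec$necrotic_fraction_by_class >= 0),
    all(spec$necrotic_fraction_by_class <= 1),
    length(spec$voxel_spacing) == 3L, all(spec$voxel_spacing > 0),
    length(spec$hazard_coefficients) == 4L,
    spec$rim_hu_sd >= 0, spec$core_hu_sd >= 0,
    spec$texture_correlation_length >= 0,
    spec$baseline_hazard_rate > 0, spec$censoring_rate >= 0
  )
  invisible(spec)
}

# Unit-variance spatially correlated Gaussian field via FFT smoothing of
# white noise (circular convolution with an isotropic Gaussian kernel).
correlated_field <- function(dm, sigma) {
  z <- array(stats::rnorm(prod(dm)), dm)
  if (sigma <= 0) {
    return(z)
  }
  k1 <- function(n) {
    d <- c(0:(n %/% 2), if (n > 1) -((n - n %/% 2 - 1):1))
    stats::dnorm(d, sd = sigma)
  }
  ker <- outer(outer(k1(dm[1]), k1(dm[2])), k1(dm[3]))
  ker <- ker / sum(ker)
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(ker), inverse = TRUE)) /
    prod(dm)
  s <- stats::sd(sm)
  if (s > 0) sm / s else sm
}

#' Generate one synthetic tumor volume
#'
#' Draws an axis-aligned ellipsoidal tumor (per-patient random radii) at the
#' grid centre: an inner core ellipsoid holding the class's necrotic volume
#' fraction at `core_hu_mean`, an enhancing rim at `rim_hu_mean`, with
#' spatially correlated Gaussian texture of the spec's correlation length.
#' Metastasis-class tumors receive the larger necrotic fraction and a 50%
#' higher rim texture amplitude. Background voxels emulate unremarkable soft
#' tissue (~40 HU).
#'
#' @param spec a [cohort_spec()].
#' @param class_label 0 (no metastasis) or 1 (metastasis).
#' @param seed integer seed; same spec + seed is bit-identical.
#' @param patient_id identifier stored with the volume.
#' @return A `tumor_volume`: list with `intensities` (3D HU array), `mask`
#'   (logical 3D array), `spacing`, `patient_id`, `class_label`.
#' @export
generate_tumor_volume <- function(spec, class_label, seed,
                                  patient_id = "P001") {
  validate_cohort_spec(spec)
  stopifnot(class_label %in% c(0, 1))
  set.seed(seed)

  dm <- rep(spec$grid_size, 3L)
  sp <- spec$voxel_spacing

  # per-patient geometry: equivalent radius 7-10 mm, mild anisotropy
  r_eq <- stats::runif(1, 7, 10)
  f <- exp(stats::runif(3, -0.15, 0.15))
  f <- f / prod(f)^(1 / 3)
  radii <- r_eq * f # mm, semi-axes

  half_extent <- (dm / 2 - 1.5) * sp
  if (any(radii > half_extent)) {
    stop("grid too small to contain the tumor; increase grid_size", call. = FALSE)
  }

  centre <- (dm + 1) / 2
  ax <- lapply(1:3, function(k) ((1:dm[k]) - centre[k]) * sp[k])
  d2 <- outer(outer((ax[[1]] / radii[1])^2, (ax[[2]] / radii[2])^2, `+`),
              (ax[[3]] / radii[3])^2, `+`)
  mask <- d2 <= 1

  nf <- spec$necrotic_fraction_by_class[class_label + 1L]
  core <- d2 <= nf^(2 / 3) # scaling all radii by nf^(1/3) scales d2 cut

  rim_sd <- spec$rim_hu_sd * if (class_label == 1) 1.5 else 1
  noise <- correlated_field(dm, spec$texture_correlation_length)

  intens <- array(40, dm) + 15 * array(stats::rnorm(prod(dm)), dm)
  base <- ifelse(core, spec$core_hu_mean, spec$rim_hu_mean)
  sdmap <- ifelse(core, spec$core_hu_sd, rim_sd)
  intens[mask] <- base[mask] + (noise * sdmap)[mask]

  structure(
    list(intensities = intens, mask = mask, spacing = sp,
         patient_id = patient_id, class_label = class_label),
    class = "tumor_volume"
  )
}

# The four signature features of one volume (cheap path used by the
# survival generator; identical definitions to the full extractor).
signature_features_of_volume <- function(volume, inner_fraction = 0.5) {
  rois <- partition_roi(volume$mask, volume$spacing, inner_fraction)
  inner <- if (any(rois$inner)) rois$inner else rois$whole
  outer_roi <- rois$outer
  c(
    INNER_Min_Hist = unname(min(volume$intensities[inner])),
    INNER_MaxProbability_GLCM =
      unname(glcm_features(volume$intensities, inner)["MaxProbability"]),
    OUTER_Energy_Hist =
      unname(histogram_features(volume$intensities[outer_roi])["Energy"]),
    Under80HURatio = unname(mean(volume$intensities[volume$mask] < 80))
  )
}

#' Generate a full synthetic cohort of images and outcomes
#'
#' Generates `n_patients` tumor volumes with `round(n * metastasis_fraction)`
#' metastasis-class cases, computes each patient's four signature features,
#' and draws metastasis-free survival from an exponential proportional-
#' hazards model: subject hazard `baseline_hazard_rate *
#' exp(sum(hazard_coefficients * z))` where `z` are the cohort-standardized
#' signature features, with independent exponential censoring at
#' `censoring_rate`. Time unit is months.
#'
#' @param spec a [cohort_spec()]; `spec$seed` drives all randomness.
#' @return A `synthetic_cohort`: list with `volumes` (list of
#'   `tumor_volume`), `outcomes` (data.frame: patient_id, metastasis, time,
#'   event), `signature` (data.frame of the four true signature features
#'   used by the survival generator) and `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_patients
  n_pos <- round(n * spec$metastasis_fraction)
  labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
  ids <- sprintf("P%03d", seq_len(n))

  volumes <- lapply(seq_len(n), function(i) {
    generate_tumor_volume(spec, labels[i],
                          seed = derive_seed(spec$seed, paste0("volume", i)),
                          patient_id = ids[i])
  })

  sig <- as.data.frame(t(vapply(volumes, signature_features_of_volume,
                                numeric(4L))))
  rownames(sig) <- ids

  z <- scale(as.matrix(sig))
  z[is.nan(z)] <- 0 # constant feature across cohort carries no hazard signal
  lp <- drop(z %*% spec$hazard_coefficients)

  set.seed(derive_seed(spec$seed, "outcomes"))
  t_event <- stats::rexp(n, rate = spec$baseline_hazard_rate * exp(lp))
  t_cens <- if (spec$censoring_rate > 0) {
    stats::rexp(n, rate = spec$censoring_rate)
  } else {
    rep(Inf, n)
  }
  outcomes <- data.frame(
    patient_id = ids,
    metastasis = labels,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE
  )

  structure(list(volumes = volumes, outcomes = outcomes, signature = sig,
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d patients (%d metastasis / %d metastasis-free), %d events\n",
    nrow(x$outcomes), sum(x$outcomes$metastasis),
    sum(1 - x$outcomes$metastasis), sum(x$outcomes$event)))
  cat(sprintf("  grid %d^3, spacing %s mm\n", x$spec$grid_size,
              paste(format(x$spec$voxel_spacing), collapse = "x")))
  invisible(x)
}

#' Generate gene expression with planted feature correlations
#'
#' Builds a non-negative expression matrix (genes x samples) in which
#' `n_signal_per_feature` genes per radiomics feature are monotone functions
#' of that feature (linear on the log scale: `sign * effect * z(feature) +
#' N(0, noise_sd)`, exponentiated), and the remaining genes are pure
#' log-normal noise. A deterministic share `negative_fraction` of each
#' feature's signal genes carries a negative sign. By default the share is
#' 0.91 for `INNER_Min_Hist` and 0.09 for every other feature, emulating the
#' sign structure the risk model implies (low core minima mean more necrosis
#' and higher risk).
#'
#' @param features data.frame / matrix of samples x radiomics features
#'   (typically the four signature columns).
#' @param n_genes total genes; at least
#'   `n_signal_per_feature * ncol(features)`.
#' @param n_signal_per_feature planted signal genes per feature.
#' @param effect log-scale effect size of a signal gene per 1-SD feature
#'   change.
#' @param noise_sd log-scale Gaussian noise sd (0 allowed only with a
#'   nonzero effect).
#' @param negative_fraction scalar or per-feature vector of the share of
#'   negative-sign signal genes; `NULL` for the default sign structure.
#' @param seed integer seed.
#' @return Numeric matrix genes x samples with attribute `signal_genes`, a
#'   data.frame (gene_id, feature, effect, sign) covering the planted genes.
#' @export
generate_expression <- function(features, n_genes = 200L,
                                n_signal_per_feature = 10L,
                                effect = 1, noise_sd = 0.5,
                                negative_fraction = NULL, seed = 1L) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) >= 2L, ncol(features) >= 1L)
  if (n_signal_per_feature * ncol(features) > n_genes) {
    stop("n_signal_per_feature x n_features exceeds n_genes", call. = FALSE)
  }
  if (effect == 0 && noise_sd == 0) {
    stop("effect 0 with noise_sd 0 would generate constant genes", call. = FALSE)
  }
  if (is.null(negative_fraction)) {
    negative_fraction <- ifelse(colnames(features) == "INNER_Min_Hist",
                                0.91, 0.09)
  }
  negative_fraction <- rep_len(negative_fraction, ncol(features))

  set.seed(seed)
  n_s <- nrow(features)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  expr <- matrix(stats::rnorm(n_genes * n_s, sd = noise_sd),
                 nrow = n_genes, dimnames = list(gene_ids, rownames(features)))

  z <- scale(as.matrix(features))
  z[is.nan(z)] <- 0
  ann <- NULL
  g <- 0L
  for (j in seq_len(ncol(features))) {
    n_neg <- round(negative_fraction[j] * n_signal_per_feature)
    signs <- c(rep(-1, n_neg), rep(1, n_signal_per_feature - n_neg))
    for (s in signs) {
      g <- g + 1L
      expr[g, ] <- expr[g, ] + s * effect * z[, j]
      ann <- rbind(ann, data.frame(gene_id = gene_ids[g],
                                   feature = colnames(features)[j],
                                   effect = effect, sign = s,
                                   stringsAsFactors = FALSE))
    }
  }
  out <- exp(expr) # monotone link to a non-negative RPKM-like scale
  attr(out, "signal_genes") <- ann
  out
}

#' Generate a class-labelled feature table with planted signal columns
#'
#' Designed selection fixture: `n_signal` feature columns differ between the
#' two classes by `delta` standard deviations, the remaining columns are
#' pure standard-normal noise. Used to measure the stability-selection
#' operating characteristics (recovery of true signal columns, rejection of
#' null columns) under a known ground truth, which the image-based cohort
#' cannot provide because its radiomics features are mutually correlated.
#'
#' @param n_per_class length-2 counts (class 0, class 1).
#' @param n_features total feature columns.
#' @param n_signal number of signal columns (named `SIG1..`; the rest are
#'   `NULL1..`).
#' @param delta class mean shift of signal columns, in SD units.
#' @param seed integer seed.
#' @return List with `features` (data.frame) and `labels` (0/1 vector).
#' @export
generate_signal_features <- function(n_per_class = c(46L, 12L),
                                     n_features = 121L, n_signal = 4L,
                                     delta = 3, seed = 1L) {
  stopifnot(n_signal <= n_features, all(n_per_class >= 1L))
  set.seed(seed)
  n <- sum(n_per_class)
  labels <- rep(c(0L, 1L), n_per_class)
  x <- matrix(stats::rnorm(n * n_features), n, n_features)
  x[labels == 1L, seq_len(n_signal)] <-
    x[labels == 1L, seq_len(n_signal)] + delta
  colnames(x) <- c(sprintf("SIG%d", seq_len(n_signal)),
                   sprintf("NULL%d", seq_len(n_features - n_signal)))
  list(features = as.data.frame(x), labels = labels)
}
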