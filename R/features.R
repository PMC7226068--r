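#' Semantic Hounsfield-unit ratio features
#'
#' Fraction of in-mask voxels whose attenuation lies strictly under each
#' threshold. On nephrographic-phase contrast CT these ratios proxy the
#' non-enhancing (necrotic / hypoxic) portion of the tumor. The default
#' thresholds 100 and 80 HU yield `Under100HURatio` and `Under80HURatio`.
#'
#' @param intensities numeric 3D array of HU values.
#' @param mask logical 3D array, non-empty, same shape.
#' @param thresholds HU cut points (strict `<`).
#' @return Named numeric vector of per-threshold ratios in \[0, 1\].
#' @export
semantic_hu_ratios <- function(intensities, mask, thresholds = c(100, 80)) {
  check_mask(mask)
  mask <- array(as.logical(mask), dim(mask))
  stopifnot(identical(dim(intensities), dim(mask)))
  vals <- intensities[mask]
  out <- vapply(thresholds, function(t) mean(vals < t), numeric(1))
  names(out) <- sprintf("Under%gHURatio", thresholds)
  out
}

#' Names of the feature registry
#'
#' The extractor's frozen feature registry: (19 histogram + 16 GLCM +
#' 2 ISZM) texture features per ROI (WHOLE/INNER/OUTER), 8 morphology
#' features on the whole mask, and 2 semantic HU-ratio features — 121 columns.
#' Texture columns follow the `<ROI>_<Feature>_<Family>` scheme (for example
#' `INNER_Min_Hist`, `OUTER_Energy_Hist`, `INNER_MaxProbability_GLCM`).
#'
#' @return Character vector of the 121 feature names in stable table order.
#' @export
feature_registry <- function() {
  hist_names <- c("Min", "Max", "Mean", "Median", "P10", "P90", "IQR",
                  "Range", "MAD", "rMAD", "RMS", "SD", "Variance",
                  "Skewness", "Kurtosis", "Entropy", "Uniformity", "Energy",
                  "TotalEnergy")
  glcm_names <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
                  "ClusterTendency", "Contrast", "Correlation",
                  "DifferenceEntropy", "Dissimilarity", "ASM", "Entropy",
                  "IDM", "IMC1", "IMC2", "MaxProbability", "SumAverage",
                  "SumEntropy")
  iszm_names <- c("ZonePercentage", "SizeZoneNonUniformityNormalized")
  morph_names <- c("Volume", "SurfaceArea", "SurfaceVolumeRatio",
                   "Sphericity", "Compactness", "Maximum3DDiameter",
                   "Elongation", "Flatness")
  texture <- unlist(lapply(c("WHOLE", "INNER", "OUTER"), function(roi) {
    c(paste0(roi, "_", hist_names, "_Hist"),
      paste0(roi, "_", glcm_names, "_GLCM"),
      paste0(roi, "_", iszm_names, "_ISZM"))
  }))
  c(texture, paste0(morph_names, "_Morph"),
    "Under100HURatio", "Under80HURatio")
}

#' Signature feature names of the four-feature radiomics model
#' @return Character vector of the four prognostic signature features.
#' @export
signature_features <- function() {
  c("INNER_Min_Hist", "INNER_MaxProbability_GLCM",
    "OUTER_Energy_Hist", "Under80HURatio")
}

# All texture features (hist + GLCM + ISZM) of one ROI.
texture_features_roi <- function(intensities, mask, voxel_volume,
                                 hist_bins = 128L, glcm_bins = 128L,
                                 iszm_bins = 32L) {
  c(
    histogram_features(intensities[mask], n_bins = hist_bins,
                       voxel_volume = voxel_volume),
    glcm_features(intensities, mask, n_bins = glcm_bins),
    iszm_features(intensities, mask, n_bins = iszm_bins)
  )
}

#' Extract the full radiomics feature vector of one tumor volume
#'
#' Partitions the tumor mask into whole/inner/outer ROIs, computes the
#' 37 texture features on each ROI, the 8 morphology features on the whole
#' mask, and the 2 semantic HU ratios on the whole mask: 121 features.
#' A mask whose core erodes away falls back to the whole ROI for the
#' inner-family features (flagged by a warning naming the patient).
#'
#' @param volume a `tumor_volume` (list with `intensities`, `mask`,
#'   `spacing`, `patient_id`), e.g. from [generate_tumor_volume()].
#' @param inner_fraction core radius fraction passed to [partition_roi()].
#' @return Named numeric vector of 121 features, ordered as
#'   [feature_registry()].
#' @export
extract_features <- function(volume, inner_fraction = 0.5) {
  stopifnot(is.list(volume),
            all(c("intensities", "mask", "spacing") %in% names(volume)))
  mask <- array(as.logical(volume$mask), dim(volume$mask))
  check_mask(mask)
  rois <- partition_roi(mask, volume$spacing, inner_fraction)
  voxvol <- prod(volume$spacing)

  if (!any(rois$inner)) {
    warning(sprintf(
      "patient %s: inner ROI empty after erosion; inner features fall back to the whole ROI",
      as.character(volume$patient_id %||% "?")), call. = FALSE)
    rois$inner <- rois$whole
  }

  vals <- c(
    texture_features_roi(volume$intensities, rois$whole, voxvol),
    texture_features_roi(volume$intensities, rois$inner, voxvol),
    texture_features_roi(volume$intensities, rois$outer, voxvol),
    morphology_features(mask, volume$spacing),
    semantic_hu_ratios(volume$intensities, mask)
  )
  names(vals) <- feature_registry()
  vals
}

#' Extract the patients-by-features radiomics table of a cohort
#'
#' @param cohort list of `tumor_volume` objects.
#' @param inner_fraction core radius fraction for the ROI partition.
#' @return `data.frame` with rownames = patient ids and the 121 registry
#'   features as columns; no missing values.
#' @export
extract_feature_table <- function(cohort, inner_fraction = 0.5) {
  stopifnot(length(cohort) >= 1L)
  rows <- lapply(cohort, function(v) {
    tryCatch(
      extract_features(v, inner_fraction = inner_fraction),
      error = function(e) {
        stop(sprintf("feature extraction failed for patient %s: %s",
                     as.character(v$patient_id %||% "?"),
                     conditionMessage(e)), call. = FALSE)
      }
    )
  })
  tab <- as.data.frame(do.call(rbind, rows))
  rownames(tab) <- vapply(seq_along(cohort), function(i) {
    as.character(cohort[[i]]$patient_id %||% sprintf("P%03d", i))
  }, character(1))
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
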