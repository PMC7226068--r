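test_that("generators are bit-identical under a fixed seed", {
  spec <- cohort_spec(n_patients = 4, seed = 9)
  v1 <- generate_tumor_volume(spec, 1L, seed = 3)
  v2 <- generate_tumor_volume(spec, 1L, seed = 3)
  expect_identical(v1$intensities, v2$intensities)
  expect_identical(v1$mask, v2$mask)

  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$outcomes, c2$outcomes)
  expect_identical(c1$signature, c2$signature)
  expect_identical(c1$volumes[[2]]$intensities, c2$volumes[[2]]$intensities)
})

test_that("degenerate settings produce a constant-intensity tumor", {
  spec <- cohort_spec(rim_hu_mean = 60, rim_hu_sd = 0, core_hu_mean = 60,
                      core_hu_sd = 0, necrotic_fraction_by_class = c(0, 0))
  v <- generate_tumor_volume(spec, 0L, seed = 1)
  expect_equal(length(unique(v$intensities[v$mask])), 1L)
  expect_equal(unique(v$intensities[v$mask]), 60)
})

test_that("a fully necrotic 20-HU tumor lies almost entirely under 80 HU", {
  spec <- cohort_spec(necrotic_fraction_by_class = c(1, 1), core_hu_mean = 20)
  v <- generate_tumor_volume(spec, 1L, seed = 2)
  expect_gte(mean(v$intensities[v$mask] < 80), 0.99)
})

test_that("class counts follow the metastasis fraction after rounding", {
  ch <- small_cohort(n = 58, seed = 21)
  expect_equal(sum(ch$outcomes$metastasis), 12)
  expect_equal(sum(1 - ch$outcomes$metastasis), 46)
  expect_true(all(ch$outcomes$time > 0))
  expect_true(all(ch$outcomes$event %in% 0:1))
})

test_that("metastasis-class tumors have larger under-80-HU ratios", {
  spec <- cohort_spec(n_patients = 100, metastasis_fraction = 0.5, seed = 31)
  ch <- generate_cohort(spec)
  u80 <- ch$signature$Under80HURatio
  met <- ch$outcomes$metastasis == 1
  expect_gt(mean(u80[met]), mean(u80[!met]))
})

test_that("a null hazard vector yields near-zero Cox coefficients", {
  spec <- cohort_spec(n_patients = 150, metastasis_fraction = 0.5,
                      hazard_coefficients = c(0, 0, 0, 0), seed = 17)
  ch <- generate_cohort(spec)
  z <- as.data.frame(scale(as.matrix(ch$signature)))
  fit <- fit_rrs_model(z, ch$outcomes)$fit
  zstat <- coef(fit) / sqrt(diag(vcov(fit)))
  expect_true(all(abs(zstat) < 4))
})

test_that("a noiseless planted gene is a perfect monotone image of its feature", {
  feats <- data.frame(INNER_Min_Hist = rnorm(12), Under80HURatio = runif(12))
  rownames(feats) <- sprintf("S%02d", 1:12)
  expr <- generate_expression(feats, n_genes = 20, n_signal_per_feature = 5,
                              effect = 1, noise_sd = 0, seed = 3)
  ann <- attr(expr, "signal_genes")
  expect_equal(nrow(ann), 10)
  for (k in seq_len(nrow(ann))) {
    rho <- cor(expr[ann$gene_id[k], ], feats[[ann$feature[k]]],
               method = "spearman")
    expect_equal(rho, ann$sign[k])
  }
  expect_true(all(expr > 0))
})

test_that("expression generation rejects the constant-gene degenerate case", {
  feats <- data.frame(a = rnorm(8))
  expect_error(generate_expression(feats, effect = 0, noise_sd = 0),
               "constant genes")
  expect_error(
    generate_expression(feats, n_genes = 10, n_signal_per_feature = 20),
    "exceeds")
})

test_that("an undersized grid is rejected as a sizing error", {
  spec <- cohort_spec(grid_size = 16, voxel_spacing = c(0.5, 0.5, 0.5))
  expect_error(generate_tumor_volume(spec, 0L, seed = 1), "grid too small")
})
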