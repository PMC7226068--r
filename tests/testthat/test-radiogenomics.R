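make_feats <- function(n = 11, seed = 2) {
  set.seed(seed)
  f <- data.frame(INNER_Min_Hist = rnorm(n), INNER_MaxProbability_GLCM = runif(n),
                  OUTER_Energy_Hist = rnorm(n, 100, 20), Under80HURatio = runif(n))
  rownames(f) <- sprintf("S%02d", seq_len(n))
  f
}

test_that("monotone genes are retained with the right sign and rho", {
  f <- make_feats()
  expr <- rbind(
    up = exp(f$Under80HURatio),        # increasing transform
    down = 1 / (1 + f$Under80HURatio), # decreasing transform
    flat1 = rnorm(11), flat2 = rnorm(11), flat3 = rnorm(11),
    flat4 = rnorm(11), flat5 = rnorm(11))
  colnames(expr) <- rownames(f)
  tgs <- trait_gene_correlation(expr, f["Under80HURatio"])
  s <- tgs$Under80HURatio
  expect_true(all(c("up", "down") %in% s$gene_id))
  expect_equal(s$rho[s$gene_id == "up"], 1)
  expect_equal(s$sign[s$gene_id == "up"], 1)
  expect_equal(s$rho[s$gene_id == "down"], -1)
  expect_equal(s$sign[s$gene_id == "down"], -1)
  expect_true(all(s$p < 0.05))
})

test_that("constant genes are skipped and tiny overlaps rejected", {
  f <- make_feats()
  expr <- rbind(g1 = rnorm(11), g2 = rep(3, 11))
  colnames(expr) <- rownames(f)
  expect_warning(trait_gene_correlation(expr, f), "constant gene")
  expect_error(trait_gene_correlation(expr[, 1:4], f[1:4, ]), "at least 5")
})

test_that("the planted 91% negative-sign share is recovered within 5 points", {
  negs <- vapply(1:6, function(seed) {
    f <- make_feats(seed = seed + 100)
    expr <- generate_expression(f, n_genes = 500, n_signal_per_feature = 100,
                                effect = 1.5, noise_sd = 0.4, seed = seed)
    tgs <- trait_gene_correlation(expr, f["INNER_Min_Hist"])
    s <- tgs$INNER_Min_Hist
    ann <- attr(expr, "signal_genes")
    planted <- s$gene_id %in% ann$gene_id[ann$feature == "INNER_Min_Hist"]
    mean(s$sign[planted] < 0)
  }, numeric(1))
  expect_lt(abs(mean(negs) - 0.91), 0.05)
})

test_that("Jaccard similarities follow the set-overlap identities", {
  J <- jaccard_matrix(list(a = c("a", "b", "c"), b = c("b", "c", "d")))
  expect_equal(J["a", "b"], 0.5)
  expect_equal(diag(J), c(a = 1, b = 1))
  J2 <- jaccard_matrix(list(x = letters[1:3], y = letters[5:7]))
  expect_equal(J2["x", "y"], 0)
  set.seed(3)
  sets <- lapply(1:5, function(i) sample(letters, sample(3:10, 1)))
  names(sets) <- paste0("s", 1:5)
  J3 <- jaccard_matrix(sets)
  expect_equal(J3, t(J3))
  expect_true(all(J3 >= 0 & J3 <= 1))
  expect_equal(unname(diag(J3)), rep(1, 5))
  expect_error(jaccard_matrix(list(a = character(0), b = "x")), "empty")
})

test_that("enrichment scores are extreme for a sample's own top genes", {
  set.seed(9)
  expr <- matrix(rexp(400 * 12), 400,
                 dimnames = list(sprintf("G%03d", 1:400), sprintf("S%02d", 1:12)))
  top50 <- names(sort(expr[, 5], decreasing = TRUE))[1:50]
  es <- enrichment_scores(expr, list(top = top50))
  expect_equal(unname(which.max(es["top", ])), 5)
})

test_that("scores are invariant to monotone transforms and label shuffles", {
  set.seed(10)
  expr <- matrix(rexp(200 * 8), 200,
                 dimnames = list(sprintf("G%03d", 1:200), sprintf("S%02d", 1:8)))
  sets <- list(s1 = sprintf("G%03d", 1:30), s2 = sprintf("G%03d", 101:140))
  es <- enrichment_scores(expr, sets)
  es_mono <- enrichment_scores(log1p(expr)^2, sets)
  expect_equal(es, es_mono)
  perm <- sample(rownames(expr))
  expr_shuf <- expr
  rownames(expr_shuf) <- perm
  map <- setNames(perm, rownames(expr))
  sets_shuf <- lapply(sets, function(s) unname(map[s]))
  expect_equal(unclass(enrichment_scores(expr_shuf, sets_shuf)), unclass(es))
})

test_that("a random set's score sits inside the permutation null band", {
  set.seed(12)
  expr <- matrix(rnorm(300 * 6), 300,
                 dimnames = list(sprintf("G%03d", 1:300), sprintf("S%02d", 1:6)))
  rs <- sample(rownames(expr), 40)
  es <- enrichment_scores(expr, list(r = rs))
  null_es <- replicate(1000, {
    enrichment_scores(expr[, 1, drop = FALSE],
                      list(r = sample(rownames(expr), 40)))[1, 1]
  })
  expect_lt(abs(es[1, 1] - mean(null_es)) / sd(null_es), 3.5)
  expect_error(enrichment_scores(expr, list(tiny = rs[1:3])), "fewer than 5")
})

test_that("planted ES clusters are recovered exactly and drive survival", {
  set.seed(15)
  n_per <- 50
  truth <- rep(1:3, each = n_per)
  es <- rbind(s1 = rnorm(3 * n_per, c(-4, 0, 4)[truth], 0.4),
              s2 = rnorm(3 * n_per, c(-4, 0, 4)[truth], 0.4))
  colnames(es) <- sprintf("S%03d", seq_len(3 * n_per))
  rate <- c(0.005, 0.01, 0.08)[truth]
  out <- data.frame(time = rexp(3 * n_per, rate), event = 1L)
  res <- cluster_and_survival(es, out, k = 3)
  expect_equal(adjusted_rand_index(res$labels, truth), 1)
  expect_equal(as.character(res$labels[1]), "low")
  expect_equal(as.character(res$labels[3 * n_per]), "high")
  expect_lt(res$logrank_p, 0.05)
  expect_error(cluster_and_survival(es, out, k = 1), "at least 2")
  expect_error(cluster_and_survival(es[, 1:3], out[1:3, ], k = 5), "exceeds")
})

test_that("high-ES-driven hazards are detected in most replicate cohorts", {
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    n_per <- 50
    truth <- rep(1:3, each = n_per)
    es <- rbind(s1 = rnorm(3 * n_per, c(-3, 0, 3)[truth], 0.7),
                s2 = rnorm(3 * n_per, c(-3, 0, 3)[truth], 0.7))
    colnames(es) <- sprintf("S%03d", seq_len(3 * n_per))
    out <- data.frame(time = rexp(3 * n_per, c(0.01, 0.02, 0.06)[truth]),
                      event = 1L)
    res <- cluster_and_survival(es, out, k = 3)
    hits <- hits + (res$logrank_p < 0.05)
  }
  expect_gte(hits, 9L)
})
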