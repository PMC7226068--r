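#' Trait-associated gene sets by Spearman correlation
#'
#' Correlates every gene's expression with every radiomics feature across the
#' shared samples (Spearman, two-sided). Genes with p < `alpha` form the
#' feature's trait-associated gene set, annotated with rho, p and the
#' correlation sign, plus the `top_n` subset ranked by |rho|. P-values use
#' the exact permutation distribution for fewer than 10 samples and the
#' t-approximation otherwise (small WTS cohorts sit right at this boundary).
#' By default no multiple-testing correction is applied to the per-gene
#' screen; `fdr = TRUE` switches the threshold to Benjamini-Hochberg
#' adjusted p-values.
#'
#' @param expression numeric matrix genes x samples.
#' @param features data.frame samples x radiomics features (typically the
#'   signature columns); rows matched to expression columns by name.
#' @param alpha per-gene significance level (default 0.05).
#' @param top_n size of the |rho|-ranked subset (default 100).
#' @param fdr apply Benjamini-Hochberg adjustment before thresholding.
#' @return `trait_gene_sets`: named list (one element per feature) of
#'   data.frames (gene_id, rho, p, sign) sorted by |rho| descending, with
#'   attribute `top` holding the top-n subsets as character vectors.
#' @export
trait_gene_correlation <- function(expression, features, alpha = 0.05,
                                   top_n = 100L, fdr = FALSE) {
  expression <- as.matrix(expression)
  features <- as.data.frame(features)
  shared <- intersect(colnames(expression), rownames(features))
  if (length(shared) == 0L &&
      ncol(expression) == nrow(features)) {
    shared <- seq_len(ncol(expression)) # positional alignment
    expr <- expression
    feat <- features
  } else {
    expr <- expression[, shared, drop = FALSE]
    feat <- features[shared, , drop = FALSE]
  }
  n <- ncol(expr)
  if (n < 5L) {
    stop("need at least 5 shared samples between expression and features",
         call. = FALSE)
  }

  const <- apply(expr, 1, function(g) stats::var(g) == 0)
  if (any(const)) {
    warning(sprintf("skipping %d constant gene row(s)", sum(const)),
            call. = FALSE)
    expr <- expr[!const, , drop = FALSE]
  }

  sets <- lapply(names(feat), function(fn) {
    res <- spearman_screen(expr, feat[[fn]])
    keep <- if (fdr) stats::p.adjust(res$p, "BH") < alpha else res$p < alpha
    res <- res[keep, , drop = FALSE]
    res[order(-abs(res$rho)), , drop = FALSE]
  })
  names(sets) <- names(feat)
  tops <- lapply(sets, function(s) utils::head(s$gene_id, top_n))
  structure(sets, top = tops, alpha = alpha, class = "trait_gene_sets")
}

# Vectorized Spearman rho + p of every gene (rows) against one feature.
spearman_screen <- function(expr, y) {
  n <- length(y)
  use_exact <- n < 10L
  has_ties <- function(v) anyDuplicated(v) > 0L
  if (use_exact || has_ties(y)) {
    res <- t(apply(expr, 1, function(g) {
      ct <- suppressWarnings(
        stats::cor.test(g, y, method = "spearman", exact = use_exact)
      )
      c(unname(ct$estimate), ct$p.value)
    }))
    rho <- res[, 1]
    p <- res[, 2]
  } else {
    ry <- rank(y)
    rg <- t(apply(expr, 1, rank))
    rho <- drop(stats::cor(t(rg), ry))
    tt <- rho * sqrt((n - 2) / pmax(1e-12, 1 - rho^2))
    p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    p[abs(rho) >= 1] <- 0
  }
  data.frame(gene_id = rownames(expr), rho = rho, p = p,
             sign = sign(rho), stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.trait_gene_sets <- function(x, ...) {
  cat("Trait-associated gene sets (alpha =", attr(x, "alpha"), ")\n")
  for (fn in names(x)) {
    s <- x[[fn]]
    negf <- if (nrow(s)) mean(s$sign < 0) else NA
    cat(sprintf("  %-28s %4d genes (%.0f%% negative sign)\n",
                fn, nrow(s), 100 * negf))
  }
  invisible(x)
}

#' Jaccard similarity matrix of gene sets
#'
#' \eqn{J(S_i, S_j) = |S_i \cap S_j| / |S_i \cup S_j|}: 1 on the diagonal,
#' symmetric, 0 exactly for disjoint sets.
#'
#' @param sets named list of character vectors; all non-empty.
#' @return Symmetric numeric matrix in \[0, 1\].
#' @export
jaccard_matrix <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  if (any(!vapply(sets, length, integer(1)))) {
    stop("empty gene set; Jaccard similarity is undefined", call. = FALSE)
  }
  sets <- lapply(sets, unique)
  k <- length(sets)
  out <- matrix(1, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      inter <- length(intersect(sets[[i]], sets[[j]]))
      out[i, j] <- out[j, i] <-
        inter / (length(sets[[i]]) + length(sets[[j]]) - inter)
    }
  }
  out
}

#' Per-sample rank-based gene-set enrichment scores
#'
#' For each sample, genes are ranked by within-sample expression (average
#' ranks on ties) and each set's enrichment score is the rank-sum z
#' statistic: \eqn{z = (W - n_{in}(N+1)/2) / \sqrt{n_{in} n_{out} (N+1)/12}}
#' with W the sum of in-set ranks. Higher scores mean coordinate
#' up-regulation of the set in that sample. Being rank-based, the score is
#' invariant under any strictly monotone within-sample transform of the
#' expression values.
#'
#' @param expression numeric matrix genes x samples.
#' @param gene_sets named list of character vectors, or a `trait_gene_sets`
#'   object (its top-n subsets are used). Each set must share at least 5
#'   genes with the matrix.
#' @return `es_matrix`: numeric matrix gene-set x sample.
#' @export
enrichment_scores <- function(expression, gene_sets) {
  expression <- as.matrix(expression)
  if (inherits(gene_sets, "trait_gene_sets")) {
    gene_sets <- attr(gene_sets, "top")
  }
  stopifnot(is.list(gene_sets), length(gene_sets) >= 1L)
  N <- nrow(expression)
  ranks <- apply(expression, 2, rank)

  es <- matrix(NA_real_, length(gene_sets), ncol(expression),
               dimnames = list(names(gene_sets), colnames(expression)))
  for (s in seq_along(gene_sets)) {
    inset <- rownames(expression) %in% gene_sets[[s]]
    n_in <- sum(inset)
    if (n_in < 5L) {
      stop(sprintf("gene set '%s' shares fewer than 5 genes with the matrix",
                   names(gene_sets)[s] %||% s), call. = FALSE)
    }
    w <- colSums(ranks[inset, , drop = FALSE])
    mu <- n_in * (N + 1) / 2
    sg <- sqrt(n_in * (N - n_in) * (N + 1) / 12)
    es[s, ] <- (w - mu) / sg
  }
  class(es) <- c("es_matrix", class(es))
  es
}

#' Enrichment-score subgroups and their survival difference
#'
#' Hierarchically clusters samples on their enrichment-score profiles
#' (Euclidean distance, Ward linkage), cuts the tree into `k` clusters,
#' orders clusters by mean combined enrichment (the unweighted mean over all
#' sets) into low -> high groups, and compares the extreme groups by the
#' log-rank test.
#'
#' @param es `es_matrix` (gene sets x samples) from [enrichment_scores()].
#' @param outcomes data.frame with `time`, `event`, one row per sample
#'   (aligned to the ES columns).
#' @param k number of subgroups (default 3: low/intermediate/high).
#' @return List with per-sample `labels` (ordered factor low..high),
#'   `logrank_p` between the extreme groups, and the `hclust` tree.
#' @export
cluster_and_survival <- function(es, outcomes, k = 3L) {
  es <- unclass(es)
  n <- ncol(es)
  if (k < 2L) {
    stop("k must be at least 2", call. = FALSE)
  }
  if (k > n) {
    stop("k exceeds the number of samples", call. = FALSE)
  }
  stopifnot(nrow(outcomes) == n)

  tree <- stats::hclust(stats::dist(t(es)), method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  combined <- colMeans(es)
  ord <- order(vapply(seq_len(k), function(g) mean(combined[raw == g]),
                      numeric(1)))
  lab_names <- if (k == 3L) {
    c("low", "intermediate", "high")
  } else {
    paste0("ES", seq_len(k))
  }
  labels <- factor(lab_names[match(raw, ord)], levels = lab_names,
                   ordered = TRUE)

  extreme <- labels %in% c(lab_names[1], lab_names[k])
  sd_ <- survival::survdiff(
    survival::Surv(outcomes$time[extreme], outcomes$event[extreme]) ~
      droplevels(labels[extreme]))
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)

  list(labels = labels, logrank_p = p, tree = tree)
}
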