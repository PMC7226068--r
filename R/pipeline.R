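#' Run the whole radiomics/radiogenomics pipeline on a synthetic cohort
#'
#' Executes the full analysis end to end: simulate the cohort, extract the
#' 121-feature table, balance classes with ADASYN, select the stable
#' signature by bootstrapped LASSO, evaluate the three classifiers, fit the
#' Cox radiomics risk score on the original (unbalanced) cohort, find the
#' optimal cutoff and stratify survival, then link the signature features to
#' generated expression (trait-associated gene sets, Jaccard overlap,
#' enrichment scores, ES-subgroup survival). One global seed deterministically
#' derives per-stage seeds by stable hashing of the stage name, so every
#' stage is independently reproducible. If `out_dir` is given, stage outputs
#' (CSV/TSV/GMT/JSON) and a run manifest are written there.
#'
#' @param config list with optional entries `cohort` (a [cohort_spec()]),
#'   `selection` (a [selection_config()]), `inner_fraction`,
#'   `expression` (list: n_genes, n_signal_per_feature, effect, noise_sd,
#'   n_samples), `risk` (list: search_band), `genes` (list: alpha, top_n, k),
#'   and `seed`; or a path to a YAML file holding those entries.
#' @param out_dir optional output directory for stage artifacts.
#' @return A `pipeline_result` list with every stage's output and a
#'   `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  spec <- config$cohort %||% cohort_spec(seed = derive_seed(seed, "simulate"))
  if (!inherits(spec, "cohort_spec")) {
    spec <- do.call(cohort_spec, spec)
  }
  selcfg <- config$selection %||%
    selection_config(n_bootstrap = 500L, seed = derive_seed(seed, "select"))
  if (!inherits(selcfg, "selection_config")) {
    selcfg <- do.call(selection_config, selcfg)
  }
  inner_fraction <- config$inner_fraction %||% 0.5
  expr_cfg <- utils::modifyList(
    list(n_genes = 200L, n_signal_per_feature = 25L, effect = 1.2,
         noise_sd = 0.5, n_samples = 11L),
    config$expression %||% list())
  risk_cfg <- utils::modifyList(list(search_band = c(15, 85)),
                                config$risk %||% list())
  genes_cfg <- utils::modifyList(list(alpha = 0.05, top_n = 100L, k = 3L),
                                 config$genes %||% list())

  t0 <- Sys.time()
  stages <- character(0)
  step <- function(name) {
    stages <<- c(stages, name)
    message(sprintf("[%s] stage: %s", format(Sys.time(), "%H:%M:%S"), name))
  }

  step("simulate")
  cohort <- generate_cohort(spec)

  step("features")
  feats <- extract_feature_table(cohort$volumes, inner_fraction)
  labels <- cohort$outcomes$metastasis

  step("balance")
  bal <- adasyn_balance(feats, labels, k = selcfg$adasyn_k,
                        seed = derive_seed(seed, "adasyn"))

  step("select")
  sel <- bootstrap_lasso_selection(bal$features, bal$labels, selcfg)
  signature <- sel$signature
  if (!length(signature)) {
    signature <- names(sort(sel$frequency, decreasing = TRUE))[1:4]
    warning("no feature reached the stability threshold; using the 4 most frequent",
            call. = FALSE)
  }

  step("classify")
  report <- evaluate_classifiers(bal$features[signature], bal$labels, selcfg)
  importance <- logistic_importance(bal$features[signature], bal$labels)

  step("risk")
  model <- fit_rrs_model(feats[signature], cohort$outcomes)
  scores <- compute_rrs(model, feats)
  cut <- optimal_cutoff(scores, cohort$outcomes, risk_cfg$search_band)
  strat <- km_logrank(scores, cut$cutoff, cohort$outcomes)

  step("genes")
  n_g <- min(expr_cfg$n_samples, nrow(feats))
  genomic_idx <- seq_len(n_g) # genomic subcohort: first n_samples patients
  expr <- generate_expression(
    feats[genomic_idx, signature, drop = FALSE],
    n_genes = expr_cfg$n_genes,
    n_signal_per_feature = expr_cfg$n_signal_per_feature,
    effect = expr_cfg$effect, noise_sd = expr_cfg$noise_sd,
    seed = derive_seed(seed, "expression"))
  tgs <- trait_gene_correlation(expr, feats[genomic_idx, signature, drop = FALSE],
                                alpha = genes_cfg$alpha,
                                top_n = genes_cfg$top_n)
  jac <- jaccard_matrix(lapply(tgs, function(s) s$gene_id))
  es <- enrichment_scores(expr, tgs)
  subgroups <- cluster_and_survival(es, cohort$outcomes[genomic_idx, ],
                                    k = min(genes_cfg$k, n_g))

  manifest <- list(
    seed = seed,
    stages = stages,
    n_patients = spec$n_patients,
    n_metastasis = sum(labels),
    signature = signature,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = format(t0, "%Y-%m-%d %H:%M:%S")
  )

  result <- structure(
    list(cohort = cohort, features = feats, balanced = bal, selection = sel,
         classifier_report = report, importance = importance,
         rrs_model = model, scores = scores, cutoff = cut,
         stratification = strat, expression = expr, trait_genes = tgs,
         jaccard = jac, es = es, subgroups = subgroups,
         manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir)
  }
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$features,
                   file.path(out_dir, "features.csv"))
  utils::write.csv(result$cohort$outcomes,
                   file.path(out_dir, "outcomes.csv"), row.names = FALSE)
  utils::write.table(result$expression, file.path(out_dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  write_gmt(attr(result$trait_genes, "top"),
            file.path(out_dir, "trait_gene_sets.gmt"))
  jsonlite::write_json(
    list(frequency = as.list(result$selection$frequency),
         signature = result$selection$signature),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(coefficients = as.list(coef(result$rrs_model)),
         cutoff = result$cutoff$cutoff,
         cutoff_percentile = result$cutoff$percentile,
         hr = result$stratification$hr,
         logrank_p = result$stratification$logrank_p),
    file.path(out_dir, "risk.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Radiomics pipeline result\n")
  cat(sprintf("  cohort: %d patients, %d metastasis\n",
              nrow(x$features), x$manifest$n_metastasis))
  cat("  signature:", paste(x$manifest$signature, collapse = ", "), "\n")
  cat(sprintf("  cutoff %.4f (%.1f%%), HR %.3f, log-rank p %.4g\n",
              x$cutoff$cutoff, 100 * x$cutoff$percentile,
              x$stratification$hr, x$stratification$logrank_p))
  invisible(x)
}
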