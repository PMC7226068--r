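#' Configuration of the stability-selection stage
#'
#' @param n_bootstrap number of bootstrap replicates (study setting 10,000;
#'   smaller values are appropriate for interactive use).
#' @param holdout_ratio fraction of patients held out per replicate.
#' @param cv_folds folds of the internal cross-validation choosing the LASSO
#'   penalty.
#' @param frequency_threshold selection-frequency cut defining the stable
#'   signature.
#' @param adasyn_k neighbourhood size of the ADASYN oversampler.
#' @param adasyn_mode `"global"` balances once before the bootstrap loop
#'   (the study's stated order); `"per_bootstrap"` re-balances inside each
#'   training split, avoiding synthetic-neighbour leakage across splits.
#' @param seed integer seed.
#' @return A validated `selection_config` list.
#' @export
selection_config <- function(n_bootstrap = 10000L, holdout_ratio = 0.2,
                             cv_folds = 5L, frequency_threshold = 0.95,
                             adasyn_k = 5L,
                             adasyn_mode = c("global", "per_bootstrap"),
                             seed = 1L) {
  adasyn_mode <- match.arg(adasyn_mode)
  stopifnot(holdout_ratio > 0, holdout_ratio < 1,
            frequency_threshold > 0, frequency_threshold <= 1,
            n_bootstrap >= 1L, cv_folds >= 2L, adasyn_k >= 1L)
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 holdout_ratio = holdout_ratio,
                 cv_folds = as.integer(cv_folds),
                 frequency_threshold = frequency_threshold,
                 adasyn_k = as.integer(adasyn_k),
                 adasyn_mode = adasyn_mode,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' ADASYN adaptive synthetic oversampling
#'
#' Balances a two-class feature table by synthesizing minority-class points.
#' Each minority point is weighted by the share of majority points among its
#' k nearest neighbours (density-adaptive: harder regions get more synthetic
#' mass); each synthetic point is a convex combination of a minority point
#' and one of its k nearest minority neighbours. Distances are Euclidean on
#' internally z-scored features; synthetic points are generated in the
#' original feature space. Original rows are always retained as a prefix of
#' the output.
#'
#' @param features data.frame of patients x features.
#' @param labels binary vector (0/1) per patient.
#' @param k neighbourhood size (minority class must exceed k).
#' @param seed integer seed.
#' @return List with balanced `features` and `labels`; synthetic rows carry
#'   rownames `SYN...`.
#' @export
adasyn_balance <- function(features, labels, k = 5L, seed = 1L) {
  features <- as.data.frame(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("ADASYN needs both classes present", call. = FALSE)
  }
  counts <- table(factor(labels, levels = c(0, 1)))
  minority <- if (counts[["1"]] <= counts[["0"]]) 1L else 0L
  n_min <- min(counts)
  n_maj <- max(counts)
  if (n_min < k + 1L) {
    stop(sprintf(
      "minority class has %d cases but ADASYN with k = %d needs at least %d; lower k",
      n_min, k, k + 1L), call. = FALSE)
  }
  g_total <- n_maj - n_min
  if (g_total == 0L) {
    return(list(features = features, labels = labels))
  }

  x <- as.matrix(features)
  xs <- scale(x)
  xs[is.nan(xs)] <- 0
  d <- as.matrix(stats::dist(xs))
  diag(d) <- Inf

  min_idx <- which(labels == minority)
  # ratio of majority neighbours among the k nearest of each minority point
  r <- vapply(min_idx, function(i) {
    nn <- order(d[i, ])[seq_len(k)]
    mean(labels[nn] != minority)
  }, numeric(1))
  w <- if (sum(r) > 0) r / sum(r) else rep(1 / length(r), length(r))
  g_i <- round(w * g_total)

  set.seed(seed)
  syn <- vector("list", length(min_idx))
  for (m in seq_along(min_idx)) {
    if (g_i[m] == 0L) next
    i <- min_idx[m]
    nn_min <- min_idx[order(d[i, min_idx])][seq_len(k)]
    picks <- nn_min[sample.int(k, g_i[m], replace = TRUE)]
    lam <- stats::runif(g_i[m])
    syn[[m]] <- x[rep(i, g_i[m]), , drop = FALSE] * (1 - lam) +
      x[picks, , drop = FALSE] * lam
  }
  syn <- do.call(rbind, syn)
  if (is.null(syn)) {
    return(list(features = features, labels = labels))
  }
  syn <- as.data.frame(syn)
  colnames(syn) <- colnames(features)
  rownames(syn) <- sprintf("SYN%04d", seq_len(nrow(syn)))
  list(
    features = rbind(features, syn),
    labels = c(labels, rep(minority, nrow(syn)))
  )
}

# Stratified train/holdout split indices (without replacement).
stratified_split <- function(labels, holdout_ratio) {
  train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, round(length(idx) * (1 - holdout_ratio)))
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

#' Bootstrapped LASSO stability selection of prognostic features
#'
#' Repeats, `n_bootstrap` times: draw a stratified (1 - holdout) training
#' split, z-score the features on that split, fit an L1-penalized logistic
#' regression with the penalty chosen by `cv_folds`-fold cross-validation
#' (minimum-deviance lambda), and record which features carry nonzero
#' coefficients. The stable signature is the set of features selected in at
#' least `frequency_threshold` of replicates. With `adasyn_mode = "global"`
#' the caller is expected to balance classes once beforehand (see
#' [adasyn_balance()]); with `"per_bootstrap"` each training split is
#' balanced internally.
#'
#' @param features data.frame of patients x features (constant columns are
#'   dropped with a warning).
#' @param labels binary outcome per patient.
#' @param config a [selection_config()].
#' @return An object of class `stability_selection`: list with `frequency`
#'   (named, per feature), `signature`, `threshold`, `n_bootstrap`.
#' @export
bootstrap_lasso_selection <- function(features, labels, config = selection_config()) {
  features <- as.data.frame(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels))
  if (min(table(labels)) < 2L) {
    stop("need at least 2 patients per class", call. = FALSE)
  }

  const <- vapply(features, function(col) stats::var(col) == 0, logical(1))
  if (any(const)) {
    warning(sprintf("dropping %d constant feature column(s): %s",
                    sum(const),
                    paste(utils::head(names(features)[const], 5), collapse = ", ")),
            call. = FALSE)
    features <- features[!const]
  }

  x_all <- as.matrix(features)
  p <- ncol(x_all)
  hits <- numeric(p)
  names(hits) <- colnames(x_all)

  set.seed(config$seed)
  for (b in seq_len(config$n_bootstrap)) {
    train <- stratified_split(labels, config$holdout_ratio)
    x <- x_all[train, , drop = FALSE]
    y <- labels[train]
    if (config$adasyn_mode == "per_bootstrap") {
      bal <- adasyn_balance(as.data.frame(x), y, k = config$adasyn_k,
                            seed = config$seed + b)
      x <- as.matrix(bal$features)
      y <- bal$labels
    }
    x <- scale(x)
    x[is.nan(x)] <- 0
    foldid <- sample(rep_len(seq_len(config$cv_folds), length(y)))
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                            foldid = foldid, standardize = FALSE)
    beta <- stats::coef(cv, s = "lambda.min")[-1, 1]
    hits[beta != 0] <- hits[beta != 0] + 1
  }

  freq <- hits / config$n_bootstrap
  structure(
    list(frequency = freq,
         signature = names(freq)[freq >= config$frequency_threshold],
         threshold = config$frequency_threshold,
         n_bootstrap = config$n_bootstrap),
    class = "stability_selection"
  )
}

#' @export
print.stability_selection <- function(x, ...) {
  cat(sprintf("Stability selection over %d bootstrap replicates (threshold %.2f)\n",
              x$n_bootstrap, x$threshold))
  if (length(x$signature)) {
    cat("Signature:\n")
    for (f in x$signature) {
      cat(sprintf("  %-30s frequency %.4f\n", f, x$frequency[f]))
    }
  } else {
    cat("No feature reached the selection threshold.\n")
  }
  invisible(x)
}

#' @export
plot.stability_selection <- function(x, top = 20L, ...) {
  f <- sort(x$frequency, decreasing = TRUE)
  f <- utils::head(f, top)
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(f), horiz = TRUE, las = 1,
                    xlab = "selection frequency", xlim = c(0, 1), ...)
  graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}

binary_metrics <- function(truth, score, label = NULL) {
  auc <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  pred <- as.integer(score >= 0.5)
  c(AUC = auc,
    Sensitivity = mean(pred[truth == 1] == 1),
    Specificity = mean(pred[truth == 0] == 0),
    Accuracy = mean(pred == truth))
}

#' Evaluate the signature with three classifiers over bootstrap splits
#'
#' For each replicate, trains a regularized (ridge) logistic model, a
#' linear-kernel SVM and a 50-tree random forest on a stratified training
#' split of the signature features and evaluates AUC, sensitivity,
#' specificity and accuracy on both the training and the holdout split;
#' reports bootstrap means. A replicate whose holdout lacks a class is
#' resampled.
#'
#' @param features data.frame restricted to the signature columns.
#' @param labels binary outcome per patient.
#' @param config a [selection_config()]; `n_bootstrap` controls replicates.
#' @return `classifier_report`: 3 x 2 x 4 array (classifier x split x
#'   metric) of bootstrap means, with `n_bootstrap` attribute.
#' @export
evaluate_classifiers <- function(features, labels, config = selection_config()) {
  features <- as.data.frame(features)
  labels <- as.integer(labels)
  stopifnot(ncol(features) >= 1L, nrow(features) == length(labels))

  classifiers <- c("logistic", "svm_linear", "random_forest")
  acc <- array(0, c(3, 2, 4),
               dimnames = list(classifiers, c("train", "test"),
                               c("AUC", "Sensitivity", "Specificity", "Accuracy")))
  set.seed(config$seed)
  x_all <- as.matrix(features)

  done <- 0L
  while (done < config$n_bootstrap) {
    train <- stratified_split(labels, config$holdout_ratio)
    test <- setdiff(seq_along(labels), train)
    if (length(unique(labels[test])) < 2L || length(unique(labels[train])) < 2L) {
      next # degenerate holdout; resample
    }
    done <- done + 1L

    mu <- colMeans(x_all[train, , drop = FALSE])
    sdv <- apply(x_all[train, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    xs <- sweep(sweep(x_all, 2, mu), 2, sdv, `/`)
    xtr <- xs[train, , drop = FALSE]
    xte <- xs[test, , drop = FALSE]
    ytr <- labels[train]

    # ridge-regularized logistic (two-column x required by glmnet)
    xtr2 <- if (ncol(xtr) == 1L) cbind(xtr, 0) else xtr
    xte2 <- if (ncol(xte) == 1L) cbind(xte, 0) else xte
    fit_lr <- glmnet::glmnet(xtr2, ytr, family = "binomial", alpha = 0,
                             lambda = 0.01, standardize = FALSE)
    p_lr <- list(train = stats::predict(fit_lr, xtr2, type = "response")[, 1],
                 test = stats::predict(fit_lr, xte2, type = "response")[, 1])

    fit_svm <- e1071::svm(xtr, factor(ytr), kernel = "linear",
                          probability = TRUE)
    p_svm <- lapply(list(train = xtr, test = xte), function(xx) {
      attr(stats::predict(fit_svm, xx, probability = TRUE),
           "probabilities")[, "1"]
    })

    fit_rf <- randomForest::randomForest(xtr, factor(ytr), ntree = 50L)
    p_rf <- lapply(list(train = xtr, test = xte), function(xx) {
      stats::predict(fit_rf, xx, type = "prob")[, "1"]
    })

    probs <- list(logistic = p_lr, svm_linear = p_svm, random_forest = p_rf)
    for (cl in classifiers) {
      acc[cl, "train", ] <- acc[cl, "train", ] +
        binary_metrics(ytr, probs[[cl]]$train)
      acc[cl, "test", ] <- acc[cl, "test", ] +
        binary_metrics(labels[test], probs[[cl]]$test)
    }
  }
  out <- acc / config$n_bootstrap
  attr(out, "n_bootstrap") <- config$n_bootstrap
  class(out) <- c("classifier_report", class(out))
  out
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("Classifier report (bootstrap means over %d replicates)\n",
              attr(x, "n_bootstrap")))
  y <- x
  attributes(y) <- attributes(x)[c("dim", "dimnames")]
  for (split in c("train", "test")) {
    cat("\n", split, ":\n", sep = "")
    print(round(y[, split, ], 4))
  }
  invisible(x)
}

#' Multivariate logistic importance of the signature
#'
#' Unpenalized multivariate logistic regression of the metastasis label on
#' the signature features; the importance of each feature is its weight and
#' odds ratio `exp(weight)`. Perfect separation is reported with a warning
#' and weights capped at +/- 20 on the linear scale.
#'
#' @param features data.frame restricted to the signature columns.
#' @param labels binary outcome per patient.
#' @return data.frame with feature, weight, odds_ratio.
#' @export
logistic_importance <- function(features, labels) {
  features <- as.data.frame(features)
  labels <- as.integer(labels)
  stopifnot(ncol(features) >= 1L)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm(labels ~ ., data = cbind(features, labels = labels),
               family = stats::binomial())
  )
  w <- stats::coef(fit)[-1]
  eps <- 1e-8
  separated <- any(stats::fitted(fit) < eps | stats::fitted(fit) > 1 - eps)
  if (any(abs(w) > 20, na.rm = TRUE) || !fit$converged || separated) {
    warning("possible perfect separation: weights capped at |20|", call. = FALSE)
    w <- pmin(pmax(w, -20), 20)
  }
  data.frame(feature = names(w), weight = unname(w),
             odds_ratio = exp(unname(w)), stringsAsFactors = FALSE)
}
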