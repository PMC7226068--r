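test_that("ADASYN leaves balanced input unchanged and rejects bad input", {
  x <- data.frame(a = rnorm(20), b = rnorm(20))
  y <- rep(c(0, 1), each = 10)
  out <- adasyn_balance(x, y, k = 3)
  expect_identical(out$features, x)
  expect_identical(out$labels, as.integer(y))
  expect_error(adasyn_balance(x, rep(0, 20)), "both classes")
  expect_error(adasyn_balance(x[1:12, ], c(rep(0, 10), 1, 1), k = 5),
               "lower k")
})

test_that("ADASYN balances a 46/12 cohort and keeps originals as a prefix", {
  set.seed(4)
  x <- data.frame(matrix(rnorm(58 * 5), 58))
  x[47:58, 1] <- x[47:58, 1] + 2
  y <- rep(c(0L, 1L), c(46, 12))
  out <- adasyn_balance(x, y, k = 5, seed = 2)
  counts <- table(out$labels)
  expect_lte(abs(counts[["0"]] - counts[["1"]]), 2)
  expect_equal(out$features[1:58, ], x, ignore_attr = TRUE)
  expect_identical(out$labels[1:58], y)
  # determinism
  out2 <- adasyn_balance(x, y, k = 5, seed = 2)
  expect_identical(out$features, out2$features)
})

test_that("every synthetic point lies on a segment between two minority points", {
  set.seed(8)
  x <- data.frame(matrix(rnorm(40 * 3), 40))
  y <- rep(c(0L, 1L), c(32, 8))
  out <- adasyn_balance(x, y, k = 4, seed = 6)
  syn <- as.matrix(out$features[-(1:40), , drop = FALSE])
  minority <- as.matrix(x[y == 1L, ])
  on_some_segment <- function(s) {
    for (i in seq_len(nrow(minority))) {
      for (j in seq_len(nrow(minority))) {
        if (i == j) next
        d <- minority[j, ] - minority[i, ]
        t <- (s - minority[i, ]) / d
        if (max(t) - min(t) < 1e-8 && t[1] >= -1e-8 && t[1] <= 1 + 1e-8) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  expect_true(all(apply(syn, 1, on_some_segment)))
})

test_that("stability selection recovers planted features and is deterministic", {
  fx <- generate_signal_features(c(30, 12), n_features = 20, n_signal = 3,
                                 delta = 3, seed = 2)
  bal <- adasyn_balance(fx$features, fx$labels, k = 5, seed = 1)
  cfg <- selection_config(n_bootstrap = 60, seed = 10)
  sel <- bootstrap_lasso_selection(bal$features, bal$labels, cfg)
  expect_true(all(c("SIG1", "SIG2", "SIG3") %in% sel$signature))
  expect_true(all(sel$frequency >= 0 & sel$frequency <= 1))

  cfg1 <- selection_config(n_bootstrap = 1, seed = 33)
  s1 <- bootstrap_lasso_selection(bal$features, bal$labels, cfg1)
  s2 <- bootstrap_lasso_selection(bal$features, bal$labels, cfg1)
  expect_identical(s1$frequency, s2$frequency)
})

test_that("constant columns are dropped with a warning, not an error", {
  fx <- generate_signal_features(c(20, 10), n_features = 10, n_signal = 2,
                                 delta = 3, seed = 5)
  fx$features$flat <- 1
  cfg <- selection_config(n_bootstrap = 5, seed = 1)
  expect_warning(sel <- bootstrap_lasso_selection(fx$features, fx$labels, cfg),
                 "constant")
  expect_false("flat" %in% names(sel$frequency))
})

test_that("a duplicated feature splits selections: at most one picked per fit", {
  fx <- generate_signal_features(c(30, 12), n_features = 10, n_signal = 1,
                                 delta = 4, seed = 12)
  fx$features$SIG1copy <- fx$features$SIG1 + rnorm(42, sd = 1e-9)
  cfg <- selection_config(n_bootstrap = 40, seed = 2)
  sel <- bootstrap_lasso_selection(fx$features, fx$labels, cfg)
  # the collinear pair shares the signal: the pairwise minimum cannot be high
  expect_lt(min(sel$frequency[c("SIG1", "SIG1copy")]), 0.95)
  expect_gt(max(sel$frequency[c("SIG1", "SIG1copy")]) +
              min(sel$frequency[c("SIG1", "SIG1copy")]), 0.9)
})

test_that("classifiers separate a separable cohort and stay within range", {
  fx <- generate_signal_features(c(25, 25), n_features = 4, n_signal = 4,
                                 delta = 6, seed = 3)
  cfg <- selection_config(n_bootstrap = 20, seed = 4)
  rep_ <- evaluate_classifiers(fx$features, fx$labels, cfg)
  expect_true(all(rep_ >= 0 & rep_ <= 1))
  for (cl in rownames(rep_)) {
    expect_gte(rep_[cl, "test", "AUC"], 0.95)
  }
  # train metrics should not fall below test on average
  expect_true(all(rep_[, "train", "AUC"] >= rep_[, "test", "AUC"] - 0.02))
})

test_that("permuted labels leave test AUC at chance level", {
  set.seed(99)
  fx <- generate_signal_features(c(30, 30), n_features = 4, n_signal = 4,
                                 delta = 3, seed = 7)
  labels <- sample(fx$labels)
  cfg <- selection_config(n_bootstrap = 200, seed = 8)
  rep_ <- evaluate_classifiers(fx$features, labels, cfg)
  for (cl in rownames(rep_)) {
    expect_gte(rep_[cl, "test", "AUC"], 0.4)
    expect_lte(rep_[cl, "test", "AUC"], 0.6)
  }
})

test_that("logistic importance reports OR = exp(weight) and handles separation", {
  fx <- generate_signal_features(c(40, 25), n_features = 3, n_signal = 2,
                                 delta = 1, seed = 6)
  imp <- logistic_importance(fx$features, fx$labels)
  expect_equal(imp$odds_ratio, exp(imp$weight), tolerance = 1e-6)
  expect_equal(nrow(imp), 3)

  sep <- generate_signal_features(c(15, 15), n_features = 2, n_signal = 2,
                                  delta = 30, seed = 2)
  expect_warning(imp2 <- logistic_importance(sep$features, sep$labels),
                 "separation")
  expect_true(all(abs(imp2$weight) <= 20))
})
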