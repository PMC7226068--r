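paper_coefs <- c(INNER_Min_Hist = -0.1020, INNER_MaxProbability_GLCM = 0.0343,
                 OUTER_Energy_Hist = 0.4302, Under80HURatio = 0.6369)

test_that("the risk score is the plain linear predictor", {
  zero <- c(INNER_Min_Hist = 0, INNER_MaxProbability_GLCM = 0,
            OUTER_Energy_Hist = 0, Under80HURatio = 0)
  expect_equal(compute_rrs(paper_coefs, zero), 0)
  ones <- zero + 1
  expect_equal(round(compute_rrs(paper_coefs, ones), 4), 0.9994)
  # monotone in a positively weighted feature
  grid <- seq(0, 1, by = 0.1)
  scores <- vapply(grid, function(u) {
    compute_rrs(paper_coefs, replace(ones, "Under80HURatio", u))
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  # linearity in the feature vector
  a <- runif(4)
  names(a) <- names(paper_coefs)
  expect_equal(compute_rrs(paper_coefs, as.list(3 * a)),
               3 * compute_rrs(paper_coefs, as.list(a)), tolerance = 1e-12)
  expect_error(compute_rrs(paper_coefs, c(INNER_Min_Hist = 1)),
               "Under80HURatio")
})

test_that("the Cox fit recovers planted coefficients and rejects no-event data", {
  set.seed(20)
  n <- 300
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  beta <- c(a = 0.5, b = -0.7)
  t_ev <- rexp(n, rate = 0.02 * exp(as.matrix(x) %*% beta))
  t_cn <- rexp(n, rate = 0.01)
  out <- data.frame(time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn))
  m <- fit_rrs_model(x, out)
  se <- sqrt(diag(vcov(m$fit)))
  expect_true(all(abs(coef(m) - beta) < 3 * se))

  out0 <- data.frame(time = out$time, event = 0)
  expect_error(fit_rrs_model(x, out0), "at least one event")
  expect_error(fit_rrs_model(x, data.frame(time = c(-1, rep(1, n - 1)),
                                           event = out$event)), "positive")

  # duplicating every patient leaves the estimate essentially unchanged
  # (duplication creates ties, so Efron correction moves it slightly)
  m2 <- fit_rrs_model(rbind(x, x), rbind(out, out))
  expect_equal(coef(m2), coef(m), tolerance = 0.02)
})

test_that("the grid search maximizes the log-rank statistic over the band", {
  set.seed(5)
  n <- 60
  scores <- c(rnorm(n / 2, 0, 0.3), rnorm(n / 2, 4, 0.3))
  rate <- ifelse(scores > 2, 0.08, 0.01)
  out <- data.frame(time = rexp(n, rate), event = 1L)
  res <- optimal_cutoff(scores, out)
  expect_gt(res$cutoff, 1)
  expect_lt(res$cutoff, 3.5)
  expect_gte(res$percentile, 0.15)
  expect_lte(res$percentile, 0.85)
  # exhaustive oracle: no candidate in the band beats the returned statistic
  lims <- quantile(scores, c(0.15, 0.85))
  cand <- unique(scores[scores >= lims[1] & scores <= lims[2]])
  stats <- vapply(cand, function(cc) {
    g <- scores > cc
    if (sum(g) < 3 || sum(!g) < 3) return(-Inf)
    survival::survdiff(survival::Surv(out$time, out$event) ~ g)$chisq
  }, numeric(1))
  expect_gte(res$statistic, max(stats) - 1e-9)
  expect_error(optimal_cutoff(rep(1, n), out), "constant")
})

test_that("group labels are invariant to joint monotone transforms", {
  set.seed(6)
  scores <- rnorm(40)
  out <- data.frame(time = rexp(40, 0.05), event = rbinom(40, 1, 0.7))
  cut <- optimal_cutoff(scores, out)
  s1 <- km_logrank(scores, cut$cutoff, out)
  s2 <- km_logrank(exp(scores), exp(cut$cutoff), out)
  expect_identical(s1$group, s2$group)
  expect_equal(s1$logrank_p, s2$logrank_p)
})

test_that("identical survival in both groups gives HR 1 and p 1", {
  base <- data.frame(time = c(5, 10, 15, 20, 25, 30), event = c(1, 1, 0, 1, 0, 1))
  out <- rbind(base, base)
  scores <- rep(c(0, 1), each = 6)
  s <- km_logrank(scores, 0.5, out)
  expect_equal(s$hr, 1, tolerance = 1e-6)
  expect_equal(s$logrank_p, 1, tolerance = 1e-6)
})

test_that("a planted hazard ratio of 8 is detected and estimated to 2x", {
  ph <- planted_hr_outcomes(100, hr = 8, seed = 14)
  s <- km_logrank(ph$scores, 0.5, ph$outcomes)
  expect_lt(s$logrank_p, 0.01)
  expect_gt(s$hr, 4)
  expect_lt(s$hr, 16)
  # KM estimator properties
  km <- s$km
  expect_true(all(diff(km$surv[seq_len(km$strata[1])]) <= 0))
  expect_lte(max(km$surv), 1)
})

test_that("validation refits coefficients and demands the signature columns", {
  set.seed(30)
  n <- 80
  x <- data.frame(INNER_Min_Hist = rnorm(n), Under80HURatio = runif(n))
  t_ev <- rexp(n, 0.03 * exp(0.8 * x$Under80HURatio))
  out <- data.frame(time = t_ev, event = 1L)
  disc <- fit_rrs_model(x, out)
  val <- validate_rrs(x, out, names(x))
  expect_equal(coef(val$model), coef(disc))
  expect_error(validate_rrs(x["INNER_Min_Hist"], out, names(x)),
               "Under80HURatio")
})

test_that("stratification is significant across seeds on planted-effect cohorts", {
  hits <- 0L
  for (seed in 1:5) {
    ph <- planted_hr_outcomes(75, hr = 6, seed = seed)
    cut <- optimal_cutoff(ph$scores, ph$outcomes)
    s <- km_logrank(ph$scores, cut$cutoff, ph$outcomes)
    hits <- hits + (s$logrank_p < 0.05)
  }
  expect_gte(hits, 4L)
})
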