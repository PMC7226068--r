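#' Fit the radiomics risk-score (RRS) Cox model
#'
#' Multivariate Cox proportional-hazards fit of time-to-metastasis on the
#' signature features (partial likelihood, Efron tie handling). The linear
#' predictor of the fitted model is the radiomics risk score
#' \eqn{RRS_i = \sum_f \beta_f x_{if}} (no baseline term).
#'
#' @param features data.frame of patients x signature features, rows aligned
#'   with `outcomes`.
#' @param outcomes data.frame with columns `time` (months > 0) and `event`
#'   (0/1); at least one event.
#' @return An object of class `rrs_model` with the fitted `coefficients`,
#'   the feature names and the underlying `survival::coxph` fit.
#' @seealso [compute_rrs()], [optimal_cutoff()], [km_logrank()]
#' @export
fit_rrs_model <- function(features, outcomes) {
  features <- as.data.frame(features)
  stopifnot(all(c("time", "event") %in% names(outcomes)),
            nrow(features) == nrow(outcomes))
  if (any(outcomes$time <= 0)) {
    stop("survival times must be positive", call. = FALSE)
  }
  if (sum(outcomes$event) < 1) {
    stop("Cox fit needs at least one event", call. = FALSE)
  }
  dat <- cbind(features, .time = outcomes$time, .event = outcomes$event)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(features)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  beta <- stats::coef(fit)
  names(beta) <- names(features)
  if (any(!is.finite(beta))) {
    stop("Cox fit did not converge to finite coefficients", call. = FALSE)
  }
  structure(
    list(coefficients = beta, signature = names(features), fit = fit),
    class = "rrs_model"
  )
}

#' @export
print.rrs_model <- function(x, ...) {
  cat("Radiomics risk score (Cox proportional hazards)\n")
  cat("RRS =", paste(sprintf("%+.4f*%s", x$coefficients, x$signature),
                     collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.rrs_model <- function(object, ...) object$coefficients

#' @export
summary.rrs_model <- function(object, ...) summary(object$fit, ...)

#' @export
predict.rrs_model <- function(object, newdata, ...) {
  compute_rrs(object, newdata)
}

#' Compute the radiomics risk score
#'
#' `RRS = sum(coefficients * features)`: the Cox linear predictor without
#' any baseline or centering term, so it is exactly linear in the features.
#'
#' @param model an `rrs_model`, or a named coefficient vector.
#' @param features named numeric vector, or a data.frame of patients x
#'   features containing all signature columns.
#' @return Numeric RRS, one value per patient.
#' @export
compute_rrs <- function(model, features) {
  beta <- if (inherits(model, "rrs_model")) model$coefficients else model
  stopifnot(!is.null(names(beta)))
  if (is.null(dim(features))) {
    features <- as.data.frame(as.list(features), check.names = FALSE)
  }
  features <- as.data.frame(features)
  missing <- setdiff(names(beta), names(features))
  if (length(missing)) {
    stop("missing signature feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  drop(as.matrix(features[names(beta)]) %*% beta)
}

#' Optimal risk-score cutoff by log-rank grid search
#'
#' Scans every unique score value inside the percentile `search_band` as a
#' candidate high/low split and returns the cutoff maximizing the log-rank
#' chi-squared statistic, requiring at least 3 patients on each side. Ties in
#' the statistic are broken toward the median score. The band keeps the
#' search away from degenerate tiny groups.
#'
#' @param scores numeric RRS per patient.
#' @param outcomes data.frame with `time` and `event`.
#' @param search_band percentile pair, default `c(15, 85)`.
#' @return List with `cutoff` (a group boundary: high risk is
#'   `score > cutoff`), `percentile` (proportion of patients at or below the
#'   cutoff) and `statistic`.
#' @export
optimal_cutoff <- function(scores, outcomes, search_band = c(15, 85)) {
  stopifnot(length(scores) == nrow(outcomes))
  if (length(unique(scores)) < 2L) {
    stop("scores are constant; no cutoff exists", call. = FALSE)
  }
  lim <- stats::quantile(scores, search_band / 100)
  cand <- sort(unique(scores[scores >= lim[1] & scores <= lim[2]]))
  n <- length(scores)
  keep <- vapply(cand, function(cc) {
    nh <- sum(scores > cc)
    nh >= 3L && (n - nh) >= 3L
  }, logical(1))
  cand <- cand[keep]
  if (!length(cand)) {
    stop("no candidate cutoff leaves at least 3 patients per group", call. = FALSE)
  }
  stat <- vapply(cand, function(cc) {
    g <- scores > cc
    survival::survdiff(survival::Surv(outcomes$time, outcomes$event) ~ g)$chisq
  }, numeric(1))
  best <- stat == max(stat)
  med <- stats::median(scores)
  pick <- which(best)[which.min(abs(cand[best] - med))]
  list(cutoff = cand[pick],
       percentile = mean(scores <= cand[pick]),
       statistic = stat[pick])
}

#' Kaplan-Meier stratification of high- and low-risk groups
#'
#' Splits patients at the cutoff (`high = score > cutoff`), estimates
#' Kaplan-Meier curves per group, tests the difference by the log-rank test,
#' and reports the hazard ratio (with 95% CI) of a single-covariate Cox fit
#' on the binary group indicator. P-values of a cutoff chosen by grid search
#' are optimistic; see `permutation_p` in the returned object's help for the
#' adjusted option.
#'
#' @param scores numeric RRS per patient.
#' @param cutoff group boundary.
#' @param outcomes data.frame with `time` and `event`.
#' @param n_permutations if > 0, additionally computes a permutation-adjusted
#'   p-value re-running the full cutoff search on score-permuted data.
#' @param search_band band forwarded to the permutation re-search.
#' @return `risk_stratification`: list with per-patient `group`, `hr`,
#'   `hr_ci`, `logrank_p`, optional `permutation_p`, and the `survfit`
#'   curves.
#' @export
km_logrank <- function(scores, cutoff, outcomes, n_permutations = 0L,
                       search_band = c(15, 85)) {
  stopifnot(length(scores) == nrow(outcomes))
  group <- factor(ifelse(scores > cutoff, "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) == 0L)) {
    stop("cutoff leaves one group empty", call. = FALSE)
  }
  srv <- survival::Surv(outcomes$time, outcomes$event)
  sd_ <- survival::survdiff(srv ~ group)
  logrank_p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  cox <- survival::coxph(srv ~ group)
  hr <- unname(exp(stats::coef(cox)))
  ci <- exp(stats::confint(cox))

  perm_p <- NA_real_
  if (n_permutations > 0L) {
    obs <- sd_$chisq
    exceed <- 0L
    for (i in seq_len(n_permutations)) {
      sc <- sample(scores)
      co <- tryCatch(optimal_cutoff(sc, outcomes, search_band),
                     error = function(e) NULL)
      if (is.null(co)) next
      if (co$statistic >= obs) exceed <- exceed + 1L
    }
    perm_p <- (exceed + 1) / (n_permutations + 1)
  }

  structure(
    list(group = group, scores = scores, cutoff = cutoff,
         hr = hr, hr_ci = ci, logrank_p = logrank_p,
         permutation_p = perm_p,
         km = survival::survfit(srv ~ group),
         outcomes = outcomes),
    class = "risk_stratification"
  )
}

#' @export
print.risk_stratification <- function(x, ...) {
  cat(sprintf("Risk stratification at cutoff %.4f: %d low / %d high\n",
              x$cutoff, sum(x$group == "low"), sum(x$group == "high")))
  cat(sprintf("  HR = %.4f (95%% CI %.4f-%.4f), log-rank p = %.4g\n",
              x$hr, x$hr_ci[1], x$hr_ci[2], x$logrank_p))
  if (!is.na(x$permutation_p)) {
    cat(sprintf("  permutation-adjusted p = %.4g\n", x$permutation_p))
  }
  invisible(x)
}

#' @export
plot.risk_stratification <- function(x, ...) {
  graphics::plot(x$km, col = c("#2166AC", "#B2182B"), lwd = 2,
                 xlab = "months", ylab = "metastasis-free survival", ...)
  graphics::legend("bottomleft", legend = levels(x$group), lwd = 2,
                   col = c("#2166AC", "#B2182B"), bty = "n")
  invisible(x)
}

#' Validate the signature on an independent cohort
#'
#' Keeps the signature feature names but refits the Cox coefficients and the
#' optimal cutoff on the validation cohort, then stratifies it — the
#' protocol used for external validation of the risk score.
#'
#' @param features_val validation feature table (must contain the signature
#'   columns).
#' @param outcomes_val validation outcome table (`time`, `event`; needs
#'   events).
#' @param signature character vector of signature feature names.
#' @param search_band cutoff search band.
#' @return List with the refitted `model`, the `cutoff` search result and
#'   the `stratification`.
#' @export
validate_rrs <- function(features_val, outcomes_val, signature,
                         search_band = c(15, 85)) {
  features_val <- as.data.frame(features_val)
  missing <- setdiff(signature, names(features_val))
  if (length(missing)) {
    stop("validation table lacks signature feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  model <- fit_rrs_model(features_val[signature], outcomes_val)
  scores <- compute_rrs(model, features_val)
  cut <- optimal_cutoff(scores, outcomes_val, search_band)
  strat <- km_logrank(scores, cut$cutoff, outcomes_val)
  list(model = model, cutoff = cut, stratification = strat)
}
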