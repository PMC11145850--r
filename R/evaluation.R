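## Classification evaluation and threshold calibration: ROC/AUC with DeLong
## confidence intervals, the Youden-J optimal cutoff, Cohen's kappa with the
## conventional interpretation bands, and the agreement statistics
## (percent agreement, sensitivity, specificity) used to compare risk calls
## against pathologist grades.

#' Build a 2x2 confusion table
#'
#' Rows are the truth (`low` = NHG1-like, `high` = NHG3-like), columns the
#' call.
#'
#' @param truth,call vectors coercible to `"low"`/`"high"` factors.
#' @return 2x2 integer matrix of class `confusion_table`.
#' @export
confusion_table <- function(truth, call) {
  lv <- c("low", "high")
  tt <- table(factor(truth, levels = lv), factor(call, levels = lv))
  m <- matrix(as.integer(tt), 2, 2, dimnames = list(truth = lv, call = lv))
  structure(m, class = c("confusion_table", "matrix"))
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' The AUC equals the normalised Mann-Whitney U statistic (ties counted
#' one-half): the probability that a random positive outscores a random
#' negative. The 95% CI uses DeLong's method (the pROC default);
#' `ci_method = "bootstrap"` switches to 2000 stratified resamples.
#'
#' @param scores numeric predictor.
#' @param labels binary labels (0/1, logical, or `"low"`/`"high"`).
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param seed RNG seed for the bootstrap.
#' @return object of class `roc_result`: list with `thresholds`,
#'   `sensitivities`, `specificities`, `auc`, `auc_ci95`.
#' @export
roc_auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                    seed = 1) {
  ci_method <- match.arg(ci_method)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2)
    stop("both classes must be present to compute a ROC curve")
  r <- pROC::roc(response = y, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  ci <- if (ci_method == "delong") {
    ## pROC warns that the DeLong CI of a degenerate AUC of 1 is 1-1
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  } else {
    with_seed(derive_seed(seed, "auc_boot"),
              as.numeric(pROC::ci.auc(r, method = "bootstrap",
                                      boot.n = 2000, progress = "none")))
  }
  structure(list(thresholds = r$thresholds,
                 sensitivities = r$sensitivities,
                 specificities = r$specificities,
                 auc = as.numeric(pROC::auc(r)),
                 auc_ci95 = ci[c(1, 3)]),
            class = "roc_result")
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    l <- as.character(labels)
    stopifnot(all(l %in% c("low", "high")))
    as.integer(l == "high")
  } else as.integer(labels)
}

#' Youden-J optimal threshold
#'
#' Evaluates `J = sensitivity + specificity - 1` (with calls made as
#' `score >= cutoff`) at every midpoint between consecutive sorted unique
#' scores plus `-Inf`/`+Inf` sentinels, and returns the lowest cutoff
#' attaining the maximum.
#'
#' @param scores numeric predictor.
#' @param labels binary labels.
#' @return scalar threshold.
#' @export
youden_threshold <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2)
    stop("both classes must be present to calibrate a threshold")
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, Inf)
  J <- vapply(cand, function(t) {
    mean(scores[y == 1] >= t) + mean(scores[y == 0] < t) - 1
  }, numeric(1))
  cand[which.max(J)]   # which.max takes the first, i.e. lowest, maximiser
}

#' Cohen's kappa with interpretation band
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed and `p_e` the
#' chance agreement from the marginals; the 95% CI uses the asymptotic
#' standard error `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`. Bands follow the
#' conventional cut points (slight / fair / moderate / substantial / almost
#' perfect at 0.21, 0.41, 0.61, 0.81), boundaries assigned upward, so
#' kappa = 0.81 is "almost perfect".
#'
#' @param table square k x k contingency matrix (e.g. a
#'   [confusion_table()]), raters in rows/columns.
#' @return object of class `kappa_result`: list with `kappa`, `ci95`,
#'   `band`, `p_o`, `p_e`, `n`.
#' @export
cohens_kappa <- function(table) {
  m <- unclass(as.matrix(table))
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  n <- sum(m)
  if (n <= 0) stop("empty table")
  p_o <- sum(diag(m)) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  if (1 - p_e < 1e-12)
    stop("degenerate marginals: chance agreement is 1, kappa undefined")
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  structure(list(kappa = kappa,
                 ci95 = kappa + c(-1, 1) * qnorm(0.975) * se,
                 band = kappa_band(kappa),
                 p_o = p_o, p_e = p_e, n = n),
            class = "kappa_result")
}

#' @rdname cohens_kappa
#' @param kappa numeric kappa value.
#' @export
kappa_band <- function(kappa) {
  stopifnot(is.numeric(kappa), kappa >= -1, kappa <= 1)
  if (kappa < 0.21) "slight"
  else if (kappa < 0.41) "fair"
  else if (kappa < 0.61) "moderate"
  else if (kappa < 0.81) "substantial"
  else "almost perfect"
}

#' Agreement statistics from a confusion table
#'
#' Percent agreement is the diagonal share of the total, reported to one
#' decimal with half-up rounding as conventionally printed. Sensitivity is
#' the probability of a high call among truly high (NHG3) patients,
#' specificity the probability of a low call among truly low (NHG1)
#' patients. A zero denominator yields `NA` for that statistic.
#'
#' @param table a [confusion_table()] (truth in rows: low, high).
#' @return list with `percent_agreement`, `sensitivity`, `specificity`.
#' @export
agreement_stats <- function(table) {
  m <- unclass(as.matrix(table))
  stopifnot(all(dim(m) == c(2, 2)))
  tot <- sum(m)
  pa <- if (tot > 0) round_half_up(100 * sum(diag(m)) / tot, 1) else NA_real_
  sens <- if (sum(m[2, ]) > 0) m[2, 2] / sum(m[2, ]) else NA_real_
  spec <- if (sum(m[1, ]) > 0) m[1, 1] / sum(m[1, ]) else NA_real_
  list(percent_agreement = pa, sensitivity = sens, specificity = spec)
}

#' Full evaluation report
#'
#' @param scores patient scores.
#' @param labels binary reference labels.
#' @param calls optional risk-group calls (`"low"`/`"high"`); computed from
#'   the Youden threshold when omitted.
#' @return list: `roc`, `threshold`, `confusion`, `kappa`, `agreement`.
#' @export
evaluate_classification <- function(scores, labels, calls = NULL) {
  roc <- roc_auc(scores, labels)
  thr <- youden_threshold(scores, labels)
  if (is.null(calls)) calls <- ifelse(scores >= thr, "high", "low")
  truth <- ifelse(as_binary_labels(labels) == 1, "high", "low")
  ct <- confusion_table(truth, calls)
  list(roc = roc, threshold = thr, confusion = ct,
       kappa = cohens_kappa(ct), agreement = agreement_stats(ct))
}
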