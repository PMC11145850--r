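## Patient-level aggregation: all QC-passing tile scores from all of a
## patient's slides are pooled and summarised by an upper percentile - the
## 99th for biopsies (tiny tissue, dense overlap) and the 75th for
## resections (tumour-restricted tiles) - then binarised against a
## calibrated threshold into DeepGrade-low / DeepGrade-high.

#' Aggregation configuration
#'
#' @param mode `"biopsy"` or `"resection"`; sets the default percentile (99
#'   and 75 respectively).
#' @param percentile upper percentile of pooled tile scores in (0, 100].
#' @param threshold decision cutoff in `[0, 1]`; `NA` until calibrated.
#' @param interpolation percentile estimator: `"linear"` (default,
#'   interpolates between order statistics) or `"nearest_rank"`.
#' @return an object of class `aggregation_config`.
#' @export
aggregation_config <- function(mode = c("biopsy", "resection"),
                               percentile = NULL, threshold = NA_real_,
                               interpolation = c("linear", "nearest_rank")) {
  mode <- match.arg(mode)
  interpolation <- match.arg(interpolation)
  percentile <- percentile %||% switch(mode, biopsy = 99, resection = 75)
  if (!is.numeric(percentile) || percentile <= 0 || percentile > 100)
    stop_config("percentile", "must be in (0, 100]")
  if (!is.na(threshold) && !is_prob(threshold))
    stop_config("threshold", "must be in [0, 1]")
  structure(list(mode = mode, percentile = percentile, threshold = threshold,
                 interpolation = interpolation),
            class = "aggregation_config")
}

#' Aggregate a patient's tile scores into one score
#'
#' The configured percentile of the pooled `p_high` values across every tile
#' of every slide of the patient. With linear interpolation the estimator is
#' the standard order-statistic interpolation (quantile type 7); the
#' aggregate is invariant to how tiles are partitioned into slides and
#' monotone in every tile score.
#'
#' @param p_high numeric vector of pooled tile probabilities in `[0, 1]`.
#' @param config an [aggregation_config()].
#' @return scalar score in `[0, 1]`.
#' @export
aggregate_patient_score <- function(p_high, config = aggregation_config()) {
  if (length(p_high) == 0)
    stop("patient has no QC-passing tiles")
  stopifnot(all(p_high >= 0 & p_high <= 1))
  p <- config$percentile / 100
  if (config$interpolation == "linear") {
    unname(quantile(p_high, p, type = 7))
  } else {
    s <- sort(p_high)
    s[max(1L, ceiling(p * length(s)))]
  }
}

#' Binarise a patient score into a risk group
#'
#' DeepGrade-high iff `score >= threshold` (scores exactly at the threshold
#' are called high).
#'
#' @param score aggregated patient score.
#' @param config an [aggregation_config()] carrying the calibrated
#'   threshold, or a bare numeric threshold.
#' @param patient_id,n_tiles metadata stored on the call.
#' @return an object of class `risk_call`: list with `patient_id`,
#'   `n_tiles`, `score`, `risk_group` (`"low"`/`"high"`), `threshold_used`.
#' @export
assign_risk <- function(score, config, patient_id = NA_character_,
                        n_tiles = NA_integer_) {
  thr <- if (is.numeric(config)) config else config$threshold
  if (is.null(thr) || is.na(thr))
    stop("decision threshold is unset; calibrate with youden_threshold() first")
  stopifnot(is.numeric(score), length(score) == 1)
  structure(list(patient_id = patient_id, n_tiles = n_tiles, score = score,
                 risk_group = if (score >= thr) "high" else "low",
                 threshold_used = thr),
            class = "risk_call")
}

#' Risk calls for a table of patient scores
#'
#' @param scores data.frame with columns `patient_id`, `score`, `n_tiles`.
#' @param config an [aggregation_config()] with a calibrated threshold.
#' @return data.frame: patient_id, mode, n_tiles, score, threshold,
#'   risk_group.
#' @export
call_patients <- function(scores, config) {
  calls <- lapply(seq_len(nrow(scores)), function(i)
    assign_risk(scores$score[i], config, scores$patient_id[i],
                scores$n_tiles[i]))
  data.frame(patient_id = scores$patient_id,
             mode = config$mode,
             n_tiles = scores$n_tiles,
             score = scores$score,
             threshold = config$threshold,
             risk_group = vapply(calls, `[[`, character(1), "risk_group"),
             stringsAsFactors = FALSE)
}
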