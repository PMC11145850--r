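## Recurrence-free survival of the DeepGrade risk groups: Kaplan-Meier
## product-limit curves per group and a multivariable Cox proportional-
## hazards model (Efron tie handling) with age in years as the second
## covariate, plus the ER+/HER2- subgroup restriction.

#' Validate survival records
#'
#' @param records data.frame with columns `rfs_days` (>= 0), `event`
#'   (0/1), `risk_group` (`"low"`/`"high"`), and optionally `age`,
#'   `er_status`, `her2_status`, `patient_id`.
#' @return the records, invisibly, or an error.
#' @export
validate_survival_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("rfs_days", "event", "risk_group") %in% names(records)))
  if (any(records$rfs_days < 0, na.rm = TRUE))
    stop("rfs_days must be non-negative")
  if (!all(records$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (recurrence or death)")
  if (!all(records$risk_group %in% c("low", "high")))
    stop("risk_group must be 'low' or 'high'")
  invisible(records)
}

#' Kaplan-Meier estimate per risk group
#'
#' Product-limit estimator of recurrence-free survival, one curve per risk
#' group; each curve starts at 1 and is non-increasing. Empty groups are
#' omitted with a warning.
#'
#' @param records see [validate_survival_records()].
#' @return list with `fit` (a `survfit` object) and `curves`, a data.frame
#'   of step coordinates: risk_group, time, surv, n_risk, n_event.
#' @export
km_estimate <- function(records) {
  validate_survival_records(records)
  present <- intersect(c("low", "high"), unique(records$risk_group))
  if (length(present) < 2)
    warning("empty risk group omitted: only '", present, "' present")
  records$risk_group <- factor(records$risk_group, levels = present)
  fit <- survival::survfit(
    survival::Surv(rfs_days, event) ~ risk_group, data = records)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(present, length(s$time))
         else sub("^risk_group=", "", as.character(s$strata))
  list(fit = fit,
       curves = data.frame(risk_group = grp, time = s$time, surv = s$surv,
                           n_risk = s$n.risk, n_event = s$n.event,
                           stringsAsFactors = FALSE))
}

#' Multivariable Cox model: risk group adjusted for age
#'
#' Partial-likelihood maximisation with Efron tie handling. Records with
#' missing age are dropped and counted. The hazard ratio, Wald 95% CI and
#' p-value are reported for DeepGrade-high versus -low, together with the
#' per-year age hazard ratio.
#'
#' @param records see [validate_survival_records()]; must include `age`
#'   unless `adjust_age = FALSE`.
#' @param adjust_age include age (years, continuous) as a covariate
#'   (default `TRUE`).
#' @return object of class `cox_fit`: list with `hr_risk_group`, `ci95`,
#'   `p_value`, `hr_age`, `n_used`, `n_events`, `n_missing_age`, `model`.
#' @export
cox_fit <- function(records, adjust_age = TRUE) {
  validate_survival_records(records)
  n_missing_age <- 0L
  if (adjust_age) {
    stopifnot("age" %in% names(records))
    n_missing_age <- sum(is.na(records$age))
    records <- records[!is.na(records$age), , drop = FALSE]
  }
  if (sum(records$event) < 2)
    stop("fewer than two events: Cox model cannot be fitted")
  if (length(unique(records$risk_group)) < 2)
    stop("risk_group is constant: hazard ratio undefined")
  records$risk_group <- factor(records$risk_group, levels = c("low", "high"))
  fml <- if (adjust_age)
    survival::Surv(rfs_days, event) ~ risk_group + age
  else survival::Surv(rfs_days, event) ~ risk_group
  fit <- survival::coxph(fml, data = records, ties = "efron")
  if (!is.null(fit$info) && !is.null(fit$info$convergence) &&
      fit$info$convergence != 0)
    stop("Cox model failed to converge")
  sm <- summary(fit)
  co <- sm$coefficients["risk_grouphigh", ]
  ci <- sm$conf.int["risk_grouphigh", c("lower .95", "upper .95")]
  structure(list(hr_risk_group = unname(co["exp(coef)"]),
                 ci95 = unname(ci),
                 p_value = unname(co["Pr(>|z|)"]),
                 hr_age = if (adjust_age)
                   unname(sm$coefficients["age", "exp(coef)"]) else NA_real_,
                 n_used = sm$n, n_events = sm$nevent,
                 n_missing_age = n_missing_age, model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH (Efron): HR high vs low = %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              x$hr_risk_group, x$ci95[1], x$ci95[2], x$p_value))
  cat(sprintf("  n = %d, events = %d, missing age dropped = %d\n",
              x$n_used, x$n_events, x$n_missing_age))
  invisible(x)
}

#' Restrict records to the ER-positive / HER2-negative subgroup
#'
#' Keeps exactly the records with `er_status == "pos"` and
#' `her2_status == "neg"`; missing status is excluded. Idempotent.
#'
#' @param records data.frame with `er_status` and `her2_status`.
#' @param er,her2 required statuses (defaults `"pos"`, `"neg"`).
#' @return the filtered records.
#' @export
subgroup_filter <- function(records, er = "pos", her2 = "neg") {
  stopifnot(all(c("er_status", "her2_status") %in% names(records)))
  keep <- !is.na(records$er_status) & records$er_status == er &
          !is.na(records$her2_status) & records$her2_status == her2
  records[keep, , drop = FALSE]
}

#' Export a Cox fit as forest-plot rows
#'
#' @param fit a `cox_fit`.
#' @return data.frame: term, hr, ci_low, ci_high, p, n, n_events.
#' @export
cox_forest_rows <- function(fit) {
  sm <- summary(fit$model)
  data.frame(term = rownames(sm$coefficients),
             hr = unname(sm$coefficients[, "exp(coef)"]),
             ci_low = unname(sm$conf.int[, "lower .95"]),
             ci_high = unname(sm$conf.int[, "upper .95"]),
             p = unname(sm$coefficients[, "Pr(>|z|)"]),
             n = sm$n, n_events = sm$nevent,
             stringsAsFactors = FALSE)
}
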