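#' Coverage-aware confusion-matrix metrics
#'
#' Summarizes pooled conformal classification predictions against the true
#' outcome. Inconclusive predictions (empty or two-class prediction sets) are
#' excluded from sensitivity, specificity and MCC and enter only the coverage
#' (fraction conclusive). The positive class is death
#' (\code{"non-survivor"}).
#'
#' @param preds Data.frame from \code{\link{predict_set}} /
#'   \code{\link{cross_validate}} with columns \code{set} and
#'   \code{conclusive}.
#' @param truth Character/factor vector of true labels
#'   (\code{"survivor"} / \code{"non-survivor"}), aligned with \code{preds}.
#' @param positive Positive-class label, default \code{"non-survivor"}.
#' @return An object of class \code{performance_summary}: \code{se},
#'   \code{sp}, \code{mcc}, \code{coverage}, the raw counts, and the
#'   conclusive-set prevalence.
#' @export
confusion_metrics <- function(preds, truth, positive = "non-survivor") {
  truth <- as.character(truth)
  stopifnot(nrow(preds) == length(truth))
  conclusive <- preds$conclusive
  coverage <- mean(conclusive)
  if (!any(conclusive)) {
    warning("no conclusive predictions; Se/Sp/MCC undefined")
    out <- list(se = NA_real_, sp = NA_real_, mcc = NA_real_,
                coverage = coverage, tp = 0L, fn = 0L, tn = 0L, fp = 0L,
                prevalence_conclusive = NA_real_, positive = positive)
    class(out) <- "performance_summary"
    return(out)
  }
  pred_cl <- preds$set[conclusive]
  true_cl <- truth[conclusive]
  tp <- sum(pred_cl == positive & true_cl == positive)
  fn <- sum(pred_cl != positive & true_cl == positive)
  tn <- sum(pred_cl != positive & true_cl != positive)
  fp <- sum(pred_cl == positive & true_cl != positive)
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  out <- list(se = se, sp = sp, mcc = mcc, coverage = coverage,
              tp = tp, fn = fn, tn = tn, fp = fp,
              prevalence_conclusive = (tp + fn) / (tp + fn + tn + fp),
              positive = positive)
  class(out) <- "performance_summary"
  out
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("performance_summary (positive = %s)\n", x$positive))
  cat(sprintf("  Se %.2f  Sp %.2f  MCC %.2f  Cov %.2f  (TP %d FN %d TN %d FP %d)\n",
              x$se, x$sp, x$mcc, x$coverage, x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Re-express predictive values at an arbitrary prevalence
#'
#' Bayes identities convert sensitivity and specificity into positive and
#' negative predictive value and overall detection accuracy at a chosen
#' event prevalence, allowing metrics estimated in one cohort to be restated
#' at an external mortality rate:
#' \deqn{PPV = \frac{Se\,\pi}{Se\,\pi + (1-Sp)(1-\pi)}, \quad
#'       NPV = \frac{Sp\,(1-\pi)}{Sp\,(1-\pi) + (1-Se)\,\pi}, \quad
#'       Acc = Se\,\pi + Sp\,(1-\pi).}
#'
#' @param se,sp Sensitivity and specificity in [0, 1].
#' @param prevalence Event prevalence pi in [0, 1].
#' @return A list with \code{ppv}, \code{npv}, \code{acc}; a 0/0 predictive
#'   value is returned as \code{NaN} with a warning.
#' @examples
#' adjust_prevalence(0.78, 1.00, 0.47)
#' @export
adjust_prevalence <- function(se, sp, prevalence) {
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1)
  if (prevalence < 0 || prevalence > 1)
    stop("prevalence must lie in [0, 1]")
  pi <- prevalence
  ppv_d <- se * pi + (1 - sp) * (1 - pi)
  npv_d <- sp * (1 - pi) + (1 - se) * pi
  if (ppv_d == 0 || npv_d == 0)
    warning("degenerate predictive value (0/0)")
  list(
    ppv = if (ppv_d > 0) se * pi / ppv_d else NaN,
    npv = if (npv_d > 0) sp * (1 - pi) / npv_d else NaN,
    acc = se * pi + sp * (1 - pi)
  )
}

#' Fit and cross-validated regression metrics
#'
#' R-squared from fitted values, Q-squared from out-of-fold predictions
#' (1 - PRESS/TSS), and conformal accuracy as the fraction of prediction
#' intervals containing the truth.
#'
#' @param y True outcome.
#' @param yhat_fit Fitted (resubstitution) predictions; \code{NULL} to skip
#'   R-squared.
#' @param yhat_oof Out-of-fold predictions; \code{NULL} to skip Q-squared.
#' @param intervals Data.frame with \code{lo}, \code{hi}; \code{NULL} to
#'   skip conformal accuracy.
#' @return A list with \code{r2}, \code{q2}, \code{conformal_accuracy}
#'   (\code{NA} where skipped).
#' @export
regression_metrics <- function(y, yhat_fit = NULL, yhat_oof = NULL,
                               intervals = NULL) {
  y <- as.numeric(y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    warning("constant outcome; R2/Q2 undefined")
    return(list(r2 = NA_real_, q2 = NA_real_,
                conformal_accuracy = if (is.null(intervals)) NA_real_
                else mean(intervals$lo <= y & y <= intervals$hi)))
  }
  r2 <- if (is.null(yhat_fit)) NA_real_
        else 1 - sum((y - yhat_fit)^2) / tss
  q2 <- if (is.null(yhat_oof)) NA_real_
        else 1 - sum((y - yhat_oof)^2) / tss
  ca <- if (is.null(intervals)) NA_real_
        else mean(intervals$lo <= y & y <= intervals$hi)
  list(r2 = r2, q2 = q2, conformal_accuracy = ca)
}

#' Descriptive cohort mortality rates
#'
#' Cumulative mortality at each follow-up year (integer percent of patients
#' with confirmed outcome) and 4-year mortality stratified by the
#' frequent-exacerbator flag. Patients with missing days of survival are
#' excluded with a warning.
#'
#' @param metadata Data.frame with \code{status}, \code{days_survival} and
#'   \code{frequent_exacerbator}.
#' @param followup_days Follow-up horizon, default 1460.
#' @return A list: \code{yearly_mortality_pct} (named integer vector,
#'   years 1..4), \code{fe_mortality_pct}, \code{nonfe_mortality_pct},
#'   \code{n}.
#' @export
cohort_rates <- function(metadata, followup_days = 1460L) {
  md <- metadata
  miss <- is.na(md$days_survival)
  if (any(miss)) {
    warning(sprintf("%d patients without confirmed outcome excluded",
                    sum(miss)))
    md <- md[!miss, , drop = FALSE]
  }
  n <- nrow(md)
  dead <- md$status == "non-survivor"
  years <- seq_len(ceiling(followup_days / 365))
  yearly <- vapply(years, function(k)
    round(100 * sum(dead & md$days_survival <= 365 * k) / n), 0)
  names(yearly) <- paste0("year", years)
  fe <- md$frequent_exacerbator
  fe_rate <- if (any(fe)) round(100 * sum(dead & fe) / sum(fe)) else NA_real_
  nonfe_rate <- if (any(!fe)) round(100 * sum(dead & !fe) / sum(!fe))
                else NA_real_
  list(yearly_mortality_pct = yearly,
       fe_mortality_pct = fe_rate,
       nonfe_mortality_pct = nonfe_rate,
       n = n)
}

#' Tabulate a model's fitting and prediction metrics
#'
#' Combines conclusive-set metrics with prevalence-re-adjusted predictive
#' values at the reported literature mortality (47\%) and the cohort
#' mortality (32\%), mirroring the usual summary layout for categorical
#' models.
#'
#' @param summary A \code{performance_summary}.
#' @param prevalences Named numeric vector of prevalences, default
#'   \code{c(reported = 0.47, cohort = 0.32)}.
#' @return A one-row data.frame with Se/Sp/MCC/Cov and
#'   ppv/npv/acc at each prevalence.
#' @export
summarize_model <- function(summary,
                            prevalences = c(reported = 0.47, cohort = 0.32)) {
  stopifnot(inherits(summary, "performance_summary"))
  row <- data.frame(se = summary$se, sp = summary$sp, mcc = summary$mcc,
                    coverage = summary$coverage)
  for (nm in names(prevalences)) {
    adj <- adjust_prevalence(summary$se, summary$sp, prevalences[[nm]])
    row[[paste0("ppv_", nm)]] <- adj$ppv
    row[[paste0("npv_", nm)]] <- adj$npv
    row[[paste0("acc_", nm)]] <- adj$acc
  }
  row
}
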