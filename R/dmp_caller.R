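#' @title Candidate DMP selection and optimal-cutoff classification
#' @description A site is a candidate DMP when its divergence exceeds a high
#'   quantile (default the 95th percentile) of the divergence distribution
#'   fitted to its own sample and context. Candidates arise in control
#'   replicates too — those reflect background stochasticity — and the
#'   final classification cutoff is learned as the divergence threshold that
#'   best separates control candidates from treatment candidates, by
#'   maximizing a confusion-matrix criterion (Youden's J by default) over an
#'   exhaustive sweep of the observed values. Hypo- and hyper-methylation
#'   are treated equally throughout; direction is annotated, never filtered.
#' @name dmp_caller
NULL

#' Confusion-matrix performance metrics
#'
#' Standard binary-classification metrics for 0/1 labels and predictions:
#' accuracy, sensitivity (recall of class 1), specificity, false discovery
#' rate `FP / (FP + TP)` (0 when nothing is predicted positive), and
#' Youden's J = sensitivity + specificity - 1.
#'
#' @param labels,predictions equal-length 0/1 vectors.
#' @return Named list with `accuracy`, `sensitivity`, `specificity`, `fdr`,
#'   `youden`.
#' @export
performance_metrics <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  if (length(labels) == 0) stop("empty label vector")
  stopifnot(all(labels %in% 0:1), all(predictions %in% 0:1))
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  fn <- sum(labels == 1 & predictions == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = sens, specificity = spec,
       fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
       youden = sens + spec - 1)
}

#' Candidate DMPs above the fitted-distribution percentile
#'
#' @param records divergence table rows for one sample and context (see
#'   [divergence_table()]).
#' @param model the `divfit` model fitted to this sample x context's
#'   divergences.
#' @param prob percentile defining "signal" (default 0.95).
#' @param min_tv optional minimum total variation distance; unset by
#'   default.
#' @param value which divergence column the model describes
#'   (`"hdiv_w"`, the coverage-weighted default, or `"hdiv"`).
#' @return The subset of `records` with divergence strictly above
#'   `model_quantile(model, prob)` (and `tv >= min_tv` when set), with a
#'   `divergence` column holding the modeled values.
#' @export
potential_dmps <- function(records, model, prob = 0.95, min_tv = NULL,
                           value = c("hdiv_w", "hdiv")) {
  value <- match.arg(value)
  if (!is.numeric(prob) || length(prob) != 1 || prob <= 0 || prob >= 1)
    stop("prob must lie strictly in (0, 1)")
  records <- as.data.table(records)
  thr <- model_quantile(model, prob)
  out <- records[records[[value]] > thr]
  out[, divergence := out[[value]]]
  if (!is.null(min_tv)) out <- out[tv >= min_tv]
  out[]
}

#' Learn the optimal classification cutoff
#'
#' Sweeps every observed candidate divergence as a threshold for the rule
#' "divergence >= cutoff is treatment-associated" and returns the cutoff
#' maximizing the chosen criterion; ties are broken toward the smallest
#' cutoff. All five performance metrics at the chosen cutoff are reported.
#'
#' @param control_values candidate divergences from control replicates
#'   (label 0).
#' @param treatment_values candidate divergences from treatment replicates
#'   (label 1).
#' @param criterion `"youden"` (default) or `"accuracy"`.
#' @param context optional context tag carried into the result.
#' @param scorer optional function `(control_values, treatment_values) ->
#'   cutoff` replacing the sweep (hook for alternative learners).
#' @return A `cutoff_model` list: `context`, `cutoff`, `metric`, and the
#'   metrics of [performance_metrics()] at the cutoff.
#' @export
learn_cutoff <- function(control_values, treatment_values,
                         criterion = c("youden", "accuracy"),
                         context = NA_character_, scorer = NULL) {
  criterion <- match.arg(criterion)
  if (length(control_values) == 0 || length(treatment_values) == 0)
    stop("both candidate classes must be non-empty to learn a cutoff")
  if (is.null(scorer)) {
    cand <- sort(unique(c(control_values, treatment_values)))
    # P(x >= c) per class via sorted counts: vectorized sweep
    n0 <- length(control_values); n1 <- length(treatment_values)
    ge0 <- n0 - findInterval(cand, sort(control_values), left.open = TRUE)
    ge1 <- n1 - findInterval(cand, sort(treatment_values), left.open = TRUE)
    # integer-valued criterion: exact tie handling (youden ordering equals
    # ge1*n0 - ge0*n1 up to the positive factor n0*n1)
    crit <- if (criterion == "youden") ge1 * n0 - ge0 * n1
            else ge1 + (n0 - ge0)
    cutoff <- cand[which.max(crit)]   # which.max takes the first (smallest)
  } else {
    cutoff <- scorer(control_values, treatment_values)
  }
  pred <- as.integer(c(control_values, treatment_values) >= cutoff)
  labs <- c(rep(0L, length(control_values)), rep(1L, length(treatment_values)))
  met <- performance_metrics(labs, pred)
  structure(c(list(context = context, cutoff = cutoff, metric = criterion),
              met),
            class = "cutoff_model")
}

#' @export
print.cutoff_model <- function(x, ...) {
  cat(sprintf(
    "<cutoff_model %s> cutoff=%.4g (%s)  acc=%.3f sens=%.3f spec=%.3f fdr=%.3f youden=%.3f\n",
    ifelse(is.na(x$context), "-", x$context), x$cutoff, x$metric,
    x$accuracy, x$sensitivity, x$specificity, x$fdr, x$youden))
  invisible(x)
}

#' Call DMPs in a sample at the learned cutoff
#'
#' Retains candidate sites whose divergence is at or above the learned
#' cutoff and annotates direction: `hyper` when the sample level exceeds the
#' reference level, `hypo` otherwise. Both directions are retained equally.
#'
#' @param records candidate records for one treatment sample and context
#'   (output of [potential_dmps()], carrying a `divergence` column).
#' @param cutoff_model a [learn_cutoff()] result for the same context.
#' @return data.table of DMPs with a `direction` column.
#' @export
call_dmps <- function(records, cutoff_model) {
  stopifnot(inherits(cutoff_model, "cutoff_model"))
  records <- as.data.table(records)
  if (nrow(records) && !is.na(cutoff_model$context) &&
      !all(records$context == cutoff_model$context))
    stop("context mismatch: cutoff learned for ", cutoff_model$context)
  out <- records[divergence >= cutoff_model$cutoff]
  out[, direction := ifelse(p_smp > p_ref, "hyper", "hypo")]
  out[]
}
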