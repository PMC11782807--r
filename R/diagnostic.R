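#' Classify precapillary pulmonary hypertension (absence of LHD)
#'
#' Applies the hemodynamic decision rule exactly as printed: mPAP strictly
#' greater than 20 mmHg, PVR strictly greater than 2 Wood units, and PAWP
#' less than or equal to 15 mmHg.
#'
#' @param triples Data frame with numeric columns `mPAP`, `PAWP`, `PVR`
#'   (one row per examination), or a single named numeric vector.
#' @return Logical vector, `TRUE` where all three conditions hold.
#' @export
classify_precapillary <- function(triples) {
  if (is.numeric(triples) && !is.null(names(triples))) {
    triples <- as.data.frame(as.list(triples))
  }
  need <- c("mPAP", "PAWP", "PVR")
  if (!all(need %in% names(triples))) {
    abort("need complete triples: mPAP, PAWP, and PVR")
  }
  if (anyNA(triples[need])) abort("missing hemodynamic component")
  triples$mPAP > 20 & triples$PVR > 2 & triples$PAWP <= 15
}

#' Diagnostic confusion report for the precapillary-PH rule
#'
#' Applies [classify_precapillary()] to predicted and ground-truth triples
#' and tabulates the agreement. Sensitivity/specificity are `NA` when a
#' class is absent from the truth.
#'
#' @param pred,truth Aligned data frames of hemodynamic triples
#'   (columns `mPAP`, `PAWP`, `PVR`).
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `n`, `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
diagnostic_report <- function(pred, truth) {
  if (nrow(pred) != nrow(truth)) abort("pred and truth differ in length")
  p <- classify_precapillary(pred)
  t <- classify_precapillary(truth)
  confusion_report(p, t)
}

# Confusion statistics from aligned logical classifications.
confusion_report <- function(pred_pos, truth_pos) {
  tp <- sum(pred_pos & truth_pos); fp <- sum(pred_pos & !truth_pos)
  tn <- sum(!pred_pos & !truth_pos); fn <- sum(!pred_pos & truth_pos)
  n <- length(pred_pos)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn, n = n,
    accuracy = (tp + tn) / n,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}
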