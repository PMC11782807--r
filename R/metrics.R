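#' Mean absolute error
#' @param truth,pred Equal-length numeric vectors (n >= 1).
#' @return Mean of |pred - truth|, in target units.
#' @export
mae <- function(truth, pred) {
  check_pair(truth, pred, min_n = 1L)
  mean(abs(pred - truth))
}

#' Pearson correlation coefficient
#' @param truth,pred Equal-length numeric vectors (n >= 2), each with
#'   nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_corr <- function(truth, pred) {
  check_pair(truth, pred, min_n = 2L)
  if (sd(truth) == 0 || sd(pred) == 0) {
    abort("Pearson correlation undefined for zero-variance input")
  }
  cor(truth, pred)
}

#' Coefficient of determination
#'
#' `1 - SS_residual / SS_total`, with the total sum of squares taken about
#' the mean of the ground truth. Can be negative (a predictor worse than
#' the truth's mean); equals 1 for a perfect prediction and 0 for the
#' constant mean predictor.
#'
#' @param truth,pred Equal-length numeric vectors (n >= 2); `truth` must
#'   not be constant.
#' @return R-squared (<= 1, unbounded below).
#' @export
r_squared <- function(truth, pred) {
  check_pair(truth, pred, min_n = 2L)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) abort("R-squared undefined: ground truth is constant")
  1 - sum((truth - pred)^2) / ss_tot
}

check_pair <- function(truth, pred, min_n) {
  if (length(truth) != length(pred)) abort("truth and pred differ in length")
  if (length(truth) < min_n) abort(sprintf("need at least %d observations", min_n))
  if (anyNA(truth) || anyNA(pred)) abort("missing values in inputs")
  invisible(TRUE)
}

#' Regression performance report
#'
#' @param truth,pred Equal-length numeric vectors.
#' @return One-row tibble: `n`, `mae`, `pcc`, `r2`. PCC/R2 are `NA` when
#'   undefined (degenerate inputs) rather than an error.
#' @export
regression_report <- function(truth, pred) {
  tibble::tibble(
    n = length(truth),
    mae = mae(truth, pred),
    pcc = tryCatch(pearson_corr(truth, pred), error = function(e) NA_real_),
    r2 = tryCatch(r_squared(truth, pred), error = function(e) NA_real_)
  )
}

#' Bland-Altman agreement summary
#'
#' Bias is `mean(pred - truth)`; the 95% limits of agreement are
#' `bias +/- 1.96 * SD` with the sample (n-1) standard deviation of the
#' differences.
#'
#' @param truth,pred Equal-length numeric vectors (n >= 2).
#' @return One-row tibble: `bias`, `sd_diff`, `loa_lower`, `loa_upper`, `n`.
#' @export
bland_altman <- function(truth, pred) {
  check_pair(truth, pred, min_n = 2L)
  d <- pred - truth
  bias <- mean(d)
  s <- sd(d)
  tibble::tibble(bias = bias, sd_diff = s,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 n = length(d))
}
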