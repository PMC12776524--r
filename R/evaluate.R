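#' Recovery correlation between the learned index and the planted moderator
#'
#' Sample Pearson correlation; the headline recovery-accuracy metric of
#' the simulation study.
#'
#' @param z learned index values.
#' @param M planted moderator values.
#' @param absolute report `|rho|` (useful when the index orientation is
#'   not canonicalized); default FALSE.
#' @return a single correlation.
#' @export
recovery_correlation <- function(z, M, absolute = FALSE) {
  check_finite_vec(z, "z")
  check_finite_vec(M, "M")
  if (length(z) != length(M)) abort("`z` and `M` lengths differ")
  if (length(z) < 3L) abort("need at least 3 observations")
  if (sd(z) == 0 || sd(M) == 0) abort("correlation undefined for a constant vector")
  r <- cor(z, M)
  if (absolute) abs(r) else r
}

#' Root-mean-squared error
#'
#' For a `twin_fit`, the RMSE of its fitted values (or of predictions on
#' `newdata`); for plain numeric vectors, `sqrt(mean((obs - pred)^2))`.
#'
#' @param x a `twin_fit` or a numeric vector of predictions.
#' @param ... method arguments.
#' @return a single nonnegative number.
#' @export
rmse <- function(x, ...) UseMethod("rmse")

#' @rdname rmse
#' @param obs observed values.
#' @export
rmse.numeric <- function(x, obs, ...) {
  if (!length(obs)) abort("empty subset")
  if (length(x) != length(obs)) abort("lengths differ")
  sqrt(mean((obs - x)^2))
}

#' @rdname rmse
#' @param newdata optional data frame on which to predict; defaults to the
#'   fitting data.
#' @export
rmse.twin_fit <- function(x, newdata = NULL, ...) {
  if (is.null(newdata)) return(sqrt(mean(residuals(x$lm)^2)))
  if (!nrow(newdata)) abort("empty subset")
  pred <- predict(x$lm, newdata = newdata)
  rmse(pred, as.numeric(newdata[[".y"]]))
}

#' Precision-recall curve for vulnerable-group identification
#'
#' At each threshold quantile t, observations with index strictly above
#' `quantile(z, t)` are flagged; precision and recall are computed against
#' the ground-truth vulnerable mask.
#'
#' @param z learned index values.
#' @param truth_mask logical vector, the ground-truth vulnerable group
#'   (at least one positive).
#' @param thresholds quantiles of z to sweep (default 0.01-0.99).
#' @return a tibble with `threshold`, `cutoff`, `precision`, `recall`.
#' @export
precision_recall_curve <- function(z, truth_mask,
                                   thresholds = seq(0.01, 0.99, by = 0.01)) {
  check_finite_vec(z, "z")
  if (length(z) != length(truth_mask)) abort("`z` and `truth_mask` lengths differ")
  if (!any(truth_mask)) abort("`truth_mask` has no positives")
  purrr::map_dfr(thresholds, function(t) {
    cutoff <- unname(quantile(z, t, type = 7))
    flag <- z > cutoff
    tp <- sum(flag & truth_mask)
    tibble::tibble(
      threshold = t, cutoff = cutoff,
      precision = if (any(flag)) tp / sum(flag) else NA_real_,
      recall = tp / sum(truth_mask)
    )
  })
}

#' Recall of the ground-truth vulnerable group at a quantile threshold
#'
#' Fraction of the ground-truth vulnerable group (e.g. moderator above its
#' 0.84 quantile) captured by thresholding the learned index at the same
#' quantile. Ties are broken by strict exceedance.
#'
#' @inheritParams precision_recall_curve
#' @param q threshold quantile (default 0.84).
#' @return a proportion in [0, 1].
#' @export
recall_at_quantile <- function(z, truth_mask, q = 0.84) {
  pr <- precision_recall_curve(z, truth_mask, thresholds = q)
  pr$recall[1]
}

#' Recovery report for one fitted simulation cell
#'
#' Collects the Table-1-style metrics for a fitted ReGNN on simulated
#' data: end-of-training correlation with the planted moderator, twin-fit
#' RMSE and interaction p-value on the training and sensitivity sets, and
#' recall of the ground-truth vulnerable group at the quantile threshold.
#'
#' @param object a fitted `regnn`.
#' @param M the planted moderator (one value per row of the fitting data).
#' @param snr the SNR of the outcome used (recorded in the report).
#' @param quantile vulnerability threshold quantile (default 0.84).
#' @return a one-row tibble (fields `snr`, `rho`, `rmse_train`,
#'   `rmse_sensitivity`, `p_train`, `p_sensitivity`, `recall_at_q`).
#' @export
evaluate_recovery <- function(object, M, snr = NA_real_, quantile = 0.84) {
  stopifnot(inherits(object, "regnn"))
  tw_train <- fit_twin(object, subset = "train")
  tw_sens <- fit_twin(object, subset = "sensitivity")
  int_term <- tw_train$interaction_terms[1]
  p_of <- function(tw) tw$table$p.value[tw$table$term == int_term]
  truth <- vulnerable_mask(M, quantile)
  tibble::tibble(
    snr = snr,
    rho = recovery_correlation(object$z, M),
    rmse_train = rmse(tw_train),
    rmse_sensitivity = rmse(tw_sens),
    p_train = p_of(tw_train),
    p_sensitivity = p_of(tw_sens),
    recall_at_q = recall_at_quantile(object$z, truth$mask, quantile)
  )
}
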