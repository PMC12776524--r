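#' Sampling-permutation Shapley attributions
#'
#' Model-agnostic Shapley values of a scalar-valued function `f` relative
#' to a background sample: for each sampled feature ordering, features of
#' the explained row replace the background values one at a time and the
#' change in the background-averaged output is credited to the feature
#' just added. Averaging over orderings estimates the Shapley value; the
#' attributions of each row sum exactly to
#' `f(row) - mean(f(background))` (efficiency), and for a linear `f` the
#' estimator is exact for any number of orderings.
#'
#' @param f function mapping a numeric matrix (rows = observations) to a
#'   numeric vector.
#' @param X_eval matrix of rows to explain.
#' @param background matrix of background rows (the reference
#'   distribution).
#' @param n_perm number of sampled feature orderings per row (default 10).
#' @param seed optional integer seed.
#' @return a matrix (rows of `X_eval` by features) of attributions, with
#'   attributes `baseline` (mean background output) and `f_eval`.
#' @export
shap_values <- function(f, X_eval, background, n_perm = 10, seed = NULL) {
  X_eval <- as.matrix(X_eval)
  background <- as.matrix(background)
  q <- ncol(X_eval)
  if (ncol(background) != q) abort("`X_eval` and `background` widths differ")
  n_perm <- check_count(n_perm, "n_perm", lower = 1L)
  maybe_set_seed(seed)

  baseline <- mean(f(background))
  A <- matrix(0, nrow(X_eval), q, dimnames = list(NULL, colnames(X_eval)))
  for (s in seq_len(n_perm)) {
    ord <- sample.int(q)
    for (r in seq_len(nrow(X_eval))) {
      B <- background
      prev <- baseline
      for (j in ord) {
        B[, j] <- X_eval[r, j]
        cur <- mean(f(B))
        A[r, j] <- A[r, j] + (cur - prev)
        prev <- cur
      }
    }
  }
  A <- A / n_perm
  attr(A, "baseline") <- baseline
  attr(A, "f_eval") <- f(X_eval)
  A
}

#' Cross-validated Shapley feature importance
#'
#' The stability protocol of the simulation study: rows are split into
#' `folds` folds; for each fold a model is obtained on the remaining rows
#' (via `trainer`) or a fixed `predictor` is used; then, `reps` times,
#' `n_background` background rows are drawn from the in-fold training rows
#' and `n_eval` evaluation rows from the held-out fold, and the mean
#' absolute attribution per feature over the evaluation rows is recorded.
#' This yields `folds * reps` importance estimates per feature, from which
#' 95\% confidence intervals are formed. The cohort preset (single model,
#' 30 repetitions) is `folds = 1, reps = 30`.
#'
#' @param X matrix or data frame of model inputs (all rows).
#' @param predictor fixed function mapping an input matrix to the score
#'   (use for a known ground-truth moderator function); give exactly one
#'   of `predictor` / `trainer`.
#' @param trainer function taking the integer vector of training row
#'   indices and returning a predictor function (use to retrain per fold).
#' @param folds,reps protocol sizes (simulation default 5 x 10).
#' @param n_background,n_eval background/evaluation sample sizes
#'   (defaults 500 and 100).
#' @param n_perm orderings per explained row (default 10).
#' @param seed optional integer seed.
#' @return an object of class `shap_report`: `estimates` (tibble with one
#'   row per feature x fold x rep), `summary` (per-feature mean, CI and
#'   rank), and `max_abs` (the largest absolute attribution across all
#'   samples, the normalization constant).
#' @export
shap_importance_cv <- function(X, predictor = NULL, trainer = NULL,
                               folds = 5, reps = 10,
                               n_background = 500, n_eval = 100,
                               n_perm = 10, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- check_count(folds, "folds", lower = 1L)
  reps <- check_count(reps, "reps", lower = 1L)
  if (is.null(predictor) == is.null(trainer)) {
    abort("give exactly one of `predictor` or `trainer`")
  }
  maybe_set_seed(seed)

  if (folds > 1L) {
    fold_id <- sample(rep_len(seq_len(folds), n))
  } else {
    # single-model protocol: an 80/20 train/eval split
    fold_id <- ifelse(seq_len(n) %in% sample.int(n, ceiling(0.2 * n)), 1L, 0L)
  }
  feat <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  colnames(X) <- feat

  rows <- list()
  max_abs <- 0
  for (fd in seq_len(folds)) {
    test_idx <- which(fold_id == fd)
    train_idx <- setdiff(seq_len(n), test_idx)
    if (length(test_idx) < n_eval) {
      abort(sprintf("fold %d has %d rows but n_eval = %d",
                    fd, length(test_idx), n_eval))
    }
    f <- if (!is.null(predictor)) predictor else trainer(train_idx)
    for (rp in seq_len(reps)) {
      bg <- X[sample(train_idx, min(n_background, length(train_idx))), , drop = FALSE]
      ev <- X[sample(test_idx, n_eval), , drop = FALSE]
      A <- shap_values(f, ev, bg, n_perm = n_perm)
      max_abs <- max(max_abs, max(abs(A)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        feature = feat, fold = fd, rep = rp,
        mean_abs = colMeans(abs(A))
      )
    }
  }
  estimates <- dplyr::bind_rows(rows)
  new_shap_report(estimates, max_abs)
}

new_shap_report <- function(estimates, max_abs, normalized = FALSE) {
  summary <- estimates |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      estimate = mean(.data$mean_abs),
      conf.low = mean(.data$mean_abs) -
        1.96 * sd(.data$mean_abs) / sqrt(dplyr::n()),
      conf.high = mean(.data$mean_abs) +
        1.96 * sd(.data$mean_abs) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$estimate)) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(list(estimates = estimates, summary = summary,
                 max_abs = max_abs, normalized = normalized),
            class = "shap_report")
}

#' @export
print.shap_report <- function(x, ...) {
  cat(sprintf("<shap_report> %d features, %d estimates each%s\n",
              nrow(x$summary),
              nrow(x$estimates) / max(1L, nrow(x$summary)),
              if (x$normalized) " (normalized)" else ""))
  print(head(x$summary, 10))
  invisible(x)
}

#' Normalize a Shapley importance report
#'
#' Divides every importance estimate by the report's own maximum absolute
#' attribution across all cross-validation samples, mapping values to
#' [0, 1]. Applied separately to the index report and the ground-truth
#' report so each is on its own scale. Idempotent.
#'
#' @param report a `shap_report`.
#' @return the normalized `shap_report`.
#' @export
normalize_shap <- function(report) {
  stopifnot(inherits(report, "shap_report"))
  if (report$max_abs <= 0) abort("all attributions are zero; cannot normalize")
  est <- dplyr::mutate(report$estimates,
                       mean_abs = .data$mean_abs / report$max_abs)
  new_shap_report(est, max_abs = 1, normalized = TRUE)
}

#' Mean absolute rank discrepancy between two importance rankings
#'
#' For the `top_k` most important features of the first ranking, the mean
#' absolute difference between their ranks in the two rankings. For two
#' `shap_report`s the discrepancy is computed per cross-validation sample
#' (fold x repetition, paired across reports) and then averaged, so the
#' reported value reflects resampling variability.
#'
#' @param x named rank vector (1 = most important) or a `shap_report`.
#' @param y the reference ranking: a named rank vector or `shap_report`
#'   over the same features.
#' @param top_k how many leading features of `x` to compare (default 10).
#' @return a single nonnegative number.
#' @export
rank_discrepancy <- function(x, y, top_k = 10) {
  top_k <- check_count(top_k, "top_k", lower = 1L)
  if (inherits(x, "shap_report") && inherits(y, "shap_report")) {
    ranks_of <- function(est) {
      est |>
        dplyr::group_by(.data$fold, .data$rep) |>
        dplyr::mutate(r = rank(-.data$mean_abs, ties.method = "average")) |>
        dplyr::ungroup()
    }
    rx <- ranks_of(x$estimates)
    ry <- ranks_of(y$estimates)
    if (!setequal(unique(rx$feature), unique(ry$feature))) {
      abort("the two reports cover different feature sets")
    }
    if (top_k > dplyr::n_distinct(rx$feature)) {
      abort("`top_k` exceeds the number of features")
    }
    top_feats <- head(x$summary$feature, top_k)
    joined <- dplyr::inner_join(
      dplyr::filter(rx, .data$feature %in% top_feats),
      dplyr::filter(ry, .data$feature %in% top_feats),
      by = c("feature", "fold", "rep"), suffix = c("_x", "_y")
    )
    per_sample <- joined |>
      dplyr::group_by(.data$fold, .data$rep) |>
      dplyr::summarise(d = mean(abs(.data$r_x - .data$r_y)), .groups = "drop")
    return(mean(per_sample$d))
  }
  if (!setequal(names(x), names(y))) abort("rankings cover different features")
  if (top_k > length(x)) abort("`top_k` exceeds the number of features")
  top_feats <- names(sort(x))[seq_len(top_k)]
  mean(abs(x[top_feats] - y[top_feats]))
}

#' Build the exact ground-truth moderator function
#'
#' Returns the planted polynomial \eqn{M} as a function of the encoded
#' moderator columns (the same inputs the network sees), for use as the
#' `predictor` in [shap_importance_cv()] when ranking features of the
#' ground truth. When the truth was planted on the raw basis, encoded
#' inputs are first mapped back to raw numeric codes (exactly, since each
#' code is linear in its indicators).
#'
#' @param truth a `regnn_truth`.
#' @param design the `regnn_design` the truth was built from (needed for
#'   a raw-basis truth).
#' @return a function mapping an encoded input matrix to moderator values.
#' @export
moderator_function <- function(truth, design = NULL) {
  stopifnot(inherits(truth, "regnn_truth"))
  force(truth)
  if (truth$basis == "raw") {
    if (is.null(design)) abort("a raw-basis truth needs its `design`")
    force(design)
    function(X) eval_moderator_terms(truth, encoded_to_raw(design, X))
  } else {
    function(X) eval_moderator_terms(truth, as.matrix(X))
  }
}

#' Trainer closure for per-fold ReGNN refits
#'
#' Convenience wrapper for [shap_importance_cv()]: returns a `trainer`
#' that refits a ReGNN on the given training rows and exposes its frozen
#' index as the function to explain (over raw moderator inputs).
#'
#' @param data the full data frame.
#' @param outcome,focal,moderators column names, as in [regnn()].
#' @param ... further arguments to [regnn()] (epochs, learning rates, ...).
#' @return a function of the training row indices.
#' @export
regnn_trainer <- function(data, outcome, focal, moderators, ...) {
  args <- list(...)
  function(train_idx) {
    fit <- do.call(regnn, c(
      list(data = data[train_idx, , drop = FALSE], outcome = outcome,
           focal = focal, moderators = moderators,
           split = c(train = 1, sensitivity = 0)),
      args
    ))
    function(X) {
      nd <- tibble::as_tibble(as.data.frame(X))
      names(nd) <- moderators
      compute_index(fit, nd)
    }
  }
}

#' Partial dependence of the index on one input
#'
#' For each grid value the feature column is clamped to that value across
#' the whole dataset and the mean index is recorded.
#'
#' @param object a fitted `regnn`, or a function mapping an input matrix
#'   to scores.
#' @param feature input column name (or index, for a function).
#' @param data input rows; defaults to the fit's data.
#' @param grid values at which to clamp; default an even grid over the
#'   observed range.
#' @param n_grid grid length when `grid` is NULL.
#' @return a tibble with `value` and `estimate` (mean index).
#' @export
partial_dependence <- function(object, feature, data = NULL, grid = NULL,
                               n_grid = 20) {
  if (inherits(object, "regnn")) {
    data <- data %||% object$data
    X <- as.matrix(data[object$cols$moderators])
    f <- function(M) {
      nd <- tibble::as_tibble(as.data.frame(M))
      names(nd) <- object$cols$moderators
      compute_index(object, nd)
    }
  } else {
    stopifnot(is.function(object), !is.null(data))
    X <- as.matrix(data)
    f <- object
  }
  if (is.character(feature)) {
    if (!feature %in% colnames(X)) abort(sprintf("`%s` is not an input feature", feature))
    jcol <- match(feature, colnames(X))
  } else {
    jcol <- check_count(feature, "feature", lower = 1L)
    if (jcol > ncol(X)) abort("`feature` is not an input feature")
  }
  if (is.null(grid)) {
    grid <- seq(min(X[, jcol]), max(X[, jcol]), length.out = n_grid)
  }
  est <- vapply(grid, function(v) {
    Xc <- X
    Xc[, jcol] <- v
    mean(f(Xc))
  }, numeric(1))
  tibble::tibble(value = grid, estimate = est)
}
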