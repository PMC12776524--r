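#' Twin regression: classical inference around a frozen index
#'
#' With the trained network frozen, the learned index z is entered into an
#' ordinary least squares fit as an observed moderator:
#' \deqn{o = c_0 + \sum_k c_k x_k + c_n x_f + c_{int}\, z\, x_f + e,}
#' yielding standard coefficients, classical (homoskedastic) standard
#' errors, t statistics, two-sided p-values, 95\% confidence intervals and
#' variance-inflation factors.
#'
#' `fit_twin()` is generic: give it a fitted [regnn()] model (the index and
#' columns are taken from the fit, and `subset` picks the split), or a data
#' frame holding the index as a column.
#'
#' @param x a fitted `regnn` or a data frame.
#' @param ... passed on between methods.
#' @return an object of class `twin_fit`; see [tidy.twin_fit()].
#' @export
fit_twin <- function(x, ...) UseMethod("fit_twin")

#' @rdname fit_twin
#' @param subset which split of the fit's data to use: `"train"`,
#'   `"sensitivity"`, `"holdout"`, or `"all"`.
#' @export
fit_twin.regnn <- function(x, subset = c("train", "sensitivity", "holdout", "all"), ...) {
  subset <- match.arg(subset)
  idx <- if (subset == "all") seq_len(nrow(x$data)) else x$split[[subset]]
  df <- x$data[idx, , drop = FALSE]
  df[["z"]] <- x$z[idx]
  fit_twin(df, outcome = x$cols$outcome, focal = x$cols$focal,
           index = "z", linear = x$cols$linear, ...)
}

#' @rdname fit_twin
#' @param outcome,focal,index,linear column names: outcome, focal exposure,
#'   frozen index, and linear-adjustment columns.
#' @export
fit_twin.data.frame <- function(x, outcome, focal, index, linear = NULL, ...) {
  ols_inference(x, outcome = outcome, focal = focal,
                terms = c(linear, focal, index),
                interactions = setNames(list(c(focal, index)),
                                        paste0(focal, ":", index)),
                class = "twin_fit")
}

#' Moderated multiple regression with all pairwise interactions
#'
#' The classical baseline: every candidate moderator enters both as a main
#' effect and as a product with the focal exposure,
#' \deqn{o = c_0 + \sum_k c_k x_k + c_n x_f + \sum_k c^{int}_k x_k x_f + e.}
#' By default the focal exposure and the moderators are mean-centered
#' before products are formed (this changes main-effect coefficients but
#' not the interaction coefficients).
#'
#' @param data a data frame.
#' @param outcome,focal column names.
#' @param moderators columns that interact with the exposure.
#' @param linear additional linear-only columns (default none beyond
#'   `moderators`, which always enter linearly).
#' @param center mean-center the exposure and moderators before forming
#'   products (default TRUE).
#' @return an object of class `c("mmr_fit", "twin_fit")`.
#' @export
fit_mmr <- function(data, outcome, focal, moderators, linear = NULL,
                    center = TRUE) {
  df <- tibble::as_tibble(data)
  if (center) {
    df[[focal]] <- df[[focal]] - mean(df[[focal]])
    for (mcol in moderators) df[[mcol]] <- df[[mcol]] - mean(df[[mcol]])
  }
  ints <- if (length(moderators)) {
    setNames(lapply(moderators, function(mc) c(focal, mc)),
             paste0(focal, ":", moderators))
  } else {
    list()
  }
  fit <- ols_inference(df, outcome = outcome, focal = focal,
                       terms = unique(c(linear, moderators, focal)),
                       interactions = ints, class = c("mmr_fit", "twin_fit"))
  fit$centered <- center
  fit
}

# Shared OLS engine: builds the design, fits with lm(), assembles the
# inference table (coef, SE, t, p, CI, VIF).
ols_inference <- function(data, outcome, focal, terms, interactions, class) {
  df <- tibble::as_tibble(data)
  for (cn in c(outcome, unique(unlist(c(terms, interactions))))) {
    if (!cn %in% names(df)) abort(sprintf("column `%s` not found", cn))
  }
  y <- as.numeric(df[[outcome]])
  X <- as.matrix(df[unique(terms)])
  for (nm in names(interactions)) {
    pr <- interactions[[nm]]
    X <- cbind(X, as.numeric(df[[pr[1]]]) * as.numeric(df[[pr[2]]]))
    colnames(X)[ncol(X)] <- nm
  }
  n <- nrow(X); k <- ncol(X) + 1L
  if (n <= k) abort("not enough rows for the number of model terms")

  dfr <- as.data.frame(X, check.names = FALSE)
  dfr[[".y"]] <- y
  fm <- stats::as.formula(paste(
    ".y ~", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  lmfit <- lm(fm, data = dfr)
  cf <- coef(lmfit)
  if (anyNA(cf)) {
    bad <- gsub("`", "", names(cf)[is.na(cf)])
    abort(sprintf("rank-deficient design: collinear term(s) %s",
                  paste(bad, collapse = ", ")))
  }
  sm <- summary(lmfit)
  tab <- sm$coefficients
  rownames(tab) <- gsub("`", "", rownames(tab))
  tcrit <- qt(0.975, lmfit$df.residual)
  vifs <- c("(Intercept)" = NA_real_, vif(X))

  table <- tibble::tibble(
    term = rownames(tab),
    estimate = tab[, 1],
    std.error = tab[, 2],
    statistic = tab[, 3],
    p.value = tab[, 4],
    conf.low = tab[, 1] - tcrit * tab[, 2],
    conf.high = tab[, 1] + tcrit * tab[, 2],
    vif = unname(vifs[rownames(tab)])
  )
  out <- list(
    table = table, lm = lmfit, n = n,
    sigma = sm$sigma, r.squared = sm$r.squared,
    adj.r.squared = sm$adj.r.squared,
    df.residual = lmfit$df.residual,
    outcome = outcome, focal = focal,
    interaction_terms = names(interactions)
  )
  class(out) <- class
  out
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("<%s> n = %d, R2 = %.4f (adj %.4f), residual SD = %.4f\n",
              class(x)[1], x$n, x$r.squared, x$adj.r.squared, x$sigma))
  tb <- x$table
  tb$p.value <- format_pval(tb$p.value)
  print(as.data.frame(tb), digits = 4)
  invisible(x)
}

#' Tidy and glance methods for twin/MMR fits
#'
#' @param x a `twin_fit` or `mmr_fit`.
#' @param ... unused.
#' @return `tidy()`: one row per term with estimate, classical standard
#'   error, t statistic, two-sided p-value, 95\% confidence bounds and
#'   VIF. `glance()`: model-level summary.
#' @export
tidy.twin_fit <- function(x, ...) x$table

#' @rdname tidy.twin_fit
#' @export
glance.twin_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r.squared, adj.r.squared = x$adj.r.squared,
    sigma = x$sigma, df.residual = x$df.residual, nobs = x$n
  )
}

#' Variance inflation factors
#'
#' For each column j of the design, `vif_j = 1 / (1 - R2_j)` where `R2_j`
#' is from regressing column j on all other columns (with intercept).
#' Exactly collinear columns get `Inf`.
#'
#' @param X numeric matrix or data frame of model terms (no intercept
#'   column).
#' @return a named numeric vector.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) return(setNames(rep(1, ncol(X)), colnames(X)))
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, colnames(X))
}

#' Marginal effect of the exposure at given index values
#'
#' The partial derivative of the fitted conditional expectation with
#' respect to the exposure, \eqn{c_n + c_{int} z}, with a delta-method
#' standard error from the coefficient covariance.
#'
#' @param fit a `twin_fit` containing exposure and exposure-by-index terms.
#' @param z_value numeric vector of index values at which to evaluate.
#' @return a tibble with `z`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
marginal_effect <- function(fit, z_value) {
  stopifnot(inherits(fit, "twin_fit"))
  check_finite_vec(z_value, "z_value")
  int_term <- fit$interaction_terms[1]
  if (is.null(int_term) || !int_term %in% fit$table$term) {
    abort("fit has no exposure-by-index interaction term")
  }
  cf <- coef(fit$lm)
  names(cf) <- gsub("`", "", names(cf))
  V <- vcov(fit$lm)
  dimnames(V) <- lapply(dimnames(V), function(d) gsub("`", "", d))
  cn <- cf[[fit$focal]]
  ci <- cf[[int_term]]
  est <- cn + ci * z_value
  se <- sqrt(V[fit$focal, fit$focal] + z_value^2 * V[int_term, int_term] +
               2 * z_value * V[fit$focal, int_term])
  tcrit <- qt(0.975, fit$df.residual)
  tibble::tibble(z = z_value, estimate = est, std.error = se,
                 conf.low = est - tcrit * se, conf.high = est + tcrit * se)
}

#' Predicted-outcome profiles across exposure levels
#'
#' Point predictions and 95\% confidence intervals of the fitted twin
#' model over a grid of exposure values, at chosen percentiles of the
#' index, with all other covariates held at their means.
#'
#' @param fit a `twin_fit` produced by [fit_twin()].
#' @param z_levels index percentiles, in (0, 100); default `c(10, 50, 90)`.
#' @param xf_grid exposure values; default an even grid over the observed
#'   range.
#' @param n_grid grid length when `xf_grid` is NULL.
#' @return a tibble with `z_level`, `z_value`, exposure value `xf`, `fit`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
predict_profiles <- function(fit, z_levels = c(10, 50, 90), xf_grid = NULL,
                             n_grid = 25) {
  stopifnot(inherits(fit, "twin_fit"))
  if (any(z_levels <= 0 | z_levels >= 100)) {
    abort("`z_levels` are percentiles and must lie in (0, 100)")
  }
  mf <- fit$lm$model
  names(mf) <- gsub("`", "", names(mf))
  int_term <- fit$interaction_terms[1]
  index <- strsplit(int_term, ":", fixed = TRUE)[[1]][2]
  focal <- fit$focal
  xf_obs <- mf[[focal]]
  if (is.null(xf_grid)) {
    xf_grid <- seq(min(xf_obs), max(xf_obs), length.out = n_grid)
  }
  if (!length(xf_grid)) abort("`xf_grid` must be non-empty")
  zq <- quantile(mf[[index]], z_levels / 100, type = 7)

  base_cols <- setdiff(names(mf), c(".y", focal, index, int_term))
  means <- vapply(base_cols, function(cn) mean(mf[[cn]]), numeric(1))

  grid <- tidyr::expand_grid(z_level = z_levels, xf = xf_grid) |>
    dplyr::mutate(z_value = unname(zq[match(.data$z_level, z_levels)]))

  cf <- coef(fit$lm); names(cf) <- gsub("`", "", names(cf))
  V <- vcov(fit$lm)
  dimnames(V) <- lapply(dimnames(V), function(d) gsub("`", "", d))
  term_order <- names(cf)

  Xnew <- t(vapply(seq_len(nrow(grid)), function(r) {
    row <- setNames(numeric(length(term_order)), term_order)
    row["(Intercept)"] <- 1
    row[base_cols] <- means
    row[focal] <- grid$xf[r]
    row[index] <- grid$z_value[r]
    row[int_term] <- grid$xf[r] * grid$z_value[r]
    row
  }, numeric(length(term_order))))

  est <- drop(Xnew %*% cf)
  se <- sqrt(rowSums((Xnew %*% V) * Xnew))
  tcrit <- qt(0.975, fit$df.residual)
  dplyr::mutate(grid, fit = est, std.error = se,
                conf.low = est - tcrit * se, conf.high = est + tcrit * se)
}

#' Sensitivity probe: interaction p-value on a small held-out set
#'
#' Computes the index on the held-out sensitivity split (disjoint from the
#' training rows, drawn before training), refits the twin regression
#' there, and reports the two-sided p-value of the exposure-by-index term.
#' Because the t statistic scales with \eqn{\sqrt n}, a small set gives a
#' stringent test: a learned moderation that stays significant despite the
#' reduced sample size is strong and stable, while one that evaporates was
#' weak or overfit.
#'
#' @param object a fitted `regnn`.
#' @param subset which split to probe on (default `"sensitivity"`).
#' @return an object of class `sensitivity_probe`: list with `p_value`,
#'   `n`, and the underlying `fit` (a `twin_fit`).
#' @export
sensitivity_probe <- function(object, subset = "sensitivity") {
  stopifnot(inherits(object, "regnn"))
  idx <- object$split[[subset]]
  k <- length(object$cols$linear) + 4L  # + intercept, xf, z, z:xf
  if (length(idx) <= k) {
    abort(sprintf("probe subset has %d rows but the model needs more than %d",
                  length(idx), k))
  }
  tw <- fit_twin(object, subset = subset)
  int_term <- tw$interaction_terms[1]
  p <- tw$table$p.value[tw$table$term == int_term]
  structure(list(p_value = p, n = tw$n, fit = tw, subset = subset),
            class = "sensitivity_probe")
}

#' @export
print.sensitivity_probe <- function(x, ...) {
  cat(sprintf("<sensitivity_probe> n = %d (%s set): interaction p-value = %s\n",
              x$n, x$subset, format_pval(x$p_value)))
  invisible(x)
}
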