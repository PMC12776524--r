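#' Build a sparse random correlation matrix
#'
#' Constructs the base covariance for the simulated population: unit
#' diagonal, a fixed fraction of off-diagonal entries drawn uniformly from
#' `off_diag_range`, the remainder zero. The raw matrix is then made
#' positive semidefinite by clipping negative eigenvalues to zero,
#' reconstructing, and rescaling back to unit diagonal.
#'
#' @param n_vars number of variables (matrix dimension), at least 2.
#' @param off_diag_fraction proportion of off-diagonal entries that are
#'   non-zero (default 0.6).
#' @param off_diag_range length-2 numeric, the uniform range for non-zero
#'   off-diagonal entries (default `c(-0.3, 0.3)`).
#' @param seed optional integer seed.
#' @return a symmetric positive-semidefinite matrix with unit diagonal.
#' @examples
#' S <- build_covariance(10, seed = 1)
#' min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) >= -1e-10
#' @export
build_covariance <- function(n_vars = 31, off_diag_fraction = 0.6,
                             off_diag_range = c(-0.3, 0.3), seed = NULL) {
  n_vars <- check_count(n_vars, "n_vars", lower = 2L)
  check_number(off_diag_fraction, "off_diag_fraction", 0, 1)
  stopifnot(length(off_diag_range) == 2L, off_diag_range[1] <= off_diag_range[2])
  maybe_set_seed(seed)

  S <- diag(n_vars)
  ut <- which(upper.tri(S))
  n_fill <- round(off_diag_fraction * length(ut))
  if (n_fill > 0) {
    pick <- sample(ut, n_fill)
    vals <- runif(n_fill, off_diag_range[1], off_diag_range[2])
    if (any(!is.finite(vals))) abort("non-finite draw while filling the covariance")
    S[pick] <- vals
    S <- (S + t(S)) - diag(diag(S))  # symmetrize, keep unit diagonal
  }

  eg <- eigen(S, symmetric = TRUE)
  if (min(eg$values) < 0) {
    lam <- pmax(eg$values, 0)
    S <- eg$vectors %*% (lam * t(eg$vectors))
    d <- diag(S)
    if (any(d <= 0)) abort("degenerate diagonal after eigenvalue clipping")
    S <- S / sqrt(outer(d, d))
    S <- (S + t(S)) / 2
  }
  dimnames(S) <- NULL
  S
}

#' Draw the continuous base sample
#'
#' Rows are i.i.d. multivariate normal with mean zero and the given
#' covariance (via [MASS::mvrnorm()]).
#'
#' @param cov a positive-semidefinite covariance matrix.
#' @param n number of rows.
#' @param seed optional integer seed.
#' @return an `n` by `ncol(cov)` numeric matrix, columns named `x1..xp`.
#' @export
sample_base <- function(cov, n, seed = NULL) {
  n <- check_count(n, "n", lower = 1L)
  if (!is.matrix(cov) || nrow(cov) != ncol(cov) ||
      max(abs(cov - t(cov))) > 1e-8) {
    abort("`cov` must be a symmetric square matrix")
  }
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort("`cov` is not positive semidefinite")
  maybe_set_seed(seed)
  X <- MASS::mvrnorm(n, mu = rep(0, ncol(cov)), Sigma = cov, tol = 1e-6)
  if (n == 1L) X <- matrix(X, nrow = 1L)
  colnames(X) <- paste0("x", seq_len(ncol(cov)))
  X
}

#' Default mixed-type plan for the simulated population
#'
#' For a 31-column base draw the default plan keeps 16 columns continuous
#' (one of which is the focal exposure), and converts 7 to binary, 5 to
#' 3-level categorical, and 3 to 4-level ordinal variables by thresholding
#' at standard-normal quantiles (binary at 0; categorical at the tertile
#' bounds; ordinal at the quartile bounds). The resulting encoded design
#' (reference category dropped, focal excluded) has
#' 15 + 7 + 5x2 + 3 = 35 columns, the input width of the default network.
#' For other widths, every non-focal column stays continuous.
#'
#' @param n_vars number of base columns.
#' @param focal_index which column is the focal exposure (kept continuous).
#' @return a tibble with columns `column`, `type`, `cutpoints` (list).
#' @export
default_type_plan <- function(n_vars = 31, focal_index = 1) {
  n_vars <- check_count(n_vars, "n_vars", lower = 2L)
  focal_index <- check_count(focal_index, "focal_index", lower = 1L)
  if (focal_index > n_vars) abort("`focal_index` out of range")
  others <- setdiff(seq_len(n_vars), focal_index)
  types <- rep("continuous", length(others))
  if (n_vars == 31) {
    types <- rep(c("continuous", "binary", "categorical", "ordinal"),
                 times = c(15, 7, 5, 3))
  }
  cuts <- lapply(types, function(tp) {
    switch(tp,
      continuous  = numeric(0),
      binary      = 0,
      categorical = qnorm(c(1 / 3, 2 / 3)),
      ordinal     = qnorm(c(0.25, 0.5, 0.75))
    )
  })
  tibble::tibble(
    column = c(focal_index, others),
    type = c("continuous", types),
    cutpoints = c(list(numeric(0)), cuts)
  ) |> dplyr::arrange(.data$column)
}

#' Discretize the base sample and build the encoded design
#'
#' Applies a column-type plan (see [default_type_plan()]) to the continuous
#' base matrix: binary columns are thresholded to 0/1, categorical columns
#' are cut into labelled levels and one-hot encoded with the first level as
#' reference, ordinal columns are cut into graded integer scores
#' (0, 1, ...), and continuous columns pass through. The focal column must
#' be continuous; it is excluded from the encoded moderator design.
#'
#' @param base continuous numeric matrix (rows = observations).
#' @param type_plan a plan tibble as from [default_type_plan()]; `NULL` for
#'   the default.
#' @param focal_index column index of the focal exposure.
#' @return an object of class `regnn_design` with elements `raw` (tibble of
#'   mixed-type columns), `encoded` (numeric matrix), `focal` (numeric
#'   vector), `focal_name`, and `meta` (per-column typing/encoding map).
#' @export
discretize_and_encode <- function(base, type_plan = NULL, focal_index = 1) {
  stopifnot(is.matrix(base), is.numeric(base))
  p <- ncol(base)
  focal_index <- check_count(focal_index, "focal_index", lower = 1L)
  if (focal_index > p) abort("`focal_index` out of range")
  if (is.null(type_plan)) type_plan <- default_type_plan(p, focal_index)
  if (nrow(type_plan) != p) abort("`type_plan` must cover every column")
  type_plan <- dplyr::arrange(type_plan, .data$column)
  if (type_plan$type[focal_index] != "continuous") {
    abort("the focal column must be typed continuous")
  }

  raw <- list()
  enc_cols <- list()
  meta_rows <- list()
  for (k in seq_len(p)) {
    tp <- type_plan$type[k]
    cuts <- type_plan$cutpoints[[k]]
    xn <- paste0("x", k)
    xk <- base[, k]
    if (length(cuts) && any(diff(cuts) <= 0)) {
      abort(sprintf("cutpoints for column %d must be strictly increasing", k))
    }
    if (tp == "continuous") {
      raw[[xn]] <- xk
      if (k != focal_index) enc_cols[[xn]] <- xk
      meta_rows[[k]] <- list(column = k, name = xn, type = tp,
                             levels = list(character(0)),
                             encoded = list(if (k == focal_index) character(0) else xn))
    } else if (tp == "binary") {
      v <- as.integer(xk > cuts[1])
      raw[[xn]] <- v
      enc_cols[[xn]] <- as.numeric(v)
      meta_rows[[k]] <- list(column = k, name = xn, type = tp,
                             levels = list(c("0", "1")), encoded = list(xn))
    } else if (tp == "categorical") {
      lev <- paste0("L", seq_len(length(cuts) + 1L))
      f <- cut(xk, breaks = c(-Inf, cuts, Inf), labels = lev)
      present <- lev[lev %in% unique(as.character(f))]
      if (length(present) < length(lev)) {
        warn(sprintf("column %d: empty category level(s) dropped after thresholding", k))
        f <- factor(as.character(f), levels = present)
        lev <- present
      }
      raw[[xn]] <- f
      for (l in lev[-1]) {
        enc_cols[[paste0(xn, "_", l)]] <- as.numeric(f == l)
      }
      meta_rows[[k]] <- list(column = k, name = xn, type = tp,
                             levels = list(lev),
                             encoded = list(paste0(xn, "_", lev[-1])))
    } else if (tp == "ordinal") {
      v <- as.integer(cut(xk, breaks = c(-Inf, cuts, Inf))) - 1L
      raw[[xn]] <- v
      enc_cols[[xn]] <- as.numeric(v)
      meta_rows[[k]] <- list(column = k, name = xn, type = tp,
                             levels = list(as.character(0:length(cuts))),
                             encoded = list(xn))
    } else {
      abort(sprintf("unknown column type '%s'", tp))
    }
  }

  encoded <- do.call(cbind, enc_cols)
  meta <- dplyr::bind_rows(lapply(meta_rows, tibble::as_tibble))
  out <- list(
    raw = tibble::as_tibble(raw),
    encoded = encoded,
    focal = base[, focal_index],
    focal_name = "xf",
    focal_index = focal_index,
    meta = meta
  )
  class(out) <- "regnn_design"
  out
}

#' @export
print.regnn_design <- function(x, ...) {
  cnt <- table(x$meta$type)
  cat(sprintf("<regnn_design> %d obs, %d raw columns (%s), %d encoded moderator inputs\n",
              nrow(x$raw), nrow(x$meta),
              paste(names(cnt), cnt, sep = ": ", collapse = ", "),
              ncol(x$encoded)))
  invisible(x)
}

#' Decode one-hot columns back to raw labels
#'
#' Round-trip check utility: reconstructs the raw label of a categorical
#' column from its encoded indicator columns.
#'
#' @param design a `regnn_design`.
#' @param column raw column index.
#' @return a character vector of labels.
#' @export
decode_column <- function(design, column) {
  row <- design$meta[design$meta$column == column, ]
  if (nrow(row) != 1L) abort("unknown column")
  if (row$type != "categorical") abort("only categorical columns are one-hot encoded")
  lev <- row$levels[[1]]
  dummies <- design$encoded[, row$encoded[[1]], drop = FALSE]
  lab <- rep(lev[1], nrow(dummies))
  for (j in seq_along(lev[-1])) lab[dummies[, j] == 1] <- lev[j + 1]
  lab
}

#' Numeric matrix of the raw (post-discretization) variables
#'
#' The non-focal raw columns on their numeric codes: continuous values,
#' binary 0/1, categorical level codes 1..L, ordinal grades 0..k.
#'
#' @param design a `regnn_design`.
#' @return an n by (p - 1) numeric matrix, columns named after the raw
#'   variables.
#' @export
raw_matrix <- function(design) {
  stopifnot(inherits(design, "regnn_design"))
  cols <- design$meta$name[design$meta$column != design$focal_index]
  out <- vapply(cols, function(cn) as.numeric(design$raw[[cn]]),
                numeric(nrow(design$raw)))
  colnames(out) <- cols
  out
}

# Reconstruct raw numeric codes from encoded values (categorical codes are
# linear in their dummies: code = 1 + sum_l (l-1) * dummy_l).
encoded_to_raw <- function(design, E) {
  E <- as.matrix(E)
  meta <- design$meta[design$meta$column != design$focal_index, ]
  out <- matrix(0, nrow(E), nrow(meta), dimnames = list(NULL, meta$name))
  for (r in seq_len(nrow(meta))) {
    if (meta$type[r] == "categorical") {
      dums <- E[, meta$encoded[[r]], drop = FALSE]
      out[, r] <- 1 + drop(dums %*% seq_len(ncol(dums)))
    } else {
      out[, r] <- E[, meta$encoded[[r]]]
    }
  }
  out
}

#' Plant the ground-truth composite moderator
#'
#' Samples, with replacement, index pairs and triplets over the moderator
#' variables and sums their products with uniform-magnitude, random-sign
#' weights:
#' \deqn{M = \sum c_{pair} x_i x_j + \sum c_{tri} x_i x_j x_k.}
#' Repeated tuples simply contribute additively (their weights sum), and
#' self-pairs yield square terms. Linear outcome coefficients for every
#' variable and the focal exposure are drawn \eqn{N(0, \sigma_c)}.
#'
#' With the default `basis = "encoded"` the tuples and linear
#' coefficients range over the encoded moderator columns, so the planted
#' signal lives directly in the network's input space and its variance
#' stays on the scale of the reference study (var(M) around 0.2 gives a
#' noise variance near 0.034 at SNR 5). `basis = "raw"` instead plants
#' the signal on the raw post-discretization variables on their numeric
#' codes; that remains exactly representable from the encoded inputs
#' (each code is linear in its indicators) but the nonzero means of the
#' discrete codes inflate the product terms several-fold.
#'
#' @param design a `regnn_design`.
#' @param n_pairs,n_triplets number of pair/triplet terms (default 5 each).
#' @param weight_range magnitude range for tuple weights (default
#'   `c(0.05, 0.3)`).
#' @param coef_sd standard deviation of the linear coefficients
#'   (default 0.3).
#' @param basis `"encoded"` (default) or `"raw"`: the column set over
#'   which tuples and linear coefficients are drawn.
#' @param seed optional integer seed.
#' @return an object of class `regnn_truth`: tibbles `pairs` and
#'   `triplets` (indices into the basis columns), the moderator vector
#'   `M`, `linear_coefs` (named, per basis column), `focal_coef`,
#'   `basis`, and `mean_M`.
#' @export
build_moderator <- function(design, n_pairs = 5, n_triplets = 5,
                            weight_range = c(0.05, 0.3), coef_sd = 0.3,
                            basis = c("encoded", "raw"), seed = NULL) {
  stopifnot(inherits(design, "regnn_design"))
  basis <- match.arg(basis)
  n_pairs <- check_count(n_pairs, "n_pairs")
  n_triplets <- check_count(n_triplets, "n_triplets")
  stopifnot(length(weight_range) == 2L, weight_range[1] > 0,
            weight_range[1] < weight_range[2])
  if (ncol(design$encoded) < 2L) {
    abort("design must have at least 2 encoded columns")
  }
  B <- if (basis == "raw") raw_matrix(design) else design$encoded
  q <- ncol(B)
  maybe_set_seed(seed)

  draw_w <- function(k) {
    if (k == 0L) return(numeric(0))
    runif(k, weight_range[1], weight_range[2]) *
      sample(c(-1, 1), k, replace = TRUE)
  }
  pairs <- tibble::tibble(
    i = sample.int(q, n_pairs, replace = TRUE),
    j = sample.int(q, n_pairs, replace = TRUE),
    weight = draw_w(n_pairs)
  )
  triplets <- tibble::tibble(
    i = sample.int(q, n_triplets, replace = TRUE),
    j = sample.int(q, n_triplets, replace = TRUE),
    k = sample.int(q, n_triplets, replace = TRUE),
    weight = draw_w(n_triplets)
  )
  out <- list(
    pairs = pairs, triplets = triplets,
    linear_coefs = setNames(rnorm(q, 0, coef_sd), colnames(B)),
    focal_coef = rnorm(1, 0, coef_sd),
    basis = basis
  )
  out$M <- eval_moderator_terms(out, B)
  out$mean_M <- mean(out$M)
  class(out) <- "regnn_truth"
  out
}

eval_moderator_terms <- function(truth, B) {
  M <- rep(0, nrow(B))
  pr <- truth$pairs
  for (r in seq_len(nrow(pr))) {
    M <- M + pr$weight[r] * B[, pr$i[r]] * B[, pr$j[r]]
  }
  tr <- truth$triplets
  for (r in seq_len(nrow(tr))) {
    M <- M + tr$weight[r] * B[, tr$i[r]] * B[, tr$j[r]] * B[, tr$k[r]]
  }
  M
}

#' Recompute the planted moderator from its stored terms
#' @param truth a `regnn_truth`.
#' @param design the `regnn_design` it was built from.
#' @return the moderator vector.
#' @export
moderator_from_terms <- function(truth, design) {
  B <- if (truth$basis == "raw") raw_matrix(design) else design$encoded
  eval_moderator_terms(truth, B)
}

#' Generate noisy outcomes over a grid of signal-to-noise ratios
#'
#' For each requested SNR the noise variance is `var(M) / snr` and the
#' outcome is
#' \deqn{o = X c + c_f x_f + M x_f + \epsilon,\quad \epsilon \sim N(0, \sigma^2),}
#' with `X` the encoded design and `M` the planted moderator. The noise
#' vector is stored so the outcome decomposes exactly.
#'
#' @param design a `regnn_design`.
#' @param truth a `regnn_truth`.
#' @param snr positive SNR values (default `c(5, 3, 1, 0.5, 0.3, 0.1)`).
#' @param seed optional integer seed.
#' @return an object of class `regnn_outcomes`: a tibble with one row per
#'   SNR and columns `snr`, `noise_variance`, `outcome` (list), `noise`
#'   (list), plus attribute `linear_part`.
#' @export
generate_outcomes <- function(design, truth, snr = c(5, 3, 1, 0.5, 0.3, 0.1),
                              seed = NULL) {
  stopifnot(inherits(design, "regnn_design"), inherits(truth, "regnn_truth"))
  if (any(!is.finite(snr)) || any(snr <= 0)) abort("all SNR values must be positive")
  vM <- var(truth$M)
  if (vM <= 0) abort("var(M) is zero; cannot scale noise to a finite SNR")
  maybe_set_seed(seed)

  B <- if (truth$basis == "raw") raw_matrix(design) else design$encoded
  linear_part <- drop(B %*% truth$linear_coefs) +
    truth$focal_coef * design$focal
  signal <- linear_part + truth$M * design$focal
  n <- length(signal)

  rows <- purrr::map(snr, function(s) {
    sigma2 <- vM / s
    eps <- rnorm(n, 0, sqrt(sigma2))
    tibble::tibble(snr = s, noise_variance = sigma2,
                   outcome = list(signal + eps), noise = list(eps))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "linear_part") <- linear_part
  attr(out, "var_M") <- vM
  class(out) <- c("regnn_outcomes", class(out))
  out
}

#' Flag the vulnerable subgroup above a score quantile
#'
#' Marks observations whose score strictly exceeds the empirical quantile
#' (default the 84th percentile, roughly one standard deviation above the
#' mean for a normal score).
#'
#' @param score numeric vector (the planted moderator M or a learned
#'   index z).
#' @param quantile probability in (0, 1); default 0.84.
#' @return an object of class `regnn_partition`: list with `quantile`,
#'   `cutoff`, `score`, and logical `mask`.
#' @export
vulnerable_mask <- function(score, quantile = 0.84) {
  check_finite_vec(score, "score")
  check_number(quantile, "quantile", 0, 1)
  if (quantile <= 0 || quantile >= 1) abort("`quantile` must be in (0, 1)")
  if (length(unique(score)) == 1L) {
    warn("constant score: no observation strictly exceeds the quantile")
  }
  cutoff <- unname(quantile(score, quantile, type = 7))
  out <- list(quantile = quantile, cutoff = cutoff, score = score,
              mask = score > cutoff)
  class(out) <- "regnn_partition"
  out
}

#' @export
print.regnn_partition <- function(x, ...) {
  cat(sprintf("<regnn_partition> %d / %d flagged above the %.0fth percentile (cutoff %.4g)\n",
              sum(x$mask), length(x$mask), 100 * x$quantile, x$cutoff))
  invisible(x)
}

#' Simulate a complete study dataset
#'
#' One call generates the full synthetic population used throughout the
#' package: a sparse-correlation multivariate-normal base sample, mixed-type
#' discretization and one-hot encoding, a planted pair/triplet polynomial
#' moderator, and outcomes at each requested signal-to-noise ratio.
#'
#' @inheritParams build_covariance
#' @inheritParams build_moderator
#' @param basis column set for the planted signal, `"raw"` (default) or
#'   `"encoded"`; see [build_moderator()].
#' @inheritParams generate_outcomes
#' @param n number of observations (default 8000).
#' @param type_plan optional column-type plan (see [default_type_plan()]).
#' @param focal_index base column used as the focal exposure.
#' @param seed optional integer seed governing every random stage.
#' @return an object of class `regnn_sim`: `data` (tibble with outcome
#'   columns `y_snr_<snr>`, `xf`, the encoded moderator columns, and `M`),
#'   plus `design`, `truth`, `outcomes`, and `covariance`.
#' @examples
#' sim <- simulate_regnn_data(n = 200, snr = 1, seed = 1)
#' sim$data
#' @export
simulate_regnn_data <- function(n = 8000, n_vars = 31,
                                snr = c(5, 3, 1, 0.5, 0.3, 0.1),
                                n_pairs = 5, n_triplets = 5,
                                weight_range = c(0.05, 0.3), coef_sd = 0.3,
                                off_diag_fraction = 0.6,
                                off_diag_range = c(-0.3, 0.3),
                                type_plan = NULL, focal_index = 1,
                                basis = c("encoded", "raw"), seed = NULL) {
  maybe_set_seed(seed)
  S <- build_covariance(n_vars, off_diag_fraction, off_diag_range)
  base <- sample_base(S, n)
  design <- discretize_and_encode(base, type_plan, focal_index)
  truth <- build_moderator(design, n_pairs, n_triplets, weight_range, coef_sd,
                           basis = basis)
  outcomes <- generate_outcomes(design, truth, snr)

  ydf <- purrr::map(seq_len(nrow(outcomes)), ~ outcomes$outcome[[.x]])
  names(ydf) <- paste0("y_snr_", outcomes$snr)
  data <- dplyr::bind_cols(
    tibble::as_tibble(ydf),
    tibble::tibble(xf = design$focal),
    tibble::as_tibble(design$encoded),
    tibble::tibble(M = truth$M)
  )
  out <- list(data = data, design = design, truth = truth,
              outcomes = outcomes, covariance = S, seed = seed,
              moderator_cols = colnames(design$encoded))
  class(out) <- "regnn_sim"
  out
}

#' @export
print.regnn_sim <- function(x, ...) {
  cat(sprintf("<regnn_sim> n = %d, %d moderator inputs, SNR grid {%s}, var(M) = %.3f\n",
              nrow(x$data), length(x$moderator_cols),
              paste(x$outcomes$snr, collapse = ", "),
              attr(x$outcomes, "var_M")))
  invisible(x)
}

#' Write a simulated dataset to CSV with a JSON sidecar
#'
#' @param sim a `regnn_sim`.
#' @param dir output directory (created if missing).
#' @return the paths written, invisibly.
#' @export
write_regnn_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "regnn_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(dir, "data.csv")
  meta_path <- file.path(dir, "meta.json")
  write.csv(sim$data, data_path, row.names = FALSE)
  meta <- list(
    seed = sim$seed,
    n = nrow(sim$data),
    snr = sim$outcomes$snr,
    noise_variance = sim$outcomes$noise_variance,
    var_M = attr(sim$outcomes, "var_M"),
    basis = sim$truth$basis,
    pairs = sim$truth$pairs,
    triplets = sim$truth$triplets,
    linear_coefs = as.list(sim$truth$linear_coefs),
    focal_coef = sim$truth$focal_coef,
    moderator_cols = sim$moderator_cols
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(data_path, meta_path))
}
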