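#' Gaussian mixture model of a (sub)population
#'
#' Full-covariance Gaussian mixture fitted by EM (via \pkg{mclust},
#' model `"VVV"`). With `k = "bic"` the number of components is chosen
#' over `1..k_max` by the Bayesian Information Criterion (the cohort
#' protocol); the simulation protocol fixes `k = 4`.
#'
#' @param X matrix or data frame of features.
#' @param k number of components, or `"bic"` for BIC selection.
#' @param k_max largest k tried under BIC selection (default 10).
#' @param seed optional integer seed.
#' @return an object of class `regnn_gmm`: `k`, `means` (k by d),
#'   `sigmas` (d by d by k), `proportions`, `loglik`, `bic`, and the
#'   underlying \pkg{mclust} fit.
#' @export
fit_gmm <- function(X, k = "bic", k_max = 10, seed = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  d <- ncol(X)
  if (identical(k, "bic")) {
    G <- seq_len(check_count(k_max, "k_max", lower = 1L))
  } else {
    G <- check_count(k, "k", lower = 1L)
    if (nrow(X) < G * (d + 1)) {
      abort(sprintf("too few rows (%d) to fit %d full-covariance components in %d dimensions",
                    nrow(X), G, d))
    }
  }
  maybe_set_seed(seed)
  model_name <- if (d == 1L) "V" else "VVV"
  fit <- suppressWarnings(
    mclust::Mclust(X, G = G, modelNames = model_name, verbose = FALSE)
  )
  if (is.null(fit)) {
    warn("degenerate covariance: refitting with a regularizing prior")
    fit <- mclust::Mclust(X, G = G, modelNames = model_name,
                          prior = mclust::priorControl(), verbose = FALSE)
    if (is.null(fit)) abort("Gaussian mixture fit failed")
  }
  kk <- fit$G
  mu <- t(matrix(fit$parameters$mean, nrow = d))
  colnames(mu) <- colnames(X)
  if (d == 1L) {
    sig <- array(fit$parameters$variance$sigmasq, dim = c(1, 1, kk))
  } else {
    sig <- fit$parameters$variance$sigma
  }
  structure(list(k = kk, means = mu, sigmas = sig,
                 proportions = fit$parameters$pro,
                 loglik = fit$loglik, bic = fit$bic, d = d,
                 n = nrow(X), model = fit),
            class = "regnn_gmm")
}

#' @export
print.regnn_gmm <- function(x, ...) {
  cat(sprintf("<regnn_gmm> %d component(s) in %d dimensions (n = %d), loglik = %.2f\n",
              x$k, x$d, x$n, x$loglik))
  invisible(x)
}

# Mahalanobis distance between two cluster means under the arithmetic
# mean of their covariance matrices; pseudo-inverse on singularity.
pair_mahalanobis <- function(mu1, mu2, S1, S2) {
  Sbar <- (S1 + S2) / 2
  delta <- mu1 - mu2
  inv <- tryCatch(solve(Sbar), error = function(e) {
    warn("singular averaged covariance: using the pseudo-inverse")
    MASS::ginv(Sbar)
  })
  sqrt(max(0, drop(t(delta) %*% inv %*% delta)))
}

#' Match clusters between two mixture models
#'
#' Computes the Mahalanobis distance between every pair of cluster means,
#' using the average of the two clusters' covariance matrices, and finds
#' the bijective assignment (on the smaller number of clusters) that
#' minimizes the total distance. The search is exhaustive over
#' permutations when that is tractable, otherwise a greedy assignment with
#' pairwise-swap refinement is used. Matched pairs with distance above
#' `cutoff` are flagged as excluded (they count as unmatched outliers in
#' the threshold-sweep trend).
#'
#' @param reference,candidate fitted `regnn_gmm` models on the same
#'   feature space.
#' @param cutoff exclusion distance (default 10).
#' @return an object of class `cluster_match`: `pairs` (tibble with
#'   `ref`, `cand`, `distance`, `excluded`), `total_distance`,
#'   `n_excluded`, and the full `distance_matrix`.
#' @export
match_clusters <- function(reference, candidate, cutoff = 10) {
  stopifnot(inherits(reference, "regnn_gmm"), inherits(candidate, "regnn_gmm"))
  if (reference$d != candidate$d) abort("models live in different feature spaces")
  kr <- reference$k
  kc <- candidate$k
  D <- matrix(0, kr, kc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      D[i, j] <- pair_mahalanobis(reference$means[i, ], candidate$means[j, ],
                                  reference$sigmas[, , i], candidate$sigmas[, , j])
    }
  }
  swap <- kr > kc
  Dm <- if (swap) t(D) else D  # rows = smaller side
  ks <- nrow(Dm); kl <- ncol(Dm)

  n_inj <- prod((kl - ks + 1):kl)
  if (n_inj <= 50000) {
    best <- NULL; best_total <- Inf
    for (inj in all_injections(ks, kl)) {
      tot <- sum(Dm[cbind(seq_len(ks), inj)])
      if (tot < best_total) { best_total <- tot; best <- inj }
    }
  } else {
    # greedy seed + 2-swap refinement
    best <- integer(ks); taken <- logical(kl)
    for (i in order(apply(Dm, 1, min))) {
      j <- which.min(ifelse(taken, Inf, Dm[i, ]))
      best[i] <- j; taken[j] <- TRUE
    }
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (a in seq_len(ks - 1)) for (b in (a + 1):ks) {
        cur <- Dm[a, best[a]] + Dm[b, best[b]]
        alt <- Dm[a, best[b]] + Dm[b, best[a]]
        if (alt < cur - 1e-12) {
          tmp <- best[a]; best[a] <- best[b]; best[b] <- tmp
          improved <- TRUE
        }
      }
    }
    best_total <- sum(Dm[cbind(seq_len(ks), best)])
  }

  pairs <- tibble::tibble(
    ref = if (swap) best else seq_len(ks),
    cand = if (swap) seq_len(ks) else best,
    distance = Dm[cbind(seq_len(ks), best)]
  ) |>
    dplyr::mutate(excluded = .data$distance > cutoff) |>
    dplyr::arrange(.data$ref)
  structure(list(pairs = pairs, total_distance = best_total,
                 n_excluded = sum(pairs$excluded), cutoff = cutoff,
                 distance_matrix = D),
            class = "cluster_match")
}

#' @export
print.cluster_match <- function(x, ...) {
  cat(sprintf("<cluster_match> %d pair(s), total distance %.3f, %d excluded (> %g)\n",
              nrow(x$pairs), x$total_distance, x$n_excluded, x$cutoff))
  print(as.data.frame(x$pairs), digits = 4)
  invisible(x)
}

#' Threshold sweep of vulnerable-subgroup clustering
#'
#' The reference mixture is fitted to the ground-truth vulnerable
#' subgroup (moderator above its `ref_quantile` quantile); then, for each
#' threshold quantile, a candidate mixture with the same number of
#' components is fitted to the index-identified subgroup and its clusters
#' are matched to the reference. Features are the supplied inputs plus
#' the (standardized) score of the respective subgroup definition. A
#' simple linear model of matched distance on threshold summarizes the
#' precision-recall trade-off; pairs beyond the exclusion cutoff are
#' tallied separately and never enter the trend.
#'
#' @param z learned index values (full sample).
#' @param M ground-truth moderator values (full sample).
#' @param features matrix or data frame of clustering inputs (full
#'   sample; typically the network inputs).
#' @param thresholds quantile thresholds on z to sweep (default the 70th
#'   to 95th percentiles in steps of 5).
#' @param k mixture components (default 4, matched one-to-one).
#' @param ref_quantile quantile defining the ground-truth subgroup
#'   (default 0.84).
#' @param cutoff exclusion distance (default 10).
#' @param include_score append the standardized score as a clustering
#'   feature (default TRUE).
#' @param seed optional integer seed.
#' @return an object of class `threshold_sweep`: `matches` (tibble with
#'   one row per matched pair per threshold), `trend` (intercept/slope
#'   with 95\% CI), `excluded_by_threshold`, and `skipped` thresholds.
#' @export
threshold_sweep <- function(z, M, features,
                            thresholds = seq(0.70, 0.95, by = 0.05),
                            k = 4, ref_quantile = 0.84, cutoff = 10,
                            include_score = TRUE, seed = NULL) {
  check_finite_vec(z, "z")
  check_finite_vec(M, "M")
  features <- as.matrix(features)
  if (length(z) != length(M) || nrow(features) != length(z)) {
    abort("`z`, `M` and `features` must cover the same rows")
  }
  maybe_set_seed(seed)

  feat_for <- function(score, mask) {
    out <- features[mask, , drop = FALSE]
    if (include_score) {
      out <- cbind(out, score = as.numeric(scale(score))[mask])
    }
    out
  }
  min_rows <- k * (ncol(features) + as.integer(include_score) + 1L)

  ref_mask <- vulnerable_mask(M, ref_quantile)$mask
  ref_gmm <- fit_gmm(feat_for(M, ref_mask), k = k)

  matches <- list(); skipped <- numeric(0)
  for (t in thresholds) {
    mask <- vulnerable_mask(z, t)$mask
    if (sum(mask) < min_rows) {
      warn(sprintf("threshold %.2f: subgroup too small (%d rows), skipped",
                   t, sum(mask)))
      skipped <- c(skipped, t)
      next
    }
    cand <- fit_gmm(feat_for(z, mask), k = k)
    cm <- match_clusters(ref_gmm, cand, cutoff = cutoff)
    matches[[length(matches) + 1L]] <-
      dplyr::mutate(cm$pairs, threshold = t, .before = 1)
  }
  if (!length(matches)) abort("every threshold was skipped")
  matches <- dplyr::bind_rows(matches)

  kept <- dplyr::filter(matches, !.data$excluded)
  trend <- if (nrow(kept) >= 3 && dplyr::n_distinct(kept$threshold) >= 2) {
    lf <- lm(distance ~ threshold, data = kept)
    sm <- summary(lf)$coefficients
    tcrit <- qt(0.975, lf$df.residual)
    tibble::tibble(
      term = c("(Intercept)", "threshold"),
      estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
      conf.low = unname(sm[, 1] - tcrit * sm[, 2]),
      conf.high = unname(sm[, 1] + tcrit * sm[, 2])
    )
  } else {
    tibble::tibble(term = character(0), estimate = numeric(0),
                   std.error = numeric(0), conf.low = numeric(0),
                   conf.high = numeric(0))
  }

  structure(list(
    matches = matches, trend = trend,
    excluded_by_threshold = matches |>
      dplyr::group_by(.data$threshold) |>
      dplyr::summarise(n_excluded = sum(.data$excluded), .groups = "drop"),
    skipped = skipped, k = k, cutoff = cutoff,
    ref_quantile = ref_quantile, reference = ref_gmm
  ), class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> %d threshold(s), k = %d, %d pair(s) matched, %d excluded (> %g)\n",
              dplyr::n_distinct(x$matches$threshold), x$k,
              nrow(x$matches), sum(x$matches$excluded), x$cutoff))
  if (nrow(x$trend)) {
    sl <- x$trend[x$trend$term == "threshold", ]
    cat(sprintf("  distance-vs-threshold slope: %.3f [%.3f, %.3f]\n",
                sl$estimate, sl$conf.low, sl$conf.high))
  }
  invisible(x)
}
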