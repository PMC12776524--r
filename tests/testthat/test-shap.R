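test_that("attributions of a linear model match the closed form exactly", {
  set.seed(1)
  q <- 6
  b <- rnorm(q)
  f <- function(X) drop(as.matrix(X) %*% b)
  bg <- matrix(rnorm(50 * q), 50, q)
  ev <- matrix(rnorm(4 * q), 4, q)
  A <- shap_values(f, ev, bg, n_perm = 2, seed = 1)
  closed <- sweep(ev, 2, colMeans(bg)) * rep(b, each = 4)
  expect_equal(unname(A), unname(closed), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("attributions satisfy the efficiency (local additivity) axiom", {
  set.seed(2)
  net <- mlp_init(c(5, 8, 1), seed = 3)
  f <- function(X) mlp_forward(net, X)
  bg <- matrix(rnorm(40 * 5), 40, 5)
  ev <- matrix(rnorm(6 * 5), 6, 5)
  A <- shap_values(f, ev, bg, n_perm = 3, seed = 2)
  expect_equal(rowSums(A), f(ev) - attr(A, "baseline"), tolerance = 1e-10)
})

test_that("cross-validated importance follows the folds x reps protocol", {
  set.seed(3)
  X <- matrix(rnorm(300 * 4), 300, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  b <- c(2, -1, 0.5, 0)
  rep_z <- shap_importance_cv(X, predictor = function(M) drop(as.matrix(M) %*% b),
                              folds = 5, reps = 2, n_background = 30,
                              n_eval = 20, n_perm = 2, seed = 4)
  expect_equal(nrow(rep_z$estimates), 4 * 5 * 2)  # per feature x fold x rep
  counts <- dplyr::count(rep_z$estimates, feature)
  expect_true(all(counts$n == 10))
  # the strongest planted signal ranks first, the null feature last
  expect_equal(rep_z$summary$feature[1], "f1")
  expect_equal(rep_z$summary$feature[4], "f4")

  expect_error(
    shap_importance_cv(X, predictor = function(M) rowSums(M),
                       folds = 5, reps = 1, n_eval = 500),
    "n_eval"
  )
  expect_error(shap_importance_cv(X, folds = 2), "exactly one")
})

test_that("normalization maps to [0, 1], is idempotent, and checks its input", {
  set.seed(5)
  X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  rep0 <- shap_importance_cv(X, predictor = function(M) drop(M %*% c(2, 1, 0.5)),
                             folds = 2, reps = 2, n_background = 30,
                             n_eval = 20, n_perm = 2, seed = 6)
  nm <- normalize_shap(rep0)
  expect_equal(nm$max_abs, 1)
  expect_true(all(nm$estimates$mean_abs >= 0 & nm$estimates$mean_abs <= 1))
  expect_equal(nm$estimates$mean_abs, rep0$estimates$mean_abs / rep0$max_abs)
  nm2 <- normalize_shap(nm)
  expect_equal(nm2$summary$estimate, nm$summary$estimate)

  rep_zero <- rep0
  rep_zero$max_abs <- 0
  expect_error(normalize_shap(rep_zero), "zero")
})

test_that("rank discrepancy matches enumeration oracles", {
  r <- setNames(1:10, letters[1:10])
  expect_equal(rank_discrepancy(r, r, top_k = 10), 0)
  rev_r <- setNames(11 - (1:10), letters[1:10])
  expect_equal(rank_discrepancy(r, rev_r, top_k = 10), 5.0)
  expect_error(rank_discrepancy(r, rev_r, top_k = 11), "top_k")

  # identical reports have zero discrepancy
  set.seed(7)
  X <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, paste0("f", 1:4)))
  rp <- shap_importance_cv(X, predictor = function(M) drop(M %*% c(3, 2, 1, 0.1)),
                           folds = 2, reps = 2, n_background = 25,
                           n_eval = 15, n_perm = 2, seed = 8)
  expect_equal(rank_discrepancy(rp, rp, top_k = 4), 0)
})

test_that("the ground-truth moderator function reproduces the planted M", {
  sim <- small_sim()
  f <- moderator_function(sim$truth, sim$design)
  expect_equal(f(sim$design$encoded), sim$truth$M, tolerance = 1e-12)
})

test_that("importance of the planted moderator concentrates on its inputs", {
  sim <- small_sim()
  f <- moderator_function(sim$truth, sim$design)
  rp <- shap_importance_cv(sim$design$encoded, predictor = f,
                           folds = 2, reps = 2, n_background = 60,
                           n_eval = 30, n_perm = 3, seed = 9)
  used <- unique(c(sim$truth$pairs$i, sim$truth$pairs$j,
                   sim$truth$triplets$i, sim$truth$triplets$j,
                   sim$truth$triplets$k))
  basis_names <- if (sim$truth$basis == "raw") {
    colnames(raw_matrix(sim$design))
  } else {
    colnames(sim$design$encoded)
  }
  used_raw <- basis_names[used]
  meta <- sim$design$meta
  used_names <- unique(c(used_raw,
                         unlist(meta$encoded[meta$name %in% used_raw])))
  # every feature with nonzero importance encodes a planted input
  nonzero <- rp$summary$feature[rp$summary$estimate > 1e-8]
  expect_true(all(nonzero %in% used_names))
})

test_that("partial dependence is flat for constants and linear for linear maps", {
  X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  pd_const <- partial_dependence(function(M) rep(2, nrow(M)), "a", data = X,
                                 grid = c(-1, 0, 1))
  expect_equal(pd_const$estimate, rep(2, 3))

  b <- c(0.7, -0.3, 0.1)
  pd_lin <- partial_dependence(function(M) drop(M %*% b), "a", data = X,
                               grid = c(-2, 0, 2))
  slopes <- diff(pd_lin$estimate) / diff(pd_lin$value)
  expect_equal(slopes, rep(0.7, 2), tolerance = 1e-8)

  expect_error(partial_dependence(function(M) rowSums(M), "zz", data = X),
               "not an input")
})

test_that("partial dependence of a fitted index runs over its moderators", {
  fit <- medium_fit()
  pd <- partial_dependence(fit, fit$cols$moderators[1], n_grid = 5)
  expect_equal(nrow(pd), 5L)
  expect_true(all(is.finite(pd$estimate)))
})
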