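test_that("covariance construction is symmetric, PSD, unit-diagonal", {
  S <- build_covariance(31, 0.6, seed = 3)
  expect_equal(dim(S), c(31, 31))
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 31))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)

  # no off-diagonal mass -> identity
  expect_equal(build_covariance(5, 0, seed = 1), diag(5))

  # 2x2 with a single off-diagonal r has eigenvalues 1 +/- |r|
  S2 <- build_covariance(2, 1, seed = 9)
  r <- S2[1, 2]
  expect_true(abs(r) > 0)
  ev2 <- eigen(S2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev2), sort(c(1 - abs(r), 1 + abs(r))), tolerance = 1e-12)

  expect_error(build_covariance(1), "n_vars")
})

test_that("base sampling is seeded and matches the target covariance", {
  X1 <- sample_base(diag(4), 50, seed = 11)
  X2 <- sample_base(diag(4), 50, seed = 11)
  expect_identical(X1, X2)
  expect_equal(dim(X1), c(50, 4))

  # law-of-large-numbers check against the identity
  Xb <- sample_base(diag(5), 10000, seed = 2)
  expect_lt(max(abs(cov(Xb) - diag(5))), 0.05)

  bad <- matrix(c(1, 2, 2, 1), 2)  # eigenvalues 3, -1
  expect_error(sample_base(bad, 10), "positive semidefinite")
})

test_that("default mixed-type plan yields the reference encoded design", {
  sim <- small_sim()
  d <- sim$design
  expect_equal(as.integer(table(d$meta$type)[c("continuous", "binary", "categorical", "ordinal")]),
               c(16L, 7L, 5L, 3L))
  expect_equal(ncol(d$encoded), 35L)  # 15 + 7 + 5*2 + 3
  # indicators are 0/1
  dum <- d$encoded[, grepl("_L", colnames(d$encoded))]
  expect_true(all(dum %in% c(0, 1)))
  # focal column excluded from the encoded matrix
  expect_false("x1" %in% colnames(d$encoded))
})

test_that("binary thresholding at 0 halves a standard normal column", {
  X <- sample_base(diag(3), 10000, seed = 4)
  plan <- tibble::tibble(column = 1:3,
                         type = c("continuous", "binary", "continuous"),
                         cutpoints = list(numeric(0), 0, numeric(0)))
  d <- discretize_and_encode(X, plan, focal_index = 1)
  expect_equal(mean(d$encoded[, "x2"]), 0.5, tolerance = 0.02)
})

test_that("all-continuous plan passes the base through minus the focal", {
  X <- sample_base(diag(4), 30, seed = 5)
  d <- discretize_and_encode(X, focal_index = 2)
  expect_equal(unname(d$encoded), unname(X[, -2]))
  expect_equal(d$focal, X[, 2])
})

test_that("one-hot encoding round-trips the raw categorical labels", {
  sim <- small_sim()
  cat_cols <- sim$design$meta$column[sim$design$meta$type == "categorical"]
  for (k in cat_cols) {
    expect_identical(decode_column(sim$design, k),
                     as.character(sim$design$raw[[paste0("x", k)]]))
  }
})

test_that("a non-continuous focal column is rejected", {
  X <- sample_base(diag(3), 20, seed = 6)
  plan <- tibble::tibble(column = 1:3,
                         type = c("binary", "continuous", "continuous"),
                         cutpoints = list(0, numeric(0), numeric(0)))
  expect_error(discretize_and_encode(X, plan, focal_index = 1), "continuous")
})

test_that("planted moderator follows its stored pair/triplet structure", {
  sim <- small_sim()
  tr <- sim$truth
  expect_equal(nrow(tr$pairs), 5L)
  expect_equal(nrow(tr$triplets), 5L)
  w <- c(tr$pairs$weight, tr$triplets$weight)
  expect_true(all(abs(w) >= 0.05 & abs(w) <= 0.3))
  # M recomputes exactly from the stored terms
  expect_identical(tr$M, moderator_from_terms(tr, sim$design))

  # no terms -> identically zero
  empty <- build_moderator(sim$design, 0, 0, seed = 1)
  expect_identical(empty$M, rep(0, 600))
})

test_that("outcome noise variance scales as var(M)/SNR and decomposes exactly", {
  sim <- small_sim()
  vM <- var(sim$truth$M)
  for (i in seq_len(nrow(sim$outcomes))) {
    rec <- sim$outcomes[i, ]
    expect_lt(abs(rec$noise_variance - vM / rec$snr) / (vM / rec$snr), 1e-10)
    # conservation: o - noise - linear part - M*xf == 0
    recon <- attr(sim$outcomes, "linear_part") +
      sim$truth$M * sim$design$focal + rec$noise[[1]]
    expect_equal(rec$outcome[[1]], recon, tolerance = 1e-12)
  }
  # Var(noise)*SNR/var(M) == 1 holds by construction of sigma^2
  expect_equal(sim$outcomes$noise_variance * sim$outcomes$snr / vM,
               rep(1, nrow(sim$outcomes)), tolerance = 1e-10)
  expect_error(generate_outcomes(sim$design, sim$truth, snr = -1), "positive")
})

test_that("two-row hand case reproduces the outcome equation", {
  X <- matrix(c(1, 2, -1, 0.5, 3, -2), nrow = 2)  # 2 x 3
  d <- discretize_and_encode(X, focal_index = 1)
  tr <- build_moderator(d, 1, 0, seed = 2)
  out <- generate_outcomes(d, tr, snr = 1000, seed = 2)
  i <- tr$pairs$i[1]; j <- tr$pairs$j[1]; w <- tr$pairs$weight[1]
  M_hand <- w * d$encoded[, i] * d$encoded[, j]
  o_hand <- drop(d$encoded %*% tr$linear_coefs) + tr$focal_coef * d$focal +
    M_hand * d$focal + out$noise[[1]]
  expect_equal(out$outcome[[1]], o_hand, tolerance = 1e-12)
})

test_that("vulnerable mask flags the expected share above the quantile", {
  set.seed(8)
  score <- rnorm(8000)
  part <- vulnerable_mask(score, 0.84)
  # sort-based oracle: with distinct values, the rows strictly above the
  # interpolated 84th percentile are the top n - floor((n-1)*q + 1)
  oracle <- 8000 - floor((8000 - 1) * 0.84 + 1)
  expect_lte(abs(sum(part$mask) - oracle), 1)
  expect_identical(part$mask, score > part$cutoff)

  expect_warning(p0 <- vulnerable_mask(rep(1, 10), 0.5), "constant")
  expect_equal(sum(p0$mask), 0L)
})

test_that("identical seeds reproduce the full simulated dataset bit-for-bit", {
  s1 <- simulate_regnn_data(n = 150, snr = c(2, 0.5), seed = 99)
  s2 <- simulate_regnn_data(n = 150, snr = c(2, 0.5), seed = 99)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth$pairs, s2$truth$pairs)
  expect_identical(s1$covariance, s2$covariance)
})

test_that("simulated datasets round-trip through the CSV writer", {
  sim <- simulate_regnn_data(n = 40, snr = 1, seed = 13)
  dir <- withr::local_tempdir()
  paths <- write_regnn_sim(sim, dir)
  back <- read.csv(paths[1], check.names = FALSE)
  expect_equal(nrow(back), 40L)
  expect_equal(back$M, sim$truth$M, tolerance = 1e-12)
  meta <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(meta$n, 40L)
  expect_equal(meta$pairs$weight, sim$truth$pairs$weight, tolerance = 1e-12)
})
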