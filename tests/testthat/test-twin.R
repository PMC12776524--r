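test_that("twin fit recovers noiseless coefficients exactly", {
  set.seed(1)
  n <- 200
  df <- tibble::tibble(xf = rnorm(n), z = rnorm(n))
  df$y <- 1 + 2 * df$xf + 0.5 * df$z * df$xf
  tw <- fit_twin(df, outcome = "y", focal = "xf", index = "z")
  est <- setNames(tw$table$estimate, tw$table$term)
  expect_equal(est[["(Intercept)"]], 1, tolerance = 1e-8)
  expect_equal(est[["xf"]], 2, tolerance = 1e-8)
  expect_equal(est[["z"]], 0, tolerance = 1e-8)
  expect_equal(est[["xf:z"]], 0.5, tolerance = 1e-8)
})

test_that("twin fit matches a normal-equations + textbook-formula oracle", {
  set.seed(2)
  for (rep in 1:5) {
    n <- 20
    df <- tibble::tibble(a = rnorm(n), b = rnorm(n), xf = rnorm(n),
                         z = rnorm(n))
    df$y <- rnorm(n)
    tw <- fit_twin(df, outcome = "y", focal = "xf", index = "z",
                   linear = c("a", "b"))
    X <- cbind(1, df$a, df$b, df$xf, df$z, df$xf * df$z)
    bhat <- solve(t(X) %*% X, t(X) %*% df$y)
    resid <- df$y - X %*% bhat
    s2 <- sum(resid^2) / (n - ncol(X))
    se <- sqrt(diag(s2 * solve(t(X) %*% X)))
    expect_equal(tw$table$estimate, drop(bhat), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(tw$table$std.error, se, tolerance = 1e-10,
                 ignore_attr = TRUE)
    # t = coef/SE and two-sided p from the t distribution
    expect_equal(tw$table$statistic, tw$table$estimate / tw$table$std.error,
                 tolerance = 1e-12)
    expect_equal(tw$table$p.value,
                 2 * pt(abs(tw$table$statistic), n - ncol(X), lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("constant index triggers a rank-deficiency error naming the term", {
  set.seed(3)
  df <- tibble::tibble(xf = rnorm(50), z = 1)
  df$y <- rnorm(50)
  expect_error(fit_twin(df, outcome = "y", focal = "xf", index = "z"),
               "collinear")
})

test_that("MMR recovers a planted single-moderator interaction", {
  set.seed(4)
  n <- 300
  df <- tibble::tibble(x1 = rnorm(n), xf = rnorm(n))
  df$y <- 0.5 + 0.3 * df$x1 + 1.2 * df$xf + 0.7 * df$x1 * df$xf
  mm <- fit_mmr(df, outcome = "y", focal = "xf", moderators = "x1",
                center = FALSE)
  est <- setNames(mm$table$estimate, mm$table$term)
  expect_equal(est[["xf:x1"]], 0.7, tolerance = 1e-8)

  # centering changes main effects but not interaction coefficients
  mm_c <- fit_mmr(df, outcome = "y", focal = "xf", moderators = "x1",
                  center = TRUE)
  est_c <- setNames(mm_c$table$estimate, mm_c$table$term)
  expect_equal(est_c[["xf:x1"]], est[["xf:x1"]], tolerance = 1e-8)
  expect_false(isTRUE(all.equal(est_c[["xf"]], est[["xf"]], tolerance = 1e-4)))

  # no moderators reduces to a simple regression on the exposure
  mm0 <- fit_mmr(df, outcome = "y", focal = "xf", moderators = character(0))
  expect_setequal(mm0$table$term, c("(Intercept)", "xf"))
})

test_that("marginal effect is cn + cint * z and matches finite differences", {
  set.seed(5)
  n <- 200
  df <- tibble::tibble(xf = rnorm(n), z = rnorm(n))
  df$y <- 1 + 1 * df$xf + 0.5 * df$z * df$xf + 0.1 * rnorm(n)
  tw <- fit_twin(df, outcome = "y", focal = "xf", index = "z")
  est <- setNames(tw$table$estimate, tw$table$term)
  me <- marginal_effect(tw, c(-1, 0, 2))
  expect_equal(me$estimate, est[["xf"]] + est[["xf:z"]] * c(-1, 0, 2),
               tolerance = 1e-12, ignore_attr = TRUE)

  # central finite differences of the fitted surface
  h <- 1e-5
  zs <- runif(5, -2, 2)
  for (zv in zs) {
    surf <- function(xfv) {
      est[["(Intercept)"]] + est[["xf"]] * xfv + est[["z"]] * zv +
        est[["xf:z"]] * xfv * zv
    }
    fd <- (surf(1 + h) - surf(1 - h)) / (2 * h)
    expect_equal(marginal_effect(tw, zv)$estimate, fd, tolerance = 1e-8)
  }
})

test_that("VIF equals 1/(1 - R2) and flags exact collinearity", {
  # orthogonal mean-zero columns -> all VIFs exactly 1
  P <- poly(1:50, 3)
  expect_equal(unname(vif(P)), rep(1, 3), tolerance = 1e-10)

  set.seed(6)
  X <- matrix(rnorm(250), 50, 5)
  colnames(X) <- paste0("v", 1:5)
  v <- vif(X)
  for (j in 1:5) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-10)
  }

  Xd <- cbind(X, dup = X[, 1])
  expect_true(is.infinite(vif(Xd)[["dup"]]))
})

test_that("predicted profiles coincide without moderation and respect the delta method", {
  set.seed(7)
  n <- 400
  df <- tibble::tibble(xf = rnorm(n), z = rnorm(n))
  df$y <- 1 + 2 * df$xf               # neither moderation nor index effect
  tw0 <- fit_twin(df, outcome = "y", focal = "xf", index = "z")
  pr0 <- predict_profiles(tw0, xf_grid = c(-1, 0, 1))
  spread <- pr0 |>
    dplyr::group_by(xf) |>
    dplyr::summarise(d = max(fit) - min(fit))
  expect_lt(max(spread$d), 1e-6)

  # with moderation: three profiles, delta-method CI vs parametric bootstrap
  df$y <- 1 + 2 * df$xf + 0.3 * df$z + 0.5 * df$z * df$xf + rnorm(n, 0, 0.5)
  tw <- fit_twin(df, outcome = "y", focal = "xf", index = "z")
  pr <- predict_profiles(tw, xf_grid = c(0.7))
  expect_equal(nrow(pr), 3L)
  expect_error(predict_profiles(tw, z_levels = c(0, 50)), "percentiles")

  cf <- coef(tw$lm); V <- vcov(tw$lm)
  set.seed(8)
  draws <- MASS::mvrnorm(1e4, cf, V)
  zq <- quantile(df$z, 0.9, type = 7)
  xrow <- c(1, 0.7, zq, 0.7 * zq)
  boot_sd <- sd(draws %*% xrow)
  row90 <- pr[pr$z_level == 90, ]
  expect_equal(row90$std.error, boot_sd, tolerance = 0.05)
})

test_that("sensitivity probe reports the held-out interaction p-value", {
  fit <- medium_fit()
  pr <- sensitivity_probe(fit)
  tw <- fit_twin(fit, subset = "sensitivity")
  expect_identical(pr$p_value,
                   tw$table$p.value[tw$table$term == "xf:z"])
  expect_equal(pr$n, length(fit$split$sensitivity))

  # too-small probe subset errors
  sim <- small_sim()
  tiny <- regnn(sim, snr = 5, epochs = 2,
                split = c(train = 0.8, sensitivity = 0.01), seed = 1)
  expect_error(sensitivity_probe(tiny), "rows")
})

test_that("tidy and glance return the standard inference columns", {
  fit <- medium_fit()
  tw <- fit_twin(fit, subset = "train")
  td <- tidy(tw)
  expect_true(all(c("term", "estimate", "std.error", "statistic", "p.value",
                    "conf.low", "conf.high", "vif") %in% names(td)))
  gl <- glance(tw)
  expect_true(all(c("r.squared", "adj.r.squared", "sigma", "nobs") %in% names(gl)))
  expect_equal(gl$nobs, length(fit$split$train))
  td1 <- tidy(fit)
  expect_equal(nrow(td1), 35 + 3)
})
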