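test_that("network initialization has the right parameter count and is seeded", {
  net <- mlp_init(c(35, 60, 32, 1), seed = 1)
  # enumeration: (35*60 + 60) + (60*32 + 32) + (32*1 + 1)
  expect_equal(n_params(net), 35 * 60 + 60 + 60 * 32 + 32 + 32 * 1 + 1)
  expect_equal(n_params(net), 4145L)
  net2 <- mlp_init(c(35, 60, 32, 1), seed = 1)
  expect_identical(net$W, net2$W)
  expect_identical(net$b, net2$b)
  expect_error(mlp_init(c(10, 0, 1)), "positive")
  expect_error(mlp_init(c(10, 5, 2)), "width 1")
})

test_that("forward pass matches hand matrix arithmetic", {
  net <- mlp_init(c(2, 2, 1), seed = 3)
  net$W[[1]] <- matrix(c(1, -1, 0.5, 2), 2, 2)  # out x in
  net$b[[1]] <- c(0.1, -0.2)
  net$W[[2]] <- matrix(c(1, 0.5), 1, 2)
  net$b[[2]] <- 0.3
  x <- c(0.4, -0.7)
  h <- pmax(net$W[[1]] %*% x + net$b[[1]], 0)
  manual <- drop(net$W[[2]] %*% h + net$b[[2]])
  expect_equal(mlp_forward(net, matrix(x, 1)), manual, tolerance = 1e-12)
  # two identical rows give identical outputs
  z <- mlp_forward(net, rbind(x, x))
  expect_identical(z[1], z[2])
})

test_that("weighted MSE follows its definition", {
  expect_equal(weighted_mse(c(1, 2), c(3, 2), c(1, 3)), 1.0)  # (1*4 + 3*0)/4
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(weighted_mse(x, y), mean((x - y)^2))           # equal weights
  expect_equal(weighted_mse(y, y), 0)
  expect_error(weighted_mse(x, y, rep(0, 20)), "zero")
  expect_error(weighted_mse(x, y[-1]), "length")
})

test_that("zero learning rates leave all parameters at their initial values", {
  sim <- small_sim()
  fit <- regnn(sim, snr = 5, epochs = 3, lr_regression = 0, lr_network = 0,
               seed = 1)
  expect_equal(fit$coefficients$c0, 0)
  expect_equal(unname(fit$coefficients$linear), rep(0, 35))
  expect_equal(fit$coefficients$cn, 0)
  expect_equal(fit$coefficients$cint, 0)
})

test_that("training reduces the loss (descent property over several seeds)", {
  sim <- small_sim()
  for (s in 1:3) {
    fit <- regnn(sim, snr = 5, epochs = 30, seed = s)
    late <- mean(utils::tail(fit$trace$loss, 10))
    expect_lt(late, fit$trace$loss[1])
  }
})

test_that("the index is deterministic and seeded fits reproduce exactly", {
  sim <- small_sim()
  f1 <- regnn(sim, snr = 5, epochs = 5, seed = 21)
  f2 <- regnn(sim, snr = 5, epochs = 5, seed = 21)
  expect_identical(f1$z, f2$z)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(compute_index(f1), compute_index(f1))
  # index depends only on the moderator inputs
  nd <- sim$data[c(3, 3, 8), ]
  z <- compute_index(f1, nd)
  expect_identical(z[1], z[2])
})

test_that("a noiseless linear moderator is recovered almost perfectly", {
  df <- linear_truth_data(n = 800, a = 1, seed = 5)
  fit <- regnn(df, outcome = "y", focal = "xf",
               moderators = c("x1", "x2", "x3"),
               hidden = c(16, 8), dropout = 0, epochs = 150, batch_size = 50,
               seed = 2)
  expect_gt(abs(cor(fit$z, df$x1)), 0.99)
  # canonical orientation: cint nonnegative, z aligned with the moderator
  expect_gte(fit$coefficients$cint, 0)
  expect_gt(cor(fit$z, df$x1), 0.99)
})

test_that("shifting the outcome by a constant moves only the intercept", {
  df <- linear_truth_data(n = 800, a = 1, seed = 6)
  df2 <- dplyr::mutate(df, y = y + 3)
  f1 <- regnn(df, outcome = "y", focal = "xf",
              moderators = c("x1", "x2", "x3"), hidden = c(16, 8),
              dropout = 0, epochs = 300, batch_size = 50, seed = 3)
  f2 <- regnn(df2, outcome = "y", focal = "xf",
              moderators = c("x1", "x2", "x3"), hidden = c(16, 8),
              dropout = 0, epochs = 300, batch_size = 50, seed = 3)
  expect_lt(abs((f2$coefficients$c0 - f1$coefficients$c0) - 3), 0.1)
  expect_lt(max(abs(f2$coefficients$linear - f1$coefficients$linear)), 0.1)
  expect_lt(abs(f2$coefficients$cn - f1$coefficients$cn), 0.1)
})

test_that("step-1 predictions agree with the twin regression at convergence", {
  fit <- medium_fit()
  tw <- fit_twin(fit, subset = "train")
  step1 <- predict(fit)[fit$split$train]
  expect_gt(cor(step1, fitted(tw$lm)), 0.99)
})

test_that("regression-coefficient magnitude stabilizes late in training", {
  fit <- medium_fit()
  tail_l2 <- utils::tail(fit$trace$reg_l2, 20)
  expect_lt(sd(tail_l2) / mean(tail_l2), 0.05)
})

test_that("fit configuration is validated", {
  sim <- small_sim()
  expect_error(regnn(sim, snr = 5, batch_size = 1e5, seed = 1), "batch_size")
  expect_error(regnn(sim, snr = 99), "snr")
  df <- linear_truth_data(100)
  expect_error(
    regnn(df, outcome = "y", focal = "xf", moderators = c("x1", "nope")),
    "nope"
  )
  expect_error(
    regnn(df, outcome = "y", focal = "xf", moderators = c("x1", "xf")),
    "focal"
  )
})

test_that("weighted training honours sample weights in the loss", {
  df <- linear_truth_data(n = 400, seed = 9)
  df$w <- exp(rnorm(400, 0, 0.5))
  fit <- regnn(df, outcome = "y", focal = "xf",
               moderators = c("x1", "x2", "x3"), hidden = c(8),
               dropout = 0, epochs = 40, batch_size = 50,
               weights = "w", seed = 4)
  tr <- fit$split$train
  wmse <- weighted_mse(predict(fit)[tr], df$y[tr], df$w[tr])
  expect_lt(wmse, var(df$y))  # fit explains most weighted variance
  expect_true(all(is.finite(fit$trace$loss)))
})
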