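#' Fit a regression-guided neural network
#'
#' Jointly trains the outer regression and the embedded multi-layer
#' perceptron by mini-batch gradient descent on the (optionally weighted)
#' mean squared error of
#' \deqn{\hat o = c_0 + \sum_k c_k x_k + c_n x_f + c_{int}\, f(X_p)\, x_f,}
#' where \eqn{f} is the network and \eqn{X_p} the moderator inputs. The
#' regression coefficients and the network parameters are updated with
#' distinct learning rates; dropout is applied to hidden activations during
#' training only. Rows are split once, before training, into a training
#' set, a small held-out sensitivity set (used by [sensitivity_probe()]),
#' and a holdout remainder.
#'
#' After training the index is canonicalized: the sign of the output layer
#' and of \eqn{c_{int}} are flipped together if needed so that
#' \eqn{c_{int} \ge 0}, i.e. larger index values always mean a larger
#' marginal effect of the exposure ("more vulnerable"). The flip leaves
#' every prediction unchanged.
#'
#' @param data a data frame, or a `regnn_sim` (see
#'   [simulate_regnn_data()]; then `snr` selects the outcome column and
#'   moderator columns are filled in automatically).
#' @param ... passed between methods.
#' @param outcome,focal column names (length-1 character) of the outcome
#'   and the focal exposure.
#' @param moderators character vector of moderator-input columns (the
#'   network inputs).
#' @param linear character vector of columns entering the linear part;
#'   defaults to `moderators`.
#' @param hidden hidden-layer widths (default `c(60, 32)`).
#' @param dropout dropout proportion on hidden activations (default 0.2).
#' @param epochs,batch_size training budget (defaults 100 and 50).
#' @param lr_regression,lr_network learning rates for the two parameter
#'   groups (defaults 0.01 and 0.003).
#' @param weight_decay L2 penalty applied to network weights only
#'   (default 0).
#' @param optimizer `"adam"` (default) or `"sgd"` (stochastic gradient
#'   descent with classical momentum; set `momentum = 0` for plain SGD).
#'   With the default learning rates and epoch budget, plain SGD leaves
#'   the joint fit far from convergence; Adam reaches the converged
#'   regime the method's workflow assumes (see the methods vignette).
#' @param momentum momentum coefficient for `optimizer = "sgd"`
#'   (default 0.9; ignored by Adam).
#' @param weights optional column name of nonnegative sample weights
#'   (e.g. survey weights); the loss becomes the weighted MSE.
#' @param split named fractions `c(train = , sensitivity = )` summing to
#'   at most 1; the remainder is the holdout (defaults 0.80 / 0.02).
#' @param standardize standardize non-binary inputs (and the exposure) to
#'   train-split mean/SD before fitting (default TRUE).
#' @param seed optional integer seed governing split, initialization,
#'   batch order, and dropout.
#' @param trace_with optional numeric vector (one value per row of `data`,
#'   e.g. a known ground-truth moderator): the correlation between the
#'   index and this vector is recorded every epoch.
#' @return an object of class `regnn` with, among others, `coefficients`
#'   (`c0`, `linear`, `cn`, `cint`), `network` (a `regnn_mlp`), `z` (the
#'   learned index for every row), `trace` (per-epoch tibble), and `split`
#'   (row indices).
#' @seealso [fit_twin()], [sensitivity_probe()], [compute_index()]
#' @export
regnn <- function(data, ...) UseMethod("regnn")

#' @rdname regnn
#' @param snr which simulated outcome to model (a value of the simulation's
#'   SNR grid).
#' @export
regnn.regnn_sim <- function(data, snr, ..., trace_with = data$truth$M) {
  ycol <- paste0("y_snr_", snr)
  if (!ycol %in% names(data$data)) {
    abort(sprintf("no outcome at snr = %s in this simulation", format(snr)))
  }
  regnn(data$data, outcome = ycol, focal = "xf",
        moderators = data$moderator_cols, trace_with = trace_with, ...)
}

#' @rdname regnn
#' @export
regnn.data.frame <- function(data, outcome, focal, moderators,
                             linear = moderators,
                             hidden = c(60, 32), dropout = 0.2,
                             epochs = 100, batch_size = 50,
                             lr_regression = 0.01, lr_network = 0.003,
                             weight_decay = 0,
                             optimizer = c("adam", "sgd"), momentum = 0.9,
                             weights = NULL,
                             split = c(train = 0.8, sensitivity = 0.02),
                             standardize = TRUE, seed = NULL,
                             trace_with = NULL, ...) {
  optimizer <- match.arg(optimizer)
  epochs <- check_count(epochs, "epochs", lower = 0L)
  batch_size <- check_count(batch_size, "batch_size", lower = 1L)
  check_number(dropout, "dropout", 0, 1 - 1e-12)
  check_number(lr_regression, "lr_regression", lower = 0)
  check_number(lr_network, "lr_network", lower = 0)
  check_number(weight_decay, "weight_decay", lower = 0)
  for (cn in c(outcome, focal, moderators, linear, weights)) {
    if (!cn %in% names(data)) abort(sprintf("column `%s` not found in `data`", cn))
  }
  if (focal %in% moderators) abort("the focal exposure cannot be a moderator input")
  if (sum(split) > 1 + 1e-12) abort("`split` fractions must sum to at most 1")
  n <- nrow(data)
  y <- check_finite_vec(as.numeric(data[[outcome]]), "outcome")
  xf <- check_finite_vec(as.numeric(data[[focal]]), "focal")
  Xp <- as.matrix(data[moderators])
  Xl <- as.matrix(data[linear])
  w <- if (is.null(weights)) rep(1, n) else as.numeric(data[[weights]])
  if (any(w < 0) || sum(w) <= 0) abort("sample weights must be nonnegative, not all zero")
  if (!is.null(trace_with) && length(trace_with) != n) {
    abort("`trace_with` must have one value per row of `data`")
  }

  maybe_set_seed(seed)

  # ---- split drawn once, before any training
  idx <- sample.int(n)
  n_train <- floor(split[["train"]] * n)
  n_sens <- floor((split[["sensitivity"]] %||% 0) * n)
  if (n_train < batch_size) abort("`batch_size` exceeds the training-split size")
  split_idx <- list(
    train = sort(idx[seq_len(n_train)]),
    sensitivity = sort(idx[n_train + seq_len(n_sens)]),
    holdout = sort(idx[-seq_len(n_train + n_sens)])
  )

  # ---- standardization from the training split (non-binary columns)
  scale_mat <- function(X, centers, scales) {
    sweep(sweep(X, 2, centers, "-"), 2, scales, "/")
  }
  tr <- split_idx$train
  if (standardize) {
    is_bin <- apply(Xp, 2, function(v) all(v %in% c(0, 1)))
    p_center <- ifelse(is_bin, 0, colMeans(Xp[tr, , drop = FALSE]))
    p_scale <- ifelse(is_bin, 1, apply(Xp[tr, , drop = FALSE], 2, sd))
    p_scale[p_scale == 0 | !is.finite(p_scale)] <- 1
    is_bin_l <- apply(Xl, 2, function(v) all(v %in% c(0, 1)))
    l_center <- ifelse(is_bin_l, 0, colMeans(Xl[tr, , drop = FALSE]))
    l_scale <- ifelse(is_bin_l, 1, apply(Xl[tr, , drop = FALSE], 2, sd))
    l_scale[l_scale == 0 | !is.finite(l_scale)] <- 1
    f_center <- mean(xf[tr]); f_scale <- sd(xf[tr])
    if (!is.finite(f_scale) || f_scale == 0) f_scale <- 1
  } else {
    p_center <- rep(0, ncol(Xp)); p_scale <- rep(1, ncol(Xp))
    l_center <- rep(0, ncol(Xl)); l_scale <- rep(1, ncol(Xl))
    f_center <- 0; f_scale <- 1
  }
  Xp_s <- scale_mat(Xp, p_center, p_scale)
  Xl_s <- scale_mat(Xl, l_center, l_scale)
  xf_s <- (xf - f_center) / f_scale

  # ---- initialize: fan-in-scaled network, zero regression coefficients
  layer_sizes <- c(ncol(Xp), hidden, 1L)
  net <- mlp_init(layer_sizes)
  m <- ncol(Xl)
  reg0 <- rep(0, m + 3L)

  fit <- .regnn_train_cpp(
    Xl_s[tr, , drop = FALSE], xf_s[tr], Xp_s[tr, , drop = FALSE], y[tr],
    w[tr], net$W, net$b, reg0,
    dropout, lr_regression, lr_network, weight_decay,
    epochs, batch_size, optimizer,
    if (optimizer == "sgd") momentum else 0,
    if (is.null(trace_with)) matrix(0, 0, ncol(Xp)) else Xp_s,
    if (is.null(trace_with)) numeric(0) else as.numeric(trace_with)
  )
  net$W <- fit$W
  net$b <- fit$b
  reg <- drop(fit$reg)
  c0 <- reg[1]
  beta <- setNames(reg[1 + seq_len(m)], linear)
  cn <- reg[m + 2]
  cint <- reg[m + 3]

  # ---- orientation: flip the output layer and cint together so cint >= 0
  orientation <- 1
  if (cint < 0) {
    orientation <- -1
    L <- length(net$W)
    net$W[[L]] <- -net$W[[L]]
    net$b[[L]] <- -net$b[[L]]
    cint <- -cint
  }
  z <- drop(.mlp_forward_cpp(net$W, net$b, Xp_s))

  trace <- tibble::tibble(
    epoch = seq_len(epochs),
    loss = drop(fit$loss),
    reg_l2 = drop(fit$reg_l2)
  )
  if (!is.null(trace_with)) trace$rho <- orientation * drop(fit$rho)

  out <- list(
    coefficients = list(c0 = c0, linear = beta, cn = cn, cint = cint),
    network = net,
    z = z,
    trace = trace,
    split = split_idx,
    scalers = list(p_center = p_center, p_scale = p_scale,
                   l_center = l_center, l_scale = l_scale,
                   f_center = f_center, f_scale = f_scale),
    cols = list(outcome = outcome, focal = focal, moderators = moderators,
                linear = linear, weights = weights),
    config = list(hidden = hidden, dropout = dropout, epochs = epochs,
                  batch_size = batch_size, lr_regression = lr_regression,
                  lr_network = lr_network, weight_decay = weight_decay,
                  optimizer = optimizer, momentum = momentum,
                  standardize = standardize,
                  split = split, seed = seed),
    orientation = orientation,
    data = tibble::as_tibble(data)
  )
  class(out) <- "regnn"
  out
}

#' Compute the learned vulnerability index
#'
#' Deterministic forward pass of the trained (frozen) network, using the
#' standardization recorded at fit time. Dropout is never active.
#'
#' @param object a fitted `regnn`.
#' @param newdata optional data frame with the moderator columns; defaults
#'   to the training data.
#' @return a numeric vector, one index value per row.
#' @export
compute_index <- function(object, newdata = NULL) {
  stopifnot(inherits(object, "regnn"))
  newdata <- newdata %||% object$data
  Xp <- as.matrix(newdata[object$cols$moderators])
  Xp_s <- sweep(sweep(Xp, 2, object$scalers$p_center, "-"),
                2, object$scalers$p_scale, "/")
  drop(.mlp_forward_cpp(object$network$W, object$network$b, Xp_s))
}

#' @export
#' @rdname compute_index
#' @param ... unused.
predict.regnn <- function(object, newdata = NULL, ...) {
  newdata <- newdata %||% object$data
  z <- compute_index(object, newdata)
  Xl <- as.matrix(newdata[object$cols$linear])
  Xl_s <- sweep(sweep(Xl, 2, object$scalers$l_center, "-"),
                2, object$scalers$l_scale, "/")
  xf <- as.numeric(newdata[[object$cols$focal]])
  xf_s <- (xf - object$scalers$f_center) / object$scalers$f_scale
  cf <- object$coefficients
  drop(cf$c0 + Xl_s %*% cf$linear + cf$cn * xf_s + cf$cint * z * xf_s)
}

#' @export
print.regnn <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("<regnn> MLP (%s), %d epochs, batch %d, optimizer %s\n",
              paste(x$network$layer_sizes, collapse = ", "),
              x$config$epochs, x$config$batch_size, x$config$optimizer))
  cat(sprintf("  exposure `%s`: cn = %.4f, interaction cint = %.4f (orientation %+d)\n",
              x$cols$focal, cf$cn, cf$cint, x$orientation))
  cat(sprintf("  final training loss %.4f; splits: train %d / sensitivity %d / holdout %d\n",
              utils::tail(x$trace$loss, 1), length(x$split$train),
              length(x$split$sensitivity), length(x$split$holdout)))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy the outer-regression coefficients of a fitted ReGNN
#'
#' These are the coefficients reached by stochastic gradient descent in
#' step 1; for classical inference (standard errors, p-values) fit the
#' twin regression with [fit_twin()].
#'
#' @param x a fitted `regnn`.
#' @param ... unused.
#' @return a tibble with columns `term` and `estimate`.
#' @export
tidy.regnn <- function(x, ...) {
  cf <- x$coefficients
  tibble::tibble(
    term = c("(Intercept)", names(cf$linear), x$cols$focal,
             paste0(x$cols$focal, ":z")),
    estimate = unname(c(cf$c0, cf$linear, cf$cn, cf$cint))
  )
}

#' @rdname tidy.regnn
#' @export
glance.regnn <- function(x, ...) {
  tibble::tibble(
    epochs = x$config$epochs,
    final_loss = utils::tail(x$trace$loss, 1),
    reg_l2 = utils::tail(x$trace$reg_l2, 1),
    cint = x$coefficients$cint,
    n_train = length(x$split$train),
    n_sensitivity = length(x$split$sensitivity)
  )
}
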