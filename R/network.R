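#' Initialize a multi-layer perceptron
#'
#' Fully-connected network with rectifier hidden units and a linear scalar
#' output. Weights and biases are drawn from the fan-in-scaled uniform
#' \eqn{U(-1/\sqrt{fan\_in}, 1/\sqrt{fan\_in})}.
#'
#' @param layer_sizes integer vector, input width through hidden widths to
#'   the output width (which must be 1), e.g. `c(35, 60, 32, 1)`.
#' @param seed optional integer seed.
#' @return an object of class `regnn_mlp`: list with `W` (list of
#'   out-by-in weight matrices), `b` (list of bias vectors), and
#'   `layer_sizes`.
#' @examples
#' net <- mlp_init(c(35, 60, 32, 1), seed = 1)
#' n_params(net)  # 4245
#' @export
mlp_init <- function(layer_sizes, seed = NULL) {
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    abort("`layer_sizes` needs at least input and output widths, all positive")
  }
  if (layer_sizes[length(layer_sizes)] != 1L) {
    abort("the output layer must have width 1")
  }
  maybe_set_seed(seed)
  L <- length(layer_sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- layer_sizes[l]
    bound <- 1 / sqrt(fan_in)
    W[[l]] <- matrix(runif(layer_sizes[l + 1] * fan_in, -bound, bound),
                     nrow = layer_sizes[l + 1], ncol = fan_in)
    b[[l]] <- runif(layer_sizes[l + 1], -bound, bound)
  }
  structure(list(W = W, b = b, layer_sizes = as.integer(layer_sizes)),
            class = "regnn_mlp")
}

#' Number of trainable network parameters
#' @param net a `regnn_mlp`.
#' @return integer count of weights plus biases.
#' @export
n_params <- function(net) {
  stopifnot(inherits(net, "regnn_mlp"))
  sum(vapply(net$W, length, integer(1))) + sum(lengths(net$b))
}

#' Forward pass of a network
#'
#' Dropout is never applied here; this is the deterministic evaluation used
#' to produce the learned index.
#'
#' @param net a `regnn_mlp`.
#' @param X numeric matrix, rows = observations, width = network input.
#' @return numeric vector of network outputs.
#' @export
mlp_forward <- function(net, X) {
  stopifnot(inherits(net, "regnn_mlp"))
  if (!is.matrix(X)) X <- as.matrix(X)
  drop(.mlp_forward_cpp(net$W, net$b, X))
}

#' @export
print.regnn_mlp <- function(x, ...) {
  cat(sprintf("<regnn_mlp> (%s), %d parameters\n",
              paste(x$layer_sizes, collapse = ", "), n_params(x)))
  invisible(x)
}

#' Weighted mean squared error
#'
#' \deqn{\mathrm{WMSE} = \sum_i w_i (o_i - \hat o_i)^2 / \sum_i w_i.}
#' With equal weights this is the plain MSE. Used as the training loss with
#' survey weights in cohort mode.
#'
#' @param pred,obs numeric vectors of equal length.
#' @param weights optional nonnegative weights, not all zero; default equal.
#' @return a single number.
#' @export
weighted_mse <- function(pred, obs, weights = NULL) {
  check_finite_vec(pred, "pred")
  check_finite_vec(obs, "obs")
  if (length(pred) != length(obs)) abort("`pred` and `obs` lengths differ")
  if (is.null(weights)) weights <- rep(1, length(obs))
  check_finite_vec(weights, "weights")
  if (length(weights) != length(obs)) abort("`weights` length differs")
  if (any(weights < 0)) abort("`weights` must be nonnegative")
  sw <- sum(weights)
  if (sw <= 0) abort("`weights` must not be all zero")
  sum(weights * (obs - pred)^2) / sw
}
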