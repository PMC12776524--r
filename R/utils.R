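#' @importFrom rlang %||% abort warn
#' @importFrom stats var cor sd quantile rnorm runif qnorm qt pt lm coef vcov
#'   residuals fitted predict model.matrix setNames median complete.cases
#'   mahalanobis
#' @importFrom utils head write.csv read.csv
#' @importFrom mclust Mclust mclustBIC priorControl emControl
NULL

# argument checks ------------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  x
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) abort(sprintf("`%s` must be an integer", name))
  as.integer(x)
}

check_finite_vec <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric vector", name))
  }
  x
}

maybe_set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(seed)
}

# enumerate all injections from 1..k into 1..m (k <= m), as a list of
# integer vectors; used by the exhaustive cluster-matching search
all_injections <- function(k, m) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  rec <- function(chosen, remaining) {
    if (length(chosen) == k) {
      out[[length(out) + 1L]] <<- chosen
      return(invisible())
    }
    for (v in remaining) rec(c(chosen, v), setdiff(remaining, v))
  }
  rec(integer(0), seq_len(m))
  out
}

# format tiny p-values for printing; estimation keeps full doubles
format_pval <- function(p) {
  ifelse(p < 1e-300, "<1e-300", format(signif(p, 3)))
}
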