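#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif fft sd median qnorm quantile setNames predict
#' @importFrom rlang abort warn .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Logistic sigmoid
#'
#' @param x Numeric vector.
#' @return `1 / (1 + exp(-x))`, numerically stable for large `|x|`.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

# softplus with linear tail for large arguments (avoids overflow)
softplus <- function(x) {
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

# Normal draw with mean `mu`, sd `sigma`, resampled until inside [lo, hi].
rnorm_trunc <- function(n, mu, sigma, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mu, sigma)
  bad <- which(x < lo | x > hi)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    x[bad] <- rnorm(length(bad), mu, sigma)
    bad <- which(x < lo | x > hi)
    guard <- guard + 1L
  }
  if (length(bad) > 0L) x[bad] <- pmin(pmax(x[bad], lo), hi)
  x
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}
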