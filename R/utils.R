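#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Zero-truncated Poisson sampler via inverse-CDF conditioning on Y >= 1.
rztpois <- function(n, lambda) {
  stopifnot(lambda > 0)
  p0 <- stats::ppois(0, lambda)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qpois(u, lambda)
}

ztpois_mean <- function(lambda) lambda / (1 - exp(-lambda))

## Affine rescaling of covariate columns to [-5, 5] for optimization.
## Returns the scaled matrix plus per-column (centre m, slope b): z' = b * (z - m).
make_rescaler <- function(X) {
  m <- rep(0, ncol(X))
  b <- rep(1, ncol(X))
  for (j in seq_len(ncol(X))) {
    r <- range(X[, j], finite = TRUE)
    if (diff(r) > 0) {
      m[j] <- mean(r)
      b[j] <- 10 / diff(r)
    }
  }
  names(m) <- names(b) <- colnames(X)
  list(scale = function(X) sweep(sweep(X, 2, m, "-"), 2, b, "*"),
       m = m, b = b)
}

## Numerical gradient (central differences) of a scalar function.
num_grad <- function(f, x, rel_h = 1e-5) {
  g <- numeric(length(x))
  for (k in seq_along(x)) {
    h <- rel_h * (1 + abs(x[k]))
    xp <- x; xp[k] <- x[k] + h
    xm <- x; xm[k] <- x[k] - h
    g[k] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

## Log-normal confidence interval for a positive estimate with coefficient of
## variation cv: (est / C, est * C) with C = exp(z * sqrt(log(1 + cv^2))).
#' Log-normal confidence interval
#'
#' Confidence interval for a positive estimate (typically abundance) based on a
#' log-normal sampling distribution, parameterized by the coefficient of
#' variation. The multiplier is \eqn{C = \exp(z_{1-\alpha/2}\sqrt{\ln(1+CV^2)})}
#' and the interval is \eqn{(\hat N / C, \hat N C)}.
#'
#' @param est positive point estimate.
#' @param cv coefficient of variation (SE/est), on the proportion scale.
#' @param conf confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
lognormal_ci <- function(est, cv, conf = 0.95) {
  stopifnot(est >= 0, cv >= 0)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  C <- exp(z * sqrt(log(1 + cv^2)))
  c(lower = est / C, upper = est * C)
}

block_diag <- function(...) {
  mats <- Filter(Negate(is.null), list(...))
  dims <- vapply(mats, nrow, 0L)
  out <- matrix(0, sum(dims), sum(dims))
  at <- 0L
  for (M in mats) {
    idx <- at + seq_len(nrow(M))
    out[idx, idx] <- M
    at <- at + nrow(M)
  }
  out
}

fmt_num <- function(x, digits = 2) formatC(x, format = "f", digits = digits, big.mark = ",")
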