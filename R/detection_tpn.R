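## Two-piece normal multiple-covariate distance sampling (MCDS) model.
##
## Detection shape: g(x) = exp(-(x - mu)^2 / (2 sigma(x,z)^2)) with
## ln sigma(x,z) = b0 + b_a * I(x > mu) + sum_j b_j z_j + sum_k c_k I(x > mu) z_k,
## so the scale differs left and right of the apex mu and may depend on coded
## covariates, including interactions with the asymmetry indicator. Ties at
## x == mu use the left scale (the indicator fires only when the distance
## strictly exceeds the apex).

#' Two-piece normal parameter set
#'
#' @param ln_mu log apex distance; the apex `mu = exp(ln_mu)` is in metres.
#' @param intercept intercept of the log-scale model (gives the left-of-apex
#'   scale when all covariates are zero).
#' @param igrmew coefficient of the asymmetry indicator `1[x > mu]`; the
#'   right-of-apex scale at zero covariates is `exp(intercept + igrmew)`.
#' @param coefs named numeric vector of covariate coefficients on `ln sigma`.
#' @param interactions named numeric vector of coefficients for products of
#'   the asymmetry indicator with covariates (names are the covariate names).
#' @return object of class `"tpn_params"`.
#' @export
tpn_params <- function(ln_mu, intercept, igrmew,
                       coefs = numeric(0), interactions = numeric(0)) {
  coefs <- unlist(coefs); interactions <- unlist(interactions)
  if (length(coefs) && is.null(names(coefs)))
    stop("coefs must be named by covariate")
  if (length(interactions) && is.null(names(interactions)))
    stop("interactions must be named by covariate")
  structure(list(ln_mu = ln_mu, intercept = intercept, igrmew = igrmew,
                 coefs = coefs, interactions = interactions),
            class = "tpn_params")
}

## Left/right log-scales per record. z: data.frame (or list) holding the
## covariate columns named in params. Returns list(sig_l, sig_r), vectors.
tpn_sigmas <- function(params, z = NULL, n = 1L) {
  pick <- function(nms) {
    if (!length(nms)) return(matrix(0, n, 0))
    miss <- setdiff(nms, names(z))
    if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "))
    as.matrix(as.data.frame(z)[nms])
  }
  if (!is.null(z)) n <- nrow(as.data.frame(z))
  lp_l <- params$intercept +
    if (length(params$coefs)) drop(pick(names(params$coefs)) %*% params$coefs) else 0
  lp_r <- lp_l + params$igrmew +
    if (length(params$interactions))
      drop(pick(names(params$interactions)) %*% params$interactions) else 0
  list(sig_l = exp(rep_len(lp_l, n)), sig_r = exp(rep_len(lp_r, n)))
}

## Stable integral of exp(-u^2 / (2 sigma^2)) over [a, b] (a <= b, recycled).
## The pnorm difference loses all precision when (b - a)/sigma is tiny (huge
## sigma), which would otherwise fake an inflated likelihood in the flat-shape
## region of the parameter space; a midpoint rule takes over there (relative
## error O(((b-a)/sigma)^2 / 24) at the 1e-4 crossover).
norm_integral <- function(a, b, sigma) {
  n <- max(length(a), length(b), length(sigma))
  a <- rep_len(a, n); b <- rep_len(b, n); sigma <- rep_len(sigma, n)
  out <- sigma * sqrt(2 * pi) * (stats::pnorm(b / sigma) - stats::pnorm(a / sigma))
  small <- (b - a) / sigma < 1e-4   # also covers sigma = Inf (flat shape limit)
  small[is.na(small)] <- FALSE
  if (any(small)) {
    m <- (a + b) / 2
    out[small] <- ((b - a) * exp(-m^2 / (2 * sigma^2)))[small]
  }
  pmax(out, 0)
}

#' Two-piece normal detection shape
#'
#' Evaluates the detection shape `g(x, z)` in (0, 1]; `g(mu) = 1`.
#'
#' @param x perpendicular distances (m).
#' @param params a [tpn_params()] object.
#' @param z data.frame of coded covariates (recycled if a single row), or
#'   `NULL` for a covariate-free model.
#' @return numeric vector of shape values.
#' @export
tpn_g <- function(x, params, z = NULL) {
  mu <- exp(params$ln_mu)
  s <- tpn_sigmas(params, z, n = length(x))
  sig <- ifelse(x > mu, rep_len(s$sig_r, length(x)), rep_len(s$sig_l, length(x)))
  exp(-(x - mu)^2 / (2 * sig^2))
}

## Closed-form integral of g over [w_b, w] via the Gaussian CDF, handling an
## apex outside the window piecewise-correctly. Vectorized over records.
#' Integral of the two-piece normal shape over the truncation window
#'
#' @inheritParams tpn_g
#' @param w_b,w truncation window (m), `w_b < w`.
#' @return integral values (m), one per covariate record.
#' @export
tpn_normalizer <- function(params, z = NULL, w_b, w) {
  stopifnot(w_b < w)
  mu <- exp(params$ln_mu)
  s <- tpn_sigmas(params, z)
  left <- norm_integral(pmin(w_b, mu) - mu, pmin(w, mu) - mu, s$sig_l)
  right <- norm_integral(pmax(w_b, mu) - mu, pmax(w, mu) - mu, s$sig_r)
  left + right
}

## CDF of the fitted distance density f(x | z) on [w_b, w]; vectorized over
## (x, rows of z). Used by goodness of fit (probability integral transform).
tpn_cdf <- function(x, params, z = NULL, w_b, w) {
  mu <- exp(params$ln_mu)
  s <- tpn_sigmas(params, z, n = length(x))
  sig_l <- rep_len(s$sig_l, length(x)); sig_r <- rep_len(s$sig_r, length(x))
  part <- function(xx, sl, sr) {
    left <- norm_integral(pmin(w_b, mu) - mu, pmin(xx, mu) - mu, sl)
    right <- norm_integral(pmax(w_b, mu) - mu, pmax(xx, mu) - mu, sr)
    left + right
  }
  num <- part(pmin(pmax(x, w_b), w), sig_l, sig_r)
  den <- part(rep(w, length(x)), sig_l, sig_r)
  num / den
}

## Builds the covariate matrices for a fit: X (main-effect columns) and
## W (columns interacting with the asymmetry indicator).
tpn_matrices <- function(data, covariates, asym_interactions) {
  need <- union(covariates, asym_interactions)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("coded covariate column(s) not found: ",
                         paste(miss, collapse = ", "),
                         " (run code_covariates() first)")
  X <- if (length(covariates)) as.matrix(data[covariates]) else matrix(0, nrow(data), 0)
  W <- if (length(asym_interactions)) as.matrix(data[asym_interactions])
       else matrix(0, nrow(data), 0)
  list(X = X, W = W)
}

## Negative log conditional likelihood in the *scaled* covariate space.
## par = c(ln_mu, intercept, igrmew, b_cov..., c_int...).
tpn_nll <- function(par, x, Xs, Ws, w_b, w) {
  mu <- exp(par[1])
  q <- ncol(Xs); r <- ncol(Ws)
  b0 <- par[2]; ba <- par[3]
  lp_l <- b0 + if (q) drop(Xs %*% par[3 + seq_len(q)]) else 0
  lp_r <- lp_l + ba + if (r) drop(Ws %*% par[3 + q + seq_len(r)]) else 0
  sig_l <- exp(lp_l); sig_r <- exp(lp_r)
  I <- x > mu
  sig <- ifelse(I, sig_r, sig_l)
  ln_g <- -(x - mu)^2 / (2 * sig^2)
  left <- norm_integral(pmin(w_b, mu) - mu, pmin(w, mu) - mu, sig_l)
  right <- norm_integral(pmax(w_b, mu) - mu, pmax(w, mu) - mu, sig_r)
  norm <- left + right
  if (any(!is.finite(norm)) || any(norm <= 0)) return(1e10)
  val <- -sum(ln_g - log(norm))
  if (!is.finite(val)) 1e10 else val
}

#' Fit a two-piece normal MCDS model
#'
#' Maximizes the conditional likelihood of the observed perpendicular
#' distances, \eqn{\prod_i g(x_i, z_i) / \int_{w_b}^{w} g(u, z_i)\,du}, over
#' the log apex and the log-linear scale coefficients. The asymmetry
#' indicator (1 when a distance exceeds the apex) is always in the scale
#' model; further covariates enter as main effects and, optionally, as
#' products with the indicator so a covariate can act on the far side of the
#' apex only.
#'
#' Covariates are internally rescaled to \[-5, 5\] for optimization and the
#' coefficients and their covariance are mapped back to the data scale before
#' reporting, so the fit is invariant to the rescaling. Optimization is
#' quasi-Newton (BFGS) from several deterministic starting points (apex starts
#' at low distance quantiles) because the likelihood surface is piecewise in
#' the apex.
#'
#' @param data coded detections (see [code_covariates()]) with a `distance`
#'   column, already truncated to `[w_b, w]`.
#' @param covariates character vector of scale-model covariate names.
#' @param asym_interactions character vector of covariate names whose effect
#'   interacts with the asymmetry indicator.
#' @param w_b,w truncation window (m).
#' @param start optional full start vector on the data scale
#'   (`c(ln_mu, intercept, igrmew, coefs, interactions)`).
#' @param control list: `n_starts` (default 5), `reltol` (default 1e-10),
#'   `maxit` (default 1000).
#' @return object of class `"tpn_fit"` with elements `params`
#'   ([tpn_params()]), `coefficients`, `vcov`, `loglik`, `aic`, `npar`, `n`,
#'   `data`, `w_b`, `w`.
#' @export
fit_tpn <- function(data, covariates = character(0),
                    asym_interactions = character(0), w_b, w,
                    start = NULL, control = list()) {
  ctrl <- utils::modifyList(list(n_starts = 5, reltol = 1e-10, maxit = 1000), control)
  x <- data$distance
  stopifnot(length(unique(x)) >= 2, all(x >= w_b - 1e-9), all(x <= w + 1e-9))
  mats <- tpn_matrices(data, covariates, asym_interactions)
  q <- ncol(mats$X); r <- ncol(mats$W)
  Z <- cbind(mats$X, mats$W)
  resc <- make_rescaler(Z)
  Zs <- resc$scale(Z)
  Xs <- Zs[, seq_len(q), drop = FALSE]
  Ws <- Zs[, q + seq_len(r), drop = FALSE]

  ## affine map scaled -> data-scale coefficients (also the vcov Jacobian)
  p <- 3 + q + r
  A <- diag(p)
  if (q + r) {
    b <- resc$b; m <- resc$m
    for (j in seq_len(q)) {
      A[3 + j, 3 + j] <- b[j]
      A[2, 3 + j] <- -b[j] * m[j]            # intercept absorbs the centring
    }
    for (k in seq_len(r)) {
      A[3 + q + k, 3 + q + k] <- b[q + k]
      A[3, 3 + q + k] <- -b[q + k] * m[q + k] # igrmew coef absorbs it
    }
  }
  to_data_scale <- function(par) drop(A %*% par)
  to_scaled <- function(par) drop(solve(A, par))

  starts <- list()
  if (!is.null(start)) {
    stopifnot(length(start) == p)
    starts[[1]] <- to_scaled(start)
  } else {
    for (qq in c(0.05, 0.1, 0.2, 0.3, 0.5)[seq_len(ctrl$n_starts)]) {
      mu0 <- max(stats::quantile(x, qq), w_b + 0.02 * (w - w_b))
      sl0 <- stats::sd(x[x <= mu0]); sr0 <- stats::sd(x[x > mu0])
      if (!is.finite(sl0) || sl0 <= 0) sl0 <- (mu0 - w_b) / 2 + 1
      if (!is.finite(sr0) || sr0 <= 0) sr0 <- (w - mu0) / 3 + 1
      starts[[length(starts) + 1]] <-
        c(log(mu0), log(sl0), log(sr0 / sl0), rep(0, q + r))
    }
  }

  ## Box constraints (scaled space) keep the optimizer out of the flat-shape
  ## region where the scale explodes and the density degenerates to uniform.
  ## The box is far outside any plausible optimum: scales from ~(w-w_b)/1000
  ## to 5(w-w_b), left/right scale ratios to e^8, covariate scale ratios to
  ## e^20 across a covariate's observed range.
  span <- w - w_b
  lower <- c(log(w_b + 1e-4 * span), log(span) - 7, -8, rep(-2, q + r))
  upper <- c(log(w + 0.5 * span), log(5 * span), 8, rep(2, q + r))
  run_opt <- function(s0, idx = seq_len(p)) {
    s0 <- pmin(pmax(s0, lower[idx] + 1e-6), upper[idx] - 1e-6)
    try(stats::optim(s0,
                     function(par) {
                       full <- rep(0, p); full[idx] <- par
                       tpn_nll(full, x = x, Xs = Xs, Ws = Ws, w_b = w_b, w = w)
                     },
                     method = "L-BFGS-B", lower = lower[idx], upper = upper[idx],
                     control = list(factr = 1e6, maxit = ctrl$maxit)),
        silent = TRUE)
  }
  ## Warm start: fit the 3-parameter (apex + two scales) model first and grow
  ## the covariate model from its optimum, as forward selection would.
  if (q + r > 0 && is.null(start)) {
    base3 <- NULL
    for (s0 in starts) {
      o <- run_opt(s0[1:3], idx = 1:3)
      if (!inherits(o, "try-error") && (is.null(base3) || o$value < base3$value))
        base3 <- o
    }
    if (!is.null(base3))
      starts <- c(list(c(base3$par, rep(0, q + r))), starts)
  }
  cands <- list()
  for (s0 in starts) {
    opt <- run_opt(s0)
    if (inherits(opt, "try-error")) next
    opt$interior <- all(opt$par > lower + 1e-4) && all(opt$par < upper - 1e-4)
    cands[[length(cands) + 1]] <- opt
  }
  if (!length(cands)) stop("two-piece normal fit failed from every start")
  ## candidates in likelihood order, interior optima first (a boundary
  ## optimum has no valid curvature); fall through to the next candidate when
  ## the observed information at one is not invertible
  ord <- order(!vapply(cands, `[[`, TRUE, "interior"),
               vapply(cands, `[[`, 0, "value"))
  best <- NULL; vc_s <- NULL
  for (o in cands[ord]) {
    H <- try(stats::optimHess(o$par, tpn_nll, x = x, Xs = Xs, Ws = Ws,
                              w_b = w_b, w = w), silent = TRUE)
    if (inherits(H, "try-error")) next
    vi <- try(solve(H), silent = TRUE)
    if (inherits(vi, "try-error") || any(diag(vi) <= 0)) next
    best <- o; vc_s <- vi
    break
  }
  if (is.null(best))
    stop("observed information is not invertible at any optimum; ",
         "the model is ill-conditioned for these data")
  if (!best$interior)
    warning("optimum lies on a parameter bound; estimates are unreliable")
  if (best$convergence != 0)
    warning("optimizer reported non-convergence (code ", best$convergence, ")")
  par <- to_data_scale(best$par)
  vc <- A %*% vc_s %*% t(A)
  nms <- c("ln_mu", "(Intercept)", "igrmew",
           if (q) covariates, if (r) paste0("igrmew:", asym_interactions))
  names(par) <- rownames(vc) <- colnames(vc) <- nms

  params <- tpn_params(ln_mu = par[["ln_mu"]], intercept = par[["(Intercept)"]],
                       igrmew = par[["igrmew"]],
                       coefs = if (q) par[3 + seq_len(q)] else numeric(0),
                       interactions = if (r) stats::setNames(par[3 + q + seq_len(r)],
                                                             asym_interactions)
                                      else numeric(0))
  mu <- exp(par[["ln_mu"]])
  if (mu <= w_b || mu >= w)
    warning("fitted apex (", round(mu, 1), " m) lies outside the truncation window")
  ll <- -best$value
  structure(list(params = params, coefficients = par, vcov = vc,
                 loglik = ll, aic = -2 * ll + 2 * p, npar = p,
                 n = length(x), covariates = covariates,
                 asym_interactions = asym_interactions,
                 w_b = w_b, w = w, data = data,
                 convergence = best$convergence),
            class = "tpn_fit")
}

#' @export
coef.tpn_fit <- function(object, ...) object$coefficients

#' @export
vcov.tpn_fit <- function(object, ...) object$vcov

#' @export
logLik.tpn_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$n, class = "logLik")
}

#' @export
print.tpn_fit <- function(x, ...) {
  cat("Two-piece normal MCDS fit\n")
  cat("  n =", x$n, " truncation [", x$w_b, ",", x$w, "] m\n")
  cat("  apex mu =", round(exp(x$params$ln_mu), 1), "m\n")
  cat("  logLik =", round(x$loglik, 3), " AIC =", round(x$aic, 2), "\n")
  se <- sqrt(diag(x$vcov))
  print(round(cbind(Coefficient = x$coefficients, SE = se), 4))
  invisible(x)
}

#' @export
summary.tpn_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = object$coefficients / se)
  structure(list(table = tab, fit = object), class = "summary.tpn_fit")
}

#' @export
print.summary.tpn_fit <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' Predict from a two-piece normal fit
#'
#' @param object a `"tpn_fit"`.
#' @param newdata coded covariates; defaults to the fitting data.
#' @param distance distances (m) at which to evaluate.
#' @param type `"g"` for the detection shape, `"density"` for the normalized
#'   distance density on `[w_b, w]`, `"cdf"` for its CDF.
#' @param ... unused.
#' @export
predict.tpn_fit <- function(object, newdata = NULL, distance = NULL,
                            type = c("g", "density", "cdf"), ...) {
  type <- match.arg(type)
  newdata <- newdata %||% object$data
  x <- distance %||% newdata$distance
  switch(type,
    g = tpn_g(x, object$params, newdata),
    density = tpn_g(x, object$params, newdata) /
      tpn_normalizer(object$params, newdata, object$w_b, object$w),
    cdf = tpn_cdf(x, object$params, newdata, object$w_b, object$w))
}

#' Average detection curve
#'
#' Detection shape with covariates held at their observed means applied to
#' the fitted coefficients; the standard display curve for covariate models.
#'
#' @param fit a `"tpn_fit"`.
#' @param newdata coded covariates to average over (default: fitting data).
#' @param grid distances (m) at which to evaluate (default: 200 points over
#'   the truncation window).
#' @return data.frame with columns `distance` and `g`.
#' @export
average_detection_curve <- function(fit, newdata = NULL, grid = NULL) {
  newdata <- newdata %||% fit$data
  grid <- grid %||% seq(fit$w_b, fit$w, length.out = 200)
  nms <- union(fit$covariates, fit$asym_interactions)
  zbar <- as.data.frame(as.list(colMeans(as.data.frame(newdata)[nms])))
  if (!length(nms)) zbar <- NULL
  data.frame(distance = grid, g = tpn_g(grid, fit$params, zbar))
}

#' @export
plot.tpn_fit <- function(x, nbins = 15, ...) {
  curve <- average_detection_curve(x)
  h <- graphics::hist(x$data$distance, breaks = nbins, plot = FALSE)
  scale <- max(h$density) / max(curve$g)
  graphics::plot(h$mids, h$density, type = "h", lwd = 8, lend = 2,
                 col = "grey80", xlab = "Perpendicular distance (m)",
                 ylab = "Scaled detection / density", ...)
  graphics::lines(curve$distance, curve$g * scale, lwd = 2)
  invisible(x)
}

#' Simulate distances from a fitted (or specified) distance model
#'
#' Draws perpendicular distances from the fitted conditional density
#' `f(x | z)` for each covariate row, by rejection sampling against a uniform
#' proposal on the truncation window (the shape is bounded by 1).
#'
#' @param object a `"tpn_fit"`.
#' @param nsim number of datasets.
#' @param seed optional RNG seed.
#' @param newdata covariate rows (default: the fitting data); one distance is
#'   drawn per row per dataset.
#' @param ... unused.
#' @return a data.frame (nsim = 1) or list of data.frames: `newdata` with the
#'   `distance` column replaced by simulated draws.
#' @export
simulate.tpn_fit <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  newdata <- newdata %||% object$data
  n <- nrow(newdata)
  draw <- function() {
    out <- rep(NA_real_, n)
    todo <- seq_len(n)
    while (length(todo)) {
      xp <- stats::runif(length(todo), object$w_b, object$w)
      acc <- stats::runif(length(todo)) <
        tpn_g(xp, object$params, newdata[todo, , drop = FALSE])
      out[todo[acc]] <- xp[acc]
      todo <- todo[!acc]
    }
    nd <- newdata
    nd$distance <- out
    nd
  }
  if (nsim == 1) draw() else replicate(nsim, draw(), simplify = FALSE)
}
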