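## Conditional logistic mark-resight model for dual-observer capture
## histories. Each crew member "marks" groups for the other; the data are the
## histories {pilot-only, observer-only, both} of groups detected by at least
## one observer. With conditional detection probabilities p1 (pilot) and p2
## (backseat observer) and union u = p1 + p2 - p1 p2, the history
## probabilities are p1(1-p2)/u, (1-p1)p2/u and p1 p2/u (a Huggins-type
## conditional multinomial likelihood).

## Role-aware design matrix. Covariate semantics:
##   observer       -> the role indicator itself (0 pilot, 1 backseat)
##   pilot_group    -> applies to the pilot only (zeroed for the backseat)
##   observer_group -> applies to the backseat only (zeroed for the pilot)
##   distance       -> perpendicular distance in raw metres (or the value in
##                     `distance_override`)
##   anything else  -> taken as-is from the coded data
mr_design <- function(data, role, covariates, distance_override = NULL) {
  n <- nrow(data)
  M <- matrix(0, n, length(covariates) + 1L,
              dimnames = list(NULL, c("(Intercept)", covariates)))
  M[, 1] <- 1
  for (v in covariates) {
    M[, v] <- switch(v,
      observer = rep(role, n),
      pilot_group = data$pilot_group * (1 - role),
      observer_group = data$observer_group * role,
      distance = distance_override %||% data$distance,
      {
        if (is.null(data[[v]])) stop("coded covariate column not found: ", v)
        data[[v]]
      })
  }
  M
}

#' Conditional detection probability of one observer
#'
#' Inverse-logit of the fitted linear predictor for the given observer role.
#'
#' @param object coefficients (named numeric, `"(Intercept)"` first) or an
#'   `"mr_fit"`.
#' @param role `"pilot"` or `"observer"` (backseat).
#' @param data coded detections supplying the covariate columns.
#' @param distance optional distances (m) overriding `data$distance`.
#' @return vector of probabilities in (0, 1).
#' @export
mr_conditional_p <- function(object, role = c("pilot", "observer"), data,
                             distance = NULL) {
  role <- match.arg(role)
  gamma <- if (inherits(object, "mr_fit")) object$coefficients else object
  covs <- setdiff(names(gamma), "(Intercept)")
  M <- mr_design(data, role = as.numeric(role == "observer"), covs,
                 distance_override = distance)
  stats::plogis(drop(M %*% gamma[colnames(M)]))
}

mr_nll <- function(gamma, M1, M2, hist_code) {
  p1 <- stats::plogis(drop(M1 %*% gamma))
  p2 <- stats::plogis(drop(M2 %*% gamma))
  u <- p1 + p2 - p1 * p2
  pr <- cbind(p1 * (1 - p2), (1 - p1) * p2, p1 * p2) / u
  ll <- log(pr[cbind(seq_along(hist_code), hist_code)])
  val <- -sum(ll)
  if (!is.finite(val)) 1e10 else val
}

#' Fit the conditional mark-resight model
#'
#' Maximizes the conditional multinomial likelihood of the capture histories
#' of groups detected by at least one of the two observers. The `observer`
#' role indicator, the crew-group indicators and any coded covariates enter a
#' shared logistic model; continuous covariates are internally rescaled for
#' optimization and coefficients are reported on the data scale (distance in
#' raw metres).
#'
#' @param data coded detections with a `history` column
#'   (`"pilot"`/`"observer"`/`"both"`).
#' @param covariates character vector drawn from `observer`, `pilot_group`,
#'   `observer_group`, `distance`, `bed`, `pcvr5`, `stratum_indicator`, or any
#'   coded column.
#' @param control list: `reltol` (default 1e-10), `maxit` (default 1000).
#' @return object of class `"mr_fit"`: `coefficients`, `vcov`, `loglik`,
#'   `aic`, `npar`, `n`, `data`.
#' @export
fit_mr <- function(data, covariates = character(0), control = list()) {
  ctrl <- utils::modifyList(list(reltol = 1e-10, maxit = 1000), control)
  stopifnot(all(data$history %in% c("pilot", "observer", "both")))
  hist_code <- match(data$history, c("pilot", "observer", "both"))
  M1 <- mr_design(data, 0, covariates)
  M2 <- mr_design(data, 1, covariates)

  ## rescale continuous columns (shared across roles) to [-5, 5]
  p <- ncol(M1)
  A <- diag(p)
  dimnames(A) <- list(colnames(M1), colnames(M1))
  M1s <- M1; M2s <- M2
  for (j in seq_len(p)[-1]) {
    v <- colnames(M1)[j]
    if (v %in% c("observer", "pilot_group", "observer_group")) next
    r <- range(c(M1[, j], M2[, j]))
    if (diff(r) <= 0 || all(M1[, j] %in% 0:1)) next
    m <- mean(r); b <- 10 / diff(r)
    M1s[, j] <- b * (M1[, j] - m)
    M2s[, j] <- b * (M2[, j] - m)
    A[j, j] <- b
    A[1, j] <- -b * m
  }
  opt <- stats::optim(rep(0, p), mr_nll, M1 = M1s, M2 = M2s,
                      hist_code = hist_code, method = "BFGS",
                      control = list(reltol = ctrl$reltol, maxit = ctrl$maxit))
  if (opt$convergence != 0)
    warning("optimizer reported non-convergence (code ", opt$convergence, ")")
  big <- abs(opt$par[-1]) > 12
  if (any(big))
    stop("apparent complete separation on covariate(s): ",
         paste(colnames(M1)[-1][big], collapse = ", "))
  H <- stats::optimHess(opt$par, mr_nll, M1 = M1s, M2 = M2s, hist_code = hist_code)
  vc_s <- try(solve(H), silent = TRUE)
  if (inherits(vc_s, "try-error"))
    stop("observed information is not invertible; the model is ill-conditioned")
  gamma <- drop(A %*% opt$par)
  vc <- A %*% vc_s %*% t(A)
  names(gamma) <- rownames(vc) <- colnames(vc) <- colnames(M1)
  ll <- -opt$value
  structure(list(coefficients = gamma, vcov = vc, loglik = ll,
                 aic = -2 * ll + 2 * p, npar = p, n = nrow(data),
                 covariates = covariates, data = data,
                 convergence = opt$convergence),
            class = "mr_fit")
}

#' @export
coef.mr_fit <- function(object, ...) object$coefficients

#' @export
vcov.mr_fit <- function(object, ...) object$vcov

#' @export
logLik.mr_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$n, class = "logLik")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("Conditional mark-resight (dual-observer logistic) fit\n")
  cat("  n =", x$n, " logLik =", round(x$loglik, 3), " AIC =", round(x$aic, 2), "\n")
  se <- sqrt(diag(x$vcov))
  print(round(cbind(Coefficient = x$coefficients, SE = se), 4))
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = object$coefficients / se)
  structure(list(table = tab, fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' Predict conditional or union detection probabilities
#'
#' @param object an `"mr_fit"`.
#' @param newdata coded detections (default: fitting data).
#' @param distance optional distances (m) overriding `newdata$distance`.
#' @param type `"pilot"`, `"observer"`, or `"union"`
#'   (\eqn{p_1 + p_2 - p_1 p_2}).
#' @param ... unused.
#' @export
predict.mr_fit <- function(object, newdata = NULL, distance = NULL,
                           type = c("union", "pilot", "observer"), ...) {
  type <- match.arg(type)
  newdata <- newdata %||% object$data
  p1 <- mr_conditional_p(object, "pilot", newdata, distance)
  p2 <- mr_conditional_p(object, "observer", newdata, distance)
  switch(type, pilot = p1, observer = p2, union = p1 + p2 - p1 * p2)
}

#' Average detection probability at the apex
#'
#' Evaluates the union probability \eqn{p_\bullet(\hat\mu, z_i)} of the two
#' observers at the apex distance for every detected group and averages it,
#' by default with Horvitz-Thompson weights \eqn{1/\hat p_i} (supply
#' `weights`), otherwise unweighted. The standard error comes from the delta
#' method over the mark-resight coefficient covariance (weights treated as
#' fixed).
#'
#' @param fit an `"mr_fit"`.
#' @param mu apex distance (m), typically `exp(coef(tpn_fit)["ln_mu"])`.
#' @param newdata coded detections (default: the fitting data).
#' @param weights optional positive weights (e.g. `1/phat` from
#'   [detection_prob()]); `NULL` for an unweighted mean.
#' @return list with `estimate`, `se`, `ci` (normal 95%).
#' @export
apex_detection <- function(fit, mu, newdata = NULL, weights = NULL) {
  newdata <- newdata %||% fit$data
  n <- nrow(newdata)
  wts <- weights %||% rep(1, n)
  stopifnot(length(wts) == n, all(wts > 0))
  covs <- fit$covariates
  M1 <- mr_design(newdata, 0, covs, distance_override = rep(mu, n))
  M2 <- mr_design(newdata, 1, covs, distance_override = rep(mu, n))
  avg <- function(gamma) {
    p1 <- stats::plogis(drop(M1 %*% gamma))
    p2 <- stats::plogis(drop(M2 %*% gamma))
    sum(wts * (p1 + p2 - p1 * p2)) / sum(wts)
  }
  est <- avg(fit$coefficients)
  g <- num_grad(avg, fit$coefficients)
  se <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  list(estimate = est, se = se,
       ci = c(lower = est - 1.96 * se, upper = est + 1.96 * se))
}
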