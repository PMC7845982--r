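test_that("the detection shape peaks at the apex and matches its closed form", {
  p <- reference_tpn()
  mu <- exp(p$ln_mu)
  expect_equal(mu, 110.5, tolerance = 1e-3)
  zs <- expand.grid(bin2sd1000 = 0:1, tranflat = 0:1)
  for (i in seq_len(nrow(zs))) {
    z <- zs[i, , drop = FALSE]
    expect_equal(tpn_g(mu, p, z), 1)
    # strictly increasing left of the apex, strictly decreasing right of it
    xl <- seq(0, mu - 1e-6, length.out = 50)
    xr <- seq(mu + 1e-6, 2000, length.out = 50)
    expect_true(all(diff(tpn_g(xl, p, z[rep(1, 50), ])) > 0))
    expect_true(all(diff(tpn_g(xr, p, z[rep(1, 50), ])) < 0))
    # continuous at the apex
    expect_equal(tpn_g(mu - 1e-9, p, z), tpn_g(mu + 1e-9, p, z),
                 tolerance = 1e-6)
  }
  # left/right scales implied by the coefficients
  z0 <- data.frame(bin2sd1000 = 0, tranflat = 0)
  expect_equal(tpn_g(mu + exp(3.5823 + 1.8844), p, z0), exp(-0.5),
               tolerance = 1e-12)
  expect_equal(tpn_g(mu - exp(3.5823), p, z0), exp(-0.5), tolerance = 1e-12)
})

test_that("closed-form normalizer agrees with adaptive quadrature", {
  p <- reference_tpn()
  cases <- expand.grid(bin2sd1000 = 0:1, tranflat = 0:1)
  for (i in seq_len(nrow(cases))) {
    z <- cases[i, , drop = FALSE]
    closed <- tpn_normalizer(p, z, 22, 1000)
    quad <- stats::integrate(function(u) tpn_g(u, p, z[rep(1, length(u)), ]),
                             22, 1000, rel.tol = 1e-12)$value
    expect_equal(closed, quad, tolerance = 1e-8)
  }
  # symmetric, untruncated limit: sigma * sqrt(2*pi)
  sym <- tpn_params(ln_mu = log(500), intercept = log(40), igrmew = 0)
  expect_equal(tpn_normalizer(sym, NULL, -1e7, 1e7), 40 * sqrt(2 * pi),
               tolerance = 1e-10)
  # degenerate window ending at the apex: left piece only
  mu <- exp(p$ln_mu)
  z0 <- data.frame(bin2sd1000 = 0, tranflat = 0)
  left_only <- tpn_normalizer(p, z0, 22, mu)
  sig_l <- exp(3.5823)
  expect_equal(left_only,
               sig_l * sqrt(2 * pi) * (0.5 - pnorm((22 - mu) / sig_l)),
               tolerance = 1e-10)
  # stable in the flat-shape limit (huge scales): integral -> window width
  flat <- tpn_params(ln_mu = log(500), intercept = 40, igrmew = 0)
  expect_equal(tpn_normalizer(flat, NULL, 22, 1000), 978, tolerance = 1e-8)
})

test_that("the fitted density normalizes and its CDF inverts the density", {
  p <- reference_tpn()
  z <- data.frame(bin2sd1000 = 1, tranflat = 0)
  nrm <- tpn_normalizer(p, z, 22, 1000)
  total <- stats::integrate(function(u) tpn_g(u, p, z[rep(1, length(u)), ]) / nrm,
                            22, 1000, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-6)
  xs <- c(50, 110, 300, 900)
  for (x in xs) {
    num <- stats::integrate(function(u) tpn_g(u, p, z[rep(1, length(u)), ]) / nrm,
                            22, x, rel.tol = 1e-10)$value
    expect_equal(tpnmrds:::tpn_cdf(x, p, z, 22, 1000), num, tolerance = 1e-7)
  }
  expect_equal(tpnmrds:::tpn_cdf(22, p, z, 22, 1000), 0)
  expect_equal(tpnmrds:::tpn_cdf(1000, p, z, 22, 1000), 1)
})

test_that("with no asymmetry and the apex at the left edge the model is a half-normal", {
  w_b <- 22; w <- 1000; sigma <- 250
  p <- tpn_params(ln_mu = log(w_b), intercept = log(sigma), igrmew = 0)
  set.seed(4)
  x <- w_b + abs(rnorm(400, 0, sigma))
  x <- x[x <= w][1:200]
  ll_tpn <- sum(log(tpn_g(x, p, NULL) / tpn_normalizer(p, NULL, w_b, w)))
  # direct truncated half-normal log-likelihood on [w_b, w]
  ll_hn <- sum(dnorm(x, w_b, sigma, log = TRUE)) -
    length(x) * log(pnorm(w, w_b, sigma) - 0.5)
  expect_equal(ll_tpn, ll_hn, tolerance = 1e-8)
})

test_that("maximum likelihood fitting recovers known parameters", {
  sc <- small_scenario()
  sim <- simulate_survey(sc, seed = 21)
  fit <- fit_tpn(sim$detections, covariates = c("bin2sd1000", "tranflat"),
                 w_b = 22, w = 1000)
  truth <- c(ln_mu = 4.7046, "(Intercept)" = 3.5823, igrmew = 1.8844,
             bin2sd1000 = 0.6620, tranflat = 0.3724)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit) - truth[names(coef(fit))]) < 3 * se))
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$npar)
  expect_true(all(eigen(vcov(fit), symmetric = TRUE)$values > -1e-8))
  # the refit likelihood at the truth can never beat the MLE
  nll_at <- function(par) {
    pr <- tpn_params(par[1], par[2], par[3],
                     coefs = c(bin2sd1000 = unname(par[4]),
                               tranflat = unname(par[5])))
    -sum(log(tpn_g(sim$detections$distance, pr, sim$detections) /
               tpn_normalizer(pr, sim$detections, 22, 1000)))
  }
  expect_gte(nll_at(truth), -fit$loglik - 1e-6)
  expect_equal(nll_at(coef(fit)), -fit$loglik, tolerance = 1e-8)
})

test_that("the fit is invariant to affine rescaling of a covariate", {
  sc <- small_scenario()
  sim <- simulate_survey(sc, seed = 31)
  d <- sim$detections
  d$bin2big <- d$bin2sd1000 * 100
  f1 <- fit_tpn(d, covariates = c("bin2sd1000", "tranflat"), w_b = 22, w = 1000)
  f2 <- fit_tpn(d, covariates = c("bin2big", "tranflat"), w_b = 22, w = 1000)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-5)
  expect_equal(unname(coef(f2)["bin2big"]) * 100,
               unname(coef(f1)["bin2sd1000"]), tolerance = 1e-3)
})

test_that("asymmetry interactions act only beyond the apex", {
  p <- tpn_params(ln_mu = log(100), intercept = log(50), igrmew = 1,
                  interactions = c(bin2sd1000 = 0.5))
  z0 <- data.frame(bin2sd1000 = 0)
  z1 <- data.frame(bin2sd1000 = 1)
  # identical left of the apex
  expect_equal(tpn_g(60, p, z0), tpn_g(60, p, z1))
  # wider right tail when the interacting covariate is on
  expect_gt(tpn_g(400, p, z1), tpn_g(400, p, z0))
})

test_that("average detection curve peaks at the apex with value 1", {
  sc <- small_scenario()
  sim <- simulate_survey(sc, seed = 41)
  fit <- fit_tpn(sim$detections, covariates = c("bin2sd1000", "tranflat"),
                 w_b = 22, w = 1000)
  curve <- average_detection_curve(fit)
  mu <- exp(coef(fit)[["ln_mu"]])
  expect_equal(max(tpn_g(mu, fit$params,
                         curve_z <- as.data.frame(as.list(colMeans(
                           sim$detections[c("bin2sd1000", "tranflat")]))))), 1)
  expect_lt(abs(curve$distance[which.max(curve$g)] - mu), 6)
  expect_true(all(curve$g > 0 & curve$g <= 1))
})

test_that("simulated distances reproduce the generating density", {
  p <- reference_tpn()
  z <- data.frame(bin2sd1000 = 0, tranflat = 0)
  fit <- tpn_fit_from_params(p, data = cbind(z[rep(1, 4000), , drop = FALSE],
                                             distance = 100))
  d <- simulate(fit, seed = 5)
  u <- tpnmrds:::tpn_cdf(d$distance, p, d, 22, 1000)
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(d$distance >= 22 & d$distance <= 1000))
})
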