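test_that("a fixed seed makes the generator bit-identical", {
  sc <- small_scenario()
  a <- simulate_survey(sc, seed = 101)
  b <- simulate_survey(sc, seed = 101)
  expect_identical(a$detections, b$detections)
  expect_identical(a$transects, b$transects)
  expect_identical(a$truth$latent, b$truth$latent)
  c <- simulate_survey(sc, seed = 102)
  expect_false(identical(a$detections, c$detections))
})

test_that("detected distances respect the window and tables feed the readers", {
  sc <- small_scenario()
  sim <- simulate_survey(sc, seed = 7)
  expect_true(all(sim$detections$distance >= sc$w_b))
  expect_true(all(sim$detections$distance <= sc$w))
  expect_true(all(sim$detections$group_size >= 1))
  expect_true(all(sim$detections$history %in% c("pilot", "observer", "both")))
  # detected groups are a subset of the latent population
  expect_lte(nrow(sim$detections), nrow(sim$truth$latent))
  expect_equal(nrow(sim$detections), sum(sim$truth$latent$detected))

  # the emitted CSV dialect round-trips through the package readers
  dir <- withr::local_tempdir()
  write_survey(sim, dir)
  det <- read_detections(file.path(dir, "detections.csv"))
  expect_equal(nrow(det), nrow(sim$detections))
  tra <- read_transects(file.path(dir, "transects.csv"))
  expect_equal(sum(tra$length_km), sum(sim$transects$length_km))
  coded <- code_covariates(det, sim_crew_groups())
  expect_equal(coded$bed, sim$detections$bed)
  expect_equal(coded$tranflat, sim$detections$tranflat)
  expect_equal(coded$pilot_group, sim$detections$pilot_group)
  expect_equal(coded$observer_group, sim$detections$observer_group)
})

test_that("perfect detection turns the survey into a census of the strips", {
  sc <- sim_scenario(
    strata = data.frame(stratum = "A", area_km2 = 1000, n_transects = 25,
                        transect_length_km = 20, target_detections = 200),
    tpn = tpn_params(ln_mu = log(511), intercept = 20, igrmew = 0),
    mr = c("(Intercept)" = 20, observer = 0),
    cov_freq = utils::modifyList(default_cov_freq(),
                                 list(bed = 0, bin2sd1000 = 0, tranflat = 0)))
  sim <- simulate_survey(sc, seed = 3)
  expect_equal(nrow(sim$detections), nrow(sim$truth$latent))
  expect_true(all(sim$detections$history == "both"))
})

test_that("capture-history frequencies converge to the conditional multinomial", {
  # constant conditional probabilities: no covariates, no distance effect
  gamma <- c("(Intercept)" = 0.4, observer = -0.3)
  sc <- sim_scenario(
    strata = data.frame(stratum = "A", area_km2 = 5000, n_transects = 100,
                        transect_length_km = 20, target_detections = 4000),
    tpn = tpn_params(ln_mu = log(300), intercept = log(400), igrmew = 0),
    mr = gamma,
    cov_freq = utils::modifyList(default_cov_freq(),
                                 list(bed = 0, bin2sd1000 = 0, tranflat = 0)))
  sim <- simulate_survey(sc, seed = 11)
  p1 <- plogis(0.4); p2 <- plogis(0.1); u <- p1 + p2 - p1 * p2
  want <- c(both = p1 * p2, observer = (1 - p1) * p2, pilot = p1 * (1 - p2)) / u
  got <- table(sim$detections$history) / nrow(sim$detections)
  expect_gt(nrow(sim$detections), 2000)
  expect_lt(max(abs(got[names(want)] - want)), 0.02)
})

test_that("detected distances follow the shape-weighted density at scale", {
  p <- tpn_params(ln_mu = log(120), intercept = log(40), igrmew = 1.6)
  sc <- sim_scenario(
    strata = data.frame(stratum = "A", area_km2 = 50000, n_transects = 400,
                        transect_length_km = 25, target_detections = 30000),
    tpn = p, mr = c("(Intercept)" = 1.5, observer = 0),
    cov_freq = utils::modifyList(default_cov_freq(),
                                 list(bed = 0, bin2sd1000 = 0, tranflat = 0)))
  sim <- simulate_survey(sc, seed = 19)
  n <- nrow(sim$detections)
  expect_gt(n, 10000)
  breaks <- seq(22, 1000, length.out = 21)
  obs <- as.vector(table(cut(sim$detections$distance, breaks,
                             include.lowest = TRUE)))
  cdf <- tpnmrds:::tpn_cdf(breaks, p, NULL, 22, 1000)
  expd <- n * diff(cdf)
  chisq <- sum((obs - expd)^2 / expd)
  expect_gt(pchisq(chisq, length(obs) - 1, lower.tail = FALSE), 1e-3)
})

test_that("scenario densities anchor expected detections via the mean detection probability", {
  sc <- small_scenario()
  reps <- vapply(1:20, function(i)
    nrow(simulate_survey(sc, seed = 1000 + i)$detections), 0)
  # targets are 160 + 80 = 240 expected detected groups
  expect_lt(abs(mean(reps) - 240) / 240, 0.08)
})

test_that("a zero-density stratum yields no detections but a valid design", {
  sc <- sim_scenario(
    strata = data.frame(stratum = "A", area_km2 = 1000, n_transects = 10,
                        transect_length_km = 20, density_groups_km2 = 0))
  expect_warning(sim <- simulate_survey(sc, seed = 5), "expected detections")
  expect_null(sim$detections)
  expect_equal(nrow(sim$transects), 10)
  expect_s3_class(sim$design, "survey_design")
})

test_that("a scenario built from fitted models simulates and refits consistently", {
  sc0 <- small_scenario()
  sim0 <- simulate_survey(sc0, seed = 43)
  ft <- fit_tpn(sim0$detections, covariates = c("bin2sd1000", "tranflat"),
                w_b = 22, w = 1000)
  fm <- fit_mr(sim0$detections,
               covariates = c("bed", "observer", "pilot_group", "distance",
                              "pcvr5", "observer_group"))
  sc <- scenario_from_fit(ft, fm, sim0$design, target_detections = c(200, 100))
  expect_equal(sc$tpn$ln_mu, ft$params$ln_mu)
  expect_equal(sc$mr, fm$coefficients)
  sim <- simulate_survey(sc, seed = 44)
  ft2 <- fit_tpn(sim$detections, covariates = c("bin2sd1000", "tranflat"),
                 w_b = 22, w = 1000)
  fm2 <- fit_mr(sim$detections,
                covariates = c("bed", "observer", "pilot_group", "distance",
                               "pcvr5", "observer_group"))
  # refit recovers the generating coefficients (3 SE keeps the single-replicate
  # check robust across the 12 simultaneous comparisons)
  expect_true(all(abs(coef(ft2) - coef(ft)) < 3 * sqrt(diag(vcov(ft2)))))
  expect_true(all(abs(coef(fm2) - coef(fm)) < 3 * sqrt(diag(vcov(fm2)))))
})
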