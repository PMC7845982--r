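make_flat_survey <- function(w_b = 22, w = 1000) {
  # two strata, two transects each; areas equal to the covered strips so the
  # Horvitz-Thompson census limit is exact
  tr <- data.frame(stratum = rep(c("A", "B"), each = 2),
                   transect_id = c("A1", "A2", "B1", "B2"),
                   length_km = c(10, 14, 8, 8))
  a <- vapply(c("A", "B"), function(s)
    2 * (w - w_b) * sum(tr$length_km[tr$stratum == s]) / 1000, 0)
  design <- survey_design(tr, a, w = w, w_b = w_b)
  set.seed(2)
  det <- data.frame(distance = runif(12, w_b, w),
                    group_size = c(1, 2, 1, 1, 3, 1, 2, 1, 1, 1, 2, 1),
                    stratum = rep(c("A", "B"), each = 6),
                    transect_id = rep(c("A1", "A2", "B1", "B2"), each = 3))
  class(det) <- c("detections", class(det))
  list(det = det, design = design, tr = tr)
}

test_that("with perfect detection the estimator is a census", {
  s <- make_flat_survey()
  tpn <- flat_tpn_fit(n = nrow(s$det))
  phat <- detection_prob(tpn, NULL, s$det)
  expect_equal(phat, rep(1, nrow(s$det)), tolerance = 1e-9)
  est <- mrds_abundance(s$det, s$design, tpn, NULL)
  tab <- est$table
  expect_equal(tab$Nhat[tab$stratum == "A"], sum(s$det$group_size[s$det$stratum == "A"]),
               tolerance = 1e-8)
  expect_equal(tab$Nhat[tab$stratum == "Total"], sum(s$det$group_size),
               tolerance = 1e-8)
  # no detection-model uncertainty: total CV equals the encounter-rate CV
  expect_equal(tab$cv_model, rep(0, 3), tolerance = 1e-10)
  expect_equal(tab$cv, tab$cv_er, tolerance = 1e-10)
  expect_true(all(tab$lcl <= tab$Nhat & tab$Nhat <= tab$ucl))
})

test_that("detection probability composes the two stages exactly", {
  p <- reference_tpn()
  gamma <- reference_mr()
  z <- data.frame(bin2sd1000 = 0, tranflat = 0, bed = 0, pcvr5 = 0,
                  pilot_group = 0, observer_group = 0, distance = 500,
                  group_size = 1, stratum = "A", transect_id = "A1")
  tpn <- tpn_fit_from_params(p, data = z)
  mr <- mr_fit_from_coefs(gamma, data = z)
  got <- suppressWarnings(detection_prob(tpn, mr, z))
  # independent oracle: quadrature for the shape integral, inverse-logit union
  mu <- exp(p$ln_mu)
  quad <- stats::integrate(function(u) tpn_g(u, p, z[rep(1, length(u)), ]),
                           22, 1000, rel.tol = 1e-12)$value
  lp1 <- 0.7711 - 0.0013 * mu
  lp2 <- lp1 + 0.2977
  pdot <- plogis(lp1) + plogis(lp2) - plogis(lp1) * plogis(lp2)
  expect_equal(got, pdot * quad / 978, tolerance = 1e-8)

  # a constant union of 0.5 with a flat shape gives exactly 0.5
  g_half <- c("(Intercept)" = qlogis(1 - sqrt(0.5)))
  mr_half <- mr_fit_from_coefs(g_half, data = z)
  expect_equal(suppressWarnings(detection_prob(flat_tpn_fit(), mr_half, z)),
               0.5, tolerance = 1e-9)
})

test_that("encounter rates and their among-transect variance match hand computation", {
  v <- tpnmrds:::er_variance_r2(counts = c(2, 0, 4), lengths = c(1, 2, 3))
  expect_equal(v$er, 1)
  expect_equal(v$var, 0.25)   # K/(L^2(K-1)) * sum l_k^2 (n_k/l_k - ER)^2
  expect_equal(v$se, 0.5)
  expect_error(tpnmrds:::er_variance_r2(2, 5), "fewer than 2 transects")

  s <- make_flat_survey()
  er <- encounter_rates(s$det, s$design)
  LA <- 24
  expect_equal(er$er_individuals[er$stratum == "A"],
               sum(s$det$group_size[s$det$stratum == "A"]) / LA)
  expect_equal(er$er_groups[er$stratum == "A"], 6 / LA)
  expect_true(all(er$er_groups <= er$er_individuals))
  expect_true(all(er$se_individuals >= 0))
})

test_that("log-normal intervals match the closed-form multiplier", {
  est <- 1682.9; cv <- 0.1036
  C <- exp(qnorm(0.975) * sqrt(log(1 + cv^2)))
  ci <- lognormal_ci(est, cv)
  expect_equal(unname(ci), c(est / C, est * C), tolerance = 1e-12)
  # at the published scale the multiplier is ~1.2246
  expect_equal(unname(ci), c(1374.2, 2060.8), tolerance = 2e-4)
  expect_true(ci[1] <= est && est <= ci[2])
})

test_that("Horvitz-Thompson weighting never shrinks the count and p=1 forcing shrinks Nhat", {
  sc <- small_scenario()
  sim <- simulate_survey(sc, seed = 17)
  tpn <- fit_tpn(sim$detections, covariates = c("bin2sd1000", "tranflat"),
                 w_b = 22, w = 1000)
  mr <- fit_mr(sim$detections,
               covariates = c("bed", "observer", "pilot_group", "distance",
                              "pcvr5", "observer_group"))
  # this replicate carries a handful of low detection probabilities, which the
  # estimator flags (screen_probs territory); the algebraic bounds still hold
  phat <- suppressWarnings(detection_prob(tpn, mr, sim$detections))
  expect_true(all(phat > 0 & phat <= 1))
  expect_gte(sum(sim$detections$group_size / phat), sum(sim$detections$group_size))

  est_mrds <- suppressWarnings(mrds_abundance(sim$detections, sim$design, tpn, mr))
  est_perfect <- suppressWarnings(mrds_abundance(sim$detections, sim$design, tpn, NULL))
  expect_lt(est_perfect$apex$estimate, 1 + 1e-12)
  expect_lt(est_mrds$apex$estimate, 1)  # apex detection is imperfect here
  tot <- function(e) e$table$Nhat[e$table$stratum == "Total"]
  expect_lt(tot(est_perfect), tot(est_mrds))
  # variance components combine in quadrature
  t <- est_mrds$table
  expect_equal(t$cv^2, t$cv_er^2 + t$cv_model^2, tolerance = 1e-10)
  expect_true(all(t$density_per_1000km2 > 0))
})

test_that("the estimate is invariant to splitting transects in half", {
  s <- make_flat_survey()
  tpn <- flat_tpn_fit(n = nrow(s$det))
  est1 <- mrds_abundance(s$det, s$design, tpn, NULL)

  tr2 <- s$tr[rep(seq_len(nrow(s$tr)), each = 2), ]
  tr2$length_km <- tr2$length_km / 2
  tr2$transect_id <- paste0(tr2$transect_id, c("_a", "_b"))
  det2 <- s$det
  det2$transect_id <- paste0(det2$transect_id, "_a")  # tallies preserved
  areas <- stats::setNames(s$design$strata$area_km2, s$design$strata$stratum)
  design2 <- survey_design(tr2, areas, w = 1000, w_b = 22)
  est2 <- mrds_abundance(det2, design2, tpn, NULL)
  expect_equal(est2$table$Nhat, est1$table$Nhat, tolerance = 1e-10)
  # the among-transect variance reacts to the new effort partition
  expect_false(isTRUE(all.equal(est2$table$se, est1$table$se)))
})

test_that("estimator guards its preconditions", {
  s <- make_flat_survey()
  tpn <- flat_tpn_fit(n = nrow(s$det))
  bad_design <- s$design; bad_design$w <- 900
  expect_error(mrds_abundance(s$det, bad_design, tpn, NULL), "truncation differ")
  det_noid <- s$det; det_noid$transect_id <- NULL
  expect_error(mrds_abundance(det_noid, s$design, tpn, NULL), "transect_id")
  dup <- s$design
  dup$strata <- rbind(dup$strata, dup$strata[1, ])
  expect_error(mrds_abundance(s$det, dup, tpn, NULL), "duplicate stratum")
})
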