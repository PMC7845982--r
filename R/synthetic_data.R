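## Synthetic stratified dual-observer line-transect surveys with known truth,
## so every pipeline stage can be validated without field data.
##
## Default scenario: a two-stratum survey at the scale of a large aerial bear
## survey — habitat areas 8,648.2 and 2,868.7 km^2, efforts 7,436.4 km over
## 363 transects and 4,393.3 km over 219 transects, truncation window
## [22, 1000] m — with a two-piece normal detection truth (apex ~110.5 m off
## the line, as with flat-windowed aircraft) and a logistic dual-observer
## truth. Densities default so that roughly 253 and 106 groups are detected.

default_tpn_truth <- function() {
  tpn_params(ln_mu = 4.7046, intercept = 3.5823, igrmew = 1.8844,
             coefs = c(bin2sd1000 = 0.6620, tranflat = 0.3724))
}

default_mr_truth <- function() {
  c("(Intercept)" = 0.7711, bed = -1.1194, observer = 0.2977,
    pilot_group = 0.8515, distance = -0.0013, pcvr5 = -0.2971,
    observer_group = 1.0011)
}

default_cov_freq <- function() {
  list(bed = 64 / 359, bin2sd1000 = 61 / 359, tranflat = 87 / 359,
       pilot_group = 4 / 5, observer_group = 1 / 6,
       pcvr_probs = c(0.35, 0.20, 0.13, 0.10, 0.07, 0.05, 0.04, 0.03,
                      0.015, 0.01, 0.005))
}

#' Crew-group mapping used by simulated surveys
#'
#' Simulated surveys label pilots `P1` (group 0) and `P2`-`P5` (group 1), and
#' backseat observers `O1`-`O5` (group 0) and `O6` (group 1); this is the
#' matching `crew_groups` argument for [code_covariates()].
#'
#' @export
sim_crew_groups <- function() {
  list(pilots = c(P1 = 0, P2 = 1, P3 = 1, P4 = 1, P5 = 1),
       observers = c(O1 = 0, O2 = 0, O3 = 0, O4 = 0, O5 = 0, O6 = 1))
}

#' Mean detection probability under a covariate distribution
#'
#' Exact expectation of the point-independence detection probability
#' `p_dot(mu, z) * integral(g) / (w - w_b)` over the scenario's independent
#' covariate frequencies, by enumeration of all covariate combinations.
#'
#' @param tpn a [tpn_params()] truth.
#' @param mr named mark-resight coefficient vector.
#' @param cov_freq covariate frequency list (see [sim_scenario()]).
#' @param w_b,w truncation window (m).
#' @return scalar mean detection probability.
#' @export
mean_detection_prob <- function(tpn, mr, cov_freq, w_b, w) {
  pcvr <- cov_freq$pcvr_probs / sum(cov_freq$pcvr_probs)
  grid <- expand.grid(bed = 0:1, bin2sd1000 = 0:1, tranflat = 0:1,
                      pilot_group = 0:1, observer_group = 0:1,
                      pcvr5 = seq(0, 5, 0.5))
  pb <- function(p, v) ifelse(v == 1, p, 1 - p)
  wgt <- pb(cov_freq$bed, grid$bed) *
    pb(cov_freq$bin2sd1000, grid$bin2sd1000) *
    pb(cov_freq$tranflat, grid$tranflat) *
    pb(cov_freq$pilot_group, grid$pilot_group) *
    pb(cov_freq$observer_group, grid$observer_group) *
    pcvr[match(grid$pcvr5, seq(0, 5, 0.5))]
  mu <- exp(tpn$ln_mu)
  p1 <- mr_conditional_p(mr, "pilot", grid, distance = rep(mu, nrow(grid)))
  p2 <- mr_conditional_p(mr, "observer", grid, distance = rep(mu, nrow(grid)))
  pdot <- p1 + p2 - p1 * p2
  p <- pdot * tpn_normalizer(tpn, grid, w_b, w) / (w - w_b)
  sum(wgt * p)
}

#' Simulation scenario
#'
#' Defines the full generative truth for a stratified dual-observer survey.
#' In `"estimator_exact"` mode (the default) the union detection probability
#' of a group at distance x is `p_dot(mu, z) * g(x, z)` — exactly the
#' point-independence model the estimator assumes — and, conditional on
#' detection, the capture history is multinomial with the logistic
#' conditionals evaluated at x. In `"full_independence"` mode each observer
#' independently detects with `p_j(x, z) * g(x, z)`, a deliberately
#' misspecified truth for robustness studies.
#'
#' @param strata data.frame with columns `stratum`, `area_km2`, `n_transects`,
#'   `transect_length_km`, and either `density_groups_km2` or
#'   `target_detections` (expected detected groups, converted to a density
#'   via [mean_detection_prob()]).
#' @param w_b,w truncation window (m).
#' @param tpn distance-model truth ([tpn_params()]).
#' @param mr mark-resight truth (named coefficient vector).
#' @param cov_freq list of covariate frequencies: `bed`, `bin2sd1000`,
#'   `tranflat`, `pilot_group`, `observer_group` (Bernoulli probabilities)
#'   and `pcvr_probs` (11 weights over percent cover 0,10,...,100).
#' @param group_size_lambda rate of the zero-truncated Poisson group-size law
#'   (default 1.2, mean about 1.72 animals per group).
#' @param mode `"estimator_exact"` or `"full_independence"`.
#' @return object of class `"sim_scenario"`; `strata` gains
#'   `density_groups_km2`, `mean_p`, and `true_N` (expected animals,
#'   `density * mean group size * area`).
#' @export
sim_scenario <- function(strata = NULL, w_b = 22, w = 1000,
                         tpn = default_tpn_truth(), mr = default_mr_truth(),
                         cov_freq = default_cov_freq(),
                         group_size_lambda = 1.2,
                         mode = c("estimator_exact", "full_independence")) {
  mode <- match.arg(mode)
  if (is.null(strata)) {
    strata <- data.frame(
      stratum = c("9D", "10"),
      area_km2 = c(8648.2, 2868.7),
      n_transects = c(363L, 219L),
      transect_length_km = c(7436.4 / 363, 4393.3 / 219),
      target_detections = c(253, 106))
  }
  stopifnot(w_b >= 0, w_b < w, all(strata$area_km2 > 0),
            all(strata$n_transects >= 1), all(strata$transect_length_km > 0))
  mean_p <- mean_detection_prob(tpn, mr, cov_freq, w_b, w)
  if (is.null(strata$density_groups_km2)) {
    a <- 2 * (w - w_b) * strata$n_transects * strata$transect_length_km / 1000
    strata$density_groups_km2 <- strata$target_detections / (a * mean_p)
  }
  stopifnot(all(strata$density_groups_km2 >= 0))
  strata$mean_p <- mean_p
  strata$true_N <- strata$density_groups_km2 * ztpois_mean(group_size_lambda) *
    strata$area_km2
  structure(list(strata = strata, w_b = w_b, w = w, tpn = tpn, mr = mr,
                 cov_freq = cov_freq, group_size_lambda = group_size_lambda,
                 mode = mode),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Simulation scenario (", x$mode, " mode), window [",
      x$w_b, ", ", x$w, "] m\n", sep = "")
  print(x$strata, row.names = FALSE)
  invisible(x)
}

#' Scenario whose truth equals a pair of fitted models
#'
#' Enables closed-loop "refit the fit" experiments: simulate from the fitted
#' models on the fitted design and check that refitting recovers them.
#'
#' @param tpn_fit a `"tpn_fit"`.
#' @param mr_fit an `"mr_fit"`.
#' @param design a [survey_design()].
#' @param target_detections expected detected groups per stratum (in the order
#'   of `design$strata`), or `densities` (groups/km^2) directly.
#' @inheritParams sim_scenario
#' @export
scenario_from_fit <- function(tpn_fit, mr_fit, design, target_detections = NULL,
                              densities = NULL, cov_freq = default_cov_freq(),
                              group_size_lambda = 1.2,
                              mode = "estimator_exact") {
  strata <- data.frame(stratum = design$strata$stratum,
                       area_km2 = design$strata$area_km2,
                       n_transects = design$strata$n_transects,
                       transect_length_km = design$strata$effort_km /
                         design$strata$n_transects)
  if (!is.null(densities)) strata$density_groups_km2 <- densities
  else strata$target_detections <- target_detections %||%
      as.vector(table(factor(tpn_fit$data$stratum,
                             levels = design$strata$stratum)))
  sim_scenario(strata, w_b = design$w_b, w = design$w, tpn = tpn_fit$params,
               mr = mr_fit$coefficients, cov_freq = cov_freq,
               group_size_lambda = group_size_lambda, mode = mode)
}

#' Simulate one dual-observer survey
#'
#' Places groups uniformly in each transect's strip at distances uniform on
#' `[w_b, w]`, draws covariates from the scenario frequencies (transect type
#' and crew per transect; activity, cover and search conditions per group),
#' and applies the scenario's detection mode. Only detected groups appear in
#' the detections table, with their capture history; the latent population is
#' returned in `truth` and is never read by the estimation pipeline.
#'
#' @param scenario a [sim_scenario()].
#' @param seed optional RNG seed; a fixed seed makes output bit-identical.
#' @return list: `detections` (a `"detections"` data.frame in the default
#'   column dialect, with `transect_id`), `transects` (stratum, transect_id,
#'   length_km), `design` (a [survey_design()]), and `truth` (`true_N` per
#'   stratum and the latent group table).
#' @export
simulate_survey <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  w_b <- scenario$w_b; w <- scenario$w
  fq <- scenario$cov_freq
  pcvr_levels <- seq(0, 100, 10)
  pcvr_probs <- fq$pcvr_probs / sum(fq$pcvr_probs)
  mu <- exp(scenario$tpn$ln_mu)

  det_list <- list(); lat_list <- list(); tr_list <- list()
  for (i in seq_len(nrow(scenario$strata))) {
    st <- scenario$strata[i, ]
    K <- st$n_transects
    tid <- sprintf("%s-%03d", st$stratum, seq_len(K))
    lens <- rep(st$transect_length_km, K)
    t_flat <- stats::rbinom(K, 1, fq$tranflat)
    t_pgrp <- stats::rbinom(K, 1, fq$pilot_group)
    t_ogrp <- stats::rbinom(K, 1, fq$observer_group)
    pilot <- ifelse(t_pgrp == 1, sample(c("P2", "P3", "P4", "P5"), K, TRUE), "P1")
    observer <- ifelse(t_ogrp == 1, "O6", sample(paste0("O", 1:5), K, TRUE))
    tr_list[[i]] <- data.frame(stratum = st$stratum, transect_id = tid,
                               length_km = lens)

    strip_km2 <- 2 * (w - w_b) * lens / 1000
    n_k <- stats::rpois(K, st$density_groups_km2 * strip_km2)
    n <- sum(n_k)
    if (n == 0) next
    kk <- rep(seq_len(K), n_k)
    z <- data.frame(
      stratum = st$stratum,
      transect_id = tid[kk],
      distance = stats::runif(n, w_b, w),
      bed = stats::rbinom(n, 1, fq$bed),
      bin2sd1000 = stats::rbinom(n, 1, fq$bin2sd1000),
      tranflat = t_flat[kk],
      pilot_group = t_pgrp[kk],
      observer_group = t_ogrp[kk],
      percent_cover = sample(pcvr_levels, n, TRUE, prob = pcvr_probs),
      group_size = rztpois(n, scenario$group_size_lambda),
      pilot = pilot[kk], observer = observer[kk],
      stringsAsFactors = FALSE)
    z$pcvr5 <- z$percent_cover / 20

    g <- tpn_g(z$distance, scenario$tpn, z)
    p1 <- mr_conditional_p(scenario$mr, "pilot", z)
    p2 <- mr_conditional_p(scenario$mr, "observer", z)
    if (scenario$mode == "estimator_exact") {
      pdot_mu1 <- mr_conditional_p(scenario$mr, "pilot", z, distance = rep(mu, n))
      pdot_mu2 <- mr_conditional_p(scenario$mr, "observer", z, distance = rep(mu, n))
      pdot_mu <- pdot_mu1 + pdot_mu2 - pdot_mu1 * pdot_mu2
      detected <- stats::runif(n) < pdot_mu * g
      u <- p1 + p2 - p1 * p2
      pr <- cbind(p1 * (1 - p2), (1 - p1) * p2, p1 * p2) / u
      hidx <- vapply(seq_len(n), function(j)
        sample.int(3, 1, prob = pr[j, ]), 0L)
      history <- c("pilot", "observer", "both")[hidx]
    } else {
      d1 <- stats::runif(n) < p1 * g
      d2 <- stats::runif(n) < p2 * g
      detected <- d1 | d2
      history <- ifelse(d1 & d2, "both", ifelse(d1, "pilot", "observer"))
    }
    z$detected <- detected
    z$history <- ifelse(detected, history, NA_character_)
    lat_list[[i]] <- z

    d <- z[detected, , drop = FALSE]
    if (nrow(d)) {
      d$activity <- ifelse(d$bed == 1, "bedded",
                           sample(c("feeding", "standing", "walking", "running"),
                                  nrow(d), TRUE))
      d$search_distance <- ifelse(d$bin2sd1000 == 1,
                                  stats::runif(nrow(d), 1000.1, 3000),
                                  stats::runif(nrow(d), 100, 1000))
      d$transect_type <- ifelse(d$tranflat == 1, "straight", "contour")
      det_list[[length(det_list) + 1]] <-
        d[, c("distance", "search_distance", "group_size", "activity",
              "percent_cover", "transect_type", "pilot", "observer",
              "stratum", "history", "transect_id",
              "bed", "pcvr5", "bin2sd1000", "tranflat",
              "pilot_group", "observer_group")]
    }
  }
  transects <- do.call(rbind, tr_list)
  detections <- if (length(det_list)) do.call(rbind, det_list) else NULL
  if (!is.null(detections)) {
    rownames(detections) <- NULL
    class(detections) <- unique(c("detections", class(detections)))
    if (length(unique(detections$stratum)) == 2) {
      lv <- sort(unique(detections$stratum))
      detections$stratum_indicator <- as.numeric(detections$stratum == lv[2])
    }
  }
  n_expected <- sum(vapply(seq_len(nrow(scenario$strata)), function(i)
    scenario$strata$density_groups_km2[i] * 2 * (w - w_b) / 1000 *
      scenario$strata$n_transects[i] * scenario$strata$transect_length_km[i] *
      scenario$strata$mean_p[i], 0))
  if (n_expected < 30)
    warning("expected detections < 30; model fits will be unstable")
  design <- survey_design(transects,
                          stats::setNames(scenario$strata$area_km2,
                                          scenario$strata$stratum),
                          w = w, w_b = w_b)
  truth <- list(true_N = stats::setNames(scenario$strata$true_N,
                                         scenario$strata$stratum),
                latent = do.call(rbind, lat_list), scenario = scenario)
  list(detections = detections, transects = transects, design = design,
       truth = truth)
}

#' Write a simulated survey to CSV files
#'
#' Emits `detections.csv` and `transects.csv` in exactly the dialect
#' [read_detections()] and [read_transects()] consume, plus `truth.csv` (the
#' latent population, never read by the pipeline) and `scenario.yaml`.
#'
#' @param sim output of [simulate_survey()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_survey <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_detections(sim$detections, file.path(dir, "detections.csv"))
  utils::write.csv(sim$transects, file.path(dir, "transects.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth$latent, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  sc <- sim$truth$scenario
  yaml::write_yaml(list(
    mode = sc$mode, w_b = sc$w_b, w = sc$w,
    group_size_lambda = sc$group_size_lambda,
    strata = lapply(seq_len(nrow(sc$strata)), function(i) as.list(sc$strata[i, ])),
    tpn = list(ln_mu = sc$tpn$ln_mu, intercept = sc$tpn$intercept,
               igrmew = sc$tpn$igrmew, coefs = as.list(sc$tpn$coefs),
               interactions = as.list(sc$tpn$interactions)),
    mr = as.list(sc$mr), cov_freq = sc$cov_freq),
    file.path(dir, "scenario.yaml"))
  invisible(dir)
}
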