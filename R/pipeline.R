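## Config-driven pipeline entry points tying the stages together: read ->
## truncate -> code -> model selection for both stages -> goodness of fit ->
## abundance -> harvest, plus a simulation-study driver. A thin command-line
## wrapper over these functions ships in inst/cli/tpnmrds.R.

read_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

config_hash <- function(config) {
  config$out_dir <- NULL   # hash the analysis inputs, not the output location
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

run_manifest <- function(config) {
  list(package = "tpnmrds",
       version = as.character(utils::packageVersion("tpnmrds")),
       config_hash = config_hash(config))
}

write_json_out <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

tpn_fit_json <- function(fit) {
  list(model = "two-piece normal MCDS",
       coefficients = as.list(fit$coefficients),
       se = as.list(stats::setNames(sqrt(diag(fit$vcov)), names(fit$coefficients))),
       vcov = unname(fit$vcov), loglik = fit$loglik, aic = fit$aic,
       n = fit$n, apex_m = exp(fit$params$ln_mu),
       covariates = fit$covariates, asym_interactions = fit$asym_interactions,
       truncation = list(w_b = fit$w_b, w = fit$w))
}

mr_fit_json <- function(fit, apex = NULL) {
  list(model = "conditional dual-observer logistic",
       coefficients = as.list(fit$coefficients),
       se = as.list(stats::setNames(sqrt(diag(fit$vcov)), names(fit$coefficients))),
       vcov = unname(fit$vcov), loglik = fit$loglik, aic = fit$aic, n = fit$n,
       apex_p = if (!is.null(apex))
         list(estimate = apex$estimate, se = apex$se))
}

gof_json <- function(g) {
  if (is.null(g)) return(NULL)
  list(chisq = g$chisq, df = g$df, p = g$p,
       ks_stat = g$ks_stat, ks_p = g$ks_p,
       apex_contribution = g$apex_contribution)
}

#' Run the fitting stage from a configuration
#'
#' Reads and validates the detection and transect tables, truncates, codes
#' covariates, runs forward AIC selection (or fits fixed formulas) for the
#' distance and mark-resight stages, and computes goodness of fit and the
#' detection-probability screen. Artifacts are written as JSON when `out_dir`
#' is configured.
#'
#' Config fields: `detections`, `transects` (paths), optional `columns` /
#' `transect_columns` mappings, `crew_groups` (`pilots`, `observers` named 0/1
#' maps), `truncation` (`w`, `w_b`), `strata` (named areas km^2), `mcds`
#' (`candidates` or `covariates` + `asym_interactions`, optional `gof_bins`),
#' `mr` (`candidates` or `covariates`, optional `gof_bins`), optional
#' `out_dir`.
#'
#' @param config list or path to a YAML/JSON file.
#' @return list with `detections`, `design`, `tpn` (selection or fit), `mr`,
#'   `gof_mcds`, `gof_mr`, `screen`, `truncation_report`, `manifest`.
#' @export
run_fit <- function(config) {
  cfg <- read_config(config)
  for (f in c("detections", "transects", "truncation", "strata", "crew_groups"))
    if (is.null(cfg[[f]])) stop("config is missing required field: ", f)
  w <- cfg$truncation$w; w_b <- cfg$truncation$w_b %||% 0
  det <- read_detections(cfg$detections, cfg$columns %||% list())
  tra <- read_transects(cfg$transects, cfg$transect_columns %||% list())
  design <- survey_design(tra, unlist(cfg$strata), w = w, w_b = w_b)
  trunc <- truncate_detections(det, w = w, w_b = w_b)
  crew <- lapply(cfg$crew_groups, unlist)
  coded <- code_covariates(trunc$detections, crew, sd_cut = cfg$sd_cut %||% w)

  mcds_cfg <- cfg$mcds %||% list()
  tfit <- tpn_forward_fitter(w_b, w)
  if (!is.null(mcds_cfg$candidates)) {
    tpn_res <- forward_select(coded, unlist(mcds_cfg$candidates), tfit,
                              gof_fun = function(f) mcds_gof(f, nbins = mcds_cfg$gof_bins),
                              phat_fun = function(f) detection_prob(f, NULL, coded))
    tpn_fit <- tpn_res$fit
  } else {
    tpn_fit <- fit_tpn(coded,
                       covariates = unlist(mcds_cfg$covariates) %||% character(0),
                       asym_interactions = unlist(mcds_cfg$asym_interactions) %||%
                         character(0),
                       w_b = w_b, w = w)
    tpn_res <- NULL
  }
  gof_mcds <- mcds_gof(tpn_fit, nbins = mcds_cfg$gof_bins)

  mr_cfg <- cfg$mr %||% list()
  mfit <- mr_forward_fitter()
  if (!is.null(mr_cfg$candidates)) {
    mr_res <- forward_select(coded, unlist(mr_cfg$candidates), mfit,
                             gof_fun = function(f) mr_gof(f, nbins = mr_cfg$gof_bins))
    mr_fit <- mr_res$fit
  } else {
    mr_fit <- mfit(coded, unlist(mr_cfg$covariates) %||% character(0))
    mr_res <- NULL
  }
  gof_mr <- mr_gof(mr_fit, nbins = mr_cfg$gof_bins)

  phat <- suppressWarnings(detection_prob(tpn_fit, mr_fit, coded))
  screen <- screen_probs(phat)
  apex <- apex_detection(mr_fit, exp(tpn_fit$params$ln_mu), coded,
                         weights = 1 / phat)
  manifest <- run_manifest(cfg)
  out <- list(detections = coded, design = design, tpn = tpn_fit, mr = mr_fit,
              tpn_selection = tpn_res, mr_selection = mr_res,
              gof_mcds = gof_mcds, gof_mr = gof_mr, screen = screen,
              apex = apex, truncation_report = trunc[c("n_removed", "removed",
                                                       "prop_removed")],
              manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    write_json_out(c(manifest,
                     list(mcds = c(tpn_fit_json(tpn_fit),
                                   list(gof = gof_json(gof_mcds))),
                          mr = c(mr_fit_json(mr_fit, apex),
                                 list(gof = gof_json(gof_mr))),
                          screen = screen,
                          truncation = out$truncation_report["n_removed"])),
                   file.path(cfg$out_dir, "fits.json"))
  }
  out
}

#' Run the estimation stage
#'
#' Combines the fitted stages into stratified abundance (with encounter-rate
#' and model variance and log-normal intervals) and, when the config carries
#' harvest counts, harvest rates per stratum.
#'
#' Config additions over [run_fit()]: optional `harvest`, a list per stratum
#' of `counts` (1 or 2 regulatory years) and `scheme`
#' (`"annual"`/`"biennial"`).
#'
#' @param config list or path, as in [run_fit()].
#' @param fits optional result of [run_fit()] (recomputed otherwise).
#' @return list with `abundance` (an `"abundance"` object), `harvest` (named
#'   list of `"harvest_rate"` objects), `manifest`.
#' @export
run_estimate <- function(config, fits = NULL) {
  cfg <- read_config(config)
  fits <- fits %||% run_fit(cfg)
  est <- mrds_abundance(fits$detections, fits$design, fits$tpn, fits$mr)
  harv <- NULL
  if (!is.null(cfg$harvest)) {
    harv <- lapply(names(cfg$harvest), function(s) {
      if (!s %in% est$table$stratum) stop("harvest stratum not estimated: ", s)
      h <- cfg$harvest[[s]]
      H <- effective_annual_harvest(unlist(h$counts), h$scheme %||% "annual")
      harvest_rate(H, est, stratum = s)
    })
    names(harv) <- names(cfg$harvest)
  }
  manifest <- run_manifest(cfg)
  if (!is.null(cfg$out_dir)) {
    write_json_out(c(manifest, list(
      abundance = est$table,
      apex_p = list(estimate = est$apex$estimate, se = est$apex$se),
      harvest = lapply(harv, function(h)
        list(rate = h$rate, se = h$se, lcl = h$lcl, ucl = h$ucl,
             harvest = h$harvest)))),
      file.path(cfg$out_dir, "estimates.json"))
    txt <- file.path(cfg$out_dir, "estimates.txt")
    sink(txt); print(est); if (!is.null(harv)) for (h in harv) print(h); sink()
  }
  list(abundance = est, harvest = harv, manifest = manifest)
}

#' Simulation study: simulate, refit, estimate
#'
#' Runs `replicates` estimator-exact (or full-independence) surveys from a
#' scenario, refits both model stages with the scenario's true covariate
#' structure, estimates abundance, and summarizes relative bias, confidence
#' interval coverage of the true total, and Wald coverage of the true
#' coefficients.
#'
#' @param scenario a [sim_scenario()].
#' @param replicates number of replicate surveys.
#' @param seed RNG seed for the whole study.
#' @param tpn_covariates,tpn_interactions,mr_covariates covariate structure to
#'   refit (defaults: the scenario truth's structure).
#' @param progress print a dot every 10 replicates.
#' @return list: `summary` (relative bias of total N, CI coverage, coefficient
#'   coverage rates), `replicates` (per-replicate data.frame), `scenario`.
#' @export
run_simulate <- function(scenario, replicates = 100, seed = 1,
                         tpn_covariates = NULL, tpn_interactions = NULL,
                         mr_covariates = NULL, progress = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(seed)
  tpn_covariates <- tpn_covariates %||% names(scenario$tpn$coefs)
  tpn_interactions <- tpn_interactions %||% names(scenario$tpn$interactions)
  mr_covariates <- mr_covariates %||%
    setdiff(names(scenario$mr), "(Intercept)")
  true_total <- sum(scenario$strata$true_N)
  true_tpn <- c(ln_mu = scenario$tpn$ln_mu,
                "(Intercept)" = unname(scenario$tpn$intercept),
                igrmew = unname(scenario$tpn$igrmew),
                scenario$tpn$coefs,
                if (length(scenario$tpn$interactions))
                  stats::setNames(scenario$tpn$interactions,
                                  paste0("igrmew:", names(scenario$tpn$interactions))))
  rows <- list(); tpn_cover <- list(); mr_cover <- list()
  for (r in seq_len(replicates)) {
    sim <- simulate_survey(scenario)
    if (is.null(sim$detections) || nrow(sim$detections) < 30) next
    fit_t <- try(fit_tpn(sim$detections, covariates = tpn_covariates,
                         asym_interactions = tpn_interactions,
                         w_b = scenario$w_b, w = scenario$w), silent = TRUE)
    fit_m <- try(fit_mr(sim$detections, covariates = mr_covariates),
                 silent = TRUE)
    if (inherits(fit_t, "try-error") || inherits(fit_m, "try-error")) next
    est <- try(suppressWarnings(
      mrds_abundance(sim$detections, sim$design, fit_t, fit_m)), silent = TRUE)
    if (inherits(est, "try-error")) next
    tot <- est$table[est$table$stratum == "Total", ]
    rows[[length(rows) + 1]] <- data.frame(
      replicate = r, Nhat = tot$Nhat, se = tot$se, cv = tot$cv,
      lcl = tot$lcl, ucl = tot$ucl,
      covered = tot$lcl <= true_total && true_total <= tot$ucl,
      n_detections = nrow(sim$detections))
    se_t <- sqrt(diag(fit_t$vcov))
    tpn_cover[[length(tpn_cover) + 1]] <-
      abs(fit_t$coefficients - true_tpn[names(fit_t$coefficients)]) <=
        1.96 * se_t
    se_m <- sqrt(diag(fit_m$vcov))
    mr_cover[[length(mr_cover) + 1]] <-
      abs(fit_m$coefficients - scenario$mr[names(fit_m$coefficients)]) <=
        1.96 * se_m
    if (progress && r %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")
  reps <- do.call(rbind, rows)
  if (is.null(reps) || nrow(reps) < 2) stop("too few successful replicates")
  summary <- list(
    replicates_used = nrow(reps),
    true_total = true_total,
    mean_Nhat = mean(reps$Nhat),
    relative_bias = mean(reps$Nhat) / true_total - 1,
    ci_coverage = mean(reps$covered),
    tpn_coef_coverage = colMeans(do.call(rbind, tpn_cover)),
    mr_coef_coverage = colMeans(do.call(rbind, mr_cover)),
    mean_cv = mean(reps$cv),
    sd_Nhat = stats::sd(reps$Nhat))
  list(summary = summary, replicates = reps, scenario = scenario)
}
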