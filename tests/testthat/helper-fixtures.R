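## Fixture builders shared across test files. Everything is generated in code;
## no data files are shipped.

## A tiny, hand-written detections table in the default CSV dialect.
tiny_detections_df <- function() {
  data.frame(
    distance = c(150, 420, 80),
    search_distance = c(800, 1500, 600),
    group_size = c(1, 3, 2),
    activity = c("bedded", "walking", "feeding"),
    percent_cover = c(20, 0, 60),
    transect_type = c("contour", "straight", "contour"),
    pilot = c("P1", "P2", "P1"),
    observer = c("O1", "O1", "O6"),
    stratum = c("A", "A", "B"),
    history = c("both", "pilot", "observer"),
    transect_id = c("A-1", "A-2", "B-1"),
    stringsAsFactors = FALSE)
}

tiny_crew_groups <- function() {
  list(pilots = c(P1 = 0, P2 = 1), observers = c(O1 = 0, O6 = 1))
}

## Reduced-scale two-stratum scenario used where the full study scale would be
## wasteful; same truth as the default scenario.
small_scenario <- function(...) {
  sim_scenario(strata = data.frame(
    stratum = c("A", "B"),
    area_km2 = c(4000, 2000),
    n_transects = c(60, 40),
    transect_length_km = c(20, 20),
    target_detections = c(160, 80)), ...)
}

## A "flat" distance model whose shape is ~1 everywhere on the window and
## carries zero parameter uncertainty: detection is perfect given the
## mark-resight stage, which makes Horvitz-Thompson limits exact.
flat_tpn_fit <- function(w_b = 22, w = 1000, n = 10) {
  params <- tpn_params(ln_mu = log((w_b + w) / 2), intercept = 20, igrmew = 0)
  par <- c(ln_mu = params$ln_mu, "(Intercept)" = 20, igrmew = 0)
  structure(list(params = params, coefficients = par,
                 vcov = matrix(0, 3, 3, dimnames = list(names(par), names(par))),
                 loglik = 0, aic = 6, npar = 3, n = n,
                 covariates = character(0), asym_interactions = character(0),
                 w_b = w_b, w = w, data = NULL, convergence = 0),
            class = "tpn_fit")
}

## A fitted-looking tpn_fit wrapper around known parameters (zero vcov),
## so estimator-level oracles can be evaluated at exact coefficients.
tpn_fit_from_params <- function(params, w_b = 22, w = 1000, data = NULL) {
  nms <- c("ln_mu", "(Intercept)", "igrmew", names(params$coefs),
           if (length(params$interactions))
             paste0("igrmew:", names(params$interactions)))
  par <- c(params$ln_mu, params$intercept, params$igrmew,
           params$coefs, params$interactions)
  names(par) <- nms
  p <- length(par)
  structure(list(params = params, coefficients = par,
                 vcov = matrix(0, p, p, dimnames = list(nms, nms)),
                 loglik = 0, aic = 2 * p, npar = p,
                 n = if (is.null(data)) 10 else nrow(data),
                 covariates = names(params$coefs),
                 asym_interactions = names(params$interactions),
                 w_b = w_b, w = w, data = data, convergence = 0),
            class = "tpn_fit")
}

mr_fit_from_coefs <- function(gamma, data = NULL, vcov = NULL) {
  p <- length(gamma)
  vc <- vcov %||% matrix(0, p, p)
  dimnames(vc) <- list(names(gamma), names(gamma))
  structure(list(coefficients = gamma, vcov = vc, loglik = 0, aic = 2 * p,
                 npar = p, n = if (is.null(data)) 10 else nrow(data),
                 covariates = setdiff(names(gamma), "(Intercept)"),
                 data = data, convergence = 0),
            class = "mr_fit")
}

## Detection-model truth used by the published-scale examples: apex ~110.5 m,
## left scale ~36 m, right scale ~237 m.
reference_tpn <- function() {
  tpn_params(ln_mu = 4.7046, intercept = 3.5823, igrmew = 1.8844,
             coefs = c(bin2sd1000 = 0.6620, tranflat = 0.3724))
}

reference_mr <- function() {
  c("(Intercept)" = 0.7711, bed = -1.1194, observer = 0.2977,
    pilot_group = 0.8515, distance = -0.0013, pcvr5 = -0.2971,
    observer_group = 1.0011)
}
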