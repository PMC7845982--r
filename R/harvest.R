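## Harvest-rate estimation from reported legal harvest and an abundance
## estimate. Where hunts open every other regulatory year, reported harvest is
## averaged over the two-year (closed + open) period. The rate is
## H / (H + Nhat) on the post-hunt estimate; its confidence limits come from
## the abundance confidence limits by the same monotone map, and its SE is the
## abundance CV applied to the rate. No uncertainty is attached to the
## reported harvest itself (sealing makes it a near-census of legal kill);
## unreported harvest is out of scope.

#' Effective annual harvest
#'
#' @param counts reported legal harvest per regulatory year (non-negative
#'   integers).
#' @param scheme `"annual"` (one year) or `"biennial"` (exactly two
#'   consecutive years, averaged).
#' @return bears per year.
#' @export
effective_annual_harvest <- function(counts, scheme = c("annual", "biennial")) {
  scheme <- match.arg(scheme)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (scheme == "biennial") {
    if (length(counts) != 2)
      stop("biennial scheme requires exactly 2 consecutive years of counts")
    mean(counts)
  } else {
    if (length(counts) != 1) stop("annual scheme requires a single year's count")
    counts
  }
}

#' Harvest rate with confidence interval
#'
#' @param harvest effective annual harvest (bears/year), see
#'   [effective_annual_harvest()].
#' @param nhat abundance point estimate, or an `"abundance"` object together
#'   with `stratum`.
#' @param cv abundance coefficient of variation (proportion scale).
#' @param lcl,ucl abundance 95% confidence limits.
#' @param stratum stratum label, when `nhat` is an `"abundance"` object.
#' @return object of class `"harvest_rate"`: `rate`, `se`, `lcl`, `ucl`
#'   (proportions) plus the inputs. The upper rate limit uses the lower
#'   abundance limit and vice versa.
#' @export
harvest_rate <- function(harvest, nhat, cv = NULL, lcl = NULL, ucl = NULL,
                         stratum = NULL) {
  if (inherits(nhat, "abundance")) {
    if (is.null(stratum)) stop("supply a stratum label with an abundance object")
    row <- nhat$table[nhat$table$stratum == stratum, ]
    if (nrow(row) != 1) stop("stratum not found in abundance table: ", stratum)
    cv <- row$cv; lcl <- row$lcl; ucl <- row$ucl; nhat <- row$Nhat
  }
  stopifnot(harvest >= 0, nhat >= 0, !is.null(cv), !is.null(lcl), !is.null(ucl))
  if (harvest == 0 && nhat == 0) stop("harvest rate undefined: H = 0 and Nhat = 0")
  rate <- harvest / (harvest + nhat)
  structure(list(rate = rate, se = cv * rate,
                 lcl = harvest / (harvest + ucl),
                 ucl = harvest / (harvest + lcl),
                 harvest = harvest, nhat = nhat, cv = cv,
                 nhat_lcl = lcl, nhat_ucl = ucl),
            class = "harvest_rate")
}

#' @export
print.harvest_rate <- function(x, ...) {
  pct <- function(v) paste0(fmt_num(100 * v, 2), "%")
  cat("Harvest rate estimate\n")
  cat("  annual harvest:", x$harvest, " abundance:", fmt_num(x$nhat, 1),
      "(CV", paste0(fmt_num(100 * x$cv, 2), "%)"), "\n")
  cat("  rate:", pct(x$rate), " SE:", pct(x$se),
      " 95% CI: (", pct(x$lcl), ",", pct(x$ucl), ")\n")
  invisible(x)
}
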