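## Reading, validation, truncation and covariate coding for dual-observer
## line-transect survey data.
##
## Units convention (used throughout the package): perpendicular and search
## distances in metres, transect lengths in kilometres, areas in km^2. All
## unit conversions happen in the abundance estimator, nowhere else.

#' Default column mapping for detection tables
#'
#' Detection CSVs in the wild carry many column-name dialects; every reader in
#' this package goes through a configurable name mapping whose defaults are
#' listed here. Names are the internal fields, values are the expected CSV
#' column headers.
#'
#' @return named list of column names.
#' @export
detection_columns <- function() {
  list(distance        = "distance",
       search_distance = "search_distance",
       group_size      = "group_size",
       activity        = "activity",
       percent_cover   = "percent_cover",
       transect_type   = "transect_type",
       pilot           = "pilot",
       observer        = "observer",
       stratum         = "stratum",
       history         = "history",
       transect_id     = "transect_id",   # optional
       group_type      = "group_type",    # optional, retained unused
       plane_speed     = "plane_speed",   # optional, retained unused
       percent_snow    = "percent_snow")  # optional, retained unused
}

.required_detection_fields <- c("distance", "search_distance", "group_size",
                                "activity", "percent_cover", "transect_type",
                                "pilot", "observer", "stratum", "history")

.activity_levels <- c("bedded", "feeding", "standing", "walking", "running")
.transect_types <- c("contour", "straight", "hinged", "straight/hinged")

## Capture-history synonyms: who saw the group. "neither" is impossible by
## construction (only detected groups are recorded) and is rejected.
.normalize_history <- function(h) {
  h <- tolower(trimws(h))
  h[h %in% c("pilot", "pilot-only", "pilot_only", "p", "10")] <- "pilot"
  h[h %in% c("observer", "backseat", "backseat-only", "observer-only",
             "backseat_only", "o", "01")] <- "observer"
  h[h %in% c("both", "b", "11")] <- "both"
  h
}

#' Read a detections table
#'
#' Reads a CSV of detected animal groups (one row per group) and validates
#' every field. Rows that violate an invariant are reported with their line
#' numbers and reading fails, so bad data never reaches a model fit.
#'
#' @param path CSV file with a header row.
#' @param columns column-name mapping; see [detection_columns()] for defaults.
#'   Partial lists are merged over the defaults.
#' @return a `data.frame` of class `"detections"` with standardized column
#'   names: `distance` (m), `search_distance` (m), `group_size`, `activity`,
#'   `percent_cover`, `transect_type`, `pilot`, `observer`, `stratum`,
#'   `history` (one of `"pilot"`, `"observer"`, `"both"`), plus any optional
#'   columns present (`transect_id`, `group_type`, `plane_speed`,
#'   `percent_snow`).
#' @export
read_detections <- function(path, columns = list()) {
  if (!file.exists(path)) stop("detections file not found: ", path)
  cols <- utils::modifyList(detection_columns(), columns)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- vapply(.required_detection_fields,
                    function(f) !(cols[[f]] %in% names(raw)), TRUE)
  if (any(missing)) {
    stop("detections file is missing required column(s): ",
         paste(unlist(cols[.required_detection_fields][missing]), collapse = ", "),
         " (adjust the column mapping if your file uses different headers)")
  }
  out <- list()
  for (f in names(cols)) {
    if (cols[[f]] %in% names(raw)) out[[f]] <- raw[[cols[[f]]]]
  }
  as_detections(as.data.frame(out, stringsAsFactors = FALSE))
}

#' Validate and classify a detections data frame
#'
#' @param x data.frame with the standardized detection columns.
#' @return `x` with class `"detections"` prepended.
#' @export
as_detections <- function(x) {
  stopifnot(is.data.frame(x))
  miss <- setdiff(.required_detection_fields, names(x))
  if (length(miss)) stop("missing detection field(s): ", paste(miss, collapse = ", "))
  errs <- character(0)
  bad <- function(rows, what) {
    if (any(rows)) errs <<- c(errs, paste0("row ", paste(which(rows), collapse = ","),
                                           ": ", what))
  }
  x$distance <- suppressWarnings(as.numeric(x$distance))
  x$search_distance <- suppressWarnings(as.numeric(x$search_distance))
  x$group_size <- suppressWarnings(as.numeric(x$group_size))
  x$percent_cover <- suppressWarnings(as.numeric(x$percent_cover))
  x$activity <- tolower(trimws(as.character(x$activity)))
  x$transect_type <- tolower(trimws(as.character(x$transect_type)))
  x$history <- .normalize_history(as.character(x$history))
  bad(is.na(x$distance) | x$distance < 0, "distance must be a number >= 0")
  bad(is.na(x$search_distance) | x$search_distance < 0,
      "search_distance must be a number >= 0")
  bad(is.na(x$group_size) | x$group_size < 1 | x$group_size != round(x$group_size),
      "group_size must be an integer >= 1")
  bad(is.na(x$percent_cover) | !(x$percent_cover %in% seq(0, 100, 10)),
      "percent_cover must be in {0,10,...,100}")
  bad(!(x$activity %in% .activity_levels),
      paste0("activity must be one of ", paste(.activity_levels, collapse = "/")))
  bad(!(x$transect_type %in% .transect_types),
      paste0("transect_type must be one of ", paste(.transect_types, collapse = "/")))
  bad(!(x$history %in% c("pilot", "observer", "both")),
      "history must be pilot/observer/both (a 'neither' history is impossible for a detected group)")
  if (length(errs)) stop("invalid detection rows:\n  ", paste(errs, collapse = "\n  "))
  x$stratum <- as.character(x$stratum)
  class(x) <- unique(c("detections", class(x)))
  x
}

#' Write a detections table
#'
#' Inverse of [read_detections()]: writes the standardized fields back out
#' under the supplied column mapping so that read/write round-trips.
#'
#' @inheritParams read_detections
#' @param x a `"detections"` data frame.
#' @export
write_detections <- function(x, path, columns = list()) {
  cols <- utils::modifyList(detection_columns(), columns)
  out <- x[, intersect(names(cols), names(x)), drop = FALSE]
  names(out) <- unlist(cols[names(out)])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a transects table
#'
#' @param path CSV with columns for stratum and transect length (km); an
#'   optional transect id column is carried through (default: row number).
#' @param columns mapping with entries `stratum`, `length`, `transect_id`.
#' @return data.frame with columns `stratum`, `transect_id`, `length_km`.
#' @export
read_transects <- function(path, columns = list()) {
  if (!file.exists(path)) stop("transects file not found: ", path)
  cols <- utils::modifyList(list(stratum = "stratum", length = "length_km",
                                 transect_id = "transect_id"), columns)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (f in c("stratum", "length")) {
    if (!(cols[[f]] %in% names(raw)))
      stop("transects file is missing required column: ", cols[[f]])
  }
  len <- suppressWarnings(as.numeric(raw[[cols$length]]))
  if (any(is.na(len) | len <= 0)) {
    stop("invalid transect rows:\n  row ",
         paste(which(is.na(len) | len <= 0), collapse = ","),
         ": length must be a number > 0")
  }
  id <- if (cols$transect_id %in% names(raw)) as.character(raw[[cols$transect_id]])
        else as.character(seq_along(len))
  data.frame(stratum = as.character(raw[[cols$stratum]]),
             transect_id = id, length_km = len, stringsAsFactors = FALSE)
}

#' Survey design: strata, effort and truncation
#'
#' Bundles the sampled transects with stratum habitat areas and the analysis
#' truncation distances. The blind spot under the aircraft is handled as a
#' left truncation at `w_b`.
#'
#' @param transects data.frame from [read_transects()] (columns `stratum`,
#'   `transect_id`, `length_km`).
#' @param areas named numeric vector of habitat areas (km^2), one per stratum.
#' @param w right truncation distance (m).
#' @param w_b left truncation / blind-spot edge (m); `0 <= w_b < w`.
#' @return object of class `"survey_design"`.
#' @export
survey_design <- function(transects, areas, w, w_b = 0) {
  stopifnot(is.data.frame(transects), w_b >= 0, w_b < w)
  if (is.data.frame(areas)) areas <- stats::setNames(areas$area_km2, areas$stratum)
  if (is.null(names(areas)) || any(!nzchar(names(areas))))
    stop("areas must be a named vector (names = stratum labels)")
  if (any(areas <= 0)) stop("habitat areas must be > 0")
  for (s in names(areas)) {
    if (!any(transects$stratum == s)) stop("stratum has no transects: ", s)
  }
  extra <- setdiff(unique(transects$stratum), names(areas))
  if (length(extra)) stop("transects reference stratum with no area: ",
                          paste(extra, collapse = ", "))
  strata <- data.frame(
    stratum = names(areas),
    area_km2 = as.numeric(areas),
    n_transects = vapply(names(areas), function(s) sum(transects$stratum == s), 0L),
    effort_km = vapply(names(areas),
                       function(s) sum(transects$length_km[transects$stratum == s]), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(strata = strata, transects = transects, w = w, w_b = w_b),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Survey design: ", nrow(x$strata), " strata, truncation [",
      x$w_b, ", ", x$w, "] m\n", sep = "")
  print(x$strata, row.names = FALSE)
  invisible(x)
}

#' Truncate detections to the analysed strip
#'
#' Keeps detections with `w_b <= distance <= w` and reports removals per
#' stratum. Idempotent: truncating twice changes nothing.
#'
#' @param detections a `"detections"` data frame.
#' @param w right truncation distance (m).
#' @param w_b left truncation (m), `w_b < w`.
#' @return list with `detections` (retained rows), `n_removed`, and `removed`
#'   (per-stratum data.frame of removals).
#' @export
truncate_detections <- function(detections, w, w_b = 0) {
  stopifnot(w_b < w)
  keep <- detections$distance >= w_b & detections$distance <= w
  removed <- stats::aggregate(list(n_removed = !keep),
                              by = list(stratum = detections$stratum), FUN = sum)
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(detections)
  list(detections = out, n_removed = sum(!keep), removed = removed,
       prop_removed = mean(!keep))
}

#' Code analysis covariates
#'
#' Builds the deterministic coded covariates used by the detection models from
#' the raw detection fields:
#' \describe{
#'   \item{bed}{1 for bedded groups, 0 otherwise.}
#'   \item{pcvr5}{percent cover / 20, in steps of 0.5 on 0..5.}
#'   \item{bin2sd1000}{1 if the search distance exceeded `sd_cut` metres
#'     (default 1000 m, the right truncation), 0 otherwise.}
#'   \item{tranflat}{1 for straight/hinged transects, 0 for contour.}
#'   \item{pilot_group, observer_group}{0/1 crew groupings from
#'     `crew_groups`.}
#'   \item{stratum_indicator}{0/1 indicator of the second stratum level (only
#'     when exactly two strata are present).}
#' }
#' The asymmetry indicator of the two-piece normal model (1 when the distance
#' exceeds the fitted apex) depends on the fitted apex and is therefore
#' constructed inside [fit_tpn()], not here.
#'
#' @param detections a `"detections"` data frame.
#' @param crew_groups list with named 0/1 vectors `pilots` and `observers`
#'   assigning every crew id to group 0 or 1.
#' @param sd_cut search-distance cutpoint (m) for `bin2sd1000`.
#' @return the input with coded covariate columns appended.
#' @export
code_covariates <- function(detections, crew_groups, sd_cut = 1000) {
  stopifnot(is.list(crew_groups), !is.null(crew_groups$pilots),
            !is.null(crew_groups$observers))
  crew_groups <- lapply(crew_groups, unlist)   # accept YAML-style named lists
  unknown_p <- setdiff(unique(detections$pilot), names(crew_groups$pilots))
  unknown_o <- setdiff(unique(detections$observer), names(crew_groups$observers))
  if (length(unknown_p)) stop("pilot id(s) not in crew_groups$pilots: ",
                              paste(unknown_p, collapse = ", "))
  if (length(unknown_o)) stop("observer id(s) not in crew_groups$observers: ",
                              paste(unknown_o, collapse = ", "))
  if (!all(unlist(crew_groups) %in% 0:1)) stop("crew group codes must be 0 or 1")
  detections$bed <- as.numeric(detections$activity == "bedded")
  detections$pcvr5 <- detections$percent_cover / 20
  detections$bin2sd1000 <- as.numeric(detections$search_distance > sd_cut)
  detections$tranflat <- as.numeric(detections$transect_type != "contour")
  detections$pilot_group <- as.numeric(crew_groups$pilots[detections$pilot])
  detections$observer_group <- as.numeric(crew_groups$observers[detections$observer])
  strata <- sort(unique(detections$stratum))
  if (length(strata) == 2) {
    detections$stratum_indicator <- as.numeric(detections$stratum == strata[2])
  }
  detections
}
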