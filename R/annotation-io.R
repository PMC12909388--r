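#' A-P interval
#'
#' A half-open span of A-P stations (or normalized positions), `lo < hi`.
#'
#' @param lo,hi interval endpoints.
#' @return an object of class `interval`.
#' @export
interval <- function(lo, hi) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1, length(hi) == 1)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop("interval requires finite lo < hi", call. = FALSE)
  }
  structure(list(lo = lo, hi = hi), class = "interval")
}

interval_length <- function(x) x$hi - x$lo

ANNOTATION_SCHEMA_VERSION <- 1L
ANNOTATION_FIELDS <- c("schema_version", "image_id", "calibration",
                       "channel_map", "fronts", "frame_spec", "zone_polygons",
                       "epiphysis_intervals", "vertebra_interval",
                       "np_polygon", "endplate_lines")

#' Operator annotation set for one physis / vertebra image
#'
#' Collects everything an operator marks up on one micrograph: the two
#' fluorochrome front point sets, the physis frame specification, and the
#' optional morphometry annotations (zone polygons, epiphysis ossification
#' intervals, vertebral A-P interval, nucleus pulposus polygon, endplate
#' lines). All coordinates are 0-based pixels, x rightward, y downward.
#'
#' @param image_id image identifier string.
#' @param calibration a [calibration()] object. Mandatory: the scale is never
#'   inferred from the image.
#' @param fronts named list with elements `alizarin` and `oxytetracycline`,
#'   each an n x 2 matrix of control points (n >= 2).
#' @param frame_spec either the string `"auto"` (see [auto_frame()]) or a list
#'   `list(chord_start =, chord_end =, growth_sign =)`; `chord_start` is the
#'   posterior endpoint, `chord_end` the anterior endpoint.
#' @param channel_map optional named integer vector mapping fluorochrome to
#'   TIFF channel index.
#' @param zone_polygons optional list of `list(zone =, polygon =, region_tag =)`
#'   with zone in `hypertrophic`/`proliferative_reserve` and polygon a simple
#'   closed polygon (n x 2).
#' @param epiphysis_intervals optional list of
#'   `list(physis_end =, ossified = interval, total = interval)`.
#' @param vertebra_interval optional [interval()]: A-P extent of the body.
#' @param np_polygon optional simple closed polygon of the nucleus pulposus.
#' @param endplate_lines optional list of two `list(role =, p1 =, p2 =)` lines
#'   with roles `cranial` and `caudal`.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(image_id, calibration, fronts,
                           frame_spec = "auto",
                           channel_map = NULL,
                           zone_polygons = NULL,
                           epiphysis_intervals = NULL,
                           vertebra_interval = NULL,
                           np_polygon = NULL,
                           endplate_lines = NULL) {
  stopifnot(is.character(image_id), length(image_id) == 1)
  if (!inherits(calibration, "calibration")) {
    stop("field 'calibration' must be a calibration object", call. = FALSE)
  }
  if (!is.list(fronts) || !all(c("alizarin", "oxytetracycline") %in% names(fronts))) {
    stop("field 'fronts' must name both 'alizarin' and 'oxytetracycline'",
         call. = FALSE)
  }
  fronts <- lapply(fronts, function(p) {
    m <- if (is.matrix(p)) p else do.call(rbind, lapply(p, as.numeric))
    if (!is.numeric(m) || ncol(m) != 2 || nrow(m) < 2 || !all(is.finite(m))) {
      stop("field 'fronts': each front needs >= 2 finite 2-D control points",
           call. = FALSE)
    }
    unname(m)
  })
  if (!identical(frame_spec, "auto")) {
    need <- c("chord_start", "chord_end", "growth_sign")
    if (!is.list(frame_spec) || !all(need %in% names(frame_spec))) {
      stop("field 'frame_spec' must be \"auto\" or list(chord_start, chord_end, growth_sign)",
           call. = FALSE)
    }
    make_frame(frame_spec$chord_start, frame_spec$chord_end,
               frame_spec$growth_sign)  # validates
  }
  if (!is.null(zone_polygons)) {
    for (z in zone_polygons) {
      if (!z$zone %in% c("hypertrophic", "proliferative_reserve")) {
        stop(sprintf("field 'zone_polygons': unknown zone '%s'", z$zone),
             call. = FALSE)
      }
      check_polygon(z$polygon, sprintf("zone polygon (%s)", z$zone))
    }
  }
  if (!is.null(epiphysis_intervals)) {
    for (e in epiphysis_intervals) {
      if (!inherits(e$ossified, "interval") || !inherits(e$total, "interval")) {
        stop("field 'epiphysis_intervals': ossified/total must be intervals",
             call. = FALSE)
      }
    }
  }
  if (!is.null(vertebra_interval) && !inherits(vertebra_interval, "interval")) {
    stop("field 'vertebra_interval' must be an interval", call. = FALSE)
  }
  if (!is.null(np_polygon)) np_polygon <- check_polygon(np_polygon, "np_polygon")
  if (!is.null(endplate_lines)) {
    for (l in endplate_lines) {
      if (!l$role %in% c("cranial", "caudal")) {
        stop("field 'endplate_lines': role must be cranial or caudal", call. = FALSE)
      }
      if (sum((as.numeric(l$p1) - as.numeric(l$p2))^2) < 1e-18) {
        stop("field 'endplate_lines': degenerate line (p1 == p2)", call. = FALSE)
      }
    }
  }
  structure(list(image_id = image_id, calibration = calibration,
                 fronts = fronts, frame_spec = frame_spec,
                 channel_map = channel_map, zone_polygons = zone_polygons,
                 epiphysis_intervals = epiphysis_intervals,
                 vertebra_interval = vertebra_interval,
                 np_polygon = np_polygon, endplate_lines = endplate_lines),
            class = "annotation_set")
}

#' Resolve an annotation set's frame
#'
#' @param ann an [annotation_set()].
#' @return a [make_frame()] frame, built from the explicit chord or, for
#'   `"auto"`, from the alizarin front extremes ([auto_frame()]).
#' @export
resolve_frame <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  if (identical(ann$frame_spec, "auto")) {
    auto_frame(ann$fronts$alizarin, ann$fronts$oxytetracycline)
  } else {
    make_frame(ann$frame_spec$chord_start, ann$frame_spec$chord_end,
               ann$frame_spec$growth_sign)
  }
}

#' Read an annotation set from its JSON file
#'
#' The schema is documented on [annotation_set()]; unknown top-level fields
#' are ignored with a warning so that files written by newer annotators still
#' load.
#'
#' @param path path to the annotation JSON file.
#' @return a validated [annotation_set()].
#' @export
read_annotation_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  unknown <- setdiff(names(raw), ANNOTATION_FIELDS)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown annotation fields: %s",
                    paste(unknown, collapse = ", ")))
  }
  for (f in c("image_id", "calibration", "fronts")) {
    if (is.null(raw[[f]])) {
      stop(sprintf("annotation file is missing required field '%s'", f),
           call. = FALSE)
    }
  }
  cal <- calibration(raw$calibration$um_per_px, raw$calibration$delta_days)
  as_interval <- function(v) interval(v[1], v[2])
  fs <- raw$frame_spec
  if (is.null(fs)) fs <- "auto"
  if (!identical(fs, "auto")) {
    fs <- list(chord_start = as.numeric(fs$chord_start),
               chord_end = as.numeric(fs$chord_end),
               growth_sign = as.numeric(fs$growth_sign))
  }
  zones <- NULL
  if (!is.null(raw$zone_polygons) && length(raw$zone_polygons)) {
    zones <- lapply(raw$zone_polygons, function(z) {
      list(zone = z$zone, polygon = z$polygon, region_tag = z$region_tag)
    })
  }
  epi <- NULL
  if (!is.null(raw$epiphysis_intervals) && length(raw$epiphysis_intervals)) {
    epi <- lapply(raw$epiphysis_intervals, function(e) {
      list(physis_end = e$physis_end, ossified = as_interval(e$ossified),
           total = as_interval(e$total))
    })
  }
  lines <- NULL
  if (!is.null(raw$endplate_lines) && length(raw$endplate_lines)) {
    lines <- lapply(raw$endplate_lines, function(l) {
      list(role = l$role, p1 = as.numeric(l$p1), p2 = as.numeric(l$p2))
    })
  }
  annotation_set(
    image_id = raw$image_id, calibration = cal, fronts = raw$fronts,
    frame_spec = fs,
    channel_map = if (is.null(raw$channel_map)) NULL else unlist(raw$channel_map),
    zone_polygons = zones, epiphysis_intervals = epi,
    vertebra_interval = if (is.null(raw$vertebra_interval)) NULL else
      as_interval(raw$vertebra_interval),
    np_polygon = raw$np_polygon, endplate_lines = lines)
}

#' Write an annotation set to JSON
#'
#' @param ann an [annotation_set()].
#' @param path output path.
#' @export
write_annotation_set <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  out <- list(
    schema_version = ANNOTATION_SCHEMA_VERSION,
    image_id = ann$image_id,
    calibration = list(um_per_px = ann$calibration$um_per_px,
                       delta_days = ann$calibration$delta_days),
    fronts = ann$fronts,
    frame_spec = ann$frame_spec)
  if (!is.null(ann$channel_map)) out$channel_map <- as.list(ann$channel_map)
  if (!is.null(ann$zone_polygons)) out$zone_polygons <- ann$zone_polygons
  if (!is.null(ann$epiphysis_intervals)) {
    out$epiphysis_intervals <- lapply(ann$epiphysis_intervals, function(e) {
      list(physis_end = e$physis_end, ossified = c(e$ossified$lo, e$ossified$hi),
           total = c(e$total$lo, e$total$hi))
    })
  }
  if (!is.null(ann$vertebra_interval)) {
    out$vertebra_interval <- c(ann$vertebra_interval$lo, ann$vertebra_interval$hi)
  }
  if (!is.null(ann$np_polygon)) out$np_polygon <- ann$np_polygon
  if (!is.null(ann$endplate_lines)) out$endplate_lines <- ann$endplate_lines
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

COHORT_COLUMNS <- c("animal_id", "tension_group", "level", "side",
                    "rate_anterior_q", "rate_middle_h", "rate_posterior_q",
                    "rate_overall", "rate_uae", "pct_growth_modulation",
                    "thickness_hypertrophic_um", "thickness_proliferative_reserve_um",
                    "ossification_pct", "np_pct_epiphysis", "np_pct_vertebra",
                    "implant_failure")

#' Assemble a cohort record row
#'
#' One row of the long-format cohort table: one (animal, level, physis side)
#' combination with its regional rates, percent growth modulation, and
#' optional morphometry.
#'
#' @param animal_id animal identifier.
#' @param tension_group `"high"` or `"low"` tether tension group.
#' @param level level code (see [level_label()]).
#' @param side `"proximal"`, `"distal"`, or `"combined"` (disk-level sum of
#'   the two physes).
#' @param rates a [regional_rates()] object.
#' @param pct_growth_modulation percent growth modulation for the row; if
#'   missing it is computed from `rates`.
#' @param thickness_um optional named vector of zone thicknesses (um) with
#'   names `hypertrophic`, `proliferative_reserve`.
#' @param ossification_pct,np_pct_epiphysis,np_pct_vertebra optional percents.
#' @param implant_failure logical flag.
#' @return one-row `data.frame` with the documented column order.
#' @export
cohort_record <- function(animal_id, tension_group, level, side, rates,
                          pct_growth_modulation = NULL, thickness_um = NULL,
                          ossification_pct = NA_real_,
                          np_pct_epiphysis = NA_real_,
                          np_pct_vertebra = NA_real_,
                          implant_failure = FALSE) {
  tension_group <- match.arg(tension_group, c("high", "low"))
  level_label(level)  # validates
  side <- match.arg(side, c("proximal", "distal", "combined"))
  stopifnot(inherits(rates, "regional_rates"))
  if (is.null(pct_growth_modulation)) {
    pct_growth_modulation <- percent_growth_modulation(rates)
  }
  if (is.finite(rates$overall) && rates$overall > 0 &&
      !is.finite(pct_growth_modulation)) {
    stop("pct_growth_modulation must be finite when the overall rate is positive",
         call. = FALSE)
  }
  th <- function(zone) {
    if (is.null(thickness_um) || is.na(thickness_um[zone])) NA_real_
    else unname(thickness_um[zone])
  }
  data.frame(
    animal_id = as.character(animal_id), tension_group = tension_group,
    level = level, side = side,
    rate_anterior_q = rates$anterior_q, rate_middle_h = rates$middle_h,
    rate_posterior_q = rates$posterior_q, rate_overall = rates$overall,
    rate_uae = if (is.null(rates$uae)) NA_real_ else rates$uae,
    pct_growth_modulation = pct_growth_modulation,
    thickness_hypertrophic_um = th("hypertrophic"),
    thickness_proliferative_reserve_um = th("proliferative_reserve"),
    ossification_pct = ossification_pct,
    np_pct_epiphysis = np_pct_epiphysis, np_pct_vertebra = np_pct_vertebra,
    implant_failure = implant_failure,
    stringsAsFactors = FALSE)
}

#' Write a cohort table to CSV
#'
#' One row per (animal, level, side); '.' decimal separator, UTF-8, header
#' row, documented column order. Duplicate keys are refused.
#'
#' @param records a `data.frame` of rows from [cohort_record()] (or any frame
#'   with the same columns).
#' @param path output CSV path.
#' @export
write_cohort_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data.frame", call. = FALSE)
  }
  missing_cols <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop(sprintf("records lack columns: %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  key <- paste(records$animal_id, records$level, records$side, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), c("animal_id", "level", "side")][1, ]
    stop(sprintf("duplicate (animal, level, side) key: (%s, %s, %s)",
                 dup$animal_id, dup$level, dup$side), call. = FALSE)
  }
  utils::write.csv(records[, COHORT_COLUMNS], path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table written by [write_cohort_table()]
#'
#' @param path CSV path.
#' @return `data.frame` in the documented column order.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop(sprintf("cohort table lacks columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$animal_id <- as.character(df$animal_id)
  df$implant_failure <- as.logical(df$implant_failure)
  df[, COHORT_COLUMNS]
}
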