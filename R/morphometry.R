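#' Zone annotation
#'
#' A drawn region of one physeal zone on the micrograph.
#'
#' @param zone `"hypertrophic"` or `"proliferative_reserve"` (the reserve and
#'   proliferative zones are drawn and analysed as one region).
#' @param polygon simple closed polygon, n x 2 px.
#' @param region_tag optional `"anterior_quarter"`, `"middle_half"`, or
#'   `"posterior_quarter"` when the zone was drawn per sagittal region.
#' @return object of class `zone_annotation`.
#' @export
zone_annotation <- function(zone = c("hypertrophic", "proliferative_reserve"),
                            polygon, region_tag = NULL) {
  zone <- match.arg(zone)
  polygon <- check_polygon(polygon, sprintf("zone polygon (%s)", zone))
  if (!is.null(region_tag)) {
    region_tag <- match.arg(region_tag, c("anterior_quarter", "middle_half",
                                          "posterior_quarter"))
  }
  structure(list(zone = zone, polygon = polygon, region_tag = region_tag),
            class = "zone_annotation")
}

#' Mean thickness of a drawn zone
#'
#' The average thickness of a drawn area is its polygon area divided by its
#' A-P footprint — the extent of the polygon projected on the frame's
#' anterior-posterior axis — i.e. the mean height of the region over its
#' footprint, converted to micrometres. This reading of "average thickness"
#' is exact for rectangles, parallelograms and any region bounded by two
#' single-valued curves over the same footprint.
#'
#' @param zone a [zone_annotation()].
#' @param frame the physis [make_frame()] frame.
#' @param cal the image [calibration()].
#' @return mean thickness in um.
#' @export
mean_thickness <- function(zone, frame, cal) {
  stopifnot(inherits(zone, "zone_annotation"), inherits(frame, "frame"),
            inherits(cal, "calibration"))
  proj <- project_into_frame(zone$polygon, frame)
  extent <- diff(range(proj[, 1]))
  if (extent < 1e-9) stop("zone polygon has zero A-P extent", call. = FALSE)
  area <- polygon_area(zone$polygon)
  (area / extent) * cal$um_per_px
}

#' Total physeal thickness
#'
#' The metric of interest is the summed hypertrophic + proliferative/reserve
#' zone thickness. Multiple polygons of one class (e.g. drawn per region) are
#' combined by area-weighted footprint: summed area over summed extent.
#'
#' @param zones list of [zone_annotation()] objects containing at least one
#'   polygon of each class.
#' @param frame,cal as in [mean_thickness()].
#' @return total thickness in um.
#' @export
total_physeal_thickness <- function(zones, frame, cal) {
  stopifnot(is.list(zones), length(zones) > 0)
  classes <- vapply(zones, function(z) z$zone, character(1))
  missing <- setdiff(c("hypertrophic", "proliferative_reserve"), classes)
  if (length(missing)) {
    stop(sprintf("missing zone class: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  per_class <- function(cls) {
    zs <- zones[classes == cls]
    area <- sum(vapply(zs, function(z) polygon_area(z$polygon), numeric(1)))
    extent <- sum(vapply(zs, function(z) {
      diff(range(project_into_frame(z$polygon, frame)[, 1]))
    }, numeric(1)))
    if (extent < 1e-9) stop("zone polygons have zero A-P extent", call. = FALSE)
    (area / extent) * cal$um_per_px
  }
  per_class("hypertrophic") + per_class("proliferative_reserve")
}

#' Percent epiphyseal ossification
#'
#' The A-P length of the ossified epiphysis divided by the total A-P length
#' of the entire epiphysis (ossified + cartilaginous), times 100.
#'
#' @param ossified [interval()] of the ossified region (must lie within
#'   `total`).
#' @param total [interval()] of the whole epiphysis.
#' @return percent in (0, 100].
#' @export
ossification_percent <- function(ossified, total) {
  stopifnot(inherits(ossified, "interval"), inherits(total, "interval"))
  if (ossified$lo < total$lo - 1e-9 || ossified$hi > total$hi + 1e-9) {
    stop("ossified interval extends beyond the total epiphysis", call. = FALSE)
  }
  100 * interval_length(ossified) / interval_length(total)
}

#' Disk-level mean epiphyseal ossification
#'
#' The disk-level value is the mean of the two epiphyses facing the disk
#' space (the proximal vertebra's distal epiphysis and the distal vertebra's
#' proximal epiphysis).
#'
#' @param proximal_pct,distal_pct the two per-epiphysis percentages.
#' @return mean percent.
#' @export
disk_ossification_percent <- function(proximal_pct, distal_pct) {
  stopifnot(is.numeric(proximal_pct), is.numeric(distal_pct))
  (proximal_pct + distal_pct) / 2
}

#' Nucleus pulposus centroid position
#'
#' The sagittal geometric centre of the nucleus pulposus (NP) — the area
#' centroid of its drawn polygon — projected onto the A-P axis and expressed
#' as a posterior-to-anterior percentage of (a) the ossified epiphysis extent
#' and (b) the whole vertebral body extent. 50 means the centre sits at the
#' interval midpoint, < 50 posterior of it, > 50 anterior. Centroids falling
#' outside an interval give values outside `[0, 100]`; they are flagged with
#' a warning, never clamped.
#'
#' @param np_polygon simple closed polygon of the NP (px).
#' @param epiphysis [interval()] of the ossified epiphysis (A-P stations, px).
#' @param vertebra [interval()] of the vertebral body (A-P stations, px).
#' @param frame the [make_frame()] frame defining the A-P axis.
#' @return list with `pct_epiphysis`, `pct_vertebra`, `centroid_station`.
#' @export
np_location_percent <- function(np_polygon, epiphysis, vertebra, frame) {
  stopifnot(inherits(epiphysis, "interval"), inherits(vertebra, "interval"),
            inherits(frame, "frame"))
  poly <- check_polygon(np_polygon, "np_polygon")
  cen <- polygon_centroid(poly)
  station <- sum((cen - frame$origin) * frame$ap_unit)
  pct <- function(iv) 100 * (station - iv$lo) / interval_length(iv)
  pe <- pct(epiphysis); pv <- pct(vertebra)
  if (pe < 0 || pe > 100 || pv < 0 || pv > 100) {
    warning("NP centroid lies outside an annotated interval (value not clamped)")
  }
  list(pct_epiphysis = pe, pct_vertebra = pv, centroid_station = station)
}

#' Endplate landmark line
#'
#' @param p1,p2 line endpoints (px), distinct.
#' @param role `"cranial"` or `"caudal"`.
#' @return object of class `endplate_line`.
#' @export
endplate_line <- function(p1, p2, role = c("cranial", "caudal")) {
  role <- match.arg(role)
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  stopifnot(length(p1) == 2, length(p2) == 2)
  if (sum((p1 - p2)^2) < 1e-18) stop("degenerate endplate line", call. = FALSE)
  structure(list(p1 = p1, p2 = p2, role = role), class = "endplate_line")
}

#' Signed sagittal Cobb angle between two endplate lines
#'
#' The magnitude is the acute angle between the two line directions (0-90
#' degrees). The sign follows the kyphotic-positive convention: positive when
#' the lines converge on the anterior side (anterior inter-line gap narrower
#' than posterior), negative when they converge posteriorly (lordotic), zero
#' for parallel lines. Convergence is assessed by comparing the inter-line
#' gap at the anterior and posterior ends of the shorter line's A-P extent,
#' which is robust for non-intersecting segments.
#'
#' @param cranial,caudal [endplate_line()] objects.
#' @param anterior_unit unit vector pointing anteriorly in image coordinates.
#' @return signed angle in degrees.
#' @export
cobb_angle <- function(cranial, caudal, anterior_unit) {
  stopifnot(inherits(cranial, "endplate_line"), inherits(caudal, "endplate_line"))
  ap <- as.numeric(anterior_unit)
  ap <- ap / sqrt(sum(ap^2))
  d1 <- cranial$p2 - cranial$p1
  d2 <- caudal$p2 - caudal$p1
  cosang <- abs(sum(d1 * d2)) / (sqrt(sum(d1^2)) * sqrt(sum(d2^2)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  if (ang < 1e-9) return(0)
  # gap between the infinite lines at the A-P ends of the shorter segment
  nrm <- c(-ap[2], ap[1])
  line_height <- function(l, t) {
    # height of line l (along nrm) at A-P station t; lines nearly parallel to
    # the normal axis have no single-valued height and cannot be compared
    s1 <- sum(l$p1 * ap); h1 <- sum(l$p1 * nrm)
    s2 <- sum(l$p2 * ap); h2 <- sum(l$p2 * nrm)
    if (abs(s2 - s1) < 1e-9) {
      stop("endplate line is perpendicular to the anterior axis", call. = FALSE)
    }
    h1 + (h2 - h1) * (t - s1) / (s2 - s1)
  }
  len <- function(l) sqrt(sum((l$p2 - l$p1)^2))
  shorter <- if (len(cranial) <= len(caudal)) cranial else caudal
  ts <- sort(c(sum(shorter$p1 * ap), sum(shorter$p2 * ap)))
  gap <- function(t) abs(line_height(cranial, t) - line_height(caudal, t))
  sign <- if (gap(ts[2]) < gap(ts[1])) 1 else -1  # ts[2] = anterior end
  sign * ang
}
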