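#' Physis-local coordinate frame
#'
#' A frame fixes the anterior-posterior (A-P) axis and the longitudinal growth
#' axis of one physis. The A-P unit vector points from the posterior chord
#' endpoint to the anterior endpoint; the growth unit vector is the A-P vector
#' rotated +90 degrees (image convention: x right, y down) times `growth_sign`,
#' so `growth_sign` selects which side of the chord growth proceeds towards.
#'
#' @param chord_start posterior chord endpoint, numeric length-2 (px). Becomes
#'   the frame origin.
#' @param chord_end anterior chord endpoint, numeric length-2 (px).
#' @param growth_sign +1 or -1: orientation of the growth axis relative to the
#'   +90-degree rotation of the A-P axis.
#' @return An object of class `frame` with fields `origin`, `ap_unit`,
#'   `growth_unit`.
#' @examples
#' make_frame(c(0, 0), c(100, 0), +1)
#' @export
make_frame <- function(chord_start, chord_end, growth_sign = 1) {
  chord_start <- as.numeric(chord_start); chord_end <- as.numeric(chord_end)
  stopifnot(length(chord_start) == 2, length(chord_end) == 2,
            growth_sign %in% c(-1, 1))
  v <- chord_end - chord_start
  len <- sqrt(sum(v^2))
  if (!is.finite(len) || len < 1e-12) {
    stop("chord endpoints are coincident; cannot orient frame", call. = FALSE)
  }
  ap <- v / len
  growth <- growth_sign * c(-ap[2], ap[1])  # +90 deg rotation of ap
  structure(list(origin = chord_start, ap_unit = ap, growth_unit = growth),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("<frame> origin (%.2f, %.2f)  ap (%.4f, %.4f)  growth (%.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$ap_unit[1], x$ap_unit[2],
              x$growth_unit[1], x$growth_unit[2]))
  invisible(x)
}

#' Project image points into a frame's (station, height) coordinates
#'
#' @param points n x 2 matrix of pixel coordinates.
#' @param frame a [make_frame()] frame.
#' @return n x 2 matrix: column 1 = station along `ap_unit`, column 2 = height
#'   along `growth_unit`, both relative to `origin`.
#' @keywords internal
project_into_frame <- function(points, frame) {
  m <- if (is.matrix(points)) points else do.call(rbind, lapply(points, as.numeric))
  stopifnot(is.numeric(m), ncol(m) == 2)
  rel <- sweep(m, 2, frame$origin)
  cbind(station = rel %*% frame$ap_unit, height = rel %*% frame$growth_unit)
}

#' Build a traced label front from operator points
#'
#' Points clicked along one fluorochrome front are projected into the physis
#' frame, sorted by ascending A-P station, and connected piecewise-linearly.
#' No smoothing is applied: the connected polyline is the front. A front must
#' be single-valued in the station coordinate.
#'
#' @param points list or n x 2 matrix of pixel coordinates (>= 2 points).
#' @param frame the physis [make_frame()] frame.
#' @param label which fluorochrome the front belongs to: `"alizarin"` (older,
#'   administered 12-14 days pre-harvest) or `"oxytetracycline"` (at harvest).
#' @return An object of class `front` with fields `stations` (strictly
#'   increasing), `heights`, `label`.
#' @examples
#' fr <- make_frame(c(0, 0), c(100, 0), +1)
#' build_front(rbind(c(80, 10), c(0, 5), c(40, 8)), fr, "alizarin")
#' @export
build_front <- function(points, frame, label = c("alizarin", "oxytetracycline")) {
  label <- match.arg(label)
  stopifnot(inherits(frame, "frame"))
  pf <- project_into_frame(points, frame)
  if (nrow(pf) < 2) stop("a front needs at least 2 points", call. = FALSE)
  if (!all(is.finite(pf))) stop("front points contain non-finite values", call. = FALSE)
  ord <- order(pf[, 1])
  st <- pf[ord, 1]; ht <- pf[ord, 2]
  if (any(diff(st) < 1e-9)) {
    stop("front not single-valued: two points share an A-P station", call. = FALSE)
  }
  structure(list(stations = as.numeric(st), heights = as.numeric(ht),
                 label = label), class = "front")
}

#' @export
print.front <- function(x, ...) {
  cat(sprintf("<front> %s, %d points, stations [%.1f, %.1f] px\n",
              x$label, length(x$stations), min(x$stations), max(x$stations)))
  invisible(x)
}

#' Interpolated front height at an A-P station
#'
#' Piecewise-linear interpolation of the connected front. Extrapolation
#' outside the traced extent is refused: the front is only defined where the
#' operator traced it.
#'
#' @param front a [build_front()] front.
#' @param station A-P station(s), px, within the front's extent.
#' @return height(s) along the growth axis, px.
#' @export
height_at <- function(front, station) {
  stopifnot(inherits(front, "front"), is.numeric(station))
  rng <- range(front$stations)
  if (any(station < rng[1] - 1e-9 | station > rng[2] + 1e-9)) {
    stop(sprintf("station outside front extent [%.6g, %.6g]", rng[1], rng[2]),
         call. = FALSE)
  }
  station <- pmin(pmax(station, rng[1]), rng[2])
  stats::approx(front$stations, front$heights, xout = station,
                method = "linear", ties = "ordered")$y
}

#' Automatic frame from the alizarin front's extremes
#'
#' When an annotation declares `frame_spec: "auto"`, the A-P chord is the
#' segment joining the alizarin front's two extreme traced points, and the
#' growth direction is the sign that places the mean oxytetracycline height
#' above the mean alizarin height (mineralisation proceeds from the older to
#' the newer label).
#'
#' @param alizarin_points,oxytet_points point sets (px) for the two fronts.
#' @return a [make_frame()] frame.
#' @export
auto_frame <- function(alizarin_points, oxytet_points) {
  am <- if (is.matrix(alizarin_points)) alizarin_points else
    do.call(rbind, lapply(alizarin_points, as.numeric))
  om <- if (is.matrix(oxytet_points)) oxytet_points else
    do.call(rbind, lapply(oxytet_points, as.numeric))
  # extreme pair = the two points realising the polyline's diameter endpoints:
  # take the pair at maximal euclidean separation
  d <- as.matrix(stats::dist(am))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  fr <- make_frame(am[ij[1], ], am[ij[2], ], +1)
  mean_h <- function(pts) mean(project_into_frame(pts, fr)[, 2])
  if (mean_h(om) < mean_h(am)) {
    fr <- make_frame(am[ij[1], ], am[ij[2], ], -1)
  }
  fr
}
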