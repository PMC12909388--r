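# Small planar-geometry helpers shared by the annotation and morphometry code.
# Polygons are n x 2 matrices of pixel coordinates; closure is implicit (the
# last vertex connects back to the first).

as_poly_matrix <- function(polygon) {
  m <- if (is.data.frame(polygon)) as.matrix(polygon) else polygon
  if (is.list(m) && !is.matrix(m)) m <- do.call(rbind, lapply(m, as.numeric))
  if (!is.matrix(m) || ncol(m) != 2 || !is.numeric(m)) {
    stop("polygon must be an n x 2 numeric matrix of vertices", call. = FALSE)
  }
  if (!all(is.finite(m))) stop("polygon contains non-finite vertices", call. = FALSE)
  # drop an explicitly repeated closing vertex
  n <- nrow(m)
  if (n >= 2 && all(abs(m[n, ] - m[1, ]) < 1e-12)) m <- m[-n, , drop = FALSE]
  if (nrow(m) < 3) stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  m
}

polygon_area <- function(polygon) {
  m <- as_poly_matrix(polygon)
  abs(pracma::polyarea(m[, 1], m[, 2]))
}

polygon_centroid <- function(polygon) {
  m <- as_poly_matrix(polygon)
  m <- rbind(m, m[1, ])  # poly_center expects the closing vertex repeated
  pracma::poly_center(m[, 1], m[, 2])
}

# Proper-crossing test for two closed segments, excluding shared endpoints of
# adjacent polygon edges (handled by the caller).
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  (abs(d1) < 1e-12 && on_seg(p3, p4, p1)) ||
    (abs(d2) < 1e-12 && on_seg(p3, p4, p2)) ||
    (abs(d3) < 1e-12 && on_seg(p1, p2, p3)) ||
    (abs(d4) < 1e-12 && on_seg(p1, p2, p4))
}

# O(n^2) simplicity check: no two non-adjacent edges intersect.
is_simple_polygon <- function(polygon) {
  m <- as_poly_matrix(polygon)
  n <- nrow(m)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # adjacent edges share a vertex; skip them (and the wrap-around pair)
      shares <- length(intersect(edges[i, ], edges[j, ])) > 0
      if (shares) next
      if (segments_cross(m[edges[i, 1], ], m[edges[i, 2], ],
                         m[edges[j, 1], ], m[edges[j, 2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

check_polygon <- function(polygon, what = "polygon") {
  m <- as_poly_matrix(polygon)
  if (!is_simple_polygon(m)) {
    stop(sprintf("%s is self-intersecting", what), call. = FALSE)
  }
  if (polygon_area(m) <= 0) {
    stop(sprintf("%s has zero area", what), call. = FALSE)
  }
  invisible(m)
}
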