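# Planar geometry primitives used throughout the package.
# All coordinates are planar kilometres; polygons are matrices with columns
# (x, y), vertices in order, closing edge implicit (last -> first).

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorised ray-casting containment test for a set of points against one
#' simple closed polygon. Points exactly on an edge may fall on either side;
#' callers that care use a tolerance.
#'
#' @param px,py numeric vectors of point coordinates (km).
#' @param poly two-column matrix of polygon vertices (closing edge implicit).
#' @return logical vector, `TRUE` where the point is inside.
#' @export
point_in_polygon <- function(px, py, poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2L, nrow(poly) >= 3L)
  n <- nrow(poly)
  xi <- poly[, 1L]; yi <- poly[, 2L]
  xj <- xi[c(n, seq_len(n - 1L))]  # previous vertex
  yj <- yi[c(n, seq_len(n - 1L))]
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    crosses <- ((yi[k] > py) != (yj[k] > py))
    if (any(crosses)) {
      xint <- (xj[k] - xi[k]) * (py[crosses] - yi[k]) / (yj[k] - yi[k]) + xi[k]
      hit <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], hit)
    }
  }
  inside
}

#' Polygon area by the shoelace formula
#'
#' @param poly two-column vertex matrix.
#' @return absolute enclosed area (km^2).
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Clip a polygon to an axis-aligned rectangle
#'
#' Sutherland-Hodgman clipping of an arbitrary simple polygon against a
#' convex rectangular window. Used for exact area-of-intersection with
#' rectangular subdivisions and grid cells.
#'
#' @param poly two-column vertex matrix (subject polygon).
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @return two-column vertex matrix of the clipped polygon (0 rows if empty).
#' @export
clip_polygon_rect <- function(poly, xmin, xmax, ymin, ymax) {
  clip_edge <- function(pts, keep, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- matrix(numeric(0), ncol = 2L)
    prev <- pts[n, ]
    prev_in <- keep(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; cur_in <- keep(cur)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect(prev, cur))
      }
      prev <- cur; prev_in <- cur_in
    }
    out
  }
  ix <- function(p, q, val, coord) {
    t <- (val - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  pts <- poly
  pts <- clip_edge(pts, function(p) p[1L] >= xmin, function(p, q) ix(p, q, xmin, 1L))
  pts <- clip_edge(pts, function(p) p[1L] <= xmax, function(p, q) ix(p, q, xmax, 1L))
  pts <- clip_edge(pts, function(p) p[2L] >= ymin, function(p, q) ix(p, q, ymin, 2L))
  pts <- clip_edge(pts, function(p) p[2L] <= ymax, function(p, q) ix(p, q, ymax, 2L))
  pts
}

# Do two simple polygons intersect (share interior or boundary)?
# Vertex containment either way, or any pair of edges crossing.
polygons_intersect <- function(a, b) {
  if (any(point_in_polygon(a[, 1L], a[, 2L], b))) return(TRUE)
  if (any(point_in_polygon(b[, 1L], b[, 2L], a))) return(TRUE)
  segments_cross_any(a, b)
}

# Any proper crossing between edges of polygons a and b (O(n*m)).
segments_cross_any <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  a2 <- a[c(2:na, 1L), , drop = FALSE]
  b2 <- b[c(2:nb, 1L), , drop = FALSE]
  orient <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(na)) {
    d1 <- orient(a[i, 1L], a[i, 2L], a2[i, 1L], a2[i, 2L], b[, 1L], b[, 2L])
    d2 <- orient(a[i, 1L], a[i, 2L], a2[i, 1L], a2[i, 2L], b2[, 1L], b2[, 2L])
    d3 <- orient(b[, 1L], b[, 2L], b2[, 1L], b2[, 2L], a[i, 1L], a[i, 2L])
    d4 <- orient(b[, 1L], b[, 2L], b2[, 1L], b2[, 2L], a2[i, 1L], a2[i, 2L])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

# Uniform points inside a polygon by bounding-box rejection sampling.
# Exact for any simple polygon; efficiency is area(poly)/area(bbox).
sample_in_polygon <- function(n, poly) {
  if (n <= 0L) return(matrix(numeric(0), ncol = 2L))
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  out <- matrix(NA_real_, nrow = n, ncol = 2L)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    px <- stats::runif(m, xr[1L], xr[2L])
    py <- stats::runif(m, yr[1L], yr[2L])
    ok <- point_in_polygon(px, py, poly)
    take <- min(sum(ok), n - got)
    if (take > 0L) {
      idx <- which(ok)[seq_len(take)]
      out[got + seq_len(take), ] <- cbind(px[idx], py[idx])
      got <- got + take
    }
  }
  out
}

# Round half away from zero (quota rounding; base round() is banker's).
round_half_up <- function(x) floor(x + 0.5)

# Is a polygon an axis-aligned rectangle?
is_axis_rect <- function(poly, tol = 1e-9) {
  nrow(poly) == 4L &&
    length(unique(round(poly[, 1L] / tol))) == 2L &&
    length(unique(round(poly[, 2L] / tol))) == 2L
}

# Deterministic substream seeds: one shared base seed per replicate, split
# into named substreams so perturbation runs stay seed-comparable.
substream_seed <- function(seed, stream, iteration = 0L) {
  offsets <- c(sampling = 1, error = 2, ebk = 3, densify = 4,
               scenario = 5, truth = 6, plume = 7, population = 8)
  stopifnot(stream %in% names(offsets))
  base <- (as.numeric(seed) * 48271 + offsets[[stream]] * 104729 +
             as.numeric(iteration) * 7919) %% 2147483629
  as.integer(base + 1)
}
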