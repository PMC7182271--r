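# Census-like population subdivision maps.
#
# Subdivisions are a jittered rectangular tessellation of the region with
# uniform within-subdivision population density, standing in for census
# county subdivisions. The urban/rural density regimes straddle the
# 10,000 persons per square mile boundary used to classify scenario density
# (10,000 / 2.589988 km^2/mi^2 = 3861.0 persons per km^2).

URBAN_RURAL_DENSITY_KM2 <- 10000 / 2.589988  # persons per km^2

#' Generate a synthetic population subdivision map
#'
#' Tiles a rectangular region into `n` simple polygons (a seeded, jittered
#' rectangular tessellation) and allocates population with uniform density
#' within each subdivision. Densities are drawn per subdivision from the
#' regime's range: urban 4000-9000 persons/km^2 (all above the
#' 10,000/mi^2 = 3861/km^2 urban boundary), rural 20-1500 persons/km^2
#' (all below it). If `total_population` is given, per-subdivision
#' populations are rescaled to sum to it exactly (largest-remainder
#' rounding); otherwise the regime densities determine the total.
#'
#' @param n number of subdivisions (>= 1).
#' @param bbox region box `c(xmin, xmax, ymin, ymax)` in km.
#' @param regime `"urban"` or `"rural"` density regime.
#' @param total_population optional exact total to allocate.
#' @param jitter relative jitter of internal tessellation lines (0-0.45).
#' @param seed integer seed; deterministic given seed.
#' @return object of class `subdivision_map`: a list with `polygons` (list of
#'   vertex matrices), `table` (data.frame of id, population, area_km2,
#'   density_km2), and `bbox`.
#' @export
generate_population_map <- function(n = 36, bbox = c(0, 30, 0, 30),
                                    regime = c("urban", "rural"),
                                    total_population = NULL,
                                    jitter = 0.25, seed = 1) {
  regime <- match.arg(regime)
  if (n < 1L) stop("need at least one subdivision", call. = FALSE)
  if (!is.null(total_population) && total_population < 0)
    stop("total_population must be non-negative", call. = FALSE)
  w <- bbox[2L] - bbox[1L]; h <- bbox[4L] - bbox[3L]
  if (w <= 0 || h <= 0) stop("degenerate region box", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # Rows of jittered height; row i split into c_i jittered columns with
  # sum(c_i) = n, so the rectangles tile the box exactly.
  nr <- max(1L, floor(sqrt(n)))
  ncols <- rep(n %/% nr, nr)
  extra <- n - sum(ncols)
  if (extra > 0L) ncols[seq_len(extra)] <- ncols[seq_len(extra)] + 1L
  if (min(w, h) / max(ncols) < 1e-6)
    stop("region too small to tile into ", n, " subdivisions", call. = FALSE)

  jbreaks <- function(k, lo, hi, jit) {
    if (k == 1L) return(c(lo, hi))
    u <- seq(lo, hi, length.out = k + 1L)
    stepw <- (hi - lo) / k
    mid <- u[2:k] + stats::runif(k - 1L, -jit, jit) * stepw
    c(lo, sort(mid), hi)
  }

  ys <- jbreaks(nr, bbox[3L], bbox[4L], jitter)
  polys <- list(); ids <- character(0)
  for (i in seq_len(nr)) {
    xs <- jbreaks(ncols[i], bbox[1L], bbox[2L], jitter)
    for (j in seq_len(ncols[i])) {
      poly <- cbind(c(xs[j], xs[j + 1L], xs[j + 1L], xs[j]),
                    c(ys[i], ys[i], ys[i + 1L], ys[i + 1L]))
      polys[[length(polys) + 1L]] <- poly
      ids <- c(ids, sprintf("S%02d%02d", i, j))
    }
  }

  areas <- vapply(polys, polygon_area, numeric(1))
  dens_range <- if (regime == "urban") c(4000, 9000) else c(20, 1500)
  dens <- stats::runif(n, dens_range[1L], dens_range[2L])
  raw <- dens * areas
  pops <- if (is.null(total_population)) {
    round_half_up(raw)
  } else {
    allocate_conserving(raw, total_population)
  }

  structure(list(
    polygons = polys,
    table = data.frame(id = ids, population = pops, area_km2 = areas,
                       density_km2 = pops / areas,
                       stringsAsFactors = FALSE),
    bbox = bbox, regime = regime, seed = seed
  ), class = "subdivision_map")
}

# Integer allocation proportional to weights, conserving the total exactly
# (largest-remainder method).
allocate_conserving <- function(weights, total) {
  if (total == 0) return(rep(0L, length(weights)))
  if (sum(weights) <= 0) weights <- rep(1, length(weights))
  exact <- weights / sum(weights) * total
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' @export
print.subdivision_map <- function(x, ...) {
  cat("Subdivision map:", nrow(x$table), "subdivisions,",
      format(sum(x$table$population), big.mark = ","), "persons\n")
  cat(sprintf("  region: [%.1f, %.1f] x [%.1f, %.1f] km; regime: %s\n",
              x$bbox[1L], x$bbox[2L], x$bbox[3L], x$bbox[4L], x$regime))
  cat(sprintf("  density: %.0f-%.0f persons/km^2 (urban boundary %.0f)\n",
              min(x$table$density_km2), max(x$table$density_km2),
              URBAN_RURAL_DENSITY_KM2))
  invisible(x)
}

#' @export
plot.subdivision_map <- function(x, plume = NULL, ...) {
  plot(NA, xlim = x$bbox[1:2], ylim = x$bbox[3:4], asp = 1,
       xlab = "x (km)", ylab = "y (km)", main = "Population subdivisions", ...)
  d <- x$table$density_km2
  cols <- grDevices::gray(1 - 0.8 * (d - min(d)) / max(1e-9, diff(range(d))))
  for (k in seq_along(x$polygons))
    graphics::polygon(x$polygons[[k]], col = cols[k], border = "grey40")
  if (!is.null(plume))
    for (r in plume$rings) graphics::polygon(r, border = "red")
  invisible(x)
}

# Adjacency: two subdivisions are adjacent iff they share a boundary segment
# of positive length (corner contact does not count). Detected as collinear
# overlapping edge pairs, which covers tessellations exactly.
subdivision_adjacency <- function(map, tol = 1e-7) {
  n <- length(map$polygons)
  adj <- matrix(FALSE, n, n)
  edges <- lapply(map$polygons, function(p) {
    m <- nrow(p)
    cbind(p, p[c(2:m, 1L), , drop = FALSE])
  })
  seg_overlap <- function(e1, e2) {
    # both edges as (x1,y1,x2,y2); collinear + positive-length 1-D overlap
    d1 <- c(e1[3L] - e1[1L], e1[4L] - e1[2L])
    d2 <- c(e2[3L] - e2[1L], e2[4L] - e2[2L])
    cr <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
    if (abs(cr) > tol) return(FALSE)
    off <- c(e2[1L] - e1[1L], e2[2L] - e1[2L])
    if (abs(d1[1L] * off[2L] - d1[2L] * off[1L]) > tol) return(FALSE)
    len2 <- sum(d1^2)
    t1 <- sum((c(e2[1L], e2[2L]) - c(e1[1L], e1[2L])) * d1) / len2
    t2 <- sum((c(e2[3L], e2[4L]) - c(e1[1L], e1[2L])) * d1) / len2
    lo <- max(0, min(t1, t2)); hi <- min(1, max(t1, t2))
    (hi - lo) * sqrt(len2) > tol
  }
  for (i in seq_len(n - 1L)) {
    bi <- bbox_of(map$polygons[[i]])
    for (j in (i + 1L):n) {
      bj <- bbox_of(map$polygons[[j]])
      if (bi[1L] > bj[2L] + tol || bj[1L] > bi[2L] + tol ||
          bi[3L] > bj[4L] + tol || bj[3L] > bi[4L] + tol) next
      found <- FALSE
      for (a in seq_len(nrow(edges[[i]]))) {
        for (b in seq_len(nrow(edges[[j]]))) {
          if (seg_overlap(edges[[i]][a, ], edges[[j]][b, ])) { found <- TRUE; break }
        }
        if (found) break
      }
      adj[i, j] <- adj[j, i] <- found
    }
  }
  adj
}

bbox_of <- function(poly) c(range(poly[, 1L]), range(poly[, 2L]))
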