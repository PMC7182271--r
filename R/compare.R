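# Dose-band extraction, overlap heat matrices, BCD/RMSD convergence
# statistics, and population-weighted accuracy scoring.
#
# Plumes are compared over 8 dose bands: <1, 1-2, 2-3, 3-4, 4-5, 5-6, 6-7
# and >7 Gy (half-open [k, k+1), last unbounded; the first band covers
# strictly positive predictions below 1 Gy). Bands are represented as cell
# masks on the shared analysis grid; band boundaries are the 1..7 Gy level
# sets of the gridded surface.

BAND_LABELS <- c("<1", "1-2", "2-3", "3-4", "4-5", "5-6", "6-7", ">7")

#' Extract the 8 dose bands of a surface
#'
#' Bands are set differences of successive super-level regions of the
#' prediction: band k is the region with `k-1 <= dose < k` Gy (band 1:
#' `0 < dose < 1`; band 8: `dose >= 7`). Bands are pairwise disjoint and
#' their union is exactly the region with positive predicted dose. An
#' all-zero surface yields an empty (but valid) plume.
#'
#' @param surface a `kriged_surface`, or a list with `prediction` matrix
#'   and `grid`.
#' @param iteration iteration stamp carried on the result.
#' @return object of class `derived_plume`: `masks` (list of 8 logical
#'   matrices), `areas_km2`, `grid`, `band_labels`, `iteration`.
#' @export
extract_bands <- function(surface, iteration = NA_integer_) {
  pred <- surface$prediction
  grid <- surface$grid
  masks <- vector("list", 8L)
  masks[[1L]] <- pred > 0 & pred < 1
  for (k in 2:7) masks[[k]] <- pred >= (k - 1) & pred < k
  masks[[8L]] <- pred >= 7
  cell_area <- grid$cellsize^2
  structure(list(masks = masks,
                 areas_km2 = vapply(masks, sum, numeric(1)) * cell_area,
                 grid = grid, band_labels = BAND_LABELS,
                 iteration = iteration),
            class = "derived_plume")
}

# Cells at or above an integer Gy threshold t (union of bands >= t).
band_mask_at_least <- function(bands, threshold) {
  stopifnot(threshold %in% 1:7)
  Reduce(`|`, bands$masks[(threshold + 1L):8L])
}

#' Band-overlap heat matrix between two plumes
#'
#' Cell (i, j) is the average overlap percentage between band i of the
#' current plume and band j of the previous plume, as the symmetric mean of
#' the two area ratios:
#' `0.5 * (area(C_i & P_j) / area(C_i) + area(C_i & P_j) / area(P_j))`.
#' Identical plumes give the identity matrix. A diagonal cell whose band is
#' empty in both plumes counts as full overlap (1, no disagreement); a band
#' empty on one side only counts as 0.
#'
#' @param current,previous `derived_plume` objects on the same grid.
#' @return object of class `overlap_matrix`: 8 x 8 numeric matrix in
#'   `[0, 1]` with band labels, diagonal accessible via `diag()`.
#' @export
overlap_matrix <- function(current, previous) {
  stopifnot(inherits(current, "derived_plume"),
            inherits(previous, "derived_plume"))
  if (!identical(unclass(current$grid), unclass(previous$grid)))
    stop("plumes must share the same grid", call. = FALSE)
  M <- matrix(0, 8L, 8L, dimnames = list(current = BAND_LABELS,
                                         previous = BAND_LABELS))
  nc <- vapply(current$masks, sum, numeric(1))
  np <- vapply(previous$masks, sum, numeric(1))
  for (i in 1:8) {
    for (j in 1:8) {
      if (nc[i] == 0 && np[j] == 0) {
        M[i, j] <- if (i == j) 1 else 0
      } else if (nc[i] == 0 || np[j] == 0) {
        M[i, j] <- 0
      } else {
        ov <- sum(current$masks[[i]] & previous$masks[[j]])
        M[i, j] <- 0.5 * (ov / nc[i] + ov / np[j])
      }
    }
  }
  structure(M, class = c("overlap_matrix", "matrix"))
}

#' Diagonal Bray-Curtis dissimilarity of an overlap matrix
#'
#' `BCD = sum(|1 - A_i|) / sum(1 + A_i)` over the 8 diagonal overlap
#' fractions A_i (ideal overlap is 1). 0 means identical plumes; a uniform
#' diagonal `a` gives `(1 - a) / (1 + a)`, so the 90%-overlap stopping
#' threshold is 1/19.
#'
#' @param matrix an `overlap_matrix` (or any 8 x 8 matrix).
#' @return dissimilarity in `[0, 1]`.
#' @export
bcd <- function(matrix) {
  a <- diag(matrix)
  sum(abs(1 - a)) / sum(1 + a)
}

#' Root-mean-square deviation of an overlap matrix diagonal
#'
#' `RMSD = sqrt(mean((1 - A_i)^2))` over the 8 diagonal overlap fractions.
#' A uniform diagonal `a` gives `1 - a`, so the 90%-overlap stopping
#' threshold is 0.1.
#'
#' @param matrix an `overlap_matrix` (or any 8 x 8 matrix).
#' @return deviation in `[0, 1]`.
#' @export
rmsd <- function(matrix) {
  a <- diag(matrix)
  sqrt(mean((1 - a)^2))
}

#' Convergence thresholds for a given overlap stringency
#'
#' A stringency of `s` (fractional overlap between consecutive plumes)
#' corresponds to `BCD < (1 - s) / (1 + s)` and `RMSD < 1 - s`: 90% gives
#' 1/19 and 0.1; 99% gives 1/199 and 0.01.
#'
#' @param stringency fractional overlap in (0, 1).
#' @return named vector `c(bcd = ..., rmsd = ...)`.
#' @export
stringency_thresholds <- function(stringency = 0.90) {
  stopifnot(stringency > 0, stringency < 1)
  c(bcd = (1 - stringency) / (1 + stringency), rmsd = 1 - stringency)
}

#' Test the stopping rule
#'
#' The iterative workflow stops when either metric drops strictly below its
#' threshold (BCD < 1/19 OR RMSD < 0.1 at the default 90% stringency), or
#' for a non-metric reason (no new candidates, max iterations).
#'
#' @param bcd_value,rmsd_value the metrics for the current comparison.
#' @param iteration current iteration (kriging-pass count).
#' @param thresholds named vector from [stringency_thresholds()].
#' @return object of class `convergence_record`: list with `iteration`,
#'   `bcd`, `rmsd`, `thresholds`, `converged`, `stop_reason` (`"bcd"`,
#'   `"rmsd"` or `NA`).
#' @export
check_convergence <- function(bcd_value, rmsd_value, iteration = NA_integer_,
                              thresholds = stringency_thresholds(0.90)) {
  reason <- if (bcd_value < thresholds[["bcd"]]) "bcd"
            else if (rmsd_value < thresholds[["rmsd"]]) "rmsd"
            else NA_character_
  structure(list(iteration = iteration, bcd = bcd_value, rmsd = rmsd_value,
                 thresholds = thresholds, converged = !is.na(reason),
                 stop_reason = reason),
            class = "convergence_record")
}

#' Kriged comparison surface for a ground-truth plume
#'
#' The contour representation of the ground truth and the gridded derived
#' plumes are not directly comparable, so the truth is re-expressed in the
#' same form: every contour vertex, valued at its contour level, is kriged
#' (ordinary kriging, zero nugget, so the surface interpolates the vertices
#' exactly) onto the shared grid. Because the contour set spans the full
#' dose range down to 0 Gy, a 0 Gy envelope ring — the outermost ring
#' extrapolated outward by the spacing of the two lowest contours — is
#' included so the surface decays to background outside the plume instead
#' of extrapolating the positive contour values. The semivariogram is
#' fitted by weighted least squares on a seeded subsample of vertices.
#'
#' @param plume a `ground_truth_plume`.
#' @param grid a `dose_grid`.
#' @param seed seed for the vertex subsample used in semivariogram fitting.
#' @param k_neighbors moving-neighborhood size (vertex sets are large).
#' @return a `kriged_surface`.
#' @export
truth_surface <- function(plume, grid, seed = 1, k_neighbors = 64) {
  verts <- do.call(rbind, plume$rings)
  vals <- rep(plume$levels, vapply(plume$rings, nrow, integer(1)))
  # 0 Gy envelope: extrapolate the outermost ring radially outward by the
  # mean radius ratio of the two lowest contours (modest fixed offset when
  # only one ring exists).
  outer <- plume$rings[[1L]]
  rel <- sweep(outer, 2L, plume$epicenter)
  factor <- if (length(plume$rings) >= 2L) {
    r1 <- sqrt(rowSums(sweep(plume$rings[[1L]], 2L, plume$epicenter)^2))
    r2 <- sqrt(rowSums(sweep(plume$rings[[2L]], 2L, plume$epicenter)^2))
    max(mean(r1) / mean(r2), 1.05)
  } else 1.2
  zero_ring <- sweep(rel * factor, 2L, plume$epicenter, `+`)
  verts <- rbind(verts, zero_ring)
  vals <- c(vals, rep(0, nrow(zero_ring)))
  df <- new_sample_set(data.frame(
    x_km = verts[, 1L], y_km = verts[, 2L],
    true_dose_gy = vals, measured_dose_gy = vals,
    iteration = 0L, source = "manual", subdivision_id = NA_character_,
    stringsAsFactors = FALSE))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sub <- df[sample.int(nrow(df), min(nrow(df), 800L)), , drop = FALSE]
  emp <- empirical_semivariogram(sub)
  mdl <- suppressWarnings(fit_semivariogram(emp))
  mdl$nugget <- 0  # exact interpolation of contour vertices
  krige(df, model = mdl, grid = grid, method = "ordinary",
        k_neighbors = k_neighbors)
}

#' Population-weighted accuracy of a derived plume
#'
#' Converts area overlap into affected population using uniform density
#' within each subdivision: the population of any region is the sum over
#' subdivisions of `area(region & subdivision) * population / area`.
#' Recall is the percentage of the true at-or-above-threshold population
#' whose territory the derived plume captures; the false-positive fraction
#' is the percentage of the derived at-or-above-threshold population that
#' is truly below threshold.
#'
#' @param derived,truth `derived_plume` objects on the same grid.
#' @param map a `subdivision_map`.
#' @param threshold integer dose threshold in Gy (default 2; 3 for the
#'   compact high-dose contour).
#' @return list with `recall_pct`, `false_positive_pct`,
#'   `population_truth`, `population_derived`, `threshold`.
#' @export
accuracy <- function(derived, truth, map, threshold = 2) {
  stopifnot(inherits(derived, "derived_plume"), inherits(truth, "derived_plume"))
  if (!identical(unclass(derived$grid), unclass(truth$grid)))
    stop("plumes must share the same grid", call. = FALSE)
  w <- cell_population_weights(derived$grid, map)
  dmask <- as.vector(band_mask_at_least(derived, threshold))
  tmask <- as.vector(band_mask_at_least(truth, threshold))
  pop_truth <- sum(w[tmask])
  pop_derived <- sum(w[dmask])
  if (pop_truth <= 0)
    stop("ground-truth region at or above ", threshold,
         " Gy holds no population; recall undefined", call. = FALSE)
  recall <- 100 * sum(w[dmask & tmask]) / pop_truth
  fp <- if (pop_derived > 0) 100 * sum(w[dmask & !tmask]) / pop_derived else 0
  list(recall_pct = recall, false_positive_pct = fp,
       population_truth = pop_truth, population_derived = pop_derived,
       threshold = threshold)
}

#' Per-cell population weights of a grid over a subdivision map
#'
#' The population mass each grid cell carries: for rectangular
#' subdivisions the cell-subdivision intersection area is computed exactly
#' (rectangle overlap); general polygons are clipped to the cell rectangle.
#' Summing the weights over all cells of a grid that tiles the map
#' reproduces the total population exactly.
#'
#' @param grid a `dose_grid`.
#' @param map a `subdivision_map`.
#' @return numeric vector of length `nx * ny` (column-major, x fastest).
#' @export
cell_population_weights <- function(grid, map) {
  gc <- grid_centers(grid)
  cs <- grid$cellsize
  x0 <- gc$centers[, 1L] - cs / 2; x1 <- gc$centers[, 1L] + cs / 2
  y0 <- gc$centers[, 2L] - cs / 2; y1 <- gc$centers[, 2L] + cs / 2
  w <- numeric(nrow(gc$centers))
  for (k in seq_along(map$polygons)) {
    poly <- map$polygons[[k]]
    dens <- map$table$population[k] / map$table$area_km2[k]
    bb <- bbox_of(poly)
    if (is_axis_rect(poly)) {
      ox <- pmax(0, pmin(x1, bb[2L]) - pmax(x0, bb[1L]))
      oy <- pmax(0, pmin(y1, bb[4L]) - pmax(y0, bb[3L]))
      w <- w + dens * ox * oy
    } else {
      near <- which(x1 > bb[1L] & x0 < bb[2L] & y1 > bb[3L] & y0 < bb[4L])
      for (q in near) {
        clp <- clip_polygon_rect(poly, x0[q], x1[q], y0[q], y1[q])
        if (nrow(clp) >= 3L) w[q] <- w[q] + dens * polygon_area(clp)
      }
    }
  }
  w
}

#' @export
print.derived_plume <- function(x, ...) {
  cat("Derived plume (8 dose bands), iteration", x$iteration, "\n")
  print(stats::setNames(round(x$areas_km2, 2), x$band_labels))
  invisible(x)
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("Band-overlap heat matrix (current vs previous):\n")
  print(round(unclass(x), 3))
  cat(sprintf("diagonal BCD = %.4f, RMSD = %.4f\n", bcd(x), rmsd(x)))
  invisible(x)
}

#' @export
print.convergence_record <- function(x, ...) {
  cat(sprintf("Iteration %s: BCD %.4f (< %.4f?), RMSD %.4f (< %.4f?) -> %s\n",
              x$iteration, x$bcd, x$thresholds[["bcd"]],
              x$rmsd, x$thresholds[["rmsd"]],
              if (x$converged) paste0("converged (", x$stop_reason, ")")
              else "continue"))
  invisible(x)
}

#' Heat-map display of an overlap matrix
#'
#' @param x an `overlap_matrix`.
#' @param ... passed to [graphics::image()].
#' @export
plot.overlap_matrix <- function(x, ...) {
  m <- unclass(x)[, 8:1]
  graphics::image(1:8, 1:8, m, col = grDevices::gray(seq(1, 0.2, length.out = 32)),
                  axes = FALSE, xlab = "current plume band",
                  ylab = "previous plume band", zlim = c(0, 1), ...)
  graphics::axis(1, at = 1:8, labels = BAND_LABELS, las = 2)
  graphics::axis(2, at = 1:8, labels = rev(BAND_LABELS), las = 2)
  for (i in 1:8) for (j in 1:8)
    graphics::text(i, j, sprintf("%.2f", m[i, j]), cex = 0.6,
                   col = if (m[i, j] > 0.5) "white" else "black")
  invisible(x)
}

#' Write an overlap matrix as labelled CSV
#'
#' @param matrix an `overlap_matrix`.
#' @param path CSV output path.
#' @return the path, invisibly.
#' @export
write_overlap_matrix <- function(matrix, path) {
  utils::write.csv(as.data.frame(unclass(matrix)), path, row.names = TRUE)
  invisible(path)
}
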