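# Shared fixtures and independent oracles, built in code at test time.

# Small reference plume / map used across files (cheap to build).
tiny_plume <- function(seed = 7, ...) {
  generate_plume(epicenter = c(9, 15), bearing = 90, length_km = 8,
                 width_km = 2, vertex_density = 120, seed = seed, ...)
}

tiny_map <- function(seed = 3, n = 36) {
  generate_population_map(n = n, bbox = c(0, 30, 0, 30), regime = "urban",
                          seed = seed)
}

# A 3x3 regular unit tessellation with fixed populations, for adjacency and
# quota arithmetic.
grid3x3_map <- function(pops = rep(1000L, 9L), side = 10) {
  polys <- list(); ids <- character(0)
  for (i in 1:3) for (j in 1:3) {
    x0 <- (j - 1) * side; y0 <- (i - 1) * side
    polys[[length(polys) + 1L]] <-
      cbind(c(x0, x0 + side, x0 + side, x0), c(y0, y0, y0 + side, y0 + side))
    ids <- c(ids, sprintf("R%dC%d", i, j))
  }
  areas <- vapply(polys, radkrige::polygon_area, numeric(1))
  structure(list(polygons = polys,
                 table = data.frame(id = ids, population = pops,
                                    area_km2 = areas,
                                    density_km2 = pops / areas,
                                    stringsAsFactors = FALSE),
                 bbox = c(0, 3 * side, 0, 3 * side),
                 regime = "urban", seed = NA_integer_),
            class = "subdivision_map")
}

# Independent point-in-polygon oracle: pracma's implementation (distinct
# code path from the package's ray caster).
oracle_in_polygon <- function(px, py, poly) {
  pracma::inpolygon(px, py, poly[, 1L], poly[, 2L], boundary = TRUE)
}

# Independent dense kriging solver in plain R: builds the full augmented
# covariance system and solves it per prediction point with base solve().
oracle_krige <- function(coords, z, model, pred,
                         method = c("ordinary", "simple", "universal"),
                         sk_mean = mean(z)) {
  method <- match.arg(method)
  n <- nrow(coords)
  cv <- function(h) ifelse(h <= 1e-12, model$nugget + model$psill,
                           model$psill * exp(-h / model$range))
  stopifnot(model$family == "exponential")
  D <- as.matrix(stats::dist(coords))
  C <- cv(D)
  C0 <- model$nugget + model$psill
  Fm <- switch(method,
               simple = NULL,
               ordinary = matrix(1, n, 1L),
               universal = cbind(1, coords))
  p <- if (is.null(Fm)) 0L else ncol(Fm)
  A <- if (p == 0L) C else rbind(cbind(C, Fm),
                                 cbind(t(Fm), matrix(0, p, p)))
  preds <- numeric(nrow(pred)); vars <- numeric(nrow(pred))
  W <- matrix(0, nrow(pred), n)
  for (q in seq_len(nrow(pred))) {
    h <- sqrt((coords[, 1L] - pred[q, 1L])^2 + (coords[, 2L] - pred[q, 2L])^2)
    b <- cv(h)
    bf <- switch(method,
                 simple = b,
                 ordinary = c(b, 1),
                 universal = c(b, 1, pred[q, 1L], pred[q, 2L]))
    x <- solve(A, bf)
    w <- x[seq_len(n)]
    W[q, ] <- w
    if (method == "simple") {
      preds[q] <- sk_mean + sum(w * (z - sk_mean))
      vars[q] <- C0 - sum(w * b)
    } else {
      preds[q] <- sum(w * z)
      vars[q] <- C0 - sum(x * bf)
    }
  }
  list(pred = preds, var = vars, weights = W)
}

# Wrap bare coordinates + doses as a sample_set.
as_samples <- function(x, y, dose, iteration = 0L, source = "manual") {
  n <- length(x)
  dose <- rep_len(dose, n)
  radkrige:::new_sample_set(data.frame(
    x_km = x, y_km = y, true_dose_gy = dose, measured_dose_gy = dose,
    iteration = rep_len(as.integer(iteration), n),
    source = rep_len(source, n),
    subdivision_id = rep_len(NA_character_, n), stringsAsFactors = FALSE))
}

# Rasterization oracle for areas: fraction of N^2 probe cells whose center
# satisfies `inside`, times the box area.
raster_area <- function(inside_fun, bbox, n = 1000L) {
  xs <- seq(bbox[1L], bbox[2L], length.out = n + 1L)
  xs <- (xs[-1L] + xs[-(n + 1L)]) / 2
  ys <- seq(bbox[3L], bbox[4L], length.out = n + 1L)
  ys <- (ys[-1L] + ys[-(n + 1L)]) / 2
  px <- rep(xs, times = n); py <- rep(ys, each = n)
  cell <- (bbox[2L] - bbox[1L]) * (bbox[4L] - bbox[3L]) / n^2
  sum(inside_fun(px, py)) * cell
}

# Overlap matrix with a prescribed diagonal (bands as disjoint cell strips
# engineered to overlap by given fractions).
matrix_with_diagonal <- function(a) {
  stopifnot(length(a) == 8L)
  M <- diag(a)
  structure(M, class = c("overlap_matrix", "matrix"))
}
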