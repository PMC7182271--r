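# Dose bands, overlap matrices, BCD/RMSD, stopping rule, truth surface
# and population-weighted accuracy.

disk_surface <- function(value = 2.5, r = 3, center = c(5, 5), n = 200) {
  grid <- make_grid(c(0, 10, 0, 10), n = n)
  gc <- grid_centers(grid)
  inside <- (gc$centers[, 1L] - center[1L])^2 +
    (gc$centers[, 2L] - center[2L])^2 <= r^2
  list(prediction = matrix(ifelse(inside, value, 0), grid$nx, grid$ny),
       grid = grid)
}

test_that("a constant disk occupies exactly one band equal to the disk", {
  surf <- disk_surface(2.5)
  b <- extract_bands(surf)
  expect_equal(sum(b$areas_km2 > 0), 1L)
  expect_gt(b$areas_km2[3L], 0)  # the 2-3 Gy band
  expect_equal(b$areas_km2[3L], pi * 9, tolerance = 0.01)
})

test_that("bands partition the positive region and conserve area", {
  pl <- tiny_plume()
  grid <- make_grid(c(0, 20, 10, 20), n = 150)
  surf <- truth_surface(pl, grid)
  b <- extract_bands(surf)
  overlap <- Reduce(`+`, lapply(b$masks, function(m) m * 1L))
  expect_true(all(overlap <= 1L))                    # pairwise disjoint
  expect_identical(overlap == 1L, surf$prediction > 0)  # union = positive region
  expect_equal(sum(b$areas_km2), sum(surf$prediction > 0) * grid$cellsize^2)
})

test_that("band areas of an analytic cone match a 1000x1000 rasterization oracle", {
  f <- function(x, y) pmax(4 - sqrt((x - 5)^2 + (y - 5)^2), 0)
  grid <- make_grid(c(0, 10, 0, 10), n = 500)
  gc <- grid_centers(grid)
  surf <- list(prediction = matrix(f(gc$centers[, 1L], gc$centers[, 2L]),
                                   grid$nx, grid$ny), grid = grid)
  b <- extract_bands(surf)
  for (k in 1:4) {
    lo <- k - 1; hi <- if (k < 8) k else Inf
    oracle <- raster_area(function(px, py) {
      v <- f(px, py); v > 0 & v >= lo & v < hi
    }, c(0, 10, 0, 10), n = 1000L)
    expect_lt(abs(b$areas_km2[k] - oracle) / oracle, 0.01, label = paste("band", k))
  }
})

test_that("identical plumes give the identity overlap matrix; disjoint bands give 0", {
  b <- extract_bands(disk_surface(2.5))
  M <- overlap_matrix(b, b)
  expect_equal(unclass(M), diag(8), ignore_attr = TRUE)
  expect_equal(bcd(M), 0)
  expect_equal(rmsd(M), 0)
  # same band, disjoint regions: diagonal entry 0
  b2 <- extract_bands(disk_surface(2.5, center = c(2, 2), r = 1))
  M2 <- overlap_matrix(b, b2)
  expect_equal(M2[3L, 3L], 0)
})

test_that("half-overlapping equal squares give diagonal entry 0.5", {
  grid <- make_grid(c(0, 8, 0, 8), n = 160)
  gc <- grid_centers(grid)
  sq <- function(x0) {
    inside <- gc$centers[, 1L] >= x0 & gc$centers[, 1L] < x0 + 4 &
      gc$centers[, 2L] >= 2 & gc$centers[, 2L] < 6
    list(prediction = matrix(ifelse(inside, 2.5, 0), grid$nx, grid$ny),
         grid = grid)
  }
  M <- overlap_matrix(extract_bands(sq(0)), extract_bands(sq(2)))
  expect_equal(M[3L, 3L], 0.5, tolerance = 1e-9)
})

test_that("BCD and RMSD reproduce their closed forms and threshold identities", {
  # uniform diagonal 0.9: the published 90%-overlap thresholds exactly
  M9 <- matrix_with_diagonal(rep(0.9, 8L))
  expect_equal(bcd(M9), 1 / 19)
  expect_equal(rmsd(M9), 0.1)
  # uniform 0.8 gives 1/9 (hand evaluation of the BCD formula)
  expect_equal(bcd(matrix_with_diagonal(rep(0.8, 8L))), 1 / 9)
  # a single degraded band: rmsd = sqrt(0.64 / 8)
  expect_equal(rmsd(matrix_with_diagonal(c(rep(1, 7L), 0.2))),
               sqrt(0.64 / 8), tolerance = 1e-12)
  # closed forms for uniform diagonal a
  for (a in c(0.5, 0.8, 0.99)) {
    M <- matrix_with_diagonal(rep(a, 8L))
    expect_equal(bcd(M), (1 - a) / (1 + a))
    expect_equal(rmsd(M), 1 - a)
  }
})

test_that("both metrics decrease strictly as any diagonal entry improves", {
  a <- rep(0.7, 8L)
  for (i in c(1L, 5L, 8L)) {
    better <- a; better[i] <- 0.95
    expect_lt(bcd(matrix_with_diagonal(better)), bcd(matrix_with_diagonal(a)))
    expect_lt(rmsd(matrix_with_diagonal(better)), rmsd(matrix_with_diagonal(a)))
  }
})

test_that("empty-band conventions keep the identity property for weak plumes", {
  # a plume with only low-dose bands: high bands empty on both sides count
  # as full overlap, so identical plumes still give BCD = RMSD = 0
  b <- extract_bands(disk_surface(0.5))
  M <- overlap_matrix(b, b)
  expect_equal(unclass(M), diag(8), ignore_attr = TRUE)
  # one-sided empty band scores 0 on the diagonal
  M2 <- overlap_matrix(extract_bands(disk_surface(2.5)),
                       extract_bands(disk_surface(3.5)))
  expect_equal(M2[3L, 3L], 0)
  expect_equal(M2[4L, 4L], 0)
})

test_that("the stopping rule is strict OR with stringency-derived thresholds", {
  th <- stringency_thresholds(0.90)
  expect_equal(th[["bcd"]], 1 / 19)
  expect_equal(th[["rmsd"]], 0.1)
  th99 <- stringency_thresholds(0.99)
  expect_equal(th99[["bcd"]], 1 / 199)
  expect_equal(th99[["rmsd"]], 0.01)
  expect_true(check_convergence(0.04, 0.15)$converged)          # BCD branch
  expect_equal(check_convergence(0.04, 0.15)$stop_reason, "bcd")
  expect_true(check_convergence(0.06, 0.09)$converged)          # RMSD branch
  expect_equal(check_convergence(0.06, 0.09)$stop_reason, "rmsd")
  # boundary values do NOT converge (strictly below is required)
  expect_false(check_convergence(1 / 19, 0.1)$converged)
})

test_that("truth surface matches dose_at on the analysis grid and at vertices", {
  pl <- tiny_plume()
  mp <- tiny_map()
  el <- select_boundary_subdivisions(mp, pl)
  grid <- default_grid(mp, el, n = 100)
  ts <- truth_surface(pl, grid, seed = 1)
  gc <- grid_centers(grid)
  true_d <- dose_at(pl, gc$centers[, 1L], gc$centers[, 2L])
  expect_gte(mean(abs(as.vector(ts$prediction) - true_d) <= 0.5), 0.95)
  # near-exact interpolation at a contour vertex (zero nugget)
  v <- pl$rings[[6L]][10L, ]
  vg <- make_grid(c(v[1L] - 0.01, v[1L] + 0.01, v[2L] - 0.01, v[2L] + 0.01),
                  n = 1)
  tv <- truth_surface(pl, vg, seed = 1)
  expect_equal(tv$prediction[1L, 1L], pl$levels[6L], tolerance = 0.05)
  # deterministic given seed
  expect_identical(ts$prediction, truth_surface(pl, grid, seed = 1)$prediction)
})

test_that("population weighting implements the area-share formula exactly", {
  mp <- grid3x3_map(pops = c(50000L, rep(1000L, 8L)))
  # region = a 2 km^2 rectangle inside the 100 km^2 subdivision R1C1 with
  # population 50,000: credited population = 2/100 * 50000 = 1000
  grid <- make_grid(c(0, 30, 0, 30), cellsize = 0.25)
  w <- cell_population_weights(grid, mp)
  gc <- grid_centers(grid)
  region <- gc$centers[, 1L] >= 2 & gc$centers[, 1L] < 4 &
    gc$centers[, 2L] >= 3 & gc$centers[, 2L] < 4
  expect_equal(sum(w[region]), 2 / 100 * 50000, tolerance = 1e-9)
  # population conservation over the whole map
  expect_equal(sum(w), sum(mp$table$population), tolerance = 1e-6)
})

test_that("accuracy is 100/0 for identical plumes and scales with area share", {
  mp <- grid3x3_map(pops = rep(10000L, 9L))  # uniform density everywhere
  grid <- make_grid(c(0, 30, 0, 30), cellsize = 0.2)
  gc <- grid_centers(grid)
  mk <- function(xmax) {
    inside <- gc$centers[, 1L] >= 5 & gc$centers[, 1L] < xmax &
      gc$centers[, 2L] >= 12 & gc$centers[, 2L] < 18
    extract_bands(list(prediction = matrix(ifelse(inside, 2.5, 0),
                                           grid$nx, grid$ny), grid = grid))
  }
  truth <- mk(15)
  a_same <- accuracy(truth, truth, mp, 2)
  expect_equal(a_same$recall_pct, 100)
  expect_equal(a_same$false_positive_pct, 0)
  # derived covering exactly half the truth area under uniform density
  a_half <- accuracy(mk(10), truth, mp, 2)
  expect_equal(a_half$recall_pct, 50, tolerance = 1e-6)
  expect_equal(a_half$false_positive_pct, 0, tolerance = 1e-9)
  # empty truth region raises the undefined-recall error
  empty <- extract_bands(list(prediction = matrix(0, grid$nx, grid$ny),
                              grid = grid))
  expect_error(accuracy(truth, empty, mp, 2), "undefined")
})

test_that("polygon clipping areas match the rasterization oracle", {
  pl <- tiny_plume()
  outer <- pl$rings[[1L]]
  clip <- clip_polygon_rect(outer, 8, 12, 14, 16)
  got <- polygon_area(clip)
  oracle <- raster_area(function(px, py)
    point_in_polygon(px, py, outer) & px >= 8 & px <= 12 & py >= 14 & py <= 16,
    c(7.9, 12.1, 13.9, 16.1), n = 1000L)
  expect_lt(abs(got - oracle) / oracle, 0.01)
})

test_that("overlap matrices write as labelled CSV", {
  b <- extract_bands(disk_surface(2.5))
  M <- overlap_matrix(b, b)
  fp <- withr::local_tempfile(fileext = ".csv")
  write_overlap_matrix(M, fp)
  got <- utils::read.csv(fp, row.names = 1)
  expect_equal(unname(as.matrix(got)), diag(8), ignore_attr = TRUE)
})
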