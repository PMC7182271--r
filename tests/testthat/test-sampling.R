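# Boundary-subdivision selection, population-proportional sampling, dose
# error injection, and the bearing-error diagnostic.

test_that("boundary selection returns intersecting subdivisions plus edge neighbors", {
  mp <- grid3x3_map()
  # plume contained in the center tile of the 3x3 tiling
  pl <- generate_plume(epicenter = c(15, 15), bearing = 0, length_km = 3,
                       width_km = 2, vertex_density = 60, seed = 1)
  got <- sort(select_boundary_subdivisions(mp, pl))
  # center + its 4 edge-sharing neighbors (corner-touching tiles excluded)
  expect_setequal(got, c("R2C2", "R1C2", "R3C2", "R2C1", "R2C3"))

  # plume spanning two tiles picks up both neighborhoods
  pl2 <- generate_plume(epicenter = c(13, 15), bearing = 90, length_km = 9,
                        width_km = 2, vertex_density = 60, seed = 1)
  got2 <- select_boundary_subdivisions(mp, pl2)
  expect_true(all(c("R2C2", "R2C3") %in% got2))

  # brute-force adjacency: every returned non-intersecting subdivision
  # shares an edge with an intersecting one
  inter <- mp$table$id[vapply(mp$polygons, function(p)
    radkrige:::polygons_intersect(pl2$rings[[1L]], p), logical(1))]
  adj <- radkrige:::subdivision_adjacency(mp)
  for (id in setdiff(got2, inter)) {
    i <- which(mp$table$id == id)
    expect_true(any(adj[i, mp$table$id %in% inter]), label = id)
  }
  expect_error(select_boundary_subdivisions(
    mp, generate_plume(epicenter = c(500, 500), length_km = 2, width_km = 1,
                       vertex_density = 60, seed = 1)),
    "no subdivision")
})

test_that("quotas are exact (round half up) and points stay inside their subdivision", {
  mp <- grid3x3_map(pops = c(100000L, 1500L, 2499L, 2500L, 0L,
                             10000L, 700L, 300L, 499L))
  pl <- generate_plume(epicenter = c(15, 15), bearing = 0, length_km = 3,
                       width_km = 2, vertex_density = 60, seed = 1)
  s <- draw_initial_samples(mp, pl, fraction = 0.001,
                            eligible = mp$table$id, seed = 4)
  tab <- table(s$subdivision_id)
  expect_equal(unname(tab[["R1C1"]]), 100L)          # 0.1% of 100,000
  expect_equal(unname(tab[["R1C2"]]), 2L)            # round(1.5) half-up
  expect_equal(unname(tab[["R1C3"]]), 2L)            # round(2.499)
  expect_equal(unname(tab[["R2C1"]]), 3L)            # round(2.5) half-up
  expect_false("R2C2" %in% names(tab))               # zero population
  expect_false("R3C3" %in% names(tab))               # round(0.499) = 0
  for (id in names(tab)) {
    poly <- mp$polygons[[which(mp$table$id == id)]]
    sel <- s$subdivision_id == id
    expect_true(all(point_in_polygon(s$x_km[sel], s$y_km[sel], poly)))
  }
  # doubling the fraction doubles each quota
  s2 <- draw_initial_samples(mp, pl, fraction = 0.002,
                             eligible = mp$table$id, seed = 4)
  expect_equal(unname(table(s2$subdivision_id)[["R1C1"]]), 200L)
  # determinism
  s3 <- draw_initial_samples(mp, pl, fraction = 0.001,
                             eligible = mp$table$id, seed = 4)
  expect_identical(s, s3)
})

test_that("all-zero quotas raise the insufficient-sampling error", {
  mp <- grid3x3_map(pops = rep(100L, 9L))
  pl <- generate_plume(epicenter = c(15, 15), bearing = 0, length_km = 3,
                       width_km = 2, vertex_density = 60, seed = 1)
  expect_error(draw_initial_samples(mp, pl, fraction = 0.001,
                                    eligible = mp$table$id, seed = 1),
               "insufficient sampling")
})

test_that("biased sampling honors per-subdivision fractions and reduces to uniform", {
  mp <- grid3x3_map(pops = rep(10000L, 9L))
  pl <- generate_plume(epicenter = c(15, 15), bearing = 0, length_km = 3,
                       width_km = 2, vertex_density = 60, seed = 1)
  fr <- c(R2C2 = 0.0005, R2C1 = 0.002)
  s <- draw_biased_samples(mp, pl, fr, seed = 2)
  tab <- table(s$subdivision_id)
  expect_equal(unname(tab[["R2C2"]]), 5L)    # 0.05% of 10,000
  expect_equal(unname(tab[["R2C1"]]), 20L)   # 0.2% of 10,000
  # uniform fractions reproduce draw_initial_samples exactly (same seed)
  ids <- select_boundary_subdivisions(mp, pl)
  uni <- stats::setNames(rep(0.001, length(ids)), ids)
  expect_identical(draw_biased_samples(mp, pl, uni, seed = 9),
                   draw_initial_samples(mp, pl, 0.001, seed = 9))
  expect_error(draw_biased_samples(mp, pl, c(NOPE = 0.001)), "unknown")
  expect_error(draw_biased_samples(mp, pl, c(R2C2 = 0)), "in \\(0, 1\\]")
})

test_that("dose error injection is bounded, clamped at zero, and seeded", {
  s <- as_samples(runif(200, 0, 10), runif(200, 0, 10),
                  dose = rep(c(0, 0.5, 2, 7), 50L))
  e0 <- inject_dose_error(s, 0, seed = 1)
  expect_identical(e0$measured_dose_gy, s$true_dose_gy)
  e5 <- inject_dose_error(s, 0.5, seed = 1)
  expect_true(all(abs(e5$measured_dose_gy - e5$true_dose_gy) <= 0.5 + 1e-12))
  expect_true(all(e5$measured_dose_gy >= 0))
  # true dose 0 with max error 1: clamped draws live in [0, 1]
  z <- as_samples(runif(500), runif(500), dose = 0)
  e1 <- inject_dose_error(z, 1.0, seed = 3)
  expect_true(all(e1$measured_dose_gy >= 0 & e1$measured_dose_gy <= 1))
  expect_gt(mean(e1$measured_dose_gy == 0), 0.3)  # about half clamp to 0
  expect_identical(inject_dose_error(s, 0.5, seed = 8),
                   inject_dose_error(s, 0.5, seed = 8))
  expect_error(inject_dose_error(s, -0.1), ">= 0")
})

test_that("bearing error matches planar geometry and an atan2 oracle", {
  pl <- generate_plume(epicenter = c(0, 0), bearing = 90, length_km = 5,
                       width_km = 2, vertex_density = 60, seed = 1)
  # centroid exactly downwind (east for bearing 90): zero error
  s_e <- as_samples(c(4, 6), c(0, 0), dose = 1)
  expect_equal(sampling_bearing_error(s_e, pl), 0, tolerance = 1e-10)
  # centroid due north against an eastward plume: 90 degrees
  s_n <- as_samples(c(0, 0), c(2, 4), dose = 1)
  expect_equal(sampling_bearing_error(s_n, pl), 90, tolerance = 1e-10)
  # arbitrary centroid: independent atan2 oracle
  set.seed(11)
  for (rep in 1:5) {
    x <- runif(20, -5, 5); y <- runif(20, -5, 5)
    s <- as_samples(x, y, dose = 1)
    ang_math <- atan2(mean(y), mean(x))
    brg <- (90 - ang_math * 180 / pi) %% 360
    want <- abs(brg - 90) %% 360
    want <- min(want, 360 - want)
    expect_equal(sampling_bearing_error(s, pl), want, tolerance = 1e-9)
  }
  expect_error(sampling_bearing_error(as_samples(0, 0, 1), pl), "undefined")
})

test_that("sample sets survive a CSV round trip", {
  s <- as_samples(c(1.5, 2.25), c(3, 4), dose = c(0, 2.5))
  s$iteration <- c(0L, 3L); s$source <- c("initial", "densification")
  s$subdivision_id <- c("A", "B")
  fp <- withr::local_tempfile(fileext = ".csv")
  write_samples(s, fp)
  s2 <- read_samples(fp)
  expect_equal(as.data.frame(s2), as.data.frame(s))
  expect_s3_class(s2, "sample_set")
})
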