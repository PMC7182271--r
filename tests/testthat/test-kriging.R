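# Kriging engines against an independent dense-solve oracle, exact
# interpolation, variance screening, and the EBK ensemble.

model_fix <- semivariogram_model("exponential", nugget = 0.3, psill = 2,
                                 range = 4)

test_that("all three classical variants match the dense linear-solve oracle to 1e-8", {
  set.seed(7)
  n <- 9L
  coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  z <- runif(n, 0, 6)
  s <- as_samples(coords[, 1L], coords[, 2L], dose = z)
  grid <- make_grid(c(0, 10, 0, 10), n = 5)
  gc <- grid_centers(grid)
  for (m in c("ordinary", "simple", "universal")) {
    surf <- krige(s, model = model_fix, grid = grid, method = m,
                  details = TRUE)
    oracle <- oracle_krige(coords, z, model_fix, gc$centers, method = m)
    expect_equal(as.vector(surf$raw_prediction), oracle$pred,
                 tolerance = 1e-8, label = m)
    expect_equal(as.vector(surf$std_error), sqrt(pmax(oracle$var, 0)),
                 tolerance = 1e-8, label = m)
    if (m != "simple")
      expect_true(all(abs(rowSums(attr(surf, "weights")) - 1) < 1e-9),
                  label = paste(m, "weights sum to 1"))
  }
})

test_that("the moving-neighborhood path agrees with the oracle when k covers all samples", {
  set.seed(8)
  n <- 10L
  coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  z <- runif(n, 0, 6)
  gc <- grid_centers(make_grid(c(0, 10, 0, 10), n = 4))
  res <- radkrige:::.krige_cpp(coords, z, 0L, model_fix$nugget,
                               model_fix$psill, model_fix$range,
                               gc$centers, 1L, 0, n, FALSE)
  oracle <- oracle_krige(coords, z, model_fix, gc$centers, "ordinary")
  expect_equal(as.vector(res$pred), oracle$pred, tolerance = 1e-8)
})

test_that("zero nugget gives exact interpolation with zero standard error", {
  grid <- make_grid(c(0, 4, 0, 4), n = 4)
  gc <- grid_centers(grid)
  idx <- c(1L, 6L, 11L, 16L)
  s <- as_samples(gc$centers[idx, 1L], gc$centers[idx, 2L],
                  dose = c(1, 3, 0.5, 5))
  m0 <- semivariogram_model("exponential", nugget = 0, psill = 2, range = 3)
  surf <- krige(s, model = m0, grid = grid, method = "ordinary")
  expect_equal(as.vector(surf$prediction)[idx], c(1, 3, 0.5, 5),
               tolerance = 1e-7)
  expect_equal(as.vector(surf$std_error)[idx], rep(0, 4), tolerance = 1e-6)
})

test_that("constant-valued samples predict that constant everywhere (ordinary)", {
  s <- as_samples(c(1, 2, 3, 1.5), c(1, 3, 1, 2.2), dose = 4.2)
  surf <- krige(s, model = model_fix, grid = make_grid(c(0, 4, 0, 4), n = 6),
                method = "ordinary")
  expect_equal(as.vector(surf$prediction), rep(4.2, 36), tolerance = 1e-8)
})

test_that("adding a sample at a cell can only reduce the kriging variance there", {
  set.seed(9)
  s <- as_samples(runif(8, 0, 10), runif(8, 0, 10), dose = runif(8, 0, 5))
  grid <- make_grid(c(0, 10, 0, 10), n = 10)
  gc <- grid_centers(grid)
  target <- 45L
  before <- krige(s, model = model_fix, grid = grid)$std_error[target]
  s2 <- bind_samples(s, as_samples(gc$centers[target, 1L],
                                   gc$centers[target, 2L], dose = 2))
  after <- krige(s2, model = model_fix, grid = grid)$std_error[target]
  expect_lte(after, before + 1e-9)
})

test_that("duplicate coordinates are deduplicated instead of crashing the solve", {
  s <- as_samples(c(1, 1, 3, 5), c(1, 1, 3, 5), dose = c(2, 4, 1, 0))
  surf <- krige(s, model = model_fix, grid = make_grid(c(0, 6, 0, 6), n = 4))
  expect_true(all(is.finite(surf$prediction)))
  expect_true(all(is.finite(surf$std_error)))
})

test_that("predictions are clamped at 0 Gy", {
  # a steep downward trend makes universal kriging extrapolate negative
  s <- as_samples(c(1, 2, 3, 4), c(1, 1, 1, 1), dose = c(6, 4, 2, 0.5))
  surf <- krige(s, model = model_fix, grid = make_grid(c(0, 10, 0, 2), n = 20),
                method = "universal")
  expect_true(all(surf$prediction >= 0))
  expect_lt(min(surf$raw_prediction), 0)  # clamping actually did something
})

test_that("EBK with one subset and one simulation reduces to ordinary kriging with the REML fit", {
  set.seed(10)
  n <- 40L
  s <- as_samples(runif(n, 0, 10), runif(n, 0, 10), dose = runif(n, 0, 5))
  grid <- make_grid(c(0, 10, 0, 10), n = 12)
  m <- fit_semivariogram_reml(s)
  ok <- krige(s, model = m, grid = grid, method = "ordinary")
  e <- ebk(s, grid, n_subsets = 1, n_sims = 1, seed = 5)
  expect_equal(e$prediction, ok$prediction, tolerance = 1e-9)
  expect_equal(e$std_error, ok$std_error, tolerance = 1e-6)
})

test_that("EBK ensemble std_error dominates the smallest per-model kriging std_error", {
  set.seed(12)
  n <- 30L
  s <- as_samples(runif(n, 0, 10), runif(n, 0, 10),
                  dose = pmax(0, 5 - sqrt((runif(n, 0, 10) - 5)^2)))
  grid <- make_grid(c(0, 10, 0, 10), n = 8)
  e <- ebk(s, grid, n_subsets = 1, n_sims = 5, seed = 3)
  per_model_se <- lapply(e$ensemble[[1L]], function(m)
    krige(s, model = m, grid = grid, method = "ordinary")$std_error)
  min_se <- Reduce(pmin, per_model_se)
  expect_true(all(e$std_error >= min_se - 1e-8))
})

test_that("EBK is deterministic given the seed and downgrades gracefully", {
  set.seed(13)
  s <- as_samples(runif(25, 0, 10), runif(25, 0, 10), dose = runif(25, 0, 4))
  grid <- make_grid(c(0, 10, 0, 10), n = 6)
  a <- ebk(s, grid, n_subsets = 3, n_sims = 4, seed = 77)
  b <- ebk(s, grid, n_subsets = 3, n_sims = 4, seed = 77)
  expect_identical(a$prediction, b$prediction)
  expect_identical(a$std_error, b$std_error)
  # too few samples: downgrade to ordinary kriging with a message
  tiny <- as_samples(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1), dose = 1:5)
  expect_message(dn <- ebk(tiny, grid, seed = 1), "downgrading")
  expect_equal(dn$method, "ordinary")
})

test_that("the four-method comparison runs and reports a >=2 Gy overlap per variant", {
  pl <- tiny_plume()
  mp <- tiny_map()
  el <- select_boundary_subdivisions(mp, pl)
  s <- draw_initial_samples(mp, pl, eligible = el, seed = 21)
  grid <- default_grid(mp, el, n = 50)
  truth <- extract_bands(truth_surface(pl, grid))
  cmp <- kriging_method_comparison(s, grid, truth, seed = 2)
  expect_setequal(cmp$method, c("ordinary", "simple", "universal", "ebk"))
  expect_true(all(is.finite(cmp$overlap_2gy)))
  expect_true(all(cmp$overlap_2gy >= 0 & cmp$overlap_2gy <= 1))
  # the workflow's chosen methods recover a real share of the 2 Gy region
  expect_gt(cmp$overlap_2gy[cmp$method == "ordinary"], 0.3)
  expect_gt(cmp$overlap_2gy[cmp$method == "ebk"], 0.3)
})

test_that("kriging rejects degenerate inputs", {
  expect_error(krige(as_samples(1, 1, 2), model = model_fix,
                     grid = make_grid(c(0, 2, 0, 2), n = 2)),
               "at least 2")
})

test_that("surfaces write as ESRI ASCII grid with a std-error sidecar", {
  s <- as_samples(c(1, 2, 3), c(1, 2, 1), dose = c(1, 2, 3))
  surf <- krige(s, model = model_fix, grid = make_grid(c(0, 4, 0, 4), n = 4))
  fp <- withr::local_tempfile(fileext = ".asc")
  write_surface_asc(surf, fp)
  hdr <- readLines(fp, n = 6)
  expect_match(hdr[1L], "^ncols 4")
  expect_match(hdr[2L], "^nrows 4")
  expect_match(hdr[5L], "^cellsize 1")
  se <- utils::read.csv(sub("\\.asc$", "_se.csv", fp))
  expect_equal(nrow(se), 16L)
  expect_true(all(se$std_error_gy >= 0))
})
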