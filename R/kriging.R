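# Kriging engines: ordinary / simple / universal kriging and an empirical
# Bayesian kriging (EBK) approximation, all returning a gridded dose
# surface with prediction standard errors.

#' Define a prediction grid
#'
#' Square cells covering a bounding box. `n` sets the cell count along the
#' longer side; the other side gets as many cells as needed to cover.
#'
#' @param bbox `c(xmin, xmax, ymin, ymax)` in km.
#' @param n cells along the longer axis (ignored when `cellsize` given).
#' @param cellsize explicit cell size in km.
#' @param margin fractional margin added around the box (default 0).
#' @return object of class `dose_grid`: `xmin`, `ymin`, `cellsize`, `nx`,
#'   `ny`.
#' @export
make_grid <- function(bbox, n = 200, cellsize = NULL, margin = 0) {
  w <- bbox[2L] - bbox[1L]; h <- bbox[4L] - bbox[3L]
  stopifnot(w > 0, h > 0)
  if (margin > 0) {
    bbox <- bbox + c(-w, w, -h, h) * margin
    w <- bbox[2L] - bbox[1L]; h <- bbox[4L] - bbox[3L]
  }
  if (is.null(cellsize)) cellsize <- max(w, h) / n
  structure(list(xmin = bbox[1L], ymin = bbox[3L], cellsize = cellsize,
                 nx = as.integer(ceiling(w / cellsize - 1e-9)),
                 ny = as.integer(ceiling(h / cellsize - 1e-9))),
            class = "dose_grid")
}

#' Default analysis grid for a subdivision map
#'
#' 200 x 200 cells (configurable) covering the bounding box of the
#' boundary subdivisions plus a 10% margin.
#'
#' @param map a `subdivision_map`.
#' @param eligible optional subdivision ids to bound (default: all).
#' @param n cells along the longer side.
#' @return a `dose_grid`.
#' @export
default_grid <- function(map, eligible = NULL, n = 200) {
  polys <- map$polygons
  if (!is.null(eligible)) polys <- polys[map$table$id %in% eligible]
  bb <- c(min(vapply(polys, function(p) min(p[, 1L]), numeric(1))),
          max(vapply(polys, function(p) max(p[, 1L]), numeric(1))),
          min(vapply(polys, function(p) min(p[, 2L]), numeric(1))),
          max(vapply(polys, function(p) max(p[, 2L]), numeric(1))))
  make_grid(bb, n = n, margin = 0.1)
}

#' Cell-center coordinates of a grid
#'
#' @param grid a `dose_grid`.
#' @return list with vectors `x` (length nx), `y` (length ny), and an
#'   `nx*ny` x 2 matrix `centers` in column-major (x fastest) order.
#' @export
grid_centers <- function(grid) {
  x <- grid$xmin + (seq_len(grid$nx) - 0.5) * grid$cellsize
  y <- grid$ymin + (seq_len(grid$ny) - 0.5) * grid$cellsize
  list(x = x, y = y,
       centers = cbind(rep(x, times = grid$ny), rep(y, each = grid$nx)))
}

# Deduplicate effectively coincident sample coordinates (they make the
# kriging system singular); duplicates are averaged. The tolerance is tiny
# relative to a grid cell: distinct nearby samples are kept, only true
# coordinate repeats collapse.
dedup_samples <- function(samples, cellsize) {
  tol <- cellsize * 1e-6
  key <- paste(floor(samples$x_km / tol), floor(samples$y_km / tol))
  if (!anyDuplicated(key)) return(samples)
  agg <- function(v) tapply(v, key, mean)
  keys <- unique(key)
  data.frame(x_km = as.numeric(agg(samples$x_km)[keys]),
             y_km = as.numeric(agg(samples$y_km)[keys]),
             measured_dose_gy = as.numeric(agg(samples$measured_dose_gy)[keys]),
             stringsAsFactors = FALSE)
}

#' Krige a dose surface from samples
#'
#' Solves the kriging system per grid cell under a fitted semivariogram
#' model and returns predictions and kriging standard errors. Ordinary
#' kriging constrains the weights to sum to 1; universal kriging adds a
#' first-order spatial trend (1, x, y); simple kriging needs a known mean
#' (default: mean measured dose). Negative predictions are clamped to 0 Gy.
#' Samples sharing a grid cell are averaged before solving (duplicate
#' coordinates would make the system singular). A global solve is used up
#' to 500 samples; beyond that, each cell uses its `k_neighbors` nearest
#' samples.
#'
#' @param samples a `sample_set` (>= 2 distinct locations).
#' @param model a `semivariogram_model`; if `NULL`, fitted by WLS from the
#'   empirical semivariogram of the samples.
#' @param grid a `dose_grid`.
#' @param method `"ordinary"` (default), `"simple"`, or `"universal"`.
#' @param sk_mean known mean for simple kriging.
#' @param k_neighbors moving-neighborhood size for large sample sets.
#' @param details if `TRUE`, attach the weight matrix (small problems only).
#' @return object of class `kriged_surface`: `grid`, `prediction` and
#'   `std_error` matrices (dim nx x ny), `method`, `model`, `n_samples`.
#' @export
krige <- function(samples, model = NULL, grid,
                  method = c("ordinary", "simple", "universal"),
                  sk_mean = NULL, k_neighbors = 64, details = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "dose_grid"))
  pts <- dedup_samples(samples, grid$cellsize)
  if (nrow(pts) < 2L)
    stop("need at least 2 samples at distinct locations to krige",
         call. = FALSE)
  if (is.null(model)) model <- auto_model(samples)
  if (is.null(sk_mean)) sk_mean <- mean(pts$measured_dose_gy)
  gc <- grid_centers(grid)
  mcode <- match(method, c("simple", "ordinary", "universal")) - 1L
  kmax <- if (nrow(pts) > 500L) as.integer(k_neighbors) else 0L
  res <- .krige_cpp(cbind(pts$x_km, pts$y_km), pts$measured_dose_gy,
                    family_code(model$family), model$nugget, model$psill,
                    model$range, gc$centers, mcode, sk_mean, kmax,
                    details)
  surf <- structure(list(
    grid = grid,
    prediction = matrix(pmax(res$pred, 0), grid$nx, grid$ny),
    std_error = matrix(sqrt(pmax(res$var, 0)), grid$nx, grid$ny),
    method = method, model = model, n_samples = nrow(samples),
    raw_prediction = matrix(res$pred, grid$nx, grid$ny)
  ), class = "kriged_surface")
  if (details) attr(surf, "weights") <- res$weights
  surf
}

# WLS fit of the default family with a heuristic fallback for sample sets
# too small or too degenerate to support an empirical semivariogram.
auto_model <- function(samples) {
  mdl <- tryCatch({
    emp <- empirical_semivariogram(samples)
    suppressWarnings(fit_semivariogram(emp))
  }, error = function(e) NULL)
  if (!is.null(mdl)) return(mdl)
  d <- stats::dist(cbind(samples$x_km, samples$y_km))
  semivariogram_model("exponential", nugget = 0,
                      psill = max(stats::var(samples$measured_dose_gy), 1e-6),
                      range = max(max(d) / 2, 1e-6))
}

#' Empirical Bayesian kriging (ensemble approximation)
#'
#' Approximates EBK's semivariogram ensemble: samples are partitioned into
#' `n_subsets` local subsets (k-means on coordinates); within each subset a
#' base model is fitted by restricted maximum likelihood, and `n_sims - 1`
#' additional models are obtained by simulating Gaussian data from the base
#' model at the subset locations and refitting. Grid cells are assigned to
#' the nearest subset and predicted as the equal-weight mixture of ordinary
#' kriging under each ensemble model (all samples as data): prediction =
#' ensemble mean; variance = mean within-model kriging variance plus the
#' between-model spread of predictions. With `n_subsets = 1, n_sims = 1`
#' this reduces exactly to ordinary kriging with the REML-fitted model.
#' This is a declared approximation of proprietary EBK implementations, not
#' a re-derivation of any of them.
#'
#' @param samples a `sample_set`.
#' @param grid a `dose_grid`.
#' @param n_subsets number of local subsets (default 10; reduced when the
#'   sample set is small).
#' @param n_sims ensemble size per subset (default 30).
#' @param seed integer seed (simulation and subsetting).
#' @param family semivariogram family.
#' @param k_neighbors moving-neighborhood size for large sample sets.
#' @return a `kriged_surface` with `method = "ebk"` and the per-subset model
#'   ensembles in `$ensemble`.
#' @export
ebk <- function(samples, grid, n_subsets = 10, n_sims = 30, seed = 1,
                family = "exponential", k_neighbors = 64) {
  stopifnot(inherits(grid, "dose_grid"))
  pts <- dedup_samples(samples, grid$cellsize)
  n <- nrow(pts)
  if (n < 2L)
    stop("need at least 2 samples at distinct locations to krige",
         call. = FALSE)
  if (n < 10L) {
    message("ebk: too few samples for an ensemble; downgrading to ordinary kriging")
    return(krige(samples, model = NULL, grid = grid, method = "ordinary",
                 k_neighbors = k_neighbors))
  }
  n_subsets <- max(1L, min(n_subsets, n %/% 10L))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  assign_subset <- if (n_subsets == 1L) rep(1L, n) else {
    km <- stats::kmeans(cbind(pts$x_km, pts$y_km), centers = n_subsets,
                        nstart = 3L)
    km$cluster
  }

  ps <- function(df) {  # promote plain points to the sample_set interface
    new_sample_set(data.frame(x_km = df$x_km, y_km = df$y_km,
                              true_dose_gy = df$measured_dose_gy,
                              measured_dose_gy = df$measured_dose_gy,
                              iteration = 0L, source = "initial",
                              subdivision_id = NA_character_,
                              stringsAsFactors = FALSE))
  }

  ensembles <- vector("list", n_subsets)
  for (s in seq_len(n_subsets)) {
    sub <- pts[assign_subset == s, , drop = FALSE]
    base <- tryCatch(fit_semivariogram_reml(ps(sub), family = family),
                     warning = function(w) suppressWarnings(
                       fit_semivariogram_reml(ps(sub), family = family)),
                     error = function(e) NULL)
    if (is.null(base)) {
      emp <- empirical_semivariogram(ps(sub))
      base <- fit_semivariogram(emp, family)
    }
    models <- list(base)
    if (n_sims > 1L && nrow(sub) >= 5L) {
      D <- as.matrix(stats::dist(cbind(sub$x_km, sub$y_km)))
      C <- model_cov(base, D)
      dim(C) <- dim(D)
      ch <- tryCatch(chol(C + diag(1e-8, nrow(C))), error = function(e) NULL)
      mu <- mean(sub$measured_dose_gy)
      for (k in seq_len(n_sims - 1L)) {
        if (is.null(ch)) break
        zsim <- mu + as.vector(t(ch) %*% stats::rnorm(nrow(sub)))
        simdf <- sub; simdf$measured_dose_gy <- zsim
        mdl <- tryCatch({
          emp <- empirical_semivariogram(ps(simdf))
          suppressWarnings(fit_semivariogram(emp, family))
        }, error = function(e) NULL)
        if (!is.null(mdl)) models[[length(models) + 1L]] <- mdl
      }
    }
    ensembles[[s]] <- models
  }

  gc <- grid_centers(grid)
  kmax <- if (n > 500L) as.integer(k_neighbors) else 0L
  coords <- cbind(pts$x_km, pts$y_km)

  # Assign cells to nearest subset centroid.
  cell_subset <- if (n_subsets == 1L) rep(1L, nrow(gc$centers)) else {
    cent <- t(vapply(seq_len(n_subsets), function(s)
      c(mean(pts$x_km[assign_subset == s]), mean(pts$y_km[assign_subset == s])),
      numeric(2)))
    d2 <- outer(gc$centers[, 1L], cent[, 1L], "-")^2 +
      outer(gc$centers[, 2L], cent[, 2L], "-")^2
    max.col(-d2)
  }

  pred <- numeric(nrow(gc$centers)); vr <- numeric(nrow(gc$centers))
  for (s in seq_len(n_subsets)) {
    cells <- which(cell_subset == s)
    if (!length(cells)) next
    models <- ensembles[[s]]
    P <- matrix(0, length(cells), length(models))
    V <- matrix(0, length(cells), length(models))
    for (k in seq_along(models)) {
      m <- models[[k]]
      res <- .krige_cpp(coords, pts$measured_dose_gy,
                        family_code(m$family), m$nugget, m$psill, m$range,
                        gc$centers[cells, , drop = FALSE], 1L, 0, kmax,
                        FALSE)
      P[, k] <- res$pred
      V[, k] <- pmax(res$var, 0)
    }
    pm <- rowMeans(P)
    pred[cells] <- pm
    vr[cells] <- rowMeans(V) + rowMeans(P^2) - pm^2  # within + between
  }

  structure(list(
    grid = grid,
    prediction = matrix(pmax(pred, 0), grid$nx, grid$ny),
    std_error = matrix(sqrt(pmax(vr, 0)), grid$nx, grid$ny),
    method = "ebk",
    model = ensembles[[1L]][[1L]],
    ensemble = ensembles,
    n_samples = nrow(samples),
    raw_prediction = matrix(pred, grid$nx, grid$ny)
  ), class = "kriged_surface")
}

#' Krige with any supported method
#'
#' Dispatch helper used by the scenario orchestrator: `"ordinary"`,
#' `"simple"`, `"universal"` go to [krige()], `"ebk"` to [ebk()].
#'
#' @param samples a `sample_set`.
#' @param grid a `dose_grid`.
#' @param method kriging method name.
#' @param seed seed (EBK only).
#' @param ... passed on to the engine.
#' @return a `kriged_surface`.
#' @export
krige_surface <- function(samples, grid,
                          method = c("ordinary", "simple", "universal", "ebk"),
                          seed = 1, ...) {
  method <- match.arg(method)
  if (method == "ebk") ebk(samples, grid, seed = seed, ...)
  else krige(samples, grid = grid, method = method, ...)
}

#' @export
print.kriged_surface <- function(x, ...) {
  cat(sprintf("Kriged dose surface (%s): %d x %d cells of %.3g km\n",
              x$method, x$grid$nx, x$grid$ny, x$grid$cellsize))
  cat(sprintf("  prediction: %.2f-%.2f Gy; SE: %.3f-%.3f Gy; %d samples\n",
              min(x$prediction), max(x$prediction),
              min(x$std_error), max(x$std_error), x$n_samples))
  invisible(x)
}

#' @export
plot.kriged_surface <- function(x, what = c("prediction", "std_error"), ...) {
  what <- match.arg(what)
  gc <- grid_centers(x$grid)
  graphics::image(gc$x, gc$y, x[[what]], asp = 1,
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  xlab = "x (km)", ylab = "y (km)",
                  main = sprintf("Kriged %s (%s)", what, x$method), ...)
  graphics::contour(gc$x, gc$y, x$prediction, levels = 1:7, add = TRUE,
                    lwd = 0.5)
  invisible(x)
}

#' Compare kriging methods on one sample set
#'
#' Runs ordinary, simple, universal and EBK on the same samples and grid,
#' and reports, per method, the fraction of the true treatment-threshold
#' (>= 2 Gy) region recovered by the derived >= 2 Gy region (area
#' overlap) and its derived cell count. Simple kriging failing to yield a
#' contiguous plume is an expected outcome, not an error.
#'
#' @param samples a `sample_set`.
#' @param grid a `dose_grid`.
#' @param truth a `derived_plume` of the ground truth (see
#'   [truth_surface()] and [extract_bands()]).
#' @param seed seed for EBK.
#' @return data.frame with method, overlap_2gy (fraction), n_cells_2gy.
#' @export
kriging_method_comparison <- function(samples, grid, truth, seed = 1) {
  methods <- c("ordinary", "simple", "universal", "ebk")
  truth2 <- band_mask_at_least(truth, 2)
  rows <- lapply(methods, function(m) {
    surf <- krige_surface(samples, grid, method = m, seed = seed)
    der2 <- surf$prediction >= 2
    ov <- if (sum(truth2) > 0) sum(der2 & truth2) / sum(truth2) else NA_real_
    data.frame(method = m, overlap_2gy = ov, n_cells_2gy = sum(der2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
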