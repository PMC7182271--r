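# Population-proportional random sampling, simulated field measurement,
# dose-error injection, and directional sampling-bias diagnostics.
#
# A sample set is a data.frame with columns x_km, y_km, true_dose_gy,
# measured_dose_gy, iteration, source, subdivision_id, carrying class
# "sample_set". Row order is accumulation order: samples are only ever
# appended, never removed or mutated, across iterations.

new_sample_set <- function(df) {
  need <- c("x_km", "y_km", "true_dose_gy", "measured_dose_gy",
            "iteration", "source", "subdivision_id")
  stopifnot(all(need %in% names(df)))
  class(df) <- c("sample_set", "data.frame")
  df
}

empty_sample_set <- function() {
  new_sample_set(data.frame(
    x_km = numeric(0), y_km = numeric(0), true_dose_gy = numeric(0),
    measured_dose_gy = numeric(0), iteration = integer(0),
    source = character(0), subdivision_id = character(0),
    stringsAsFactors = FALSE))
}

#' Combine sample sets
#'
#' @param ... `sample_set` objects, appended in order.
#' @returns a `sample_set`.
#' @export
bind_samples <- function(...) {
  new_sample_set(do.call(rbind, lapply(list(...), as.data.frame)))
}

#' Subdivisions eligible for sampling around a plume
#'
#' Returns the ids of subdivisions that intersect the plume footprint
#' (outermost contour) plus all subdivisions sharing a boundary segment with
#' an intersecting one. Unirradiated (0 Gy) boundary samples are restricted
#' to this surrounding set so they anchor the kriged surface without
#' depressing the plume's range.
#'
#' @param map a `subdivision_map`.
#' @param plume a `ground_truth_plume`.
#' @return character vector of subdivision ids.
#' @export
select_boundary_subdivisions <- function(map, plume) {
  outer <- plume$rings[[1L]]
  hit <- vapply(map$polygons, function(p) polygons_intersect(outer, p), logical(1))
  if (!any(hit))
    stop("plume intersects no subdivision in the map", call. = FALSE)
  adj <- subdivision_adjacency(map)
  neigh <- hit
  for (i in which(hit)) neigh <- neigh | adj[i, ]
  map$table$id[neigh]
}

#' Draw the initial population-proportional random samples
#'
#' For each eligible subdivision, draws `round(fraction * population)`
#' uniform random locations inside its polygon (round half up), assigns the
#' true dose from the ground-truth plume's outer-contour rule, and sets the
#' measured dose equal to the true dose (use [inject_dose_error()] to
#' perturb it). The default fraction is 0.001, i.e. 0.1% of each
#' subdivision's population; low-density regions may need 0.2% or 1%.
#'
#' @param map a `subdivision_map`.
#' @param plume a `ground_truth_plume`.
#' @param fraction sampled proportion of each subdivision's population,
#'   in (0, 1].
#' @param eligible optional character vector of subdivision ids to sample
#'   (default: [select_boundary_subdivisions()]).
#' @param seed integer seed; deterministic given seed.
#' @return a `sample_set` with `iteration = 0`, `source = "initial"`.
#' @export
draw_initial_samples <- function(map, plume, fraction = 0.001,
                                 eligible = NULL, seed = 1) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  if (is.null(eligible)) eligible <- select_boundary_subdivisions(map, plume)
  fr <- stats::setNames(rep(fraction, length(eligible)), eligible)
  draw_biased_samples(map, plume, fr, seed = seed)
}

#' Draw samples with unequal per-subdivision fractions
#'
#' Like [draw_initial_samples()] but with a named vector of per-subdivision
#' sampling proportions, used to emulate directional sampling bias from a
#' mis-specified wind bearing (e.g. shifting two neighbouring subdivisions
#' from equal 0.1% proportions to 0.05%:0.2% or 0.01%:1.0%). With all
#' fractions equal it reproduces [draw_initial_samples()] exactly under the
#' same seed.
#'
#' @param map a `subdivision_map`.
#' @param plume a `ground_truth_plume`.
#' @param fractions named numeric vector, subdivision id -> proportion in
#'   (0, 1].
#' @param seed integer seed.
#' @return a `sample_set` with `iteration = 0`, `source = "initial"`.
#' @export
draw_biased_samples <- function(map, plume, fractions, seed = 1) {
  ids <- names(fractions)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("fractions must be a named vector of subdivision ids", call. = FALSE)
  unknown <- setdiff(ids, map$table$id)
  if (length(unknown))
    stop("unknown subdivision id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (any(fractions <= 0 | fractions > 1))
    stop("all fractions must be in (0, 1]", call. = FALSE)

  # Fixed iteration order (map order) so the draw is reproducible no matter
  # how the fractions vector is ordered.
  ids <- map$table$id[map$table$id %in% ids]
  quotas <- vapply(ids, function(id) {
    pop <- map$table$population[map$table$id == id]
    round_half_up(fractions[[id]] * pop)
  }, numeric(1))
  if (all(quotas == 0))
    stop("insufficient sampling: all subdivision quotas are zero; ",
         "increase the sampling fraction (e.g. 0.002 or 0.01)", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rows <- lapply(seq_along(ids), function(k) {
    n <- quotas[k]
    if (n == 0) return(NULL)
    poly <- map$polygons[[which(map$table$id == ids[k])]]
    pts <- sample_in_polygon(n, poly)
    data.frame(x_km = pts[, 1L], y_km = pts[, 2L],
               true_dose_gy = NA_real_, measured_dose_gy = NA_real_,
               iteration = 0L, source = "initial",
               subdivision_id = ids[k], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$true_dose_gy <- dose_at(plume, out$x_km, out$y_km)
  out$measured_dose_gy <- out$true_dose_gy
  new_sample_set(out)
}

#' Inject random dose-measurement error
#'
#' Perturbs every measured dose by an independent uniform error on
#' `[-max_error, +max_error]` Gy, clamped below at 0 Gy (doses are
#' physical). Maximum errors of 0.5 and 1.0 Gy correspond to the confidence
#' of dicentric chromosome analysis and the cytokinesis-blocked micronucleus
#' assay, respectively.
#'
#' @param samples a `sample_set`.
#' @param max_error maximum absolute error, Gy (>= 0; 0 is a no-op).
#' @param seed integer seed.
#' @return the `sample_set` with perturbed `measured_dose_gy`.
#' @export
inject_dose_error <- function(samples, max_error, seed = 1) {
  stopifnot(inherits(samples, "sample_set"))
  if (max_error < 0) stop("max_error must be >= 0", call. = FALSE)
  if (max_error == 0 || nrow(samples) == 0) {
    samples$measured_dose_gy <- samples$true_dose_gy
    return(samples)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  u <- stats::runif(nrow(samples), -max_error, max_error)
  samples$measured_dose_gy <- pmax(samples$true_dose_gy + u, 0)
  samples
}

#' Angular error between the sampled region and the wind bearing
#'
#' Measures directional sampling bias as the absolute angle between the
#' bearing from the epicenter to the sample centroid and the plume's
#' downwind bearing, in degrees between 0 and 180.
#'
#' @param samples a non-empty `sample_set`.
#' @param plume a `ground_truth_plume`.
#' @return angle in degrees.
#' @export
sampling_bearing_error <- function(samples, plume) {
  stopifnot(inherits(samples, "sample_set"))
  if (nrow(samples) == 0) stop("no samples", call. = FALSE)
  cx <- mean(samples$x_km) - plume$epicenter[1L]
  cy <- mean(samples$y_km) - plume$epicenter[2L]
  if (sqrt(cx^2 + cy^2) < 1e-9)
    stop("sample centroid coincides with the epicenter; bearing undefined",
         call. = FALSE)
  b <- theta_to_bearing(atan2(cy, cx))
  d <- abs(b - plume$bearing) %% 360
  min(d, 360 - d)
}

#' Irradiated and total sample counts
#'
#' @param samples a `sample_set`.
#' @return named vector `n_total`, `n_irradiated` (true dose > 0 Gy).
#' @export
sample_counts <- function(samples) {
  c(n_total = nrow(samples),
    n_irradiated = sum(samples$true_dose_gy > 0))
}

#' @export
print.sample_set <- function(x, ...) {
  ct <- sample_counts(x)
  cat(sprintf("Sample set: %d samples (%d irradiated), iterations %s\n",
              ct[1L], ct[2L],
              if (nrow(x)) paste(range(x$iteration), collapse = "-") else "-"))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Read/write sample sets as CSV
#'
#' Columns: x_km, y_km, true_dose_gy, measured_dose_gy, iteration, source,
#' subdivision_id.
#'
#' @param samples a `sample_set`.
#' @param path file path.
#' @return `read_samples` returns a `sample_set`; `write_samples` its path,
#'   invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$iteration <- as.integer(df$iteration)
  df$subdivision_id <- as.character(df$subdivision_id)
  new_sample_set(df)
}
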