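# Variance-guided densification: choose the next round of sampling
# locations where the kriged map is least certain among regions likely to
# exceed the treatment threshold.

#' Select densification candidates from a kriged surface
#'
#' Eligibility follows the upper-quartile threshold rule: a cell is
#' eligible when its upper-quartile predicted dose,
#' `prediction + 0.6745 * std_error` (the Gaussian 75th percentile),
#' reaches the critical threshold (default 2 Gy, the treatment-eligibility
#' level), and its center lies outside the excluded 0 Gy envelope.
#' Eligible cell centers are ranked by descending standard error (ties
#' broken deterministically by row, then column index) and accepted
#' greedily subject to (a) a minimum spacing of one grid cell between
#' accepted candidates and (b) deduplication against existing samples
#' sharing a grid cell. At most `max_n` candidates are returned; fewer (or
#' none) when eligibility is scarce — an empty set signals premature
#' stabilization to the orchestrator.
#'
#' @param surface a `kriged_surface`.
#' @param existing the accumulated `sample_set`.
#' @param threshold critical dose threshold, Gy (default 2).
#' @param max_n maximum number of new locations (default 200).
#' @param exclusion optional list of polygons (vertex matrices) forming the
#'   0 Gy envelope; cells whose centers fall inside are never selected.
#' @param iteration iteration number recorded on the candidate set.
#' @return object of class `candidate_set`: data.frame with `x_km`, `y_km`,
#'   `prediction_gy`, `std_error_gy`, plus attributes `threshold`,
#'   `requested`, `iteration`.
#' @export
densify <- function(surface, existing, threshold = 2, max_n = 200,
                    exclusion = NULL, iteration = NA_integer_) {
  stopifnot(inherits(surface, "kriged_surface"), threshold >= 0)
  grid <- surface$grid
  gc <- grid_centers(grid)
  pred <- as.vector(surface$prediction)
  se <- as.vector(surface$std_error)
  upper <- pred + 0.6745 * se
  elig <- upper >= threshold

  if (!is.null(exclusion) && length(exclusion) && any(elig)) {
    idx <- which(elig)
    px <- gc$centers[idx, 1L]; py <- gc$centers[idx, 2L]
    excluded <- rep(FALSE, length(idx))
    for (poly in exclusion)
      excluded <- excluded | point_in_polygon(px, py, poly)
    elig[idx[excluded]] <- FALSE
  }

  out <- data.frame(x_km = numeric(0), y_km = numeric(0),
                    prediction_gy = numeric(0), std_error_gy = numeric(0))
  if (any(elig)) {
    idx <- which(elig)
    ix <- ((idx - 1L) %% grid$nx) + 1L     # column (x index)
    iy <- ((idx - 1L) %/% grid$nx) + 1L    # row (y index)
    ord <- order(-se[idx], iy, ix)
    idx <- idx[ord]; ix <- ix[ord]; iy <- iy[ord]

    # occupied cells: existing samples (dedup tolerance = one grid cell)
    occ_key <- paste(floor((existing$x_km - grid$xmin) / grid$cellsize),
                     floor((existing$y_km - grid$ymin) / grid$cellsize))
    acc_ix <- integer(0); acc_iy <- integer(0); acc <- integer(0)
    for (k in seq_along(idx)) {
      key <- paste(ix[k] - 1L, iy[k] - 1L)
      if (key %in% occ_key) next
      if (length(acc) &&
          any(abs(acc_ix - ix[k]) <= 1L & abs(acc_iy - iy[k]) <= 1L)) next
      acc <- c(acc, idx[k]); acc_ix <- c(acc_ix, ix[k]); acc_iy <- c(acc_iy, iy[k])
      if (length(acc) >= max_n) break
    }
    if (length(acc))
      out <- data.frame(x_km = gc$centers[acc, 1L],
                        y_km = gc$centers[acc, 2L],
                        prediction_gy = pred[acc],
                        std_error_gy = se[acc])
  }
  structure(out, class = c("candidate_set", "data.frame"),
            threshold = threshold, requested = max_n, iteration = iteration,
            mean_se_eligible = if (any(elig)) mean(se[elig]) else NA_real_)
}

#' The 0 Gy envelope around the current plume
#'
#' Operationalizes the rule that locations within the unirradiated envelope
#' surrounding the plume need not be resampled: the envelope is the union
#' of subdivisions in which every existing sample measured 0 Gy and whose
#' polygon does not intersect the current derived plume (its > 0 Gy
#' region).
#'
#' @param map a `subdivision_map`.
#' @param samples the accumulated `sample_set`.
#' @param bands the current `derived_plume` (or `NULL` to skip the
#'   intersection test).
#' @return list of polygons (possibly empty) to pass as `exclusion` to
#'   [densify()].
#' @export
zero_envelope <- function(map, samples, bands = NULL) {
  out <- list()
  plume_cells <- if (!is.null(bands)) {
    gc <- grid_centers(bands$grid)
    any_mask <- Reduce(`|`, bands$masks)
    gc$centers[as.vector(any_mask), , drop = FALSE]
  } else NULL
  for (k in seq_along(map$polygons)) {
    id <- map$table$id[k]
    s <- samples[samples$subdivision_id %in% id, , drop = FALSE]
    if (nrow(s) == 0L || any(s$measured_dose_gy > 0)) next
    poly <- map$polygons[[k]]
    if (!is.null(plume_cells) && nrow(plume_cells) &&
        any(point_in_polygon(plume_cells[, 1L], plume_cells[, 2L], poly)))
      next
    out[[length(out) + 1L]] <- poly
  }
  out
}

#' Measure densification candidates against the ground truth
#'
#' Converts candidate locations into samples: the true dose comes from the
#' plume's outer-contour assignment rule, and the measured dose optionally
#' carries injected uniform error.
#'
#' @param candidates a `candidate_set` (or any data.frame with `x_km`,
#'   `y_km`).
#' @param plume a `ground_truth_plume`.
#' @param map optional `subdivision_map` to record subdivision ids.
#' @param max_error maximum absolute dose error, Gy (0 = exact).
#' @param seed integer seed for the error draw.
#' @param iteration iteration number recorded on the new samples.
#' @param source provenance label (default `"densification"`; use
#'   `"manual"` for hand-added locations).
#' @return a `sample_set` of the new measurements.
#' @export
measure_candidates <- function(candidates, plume, map = NULL, max_error = 0,
                               seed = 1, iteration = 1L,
                               source = "densification") {
  n <- nrow(candidates)
  sub <- rep(NA_character_, n)
  if (!is.null(map) && n) {
    for (k in seq_along(map$polygons)) {
      inside <- point_in_polygon(candidates$x_km, candidates$y_km,
                                 map$polygons[[k]])
      sub[inside & is.na(sub)] <- map$table$id[k]
    }
  }
  out <- new_sample_set(data.frame(
    x_km = candidates$x_km, y_km = candidates$y_km,
    true_dose_gy = if (n) dose_at(plume, candidates$x_km, candidates$y_km)
                   else numeric(0),
    measured_dose_gy = NA_real_,
    iteration = rep(as.integer(iteration), n),
    source = rep(source, n),
    subdivision_id = sub, stringsAsFactors = FALSE))
  out$measured_dose_gy <- out$true_dose_gy
  if (max_error > 0 && n)
    out <- inject_dose_error(out, max_error, seed = seed)
  out
}

#' Read manually chosen sampling locations
#'
#' Hook for supervised densification: a CSV of `x_km, y_km` coordinates to
#' be measured alongside (or instead of) automatic candidates.
#'
#' @param path CSV file with columns `x_km`, `y_km`.
#' @return data.frame usable as `candidates` in [measure_candidates()].
#' @export
read_manual_candidates <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x_km", "y_km") %in% names(df)))
  df$prediction_gy <- NA_real_
  df$std_error_gy <- NA_real_
  df
}

#' Write a candidate dispatch list
#'
#' @param candidates a `candidate_set`.
#' @param path CSV output path.
#' @return the path, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.csv(as.data.frame(candidates), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("Candidate set: %d of up to %d locations (threshold %.1f Gy)\n",
              nrow(x), attr(x, "requested"), attr(x, "threshold")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 4))
  invisible(x)
}
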