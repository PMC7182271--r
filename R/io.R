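# Plain-text interchange: GeoJSON for plumes and subdivision maps, ESRI
# ASCII grid for kriged surfaces, YAML for scenario configurations.
#
# Coordinates are planar km throughout. GeoJSON written here uses those
# planar coordinates directly; lon/lat input can be converted with the
# equirectangular shim below before use.

#' Write / read a ground-truth plume as GeoJSON
#'
#' One Polygon feature per contour ring with property `level_gy`, plus a
#' Point feature for the epicenter (properties `bearing_deg`). Reading
#' reconstructs a `ground_truth_plume` whose rings drive [dose_at()]; the
#' smooth generating field is not serialized (and not needed downstream).
#' Multi-part contours are unsupported input.
#'
#' @param plume a `ground_truth_plume`.
#' @param path GeoJSON file path.
#' @return `write_plume_geojson` the path invisibly; `read_plume_geojson` a
#'   `ground_truth_plume`.
#' @export
write_plume_geojson <- function(plume, path) {
  feats <- lapply(seq_along(plume$levels), function(k) {
    ring <- plume$rings[[k]]
    coords <- lapply(seq_len(nrow(ring) + 1L), function(i) {
      j <- if (i > nrow(ring)) 1L else i
      c(ring[j, 1L], ring[j, 2L])
    })
    list(type = "Feature",
         properties = list(level_gy = plume$levels[k]),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  feats[[length(feats) + 1L]] <- list(
    type = "Feature",
    properties = list(epicenter = TRUE, bearing_deg = plume$bearing,
                      weather = plume$weather),
    geometry = list(type = "Point", coordinates = plume$epicenter))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @rdname write_plume_geojson
#' @export
read_plume_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  levels <- numeric(0); rings <- list()
  epicenter <- c(NA_real_, NA_real_); bearing <- NA_real_; weather <- "none"
  for (f in gj$features) {
    if (identical(f$geometry$type, "Point")) {
      epicenter <- as.numeric(unlist(f$geometry$coordinates))
      if (!is.null(f$properties$bearing_deg))
        bearing <- as.numeric(f$properties$bearing_deg)
      if (!is.null(f$properties$weather))
        weather <- as.character(f$properties$weather)
      next
    }
    if (!identical(f$geometry$type, "Polygon")) next
    if (length(f$geometry$coordinates) != 1L)
      stop("multi-part contours are unsupported", call. = FALSE)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1L]],
                                  function(p) as.numeric(unlist(p))))
    if (all(ring[1L, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    levels <- c(levels, as.numeric(f$properties$level_gy))
    rings[[length(rings) + 1L]] <- ring
  }
  ord <- order(levels)
  levels <- levels[ord]; rings <- rings[ord]
  step <- if (length(levels) > 1L) levels[2L] - levels[1L] else levels[1L]
  structure(list(epicenter = epicenter, bearing = bearing, levels = levels,
                 rings = rings, field = NULL,
                 vertex_density = nrow(rings[[1L]]), weather = weather,
                 length_km = NA_real_, width_km = NA_real_,
                 peak_dose = max(levels), step = step, seed = NA_integer_),
            class = "ground_truth_plume")
}

#' Write / read a subdivision map as GeoJSON
#'
#' One Polygon feature per subdivision with properties `id` and
#' `population`.
#'
#' @param map a `subdivision_map`.
#' @param path GeoJSON file path.
#' @return `write_map_geojson` the path invisibly; `read_map_geojson` a
#'   `subdivision_map`.
#' @export
write_map_geojson <- function(map, path) {
  feats <- lapply(seq_along(map$polygons), function(k) {
    poly <- map$polygons[[k]]
    coords <- lapply(seq_len(nrow(poly) + 1L), function(i) {
      j <- if (i > nrow(poly)) 1L else i
      c(poly[j, 1L], poly[j, 2L])
    })
    list(type = "Feature",
         properties = list(id = map$table$id[k],
                           population = map$table$population[k]),
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @rdname write_map_geojson
#' @export
read_map_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  polys <- list(); ids <- character(0); pops <- numeric(0)
  for (f in gj$features) {
    if (!identical(f$geometry$type, "Polygon")) next
    poly <- do.call(rbind, lapply(f$geometry$coordinates[[1L]],
                                  function(p) as.numeric(unlist(p))))
    if (all(poly[1L, ] == poly[nrow(poly), ]))
      poly <- poly[-nrow(poly), , drop = FALSE]
    polys[[length(polys) + 1L]] <- poly
    ids <- c(ids, as.character(f$properties$id))
    pops <- c(pops, as.numeric(f$properties$population))
  }
  areas <- vapply(polys, polygon_area, numeric(1))
  bbox <- c(min(vapply(polys, function(p) min(p[, 1L]), numeric(1))),
            max(vapply(polys, function(p) max(p[, 1L]), numeric(1))),
            min(vapply(polys, function(p) min(p[, 2L]), numeric(1))),
            max(vapply(polys, function(p) max(p[, 2L]), numeric(1))))
  structure(list(polygons = polys,
                 table = data.frame(id = ids, population = pops,
                                    area_km2 = areas,
                                    density_km2 = pops / areas,
                                    stringsAsFactors = FALSE),
                 bbox = bbox, regime = NA_character_, seed = NA_integer_),
            class = "subdivision_map")
}

#' Equirectangular lon/lat to planar km conversion
#'
#' Import shim for geographic GeoJSON: projects longitude/latitude to
#' planar km about a reference latitude (x = 111.32 * cos(lat0) * lon,
#' y = 110.57 * lat). Adequate at city scale; the analysis itself is
#' projection-agnostic.
#'
#' @param lon,lat coordinate vectors in degrees.
#' @param lat0 reference latitude (default: mean of `lat`).
#' @return two-column matrix of x, y in km.
#' @export
lonlat_to_km <- function(lon, lat, lat0 = mean(lat)) {
  cbind(x_km = 111.32 * cos(lat0 * pi / 180) * lon,
        y_km = 110.574 * lat)
}

#' Write a kriged surface as an ESRI ASCII grid
#'
#' The prediction raster goes to `path` in the standard
#' ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value dialect (rows
#' written north to south); the standard-error raster goes to a sibling
#' `*_se.csv`.
#'
#' @param surface a `kriged_surface`.
#' @param path output path for the `.asc` raster.
#' @return the path, invisibly.
#' @export
write_surface_asc <- function(surface, path) {
  g <- surface$grid
  hdr <- c(sprintf("ncols %d", g$nx), sprintf("nrows %d", g$ny),
           sprintf("xllcorner %.6f", g$xmin), sprintf("yllcorner %.6f", g$ymin),
           sprintf("cellsize %.6f", g$cellsize), "NODATA_value -9999")
  rows <- vapply(rev(seq_len(g$ny)), function(iy)
    paste(formatC(surface$prediction[, iy], format = "g", digits = 6),
          collapse = " "), character(1))
  writeLines(c(hdr, rows), path)
  se_path <- sub("\\.asc$", "_se.csv", path)
  if (identical(se_path, path)) se_path <- paste0(path, "_se.csv")
  gc <- grid_centers(surface$grid)
  utils::write.csv(data.frame(x_km = gc$centers[, 1L], y_km = gc$centers[, 2L],
                              std_error_gy = as.vector(surface$std_error)),
                   se_path, row.names = FALSE)
  invisible(path)
}

#' Read a scenario configuration from a YAML file
#'
#' Flat keyed configuration; keys match the arguments of
#' [scenario_config()]. Unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(vals$bias_fractions))
    vals$bias_fractions <- unlist(vals$bias_fractions)
  for (nm in c("epicenter", "region_bbox", "replicate_seeds"))
    if (!is.null(vals[[nm]])) vals[[nm]] <- as.numeric(unlist(vals[[nm]]))
  do.call(scenario_config, vals)
}

#' Write run artifacts for one replicate
#'
#' Auditable per-replicate directory: accumulated samples CSV, final
#' surface-derived band areas, convergence trace, and a manifest of the
#' configuration.
#'
#' @param run a `replicate_run`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_samples(run$samples, file.path(dir, "samples.csv"))
  utils::write.csv(run$trace, file.path(dir, "convergence_trace.csv"),
                   row.names = FALSE)
  if (!is.null(run$bands))
    utils::write.csv(data.frame(band = run$bands$band_labels,
                                area_km2 = run$bands$areas_km2),
                     file.path(dir, "band_areas.csv"), row.names = FALSE)
  cfg <- run$config
  cfg_flat <- lapply(unclass(cfg), function(v)
    if (is.null(v)) NULL else v)
  manifest <- list(seed = run$seed, status = run$status,
                   stop_reason = run$stop_reason,
                   n_iterations = run$n_iterations,
                   config = cfg_flat)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(dir)
}
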