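# Scenario orchestration: run whole scenarios end-to-end (initial sampling,
# iterate krige -> densify -> measure -> compare until convergence), across
# replicates and perturbation experiments.

#' Build a scenario configuration
#'
#' Bundles every tunable of an end-to-end run with explicit seeds. The
#' defaults define the package's reference urban scenario: a 30 x 30 km
#' region tiled into 36 subdivisions at urban densities, an 8 x 2 km
#' teardrop plume peaking at 8 Gy, 0.1% initial sampling, ordinary kriging
#' on a 200 x 200-cell analysis grid, 2 Gy densification threshold with at
#' most 200 new locations per round, and the 90%-overlap stopping rule.
#'
#' @param name scenario label.
#' @param epicenter,bearing,length_km,width_km,peak_dose,step,vertex_density,weather
#'   plume parameters (see [generate_plume()]).
#' @param n_subdivisions,region_bbox,regime,total_population population-map
#'   parameters (see [generate_population_map()]).
#' @param scenario_seed seed fixing the plume and population map (shared by
#'   all replicates of the scenario).
#' @param fraction initial sampling fraction of each eligible subdivision's
#'   population (0.001 = 0.1%).
#' @param bias_fractions optional named vector of per-subdivision fractions
#'   overriding `fraction` (directional sampling bias).
#' @param kriging_method `"ordinary"`, `"simple"`, `"universal"` or
#'   `"ebk"`.
#' @param ebk_subsets,ebk_sims EBK ensemble size parameters.
#' @param grid_n analysis-grid resolution (cells along the longer side).
#' @param densify_threshold,densify_max densification threshold (Gy) and
#'   per-round candidate cap.
#' @param stringency overlap stringency of the stopping rule (0.90 or
#'   0.99).
#' @param max_error maximum absolute dose-measurement error in Gy (0, 0.5
#'   or 1.0).
#' @param max_iterations hard cap on kriging passes (default 15).
#' @param replicate_seeds integer seeds, one per replicate.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(name = "default-urban",
                            epicenter = c(9, 15), bearing = 90,
                            length_km = 8, width_km = 2,
                            peak_dose = 8, step = 0.5,
                            vertex_density = 250,
                            weather = "none",
                            n_subdivisions = 36,
                            region_bbox = c(0, 30, 0, 30),
                            regime = "urban",
                            total_population = NULL,
                            scenario_seed = 20,
                            fraction = 0.001,
                            bias_fractions = NULL,
                            kriging_method = "ordinary",
                            ebk_subsets = 10, ebk_sims = 30,
                            grid_n = 200,
                            densify_threshold = 2, densify_max = 200,
                            stringency = 0.90,
                            max_error = 0,
                            max_iterations = 15,
                            replicate_seeds = c(101, 202, 303)) {
  stopifnot(max_iterations >= 2, length(replicate_seeds) >= 1)
  structure(as.list(environment()), class = "scenario_config")
}

# Materialize the scenario-level artifacts shared by all replicates.
build_scenario <- function(config) {
  plume <- generate_plume(
    epicenter = config$epicenter, bearing = config$bearing,
    length_km = config$length_km, width_km = config$width_km,
    peak_dose = config$peak_dose, step = config$step,
    vertex_density = config$vertex_density, weather = config$weather,
    seed = substream_seed(config$scenario_seed, "plume"))
  map <- generate_population_map(
    n = config$n_subdivisions, bbox = config$region_bbox,
    regime = config$regime, total_population = config$total_population,
    seed = substream_seed(config$scenario_seed, "population"))
  eligible <- select_boundary_subdivisions(map, plume)
  grid <- default_grid(map, eligible, n = config$grid_n)
  tsurf <- truth_surface(plume, grid,
                         seed = substream_seed(config$scenario_seed, "truth"))
  list(plume = plume, map = map, eligible = eligible, grid = grid,
       truth_bands = extract_bands(tsurf), truth_surface = tsurf)
}

#' Run one scenario replicate end-to-end
#'
#' Draws the initial population-proportional samples, kriges the first
#' surface (iteration 1), then loops densify -> measure -> krige ->
#' compare, stopping when BCD or RMSD drops below threshold, when
#' densification yields no new candidates (premature stabilization), or at
#' the iteration cap. Replicates with no irradiated initial sample, or
#' whose initial surface contains no positive dose, fail with status
#' `"failed_no_plume"` rather than erroring. The whole run is a pure
#' function of the configuration and seed.
#'
#' @param config a `scenario_config`.
#' @param seed replicate seed (one shared stream split into sampling,
#'   error, EBK and densification substreams).
#' @param scenario prebuilt scenario artifacts (internal reuse across
#'   replicates); built from `config` when `NULL`.
#' @param verbose emit per-iteration metric lines to stderr.
#' @return object of class `replicate_run`: status, iteration and sample
#'   counts, accuracy at >= 2 and >= 3 Gy, stop reason, bearing error,
#'   convergence trace, final bands and the accumulated samples.
#' @export
run_replicate <- function(config, seed, scenario = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(scenario)) scenario <- build_scenario(config)
  plume <- scenario$plume; map <- scenario$map; grid <- scenario$grid
  thresholds <- stringency_thresholds(config$stringency)
  say <- function(...) if (verbose) message(sprintf(...))

  samples <- if (is.null(config$bias_fractions)) {
    draw_initial_samples(map, plume, fraction = config$fraction,
                         eligible = scenario$eligible,
                         seed = substream_seed(seed, "sampling"))
  } else {
    draw_biased_samples(map, plume, config$bias_fractions,
                        seed = substream_seed(seed, "sampling"))
  }
  if (config$max_error > 0)
    samples <- inject_dose_error(samples, config$max_error,
                                 seed = substream_seed(seed, "error"))
  bearing_err <- sampling_bearing_error(samples, plume)

  trace <- data.frame(iteration = integer(0), n_samples = integer(0),
                      n_new = integer(0), bcd = numeric(0), rmsd = numeric(0))
  fail <- function(reason) {
    structure(list(status = "failed_no_plume", failure_reason = reason,
                   n_iterations = 1L, counts = sample_counts(samples),
                   recall_2gy = NA_real_, recall_3gy = NA_real_,
                   false_positive_pct = NA_real_,
                   stop_reason = "failed", bearing_error_deg = bearing_err,
                   trace = trace, bands = NULL, samples = samples,
                   seed = seed, config = config),
              class = "replicate_run")
  }
  if (sample_counts(samples)[["n_irradiated"]] == 0L)
    return(fail("no irradiated samples in the initial draw"))

  krige_iter <- function(smp, it) {
    krige_surface(smp, grid, method = config$kriging_method,
                  seed = substream_seed(seed, "ebk", it),
                  n_subsets = config$ebk_subsets, n_sims = config$ebk_sims)
  }
  do_krige <- function(smp, it) {
    if (config$kriging_method == "ebk") krige_iter(smp, it)
    else krige_surface(smp, grid, method = config$kriging_method)
  }

  surface <- do_krige(samples, 1L)
  bands <- extract_bands(surface, iteration = 1L)
  if (all(!Reduce(`|`, bands$masks)))
    return(fail("initial kriging produced no positive-dose region"))
  say("iteration 1: %d samples (%d irradiated)",
      nrow(samples), sample_counts(samples)[["n_irradiated"]])

  iteration <- 1L
  stop_reason <- "max_iterations"
  while (iteration < config$max_iterations) {
    env <- zero_envelope(map, samples, bands)
    cand <- densify(surface, samples, threshold = config$densify_threshold,
                    max_n = config$densify_max, exclusion = env,
                    iteration = iteration + 1L)
    if (nrow(cand) == 0L) { stop_reason <- "no_new_candidates"; break }
    new <- measure_candidates(cand, plume, map = map,
                              max_error = config$max_error,
                              seed = substream_seed(seed, "error", iteration),
                              iteration = iteration + 1L)
    samples <- bind_samples(samples, new)
    iteration <- iteration + 1L
    surface <- do_krige(samples, iteration)
    new_bands <- extract_bands(surface, iteration = iteration)
    M <- overlap_matrix(new_bands, bands)
    b <- bcd(M); r <- rmsd(M)
    trace <- rbind(trace, data.frame(iteration = iteration,
                                     n_samples = nrow(samples),
                                     n_new = nrow(new), bcd = b, rmsd = r))
    say("iteration %d: +%d samples, BCD %.4f, RMSD %.4f",
        iteration, nrow(new), b, r)
    bands <- new_bands
    conv <- check_convergence(b, r, iteration, thresholds)
    if (conv$converged) { stop_reason <- conv$stop_reason; break }
  }

  acc2 <- tryCatch(accuracy(bands, scenario$truth_bands, map, 2),
                   error = function(e) NULL)
  acc3 <- tryCatch(accuracy(bands, scenario$truth_bands, map, 3),
                   error = function(e) NULL)
  structure(list(
    status = "converged",
    n_iterations = iteration,
    counts = sample_counts(samples),
    recall_2gy = if (is.null(acc2)) NA_real_ else acc2$recall_pct,
    recall_3gy = if (is.null(acc3)) NA_real_ else acc3$recall_pct,
    false_positive_pct = if (is.null(acc2)) NA_real_ else acc2$false_positive_pct,
    stop_reason = stop_reason,
    bearing_error_deg = bearing_err,
    trace = trace, bands = bands, samples = samples,
    seed = seed, config = config
  ), class = "replicate_run")
}

#' Run a scenario across replicates
#'
#' Executes [run_replicate()] for each replicate seed on the shared
#' scenario artifacts, then compares every pair of replicate plumes by
#' BCD/RMSD to quantify how much the random initial sampling locations
#' matter. Replicate failures are carried as statuses, not errors.
#'
#' @param config a `scenario_config`.
#' @param seeds replicate seeds (default `config$replicate_seeds`).
#' @param verbose emit per-iteration metric lines to stderr.
#' @return object of class `scenario_run`: `report` (one row per
#'   replicate, Table-style columns), `pairwise` (replicate-vs-replicate
#'   BCD/RMSD), `replicates` (full `replicate_run` objects), `scenario`.
#' @export
run_scenario <- function(config, seeds = config$replicate_seeds,
                         verbose = FALSE) {
  scenario <- build_scenario(config)
  reps <- lapply(seeds, function(s)
    run_replicate(config, s, scenario = scenario, verbose = verbose))
  report <- do.call(rbind, lapply(seq_along(reps), function(i) {
    r <- reps[[i]]
    data.frame(scenario = config$name, replicate = i, seed = seeds[i],
               status = r$status, n_iterations = r$n_iterations,
               n_samples_gt0 = r$counts[["n_irradiated"]],
               n_samples = r$counts[["n_total"]],
               recall_2gy = r$recall_2gy, recall_3gy = r$recall_3gy,
               false_positive_pct = r$false_positive_pct,
               stop_reason = r$stop_reason,
               bearing_error_deg = r$bearing_error_deg,
               stringsAsFactors = FALSE)
  }))
  ok <- which(vapply(reps, function(r) !is.null(r$bands), logical(1)))
  pairwise <- if (length(ok) >= 2L) {
    do.call(rbind, lapply(utils::combn(ok, 2, simplify = FALSE), function(p) {
      M <- overlap_matrix(reps[[p[1L]]]$bands, reps[[p[2L]]]$bands)
      data.frame(rep_a = p[1L], rep_b = p[2L], bcd = bcd(M), rmsd = rmsd(M))
    }))
  } else data.frame(rep_a = integer(0), rep_b = integer(0),
                    bcd = numeric(0), rmsd = numeric(0))
  structure(list(report = report, pairwise = pairwise, replicates = reps,
                 scenario = scenario, config = config),
            class = "scenario_run")
}

#' Run the measurement-error / sampling-bias perturbation suite
#'
#' Runs the scenario under every combination of dose-error model (none,
#' +/-0.5 Gy, +/-1.0 Gy) and sampling condition (unbiased; biased if
#' `bias_fractions` are supplied in the base config or as an argument),
#' with identical seeds, and reports accuracy, iteration and sample-count
#' deltas against the error-free unbiased base run.
#'
#' @param config base `scenario_config` (its `max_error` and
#'   `bias_fractions` are overridden per condition).
#' @param seeds replicate seeds shared by every condition.
#' @param errors dose-error levels to test, Gy.
#' @param bias_fractions optional named fraction vector for the biased arm.
#' @param verbose emit progress lines to stderr.
#' @return object of class `perturbation_suite`: `summary` (one row per
#'   condition with mean recall/iterations/samples and deltas vs base) and
#'   `runs` (named list of `scenario_run`s).
#' @export
run_perturbation_suite <- function(config, seeds = config$replicate_seeds,
                                   errors = c(0, 0.5, 1.0),
                                   bias_fractions = config$bias_fractions,
                                   verbose = FALSE) {
  conditions <- expand.grid(error = errors,
                            biased = c(FALSE, !is.null(bias_fractions)),
                            stringsAsFactors = FALSE)
  conditions <- unique(conditions)
  runs <- list(); rows <- list()
  base_key <- NULL
  for (k in seq_len(nrow(conditions))) {
    cf <- config
    cf$max_error <- conditions$error[k]
    cf$bias_fractions <- if (conditions$biased[k]) bias_fractions else NULL
    key <- sprintf("error%.1f_%s", cf$max_error,
                   if (conditions$biased[k]) "biased" else "unbiased")
    if (verbose) message("perturbation condition: ", key)
    runs[[key]] <- run_scenario(cf, seeds = seeds, verbose = FALSE)
    rp <- runs[[key]]$report
    okr <- rp$status == "converged"
    rows[[key]] <- data.frame(
      condition = key, error_gy = cf$max_error,
      biased = conditions$biased[k],
      n_converged = sum(okr),
      mean_recall_2gy = mean(rp$recall_2gy[okr]),
      mean_iterations = mean(rp$n_iterations[okr]),
      mean_samples_gt0 = mean(rp$n_samples_gt0[okr]),
      mean_bearing_error_deg = mean(rp$bearing_error_deg),
      stringsAsFactors = FALSE)
    if (is.null(base_key) && cf$max_error == 0 && !conditions$biased[k])
      base_key <- key
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(base_key)) {
    base <- summary[summary$condition == base_key, ]
    summary$delta_recall_2gy <- summary$mean_recall_2gy - base$mean_recall_2gy
    summary$delta_iterations <- summary$mean_iterations - base$mean_iterations
    summary$delta_samples_gt0 <- summary$mean_samples_gt0 - base$mean_samples_gt0
  }
  structure(list(summary = summary, runs = runs, base = base_key),
            class = "perturbation_suite")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario configuration:", x$name, "\n")
  cat(sprintf("  plume: %.1f x %.1f km, peak %.1f Gy, bearing %.0f deg, weather %s\n",
              x$length_km, x$width_km, x$peak_dose, x$bearing, x$weather))
  cat(sprintf("  population: %d subdivisions (%s), sampling %.2f%%%s\n",
              x$n_subdivisions, x$regime, 100 * x$fraction,
              if (is.null(x$bias_fractions)) "" else " (biased)"))
  cat(sprintf("  kriging: %s on %d-cell grid; densify >= %.1f Gy, max %d\n",
              x$kriging_method, x$grid_n, x$densify_threshold, x$densify_max))
  cat(sprintf("  stop: %.0f%% stringency (BCD < %.4f | RMSD < %.3f), max %d iterations; dose error +/-%.1f Gy\n",
              100 * x$stringency, stringency_thresholds(x$stringency)[["bcd"]],
              stringency_thresholds(x$stringency)[["rmsd"]],
              x$max_iterations, x$max_error))
  invisible(x)
}

#' @export
print.replicate_run <- function(x, ...) {
  cat(sprintf("Replicate run (seed %s): %s after %d iterations (%s)\n",
              x$seed, x$status, x$n_iterations, x$stop_reason))
  cat(sprintf("  samples: %d total, %d irradiated; bearing error %.1f deg\n",
              x$counts[["n_total"]], x$counts[["n_irradiated"]],
              x$bearing_error_deg))
  if (!is.na(x$recall_2gy))
    cat(sprintf("  recall >=2 Gy: %.1f%%, >=3 Gy: %.1f%%; FP fraction %.2f%%\n",
                x$recall_2gy, x$recall_3gy, x$false_positive_pct))
  invisible(x)
}

#' @export
print.scenario_run <- function(x, ...) {
  cat("Scenario run:", x$config$name, "-", nrow(x$report), "replicates\n")
  print.data.frame(x$report[, c("replicate", "status", "n_iterations",
                                "n_samples_gt0", "recall_2gy", "recall_3gy",
                                "false_positive_pct", "stop_reason")],
                   digits = 3)
  if (nrow(x$pairwise)) {
    cat("Replicate pairwise dissimilarity:\n")
    print.data.frame(x$pairwise, digits = 3)
  }
  invisible(x)
}

#' @export
summary.scenario_run <- function(object, ...) {
  rp <- object$report
  ok <- rp$status == "converged"
  out <- list(
    n_replicates = nrow(rp), n_converged = sum(ok),
    mean_iterations = mean(rp$n_iterations[ok]),
    mean_samples_gt0 = mean(rp$n_samples_gt0[ok]),
    mean_recall_2gy = mean(rp$recall_2gy[ok]),
    mean_recall_3gy = mean(rp$recall_3gy[ok]),
    mean_false_positive_pct = mean(rp$false_positive_pct[ok]),
    max_pairwise_bcd = if (nrow(object$pairwise)) max(object$pairwise$bcd)
                       else NA_real_)
  class(out) <- "summary.scenario_run"
  out
}

#' @export
print.summary.scenario_run <- function(x, ...) {
  cat(sprintf("%d/%d replicates converged; mean %.1f iterations, %.0f irradiated samples\n",
              x$n_converged, x$n_replicates, x$mean_iterations,
              x$mean_samples_gt0))
  cat(sprintf("mean recall >=2 Gy %.1f%%, >=3 Gy %.1f%%; FP %.2f%%; max pairwise BCD %.3f\n",
              x$mean_recall_2gy, x$mean_recall_3gy,
              x$mean_false_positive_pct, x$max_pairwise_bcd))
  invisible(x)
}

#' @export
plot.scenario_run <- function(x, ...) {
  traces <- lapply(x$replicates, `[[`, "trace")
  if (!any(vapply(traces, nrow, integer(1)) > 0)) {
    warning("no convergence traces to plot"); return(invisible(x))
  }
  ymax <- max(vapply(traces, function(t) if (nrow(t)) max(t$bcd, t$rmsd) else 0,
                     numeric(1)))
  plot(NA, xlim = c(2, max(x$report$n_iterations)), ylim = c(0, ymax * 1.05),
       xlab = "iteration", ylab = "dissimilarity",
       main = "Convergence of successive plumes", ...)
  for (i in seq_along(traces)) {
    t <- traces[[i]]
    if (!nrow(t)) next
    graphics::lines(t$iteration, t$bcd, col = i, lty = 1)
    graphics::lines(t$iteration, t$rmsd, col = i, lty = 2)
  }
  th <- stringency_thresholds(x$config$stringency)
  graphics::abline(h = th, col = "grey50", lty = 3)
  graphics::legend("topright", c("BCD", "RMSD"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Build directionally biased sampling fractions
#'
#' Emulates a wind-bearing specification error: the subdivision with the
#' largest plume overlap is under-sampled while its neighbor lying most to
#' one side of the downwind axis is over-sampled, all other eligible
#' subdivisions keeping the base fraction (the 0.05%:0.2% and 0.01%:1.0%
#' splits of the unequal-distribution experiments).
#'
#' @param map a `subdivision_map`.
#' @param plume a `ground_truth_plume`.
#' @param under,over fractions for the under/over-sampled pair.
#' @param base fraction for every other eligible subdivision.
#' @param side `"left"` or `"right"` of the downwind axis to shift toward.
#' @return named numeric vector usable as `bias_fractions`.
#' @export
wind_bias_fractions <- function(map, plume, under = 0.0005, over = 0.002,
                                base = 0.001, side = c("left", "right")) {
  side <- match.arg(side)
  eligible <- select_boundary_subdivisions(map, plume)
  idx <- which(map$table$id %in% eligible)
  outer <- plume$rings[[1L]]
  ovl <- vapply(idx, function(i) {
    bb <- bbox_of(map$polygons[[i]])
    clp <- clip_polygon_rect(outer, bb[1L], bb[2L], bb[3L], bb[4L])
    if (nrow(clp) >= 3L) polygon_area(clp) else 0
  }, numeric(1))
  under_i <- idx[which.max(ovl)]
  adj <- subdivision_adjacency(map)
  neigh <- which(adj[under_i, ] & seq_len(nrow(map$table)) %in% idx)
  if (!length(neigh))
    stop("under-sampled subdivision has no eligible neighbor", call. = FALSE)
  theta <- bearing_to_theta(plume$bearing)
  wind <- c(cos(theta), sin(theta))
  cen <- function(i) colMeans(map$polygons[[i]])
  c0 <- cen(under_i)
  lateral <- vapply(neigh, function(i) {
    d <- cen(i) - c0
    wind[1L] * d[2L] - wind[2L] * d[1L]   # + is left of the wind axis
  }, numeric(1))
  over_i <- neigh[if (side == "left") which.max(lateral) else which.min(lateral)]
  fr <- stats::setNames(rep(base, length(idx)), map$table$id[idx])
  fr[map$table$id[under_i]] <- under
  fr[map$table$id[over_i]] <- over
  fr
}

#' Aggregate scenario reports into one table
#'
#' @param ... `scenario_run` objects (or a single list of them).
#' @return data.frame with one row per replicate across scenarios.
#' @export
aggregate_reports <- function(...) {
  runs <- list(...)
  if (length(runs) == 1L && !inherits(runs[[1L]], "scenario_run"))
    runs <- runs[[1L]]
  do.call(rbind, lapply(runs, `[[`, "report"))
}
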