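# Empirical semivariogram estimation and model fitting.
#
# The semivariogram gamma(h) describes spatial dissimilarity as a function
# of lag distance h: nugget = lag-0 discontinuity (measurement noise),
# partial sill = spatially structured variance, range = correlation
# distance. Three standard bounded/asymptotic families are supported.

#' Empirical semivariogram
#'
#' Method-of-moments estimator: pairs are binned by lag distance and the
#' bin semivariance is `mean(0.5 * (z_i - z_j)^2)` over pairs in the bin.
#' Empty bins are omitted.
#'
#' @param samples a `sample_set`, or a data.frame with `x_km`, `y_km` and a
#'   dose column.
#' @param n_bins number of equal-width lag bins.
#' @param max_lag maximum lag considered (default: half the maximum
#'   inter-point distance, the conventional reliable-lag cutoff).
#' @param value column used as the variable (default measured dose).
#' @return object of class `empirical_semivariogram`: data.frame with
#'   columns `lag` (bin midpoint, km), `gamma` (Gy^2), `npairs`.
#' @export
empirical_semivariogram <- function(samples, n_bins = 15, max_lag = NULL,
                                    value = "measured_dose_gy") {
  xy <- cbind(samples$x_km, samples$y_km)
  z <- samples[[value]]
  if (nrow(unique(round(xy / 1e-9))) < 2L)
    stop("need at least 2 samples at distinct locations", call. = FALSE)
  d <- as.vector(stats::dist(xy))
  g <- 0.5 * as.vector(stats::dist(z))^2   # dist of z gives |z_i - z_j|
  if (is.null(max_lag)) max_lag <- max(d) / 2
  keep <- d > 0 & d <= max_lag
  d <- d[keep]; g <- g[keep]
  if (!length(d))
    stop("no sample pairs within max_lag", call. = FALSE)
  breaks <- seq(0, max_lag, length.out = n_bins + 1L)
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    lag = tapply(d, bin, mean),
    gamma = tapply(g, bin, mean),
    npairs = as.integer(tapply(g, bin, length)))
  out <- out[!is.na(out$gamma), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("empirical_semivariogram", "data.frame")
  attr(out, "max_lag") <- max_lag
  out
}

#' Construct a semivariogram model
#'
#' @param family `"exponential"`, `"spherical"` or `"gaussian"`.
#' @param nugget nugget variance, Gy^2 (>= 0).
#' @param psill partial sill, Gy^2 (>= 0).
#' @param range range parameter, km (> 0). For the exponential and gaussian
#'   families this is the distance-scale parameter (effective range about
#'   3x and 1.7x larger); for the spherical family the sill is reached
#'   exactly at `range`.
#' @return object of class `semivariogram_model`.
#' @export
semivariogram_model <- function(family = c("exponential", "spherical", "gaussian"),
                                nugget = 0, psill = 1, range = 1) {
  family <- match.arg(family)
  stopifnot(nugget >= 0, psill >= 0, range > 0)
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range),
            class = "semivariogram_model")
}

# Spatial correlation at lag h (1 at h = 0, decaying with h).
model_corr <- function(model, h) {
  a <- model$range
  switch(model$family,
         exponential = exp(-h / a),
         spherical = ifelse(h >= a, 0, 1 - 1.5 * (h / a) + 0.5 * (h / a)^3),
         gaussian = exp(-(h / a)^2))
}

#' Model semivariance at given lags
#'
#' `gamma(h) = nugget + psill * (1 - corr(h))` for h > 0 and 0 at h = 0.
#'
#' @param model a `semivariogram_model`.
#' @param h numeric vector of lags (km).
#' @return semivariances (Gy^2).
#' @export
semivariance <- function(model, h) {
  ifelse(h <= 0, 0, model$nugget + model$psill * (1 - model_corr(model, h)))
}

# Stationary covariance: C(0) = nugget + psill; C(h>0) = psill * corr(h).
model_cov <- function(model, h) {
  ifelse(h <= 1e-12, model$nugget + model$psill,
         model$psill * model_corr(model, h))
}

family_code <- function(family) {
  match(family, c("exponential", "spherical", "gaussian")) - 1L
}

#' Fit a semivariogram model to an empirical semivariogram
#'
#' Weighted least squares with pair-count weights: minimises
#' `sum(npairs * (gamma_model - gamma_emp)^2)` over (nugget, partial sill,
#' range) with a bounded search. If the optimizer fails, falls back with a
#' warning to the heuristic nugget = 0, partial sill = mean empirical
#' semivariance, range = half the maximum lag.
#'
#' @param emp an `empirical_semivariogram` (>= 3 points).
#' @param family model family (default exponential).
#' @return a `semivariogram_model` with attribute `"objective"`.
#' @export
fit_semivariogram <- function(emp, family = c("exponential", "spherical", "gaussian")) {
  family <- match.arg(family)
  if (nrow(emp) < 3L)
    stop("need at least 3 empirical semivariogram points", call. = FALSE)
  lag <- emp$lag; g <- emp$gamma; w <- emp$npairs
  sill0 <- max(mean(g), 1e-10)
  rng0 <- max(lag) / 2
  obj <- function(p) {
    m <- list(family = family, nugget = p[1L], psill = p[2L], range = p[3L])
    class(m) <- "semivariogram_model"
    sum(w * (semivariance(m, lag) - g)^2)
  }
  fit <- tryCatch(
    stats::optim(c(nugget = 0, psill = sill0, range = rng0), obj,
                 method = "L-BFGS-B",
                 lower = c(0, 1e-10, max(lag) * 1e-3),
                 upper = c(max(g) * 2 + 1e-9, max(g) * 4 + 1e-9, max(lag) * 10)),
    error = function(e) NULL)
  # A multi-start from a short-range guess guards against flat likelihoods.
  fit2 <- tryCatch(
    stats::optim(c(nugget = min(g) / 2, psill = sill0, range = max(lag) / 6), obj,
                 method = "L-BFGS-B",
                 lower = c(0, 1e-10, max(lag) * 1e-3),
                 upper = c(max(g) * 2 + 1e-9, max(g) * 4 + 1e-9, max(lag) * 10)),
    error = function(e) NULL)
  cand <- Filter(Negate(is.null), list(fit, fit2))
  if (!length(cand)) {
    warning("semivariogram fit failed; using heuristic fallback", call. = FALSE)
    out <- semivariogram_model(family, nugget = 0, psill = sill0, range = rng0)
    attr(out, "objective") <- NA_real_
    return(out)
  }
  best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "value"))]]
  par <- unname(best$par)
  out <- semivariogram_model(family, nugget = par[1L],
                             psill = max(par[2L], 1e-10),
                             range = par[3L])
  attr(out, "objective") <- best$value
  out
}

#' Fit a semivariogram model by restricted maximum likelihood
#'
#' Maximises the REML log-likelihood of a constant-mean Gaussian model with
#' covariance `nugget + psill * corr(h / range)` over the observed sample
#' locations. Used by the empirical Bayesian kriging ensemble; slower but
#' less biased by the mean estimate than curve fitting.
#'
#' @param samples a `sample_set` (or data.frame with coordinates and value).
#' @param family model family.
#' @param value dose column to use.
#' @return a `semivariogram_model` with attribute `"reml_loglik"`.
#' @export
fit_semivariogram_reml <- function(samples,
                                   family = c("exponential", "spherical", "gaussian"),
                                   value = "measured_dose_gy") {
  family <- match.arg(family)
  xy <- cbind(samples$x_km, samples$y_km)
  z <- samples[[value]]
  n <- nrow(xy)
  if (n < 5L) stop("need at least 5 samples for REML", call. = FALSE)
  D <- as.matrix(stats::dist(xy))
  vz <- stats::var(z)
  if (vz < 1e-12) {
    out <- semivariogram_model(family, 0, 1e-10, max(D) / 2)
    attr(out, "reml_loglik") <- NA_real_
    return(out)
  }
  X <- matrix(1, n, 1L)
  negll <- function(par) {
    nug <- exp(par[1L]); ps <- exp(par[2L]); rg <- exp(par[3L])
    m <- semivariogram_model(family, nug, ps, rg)
    C <- ps * model_corr(m, D)
    diag(C) <- nug + ps
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Ci_X <- backsolve(ch, forwardsolve(t(ch), X))
    Ci_z <- backsolve(ch, forwardsolve(t(ch), z))
    XtCiX <- crossprod(X, Ci_X)
    beta <- solve(XtCiX, crossprod(X, Ci_z))
    r <- z - X %*% beta
    Ci_r <- backsolve(ch, forwardsolve(t(ch), r))
    0.5 * (2 * sum(log(diag(ch))) + determinant(XtCiX)$modulus[1L] +
             sum(r * Ci_r))
  }
  start <- log(c(max(vz * 0.05, 1e-6), vz, max(D) / 4))
  fit <- tryCatch(stats::optim(start, negll, method = "Nelder-Mead",
                               control = list(maxit = 400)),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) {
    warning("REML fit failed; falling back to WLS semivariogram fit",
            call. = FALSE)
    emp <- empirical_semivariogram(samples, value = value)
    return(fit_semivariogram(emp, family))
  }
  out <- semivariogram_model(family, exp(fit$par[1L]), exp(fit$par[2L]),
                             exp(fit$par[3L]))
  attr(out, "reml_loglik") <- -fit$value
  out
}

#' @export
print.semivariogram_model <- function(x, ...) {
  cat(sprintf("Semivariogram model (%s): nugget %.4g, partial sill %.4g Gy^2, range %.3g km\n",
              x$family, x$nugget, x$psill, x$range))
  invisible(x)
}

#' @export
print.empirical_semivariogram <- function(x, ...) {
  cat("Empirical semivariogram:", nrow(x), "lag bins,",
      sum(x$npairs), "pairs\n")
  print.data.frame(x)
  invisible(x)
}

#' @export
plot.empirical_semivariogram <- function(x, model = NULL, ...) {
  plot(x$lag, x$gamma, pch = 16, cex = 0.4 + sqrt(x$npairs / max(x$npairs)),
       xlab = "lag (km)", ylab = expression(gamma ~ (Gy^2)),
       main = "Empirical semivariogram", ...)
  if (!is.null(model)) {
    h <- seq(0, max(x$lag), length.out = 200)
    graphics::lines(h, semivariance(model, h), col = "red")
  }
  invisible(x)
}
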