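#' Empirical semivariogram
#'
#' Bins half the mean squared difference of a spatial variable by pair lag
#' distance. Bins without pairs are dropped. With many points the pair set
#' is deterministically subsampled to keep the pair count quadratic-free.
#'
#' @param coords two-column matrix of planar coordinates (m).
#' @param values measurements at the coordinates (missing values dropped).
#' @param n_lags number of equal-width lag bins.
#' @param max_dist maximal lag (m); defaults to half the bounding-box
#'   diagonal, a common geostatistical default.
#' @param max_points cap on the number of points entering the pair set.
#' @return data frame with `lag` (mean pair distance), `gamma`
#'   (semivariance) and `n` (pair count) per bin.
#' @export
empirical_variogram <- function(coords, values, n_lags = 12, max_dist = NULL,
                                max_points = 2000) {
  coords <- as.matrix(coords)
  keep <- !is.na(values)
  coords <- coords[keep, , drop = FALSE]
  values <- values[keep]
  if (length(values) < 10) {
    divgrad_error("need at least 10 non-missing points for a variogram",
                  "divgrad_insufficient_data")
  }
  if (length(values) > max_points) {
    idx <- round(seq(1, length(values), length.out = max_points))
    coords <- coords[idx, , drop = FALSE]
    values <- values[idx]
  }
  if (is.null(max_dist)) {
    max_dist <- sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2)) / 2
  }
  d <- as.vector(stats::dist(coords))
  g <- as.vector(stats::dist(values))^2 / 2
  keep <- d > 0 & d <= max_dist
  d <- d[keep]; g <- g[keep]
  if (!length(d)) {
    divgrad_error("no point pairs within max_dist", "divgrad_insufficient_data")
  }
  bin <- pmin(ceiling(d / (max_dist / n_lags)), n_lags)
  lag <- as.vector(tapply(d, bin, mean))
  gamma <- as.vector(tapply(g, bin, mean))
  n <- as.vector(tapply(g, bin, length))
  data.frame(lag = lag, gamma = gamma, n = n)
}

#' Theoretical semivariogram models
#'
#' Spherical, exponential and Gaussian semivariance as a function of lag.
#'
#' @param h lag distances (m).
#' @param model list or `variogram_model` with `family`, `nugget`, `psill`,
#'   `range`.
#' @return semivariance values.
#' @export
variogram_values <- function(h, model) {
  n <- model$nugget; ps <- model$psill; r <- model$range
  base <- switch(model$family,
    spherical = ifelse(h < r, 1.5 * h / r - 0.5 * (h / r)^3, 1),
    exponential = 1 - exp(-h / r),
    gaussian = 1 - exp(-(h / r)^2),
    divgrad_error(paste("unknown variogram family", model$family),
                  "divgrad_invalid_parameter"))
  out <- n + ps * base
  out[h == 0] <- 0
  out
}

new_variogram_model <- function(family, nugget, psill, range) {
  structure(list(family = family, nugget = max(nugget, 0),
                 psill = max(psill, 0), range = max(range, 1e-9)),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget %.4g, partial sill %.4g, range %.4g\n",
              x$family, x$nugget, x$psill, x$range))
  invisible(x)
}

#' Fit a semivariogram model by weighted least squares
#'
#' Fits spherical, exponential and Gaussian candidates to an empirical
#' variogram, weighting squared residuals by pair counts, and returns the
#' family with the smallest weighted residual. Non-convergent or degenerate
#' fits fall back to a pure-nugget model with a warning.
#'
#' @param empirical output of [empirical_variogram()].
#' @return a `variogram_model`.
#' @export
fit_variogram <- function(empirical) {
  if (nrow(empirical) < 3) {
    divgrad_error("need at least 3 variogram bins to fit a model",
                  "divgrad_insufficient_data")
  }
  h <- empirical$lag; g <- empirical$gamma; w <- empirical$n
  if (all(g < 1e-12)) {
    return(new_variogram_model("exponential", 0, 0, max(h)))
  }
  sill0 <- max(g); nug0 <- max(min(g), 0)
  obj <- function(par, fam) {
    m <- list(family = fam, nugget = par[1]^2, psill = par[2]^2, range = par[3]^2)
    sum(w * (variogram_values(h, m) - g)^2)
  }
  best <- NULL; best_val <- Inf
  for (fam in c("spherical", "exponential", "gaussian")) {
    for (r0 in c(max(h) / 4, max(h) / 2, max(h))) {
      fit <- tryCatch(
        stats::optim(c(sqrt(nug0 + 1e-12), sqrt(max(sill0 - nug0, 1e-12)), sqrt(r0)),
                     obj, fam = fam, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$value) && fit$value < best_val) {
        best_val <- fit$value
        best <- new_variogram_model(fam, fit$par[1]^2, fit$par[2]^2, fit$par[3]^2)
      }
    }
  }
  if (is.null(best)) {
    warning("variogram fit did not converge; falling back to a pure-nugget model")
    return(new_variogram_model("exponential", stats::weighted.mean(g, w), 0, max(h)))
  }
  best
}

#' Ordinary kriging
#'
#' Predicts values at target locations as weighted sums of neighbouring
#' observations, with the weights solving the ordinary-kriging system of the
#' fitted semivariogram under the unbiasedness constraint (weights sum to
#' one). Duplicate observation sites are averaged before solving; the
#' neighbourhood is all points within twice the model range, capped at
#' `max_neighbors` nearest.
#'
#' @param model a `variogram_model`.
#' @param coords observed coordinates (m), two columns.
#' @param values observed values.
#' @param targets target coordinates (m), two columns.
#' @param max_neighbors neighbourhood cap.
#' @param return_weights if `TRUE`, attach the weight vectors (list column).
#' @return data frame with `pred` and `var` (kriging variance, `>= 0`), and
#'   optionally a `weights` list.
#' @export
krige <- function(model, coords, values, targets, max_neighbors = 64,
                  return_weights = FALSE) {
  coords <- as.matrix(coords); targets <- as.matrix(targets)
  keep <- !is.na(values)
  coords <- coords[keep, , drop = FALSE]; values <- values[keep]
  if (length(values) < 2) {
    divgrad_error("ordinary kriging needs at least 2 observations",
                  "divgrad_insufficient_data")
  }
  key <- paste(coords[, 1], coords[, 2], sep = "\r")
  if (anyDuplicated(key)) {
    agg <- rowsum(cbind(values, 1), key)
    first <- !duplicated(key)
    ord <- match(key[first], rownames(agg))
    coords <- coords[first, , drop = FALSE]
    values <- (agg[, 1] / agg[, 2])[ord]
  }
  n <- nrow(coords)
  nt <- nrow(targets)
  pred <- numeric(nt); krvar <- numeric(nt)
  wts <- if (return_weights) vector("list", nt) else NULL
  radius <- 2 * model$range
  for (t in seq_len(nt)) {
    d2 <- (coords[, 1] - targets[t, 1])^2 + (coords[, 2] - targets[t, 2])^2
    use <- which(d2 <= radius^2)
    if (length(use) < 2) use <- order(d2)[seq_len(min(2, n))]
    if (length(use) > max_neighbors) use <- use[order(d2[use])[seq_len(max_neighbors)]]
    m <- length(use)
    xs <- coords[use, , drop = FALSE]
    G <- variogram_values(as.matrix(stats::dist(xs)), model)
    Amat <- rbind(cbind(G, 1), c(rep(1, m), 0))
    rhs <- c(variogram_values(sqrt(d2[use]), model), 1)
    sol <- tryCatch(solve(Amat, rhs), error = function(e) qr.solve(Amat, rhs, tol = 1e-12))
    w <- sol[seq_len(m)]
    pred[t] <- sum(w * values[use])
    krvar[t] <- max(sum(w * rhs[seq_len(m)]) + sol[m + 1], 0)
    if (return_weights) wts[[t]] <- w
  }
  out <- data.frame(pred = pred, var = krvar)
  if (return_weights) out$weights <- I(wts)
  out
}

#' Impute missing vegetation covariates by ordinary kriging
#'
#' For each requested covariate and census year, fits a variogram to the
#' sampled sub-blocks and kriges the unsampled ones. Observed values are
#' never touched; predictions for bounded covariates are clamped to their
#' valid range (kriging itself is unconstrained). A provenance column
#' `<name>_src` records `observed` or `imputed`.
#'
#' @param grid a `census_grid`.
#' @param covariates covariate names to impute; default: all with missing
#'   values.
#' @param bounds named list of `c(lower, upper)` used for clamping.
#' @param colmap column map; defaults to the grid's own.
#' @param n_lags,max_neighbors kriging controls, see
#'   [empirical_variogram()] and [krige()].
#' @return the grid with missing entries filled and provenance columns added.
#' @export
impute_covariates <- function(grid, covariates = NULL, bounds = list(),
                              colmap = attr(grid, "colmap"), n_lags = 12,
                              max_neighbors = 32) {
  if (is.null(colmap)) {
    divgrad_error("no column map attached to the grid", "divgrad_schema_error")
  }
  if (is.null(covariates)) {
    covariates <- colmap$covariates[vapply(colmap$covariates,
                                           function(cc) anyNA(grid[[cc]]), logical(1))]
  }
  xy <- cbind(grid[[colmap$x]], grid[[colmap$y]])
  years <- unique(grid[[colmap$year]])
  for (cc in covariates) {
    src <- ifelse(is.na(grid[[cc]]), "imputed", "observed")
    for (yr in years) {
      rows <- grid[[colmap$year]] == yr
      v <- grid[[cc]][rows]
      mis <- is.na(v)
      if (!any(mis)) next
      emp <- empirical_variogram(xy[rows, , drop = FALSE], v, n_lags = n_lags)
      mod <- fit_variogram(emp)
      kr <- krige(mod, xy[rows, , drop = FALSE][!mis, , drop = FALSE], v[!mis],
                  xy[rows, , drop = FALSE][mis, , drop = FALSE],
                  max_neighbors = max_neighbors)
      filled <- kr$pred
      if (!is.null(bounds[[cc]])) {
        filled <- clamp(filled, bounds[[cc]][1], bounds[[cc]][2])
      }
      v[mis] <- filled
      grid[[cc]][rows] <- v
    }
    grid[[paste0(cc, "_src")]] <- src
  }
  grid
}
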