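#' Conditioning record for gradient predictions
#'
#' Most covariates have skewed distributions, so predictions along the
#' boundary-distance axis hold metric covariates at their medians and set
#' binary flags to zero. Covariates that are entirely missing are excluded
#' with a warning.
#'
#' @param blocks block-level data frame.
#' @param covariates metric covariate columns.
#' @param flags binary flag columns.
#' @return named list of fixed values.
#' @export
conditioning_record <- function(blocks, covariates = NULL, flags = NULL) {
  if (nrow(blocks) == 0) {
    divgrad_error("empty block table", "divgrad_invalid_parameter")
  }
  cm <- attr(blocks, "colmap")
  covariates <- covariates %||% cm$covariates
  flags <- flags %||% cm$flags
  cond <- list()
  for (cc in covariates) {
    v <- blocks[[cc]]
    if (is.null(v)) next
    if (all(is.na(v))) {
      warning(sprintf("covariate '%s' is entirely missing; excluded", cc))
      next
    }
    cond[[cc]] <- stats::median(v, na.rm = TRUE)
  }
  for (ff in flags) {
    if (!is.null(blocks[[ff]])) cond[[ff]] <- 0L
  }
  cond
}

#' Predicted response along the boundary-distance gradient
#'
#' Evaluates a fitted boosting model on a grid of signed distances to the
#' reserve boundary (negative inside the reserve), with all other covariates
#' fixed by a conditioning record. Land use follows the sign of the distance;
#' the census year is part of the conditioning. The peak is the grid argmax;
#' ties resolve to the smallest distance.
#'
#' @param model a `boost_model` whose learners include the distance
#'   predictor.
#' @param blocks block table supplying the observed distance range (and
#'   default conditioning).
#' @param cond conditioning record; defaults to
#'   [conditioning_record()] of `blocks`.
#' @param year census year to predict for.
#' @param by grid step (km).
#' @param dist_col,land_use_col,year_col column names.
#' @param range_km optional distance range; values beyond the observed range
#'   are refused unless `allow_extrapolate`.
#' @param allow_extrapolate permit prediction beyond the observed range.
#' @return data frame of class `gradient_curve` with columns `dist`, `pred`
#'   and attributes `peak_km`, `peak_value`, `cond`, `year`.
#' @export
gradient_curve <- function(model, blocks, cond = NULL, year = NULL, by = 0.5,
                           dist_col = "dist_boundary_km",
                           land_use_col = "land_use", year_col = "year",
                           range_km = NULL, allow_extrapolate = FALSE) {
  preds <- vapply(model$learners, function(L) L$predictor %||% NA_character_,
                  character(1))
  if (!dist_col %in% preds) {
    divgrad_error("model has no learner for the boundary distance",
                  "divgrad_configuration_error")
  }
  obs_range <- range(blocks[[dist_col]], na.rm = TRUE)
  if (is.null(range_km)) {
    range_km <- obs_range
  } else if (!allow_extrapolate &&
             (range_km[1] < obs_range[1] - 1e-9 || range_km[2] > obs_range[2] + 1e-9)) {
    divgrad_error("requested range extrapolates beyond observed distances",
                  "divgrad_extrapolation_error")
  }
  if (is.null(year)) year <- sort(unique(blocks[[year_col]]))[1]
  cond <- cond %||% conditioning_record(blocks)
  grid <- seq(range_km[1], range_km[2], by = by)
  nd <- data.frame(dist = grid)
  names(nd) <- dist_col
  nd[[land_use_col]] <- ifelse(grid < 0, "reserve", "pastoral")
  nd[[year_col]] <- year
  for (nm in names(cond)) nd[[nm]] <- cond[[nm]]
  pr <- predict(model, nd)$mean
  if (any(!is.finite(pr))) {
    divgrad_error("non-finite gradient predictions", "divgrad_numeric_error")
  }
  peak <- which.max(pr)
  structure(data.frame(dist = grid, pred = pr),
            peak_km = grid[peak], peak_value = pr[peak],
            cond = cond, year = year, class = c("gradient_curve", "data.frame"))
}

#' Per-distance percent change between two gradient curves
#'
#' `100 * (a - b) / b` on a shared distance grid, e.g. drought year versus
#' normal year. Distances where the reference is zero are masked as `NA`.
#'
#' @param a,b `gradient_curve` objects on identical grids.
#' @return data frame with `dist` and `change_pct`, with attributes
#'   `max_increase` and `max_decrease` (percent, `NA`-safe).
#' @export
relative_change <- function(a, b) {
  if (nrow(a) != nrow(b) || any(abs(a$dist - b$dist) > 1e-9)) {
    divgrad_error("curves must share an identical distance grid",
                  "divgrad_invalid_parameter")
  }
  ch <- 100 * (a$pred - b$pred) / b$pred
  ch[b$pred == 0] <- NA_real_
  structure(data.frame(dist = a$dist, change_pct = ch),
            max_increase = suppressWarnings(max(ch, na.rm = TRUE)),
            max_decrease = suppressWarnings(min(ch, na.rm = TRUE)),
            class = c("gradient_change", "data.frame"))
}
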