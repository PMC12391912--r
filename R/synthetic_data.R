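#' Geometric rank-abundance series
#'
#' Relative abundances of a species pool following a renormalized geometric
#' series `k (1 - k)^(i - 1)`. Savanna ungulate communities are strongly
#' dominated by a couple of migratory grazers; a geometric series with shape
#' around 0.4 reproduces that skew with a single parameter.
#'
#' @param n_species number of species (>= 1).
#' @param shape geometric parameter in (0, 1); larger values give steeper
#'   dominance.
#' @return numeric vector of length `n_species`, strictly decreasing,
#'   summing to one.
#' @examples
#' geometric_rank_abundance(5, 0.5)
#' @export
geometric_rank_abundance <- function(n_species, shape) {
  if (!is.numeric(n_species) || length(n_species) != 1 || n_species < 1 ||
      n_species != floor(n_species)) {
    divgrad_error("n_species must be a positive integer", "divgrad_invalid_parameter")
  }
  if (!is.numeric(shape) || length(shape) != 1 || !is.finite(shape) ||
      shape <= 0 || shape >= 1) {
    divgrad_error("shape must lie strictly between 0 and 1", "divgrad_invalid_parameter")
  }
  p <- shape * (1 - shape)^(seq_len(n_species) - 1)
  p / sum(p)
}

default_covariate_defs <- function() {
  # name, spatial correlation range (km), marginal mean/sd, valid bounds and
  # the planned-missingness pattern of the field protocol: grass plots in
  # three of nine sub-blocks, shrub and tree attributes in the centre
  # sub-block only, everything else recorded everywhere.
  defs <- rbind(
    data.frame(name = c("grass_cover", "grass_height", "grass_colour"),
               range_km = c(4, 4, 6), mean = c(55, 30, 3), sd = c(18, 12, 1),
               lower = c(0, 0, 1), upper = c(100, 200, 6),
               pattern = "one_in_three"),
    data.frame(name = c("shrub_cover", "shrub_height", "shrub_colour",
                        "tree_cover", "tree_height", "tree_colour"),
               range_km = c(5, 5, 6, 5, 5, 6),
               mean = c(15, 120, 3, 8, 350, 3), sd = c(10, 60, 1, 6, 150, 1),
               lower = c(0, 0, 1, 0, 0, 1), upper = c(100, 600, 6, 100, 1500, 6),
               pattern = "centre_only"),
    data.frame(name = c("rain_wet", "rain_dry", "rain_prior", "dist_water_km",
                        "dist_boma_km", "dist_old_boma_km", "dist_infra_km",
                        "elevation", "slope"),
               range_km = c(15, 15, 15, 6, 5, 5, 6, 20, 3),
               mean = c(780, 240, 60, 2.5, 6, 5, 7, 1600, 4),
               sd = c(90, 60, 25, 1.5, 3.5, 3, 4, 60, 2.5),
               lower = c(0, 0, 0, 0, 0, 0, 0, 1400, 0),
               upper = c(1500, 800, 400, 15, 40, 40, 40, 1900, 30),
               pattern = "none")
  )
  defs
}

default_flag_defs <- function() {
  # presence flags with log-odds linear in signed boundary distance
  # (livestock and human sign increase onto pastoral land, carnivores the
  # opposite way)
  data.frame(
    name = c("fire", "sheep_goats", "cattle", "carnivores", "vehicles", "litter"),
    intercept = c(-1.8, -1.2, -1.0, -1.6, -2.6, -2.2),
    slope_per_km = c(0.05, 0.22, 0.18, -0.10, 0.04, 0.10)
  )
}

#' Scenario configuration for the synthetic census generator
#'
#' Bundles and validates every knob of [simulate_landscape()]. The defaults
#' describe the study conditions the package is designed around: a 30 x 30
#' grid of 1-km blocks split by a reserve boundary at column 20 (signed
#' distances from about -19.5 km inside the reserve to +9.5 km on pastoral
#' land), a 19-species pool with geometric rank abundance dominated by two
#' migratory species, a drought census year with intensity multiplier 0.5 and
#' sub-block zero fraction 0.73 against a normal year at 0.63, a diversity
#' peak at +5 km and a biomass peak at -15 km.
#'
#' @param nx,ny grid dimensions in blocks (>= 4 each).
#' @param boundary_col boundary position: the column index east of which land
#'   is pastoral (boundary at `boundary_col` km from the west edge).
#' @param n_species species pool size (>= 2).
#' @param rank_shape geometric rank-abundance parameter in (0, 1).
#' @param years data frame with columns `year`, `multiplier` (drought scaling
#'   in (0, 1]) and `zero_target` (target sub-block zero fraction in \[0, 1\]).
#' @param diversity_peak_km,diversity_width_km centre (signed km) and width of
#'   the Gaussian kernel that locally flattens the rank-abundance curve,
#'   producing a diversity peak.
#' @param diversity_strength maximal flattening of the rank-abundance
#'   exponent, in \[0, 1).
#' @param biomass_peak_km,biomass_width_km centre and width of the Gaussian
#'   abundance kernel producing the biomass peak.
#' @param biomass_base baseline abundance level relative to the kernel peak.
#' @param abundance_scale multiplier (>= 1) on the minimal abundance scale
#'   that meets the zero-fraction targets. Values above one carry more
#'   animals in occupied sub-blocks while mean-preserving structural zeros
#'   keep the zero fractions on target; this mimics the spatial clumping of
#'   herding ungulates and keeps per-block samples deep enough that observed
#'   diversity tracks the underlying community rather than sampling depth.
#' @param block_sd standard deviation (log scale) of mean-one log-normal
#'   block-level abundance heterogeneity.
#' @param covariates covariate field definitions; see
#'   `default_covariate_defs()` for the expected columns.
#' @param flags presence-flag definitions (`name`, `intercept`,
#'   `slope_per_km`).
#' @param seed integer random seed.
#' @return a validated list of class `scenario_config`.
#' @export
scenario_config <- function(nx = 30, ny = 30, boundary_col = 20,
                            n_species = 19, rank_shape = 0.4,
                            years = data.frame(
                              year = c(1999L, 2002L),
                              multiplier = c(0.5, 1),
                              zero_target = c(0.73, 0.63)),
                            diversity_peak_km = 5, diversity_width_km = 4,
                            diversity_strength = 0.6,
                            biomass_peak_km = -15, biomass_width_km = 6,
                            biomass_base = 0.25,
                            abundance_scale = 6,
                            block_sd = 0.4,
                            covariates = default_covariate_defs(),
                            flags = default_flag_defs(),
                            seed = 1L) {
  cfg <- list(nx = as.integer(nx), ny = as.integer(ny),
              boundary_col = boundary_col,
              n_species = as.integer(n_species), rank_shape = rank_shape,
              years = years,
              diversity_peak_km = diversity_peak_km,
              diversity_width_km = diversity_width_km,
              diversity_strength = diversity_strength,
              biomass_peak_km = biomass_peak_km,
              biomass_width_km = biomass_width_km,
              biomass_base = biomass_base,
              abundance_scale = abundance_scale,
              block_sd = block_sd,
              covariates = covariates, flags = flags,
              seed = as.integer(seed))
  if (cfg$nx < 4 || cfg$ny < 4) {
    divgrad_error("grid must be at least 4 x 4 blocks", "divgrad_invalid_parameter")
  }
  if (cfg$n_species < 2) {
    divgrad_error("species pool must hold at least 2 species", "divgrad_invalid_parameter")
  }
  if (rank_shape <= 0 || rank_shape >= 1) {
    divgrad_error("rank_shape must lie in (0, 1)", "divgrad_invalid_parameter")
  }
  if (!all(c("year", "multiplier", "zero_target") %in% names(years)) ||
      nrow(years) < 1) {
    divgrad_error("years needs columns year, multiplier, zero_target",
                  "divgrad_invalid_parameter")
  }
  if (any(years$multiplier <= 0 | years$multiplier > 1)) {
    divgrad_error("year multipliers must lie in (0, 1]", "divgrad_invalid_parameter")
  }
  if (any(years$zero_target < 0 | years$zero_target > 1)) {
    divgrad_error("zero targets are proportions in [0, 1]", "divgrad_invalid_parameter")
  }
  if (diversity_width_km <= 0 || biomass_width_km <= 0) {
    divgrad_error("kernel widths must be positive", "divgrad_invalid_parameter")
  }
  if (diversity_strength < 0 || diversity_strength >= 1) {
    divgrad_error("diversity_strength must lie in [0, 1)", "divgrad_invalid_parameter")
  }
  if (boundary_col <= 0 || boundary_col >= cfg$nx) {
    divgrad_error("boundary column must fall inside the grid", "divgrad_invalid_parameter")
  }
  if (abundance_scale < 1) {
    divgrad_error("abundance_scale must be >= 1", "divgrad_invalid_parameter")
  }
  structure(cfg, class = "scenario_config")
}

default_species_names <- function(n) {
  pool <- species_attributes()$species
  if (n <= length(pool)) pool[seq_len(n)] else c(pool, sprintf("species_%02d", seq_len(n - length(pool)) + length(pool)))
}

gauss_kernel <- function(d, centre, width) exp(-(d - centre)^2 / (2 * width^2))

# Cholesky factors of exponential-correlation matrices over the block grid,
# cached per correlation range (the factor is shared by all covariates and
# years using that range; fields differ only by their random draws and sd).
grf_factory <- function(coords_km) {
  h <- as.matrix(stats::dist(coords_km))
  n <- nrow(coords_km)
  cache <- new.env(parent = emptyenv())
  function(range_km, sd) {
    key <- sprintf("r%g", range_km)
    L <- cache[[key]]
    if (is.null(L)) {
      L <- chol(exp(-h / range_km) + diag(1e-8, n))
      cache[[key]] <- L
    }
    sd * as.vector(crossprod(L, stats::rnorm(n)))
  }
}

#' Simulate a two-year sub-block census grid
#'
#' Generates the full census data structure the downstream pipeline consumes:
#' a planar grid of 1-km blocks each holding nine 333-m sub-blocks, a signed
#' distance to the reserve boundary (negative inside the reserve), per-species
#' nonnegative counts for both census years, spatially correlated vegetation
#' covariates with the planned missingness of the field protocol, and binary
#' presence flags.
#'
#' Counts arise from a Poisson law mixed over mean-one log-normal block
#' heterogeneity, with species mixing weights `p_u^gamma(d)` (renormalized)
#' whose exponent is flattened near the diversity peak, and a total-intensity
#' kernel peaking at the biomass peak. A global abundance scale is calibrated
#' by root finding so that the year with the most animals meets its sub-block
#' zero-fraction target exactly in expectation; years needing more zeros
#' receive mean-preserving structural zeros (whole sub-blocks emptied, with
#' the conditional intensity inflated so expected counts -- and therefore
#' year-over-year abundance ratios -- are untouched).
#'
#' @param config a [scenario_config()].
#' @return a `data.frame` of class `census_grid`, one row per sub-block and
#'   census year, with attributes `colmap` (see [default_colmap()]) and
#'   `truth` (latent generating quantities per block and year, see
#'   [write_truth()]).
#' @export
simulate_landscape <- function(config) {
  if (!inherits(config, "scenario_config")) {
    divgrad_error("config must be a scenario_config", "divgrad_invalid_parameter")
  }
  with_seed(config$seed, simulate_landscape_impl(config))
}

simulate_landscape_impl <- function(config) {
  nx <- config$nx; ny <- config$ny
  n_blocks <- nx * ny
  bx <- rep(seq_len(nx) - 0.5, times = ny)        # block centre x (km)
  by <- rep(seq_len(ny) - 0.5, each = nx)
  block_id <- sprintf("B%03d_%03d", rep(seq_len(nx), times = ny),
                      rep(seq_len(ny), each = nx))
  d_block <- bx - config$boundary_col              # signed km, negative in reserve
  land_use <- ifelse(d_block < 0, "reserve", "pastoral")

  species <- default_species_names(config$n_species)
  p <- geometric_rank_abundance(config$n_species, config$rank_shape)

  # species mixing weights per block: geometric series flattened near the
  # diversity peak
  gam <- 1 - config$diversity_strength *
    gauss_kernel(d_block, config$diversity_peak_km, config$diversity_width_km)
  W <- t(vapply(gam, function(g) { w <- p^g; w / sum(w) }, numeric(config$n_species)))

  # relative total-intensity surface (biomass kernel), common to all years
  shape_d <- config$biomass_base +
    gauss_kernel(d_block, config$biomass_peak_km, config$biomass_width_km)

  yrs <- config$years
  n_years <- nrow(yrs)
  # block-level heterogeneity, mean one, drawn per block and year
  tau <- config$block_sd
  B <- matrix(exp(stats::rnorm(n_blocks * n_years, -tau^2 / 2, tau)),
              nrow = n_blocks)

  # relative block intensity before global scaling, per year
  rel <- sweep(B * shape_d, 2, yrs$multiplier, `*`)   # n_blocks x n_years

  # --- calibrate the global abundance scale A -------------------------------
  # sub-block zero probability with scale A and no structural zeros:
  # mean_i exp(-A * rel_iy / 9)
  zero_nat <- function(A, y) mean(exp(-A * rel[, y] / 9))
  A_year <- vapply(seq_len(n_years), function(y) {
    f <- function(lA) zero_nat(exp(lA), y) - yrs$zero_target[y]
    if (f(log(1e-8)) < 0) {
      divgrad_error(sprintf(
        "zero-fraction target %.2f for year %s unreachable (calibration failure)",
        yrs$zero_target[y], yrs$year[y]), "divgrad_calibration_failure")
    }
    exp(stats::uniroot(f, lower = log(1e-8), upper = log(1e8), tol = 1e-10)$root)
  }, numeric(1))
  # every year's natural zero fraction is then <= its target; the structural
  # zeros below absorb the surplus introduced by abundance_scale
  A <- max(A_year) * config$abundance_scale

  # --- mean-preserving structural zeros per year ----------------------------
  s_year <- vapply(seq_len(n_years), function(y) {
    f <- function(s) mean(s + (1 - s) * exp(-A * rel[, y] / (9 * (1 - s)))) -
      yrs$zero_target[y]
    if (f(0) >= 0) return(0)
    stats::uniroot(f, lower = 0, upper = 0.999, tol = 1e-10)$root
  }, numeric(1))

  # --- assemble sub-block rows ---------------------------------------------
  off <- c(-1, 0, 1) / 3
  sub_dx <- rep(off, times = 3); sub_dy <- rep(off, each = 3)
  n_sub <- 9L
  rows_per_year <- n_blocks * n_sub
  blk <- rep(seq_len(n_blocks), each = n_sub)
  sub_idx <- rep(seq_len(n_sub), times = n_blocks)
  x_sub_km <- bx[blk] + sub_dx[sub_idx]
  y_sub_km <- by[blk] + sub_dy[sub_idx]
  d_sub <- x_sub_km - config$boundary_col

  grids <- vector("list", n_years)
  truth <- vector("list", n_years)
  for (y in seq_len(n_years)) {
    lam_block <- A * rel[, y]                       # expected animals per block
    s <- s_year[y]
    occupied <- stats::rbinom(rows_per_year, 1, 1 - s)
    lam_sub <- lam_block[blk] / (9 * (1 - s))       # conditional intensity
    counts <- matrix(0L, rows_per_year, config$n_species,
                     dimnames = list(NULL, species))
    for (u in seq_len(config$n_species)) {
      counts[, u] <- occupied * stats::rpois(rows_per_year, lam_sub * W[blk, u])
    }
    df <- data.frame(block_id = block_id[blk], sub_block = sub_idx,
                     year = yrs$year[y], land_use = land_use[blk],
                     x_m = x_sub_km * 1000, y_m = y_sub_km * 1000,
                     dist_boundary_km = d_sub,
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(counts))
    grids[[y]] <- df
    truth[[y]] <- data.frame(
      block_id = block_id, year = yrs$year[y], dist_boundary_km = d_block,
      land_use = land_use,
      total_intensity = lam_block,
      expected_shannon = apply(W, 1, function(w) exp(-sum(w * log(w)))),
      multiplier = yrs$multiplier[y],
      structural_zero = s,
      diversity_peak_km = config$diversity_peak_km,
      biomass_peak_km = config$biomass_peak_km,
      stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, grids)

  # --- covariate fields (per year, spatially correlated, block + local noise)
  defs <- config$covariates
  grf <- grf_factory(cbind(bx, by))
  for (k in seq_len(nrow(defs))) {
    vals <- numeric(nrow(grid))
    for (y in seq_len(n_years)) {
      z_blk <- grf(defs$range_km[k], defs$sd[k])
      v <- defs$mean[k] + z_blk[blk] + 0.3 * defs$sd[k] * stats::rnorm(rows_per_year)
      vals[(y - 1) * rows_per_year + seq_len(rows_per_year)] <-
        clamp(v, defs$lower[k], defs$upper[k])
    }
    miss <- switch(defs$pattern[k],
      none = rep(FALSE, n_sub),
      one_in_three = !(seq_len(n_sub) %in% c(1L, 5L, 9L)),
      centre_only = seq_len(n_sub) != 5L,
      divgrad_error(paste("unknown missingness pattern", defs$pattern[k]),
                    "divgrad_invalid_parameter"))
    vals[miss[grid$sub_block]] <- NA_real_
    grid[[defs$name[k]]] <- vals
  }

  # --- presence flags -------------------------------------------------------
  fdefs <- config$flags
  for (k in seq_len(nrow(fdefs))) {
    pr <- stats::plogis(fdefs$intercept[k] + fdefs$slope_per_km[k] * grid$dist_boundary_km)
    grid[[fdefs$name[k]]] <- stats::rbinom(nrow(grid), 1, pr)
  }

  colmap <- default_colmap(species = species,
                           covariates = defs$name,
                           flags = fdefs$name)
  structure(grid,
            colmap = colmap,
            truth = do.call(rbind, truth),
            scale = A,
            class = c("census_grid", "data.frame"))
}

#' Latent truth table of a simulated grid
#'
#' Returns the generating quantities per block and census year (expected
#' total intensity, expected Shannon diversity of the mixing weights, the
#' year multiplier and structural-zero probability, and the configured peak
#' positions), for parameter-recovery tests.
#'
#' @param config the [scenario_config()] used for simulation.
#' @param grid the simulated [simulate_landscape()] output.
#' @return data frame with one row per (block, year).
#' @export
write_truth <- function(config, grid) {
  tr <- attr(grid, "truth")
  if (is.null(tr)) {
    divgrad_error("grid carries no truth attribute; was it simulated here?",
                  "divgrad_invalid_parameter")
  }
  tr
}

#' Fraction of sub-blocks with no wild ungulates
#'
#' @param grid a `census_grid`.
#' @return named vector of zero fractions, one per census year.
#' @export
subblock_zero_fraction <- function(grid) {
  cm <- attr(grid, "colmap")
  tot <- rowSums(as.matrix(grid[, cm$species, drop = FALSE]))
  tapply(tot == 0, grid[[cm$year]], mean)
}
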