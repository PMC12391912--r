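# Small shared fixtures, built in code.

tiny_scenario <- function(seed = 1, ...) {
  scenario_config(nx = 8, ny = 8, boundary_col = 5,
                  diversity_peak_km = 1, diversity_width_km = 2,
                  biomass_peak_km = -2, biomass_width_km = 2,
                  seed = seed, ...)
}

tiny_grid <- function(seed = 1, ...) simulate_landscape(tiny_scenario(seed, ...))

# hand-built two-block grid for aggregation edge cases
toy_grid <- function() {
  df <- data.frame(
    block_id = rep(c("A", "B"), c(9, 6)),
    sub_block = c(1:9, 1:6),
    year = 1999L,
    land_use = rep(c("reserve", "pastoral"), c(9, 6)),
    x_m = 1000 * c(rep(1, 9), rep(2, 6)),
    y_m = 500,
    dist_boundary_km = rep(c(-1.5, 0.5), c(9, 6)),
    wildebeest = c(2, 1, 0, 3, 0, 4, 0, 1, 1, 5, 5, 0, 0, 0, 0),
    zebra = 0L,
    grass_cover = c(rep(4, 9), c(NA, 2, 4, NA, NA, 6)),
    fire = c(rep(0L, 9), c(0L, 1L, 0L, 0L, 0L, 0L))
  )
  cm <- default_colmap(species = c("wildebeest", "zebra"),
                       covariates = "grass_cover", flags = "fire")
  structure(df, colmap = cm, class = c("census_grid", "data.frame"))
}
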