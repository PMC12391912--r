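test_that("geometric rank abundance is a strictly decreasing simplex vector", {
  expect_equal(geometric_rank_abundance(1, 0.5), 1)
  expect_equal(geometric_rank_abundance(2, 0.5), c(2, 1) / 3)
  p <- geometric_rank_abundance(19, 0.4)
  expect_length(p, 19)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(diff(p) < 0))
  expect_gt(p[1] + p[2], 0.5)  # two dominant species carry most abundance
  expect_error(geometric_rank_abundance(5, 1.2), class = "divgrad_invalid_parameter")
  expect_error(geometric_rank_abundance(5, 0), class = "divgrad_invalid_parameter")
  expect_error(geometric_rank_abundance(0, 0.5), class = "divgrad_invalid_parameter")
})

test_that("scenario invariants are enforced", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(nx = 3), class = "divgrad_invalid_parameter")
  expect_error(scenario_config(n_species = 1), class = "divgrad_invalid_parameter")
  expect_error(scenario_config(diversity_width_km = 0), class = "divgrad_invalid_parameter")
  expect_error(scenario_config(boundary_col = 31), class = "divgrad_invalid_parameter")
  expect_error(scenario_config(years = data.frame(year = 1, multiplier = 1.5,
                                                  zero_target = 0.5)),
               class = "divgrad_invalid_parameter")
})

test_that("simulation is reproducible from the seed and structurally sound", {
  g1 <- tiny_grid(seed = 11)
  g2 <- tiny_grid(seed = 11)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  g3 <- tiny_grid(seed = 12)
  expect_false(identical(as.data.frame(g1), as.data.frame(g3)))

  cm <- attr(g1, "colmap")
  expect_length(cm$species, 19)
  cnt <- as.matrix(g1[, cm$species])
  expect_true(all(cnt >= 0) && all(cnt == floor(cnt)))
  # land use consistent with the sign of the boundary distance
  expect_true(all((g1$dist_boundary_km < 0) == (g1$land_use == "reserve")))
  # both census years, 9 sub-blocks per block
  expect_setequal(unique(g1$year), c(1999L, 2002L))
  expect_true(all(table(g1$block_id, g1$year) == 9))
})

test_that("byte-identical CSV output for identical seeds", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_subblock_csv(tiny_grid(seed = 5), f1)
  write_subblock_csv(tiny_grid(seed = 5), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("realized zero fractions hit their targets on a 30x30 grid", {
  g <- simulate_landscape(scenario_config(seed = 42))
  zf <- subblock_zero_fraction(g)
  expect_equal(unname(zf["1999"]), 0.73, tolerance = 0.02 / 0.73)
  expect_equal(unname(zf["2002"]), 0.63, tolerance = 0.02 / 0.63)
})

test_that("lowering the drought multiplier lowers expected totals; truth table is sound", {
  cfg <- tiny_scenario(seed = 3)
  g <- simulate_landscape(cfg)
  tr <- write_truth(cfg, g)
  expect_equal(nrow(tr), 8 * 8 * 2)
  expect_true(all(tr$total_intensity >= 0))
  expect_equal(unique(tr$diversity_peak_km), cfg$diversity_peak_km)
  expect_equal(unique(tr$biomass_peak_km), cfg$biomass_peak_km)
  by_year <- tapply(tr$total_intensity, tr$year, sum)
  expect_lt(by_year[["1999"]], by_year[["2002"]])
  # the intensity ratio matches the configured multiplier up to the
  # independently drawn per-year block heterogeneity (mean one, 64 blocks)
  expect_equal(unname(by_year[["1999"]] / by_year[["2002"]]), 0.5, tolerance = 0.15)
})

test_that("planned covariate missingness follows the field protocol patterns", {
  g <- tiny_grid(seed = 8)
  # grass sampled in three sub-blocks per block, shrub/tree in the centre
  expect_setequal(unique(g$sub_block[!is.na(g$grass_cover)]), c(1, 5, 9))
  expect_setequal(unique(g$sub_block[!is.na(g$shrub_cover)]), 5)
  expect_false(anyNA(g$elevation))
})
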