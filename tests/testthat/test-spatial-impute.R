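test_that("empirical variogram matches hand-computed semivariances", {
  # constant field -> zero everywhere
  set.seed(1)
  xy <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  emp <- empirical_variogram(xy, rep(3, 20), n_lags = 5)
  expect_true(all(emp$gamma == 0))
  # insufficient data
  expect_error(empirical_variogram(xy[1:5, ], rep(NA_real_, 5)),
               class = "divgrad_insufficient_data")
  # two valued points in one bin: gamma = (0-2)^2 / 2 = 2
  xy2 <- rbind(cbind(0:8, 0), c(3.5, 0.1))
  v2 <- c(2, rep(0, 8), 0)
  emp2 <- empirical_variogram(xy2, v2, n_lags = 1, max_dist = 10)
  pairs <- combn(10, 2)
  expect_equal(emp2$gamma,
               mean((v2[pairs[1, ]] - v2[pairs[2, ]])^2 / 2))
})

test_that("white-noise field plateaus at its variance", {
  set.seed(5)
  n <- 400
  xy <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
  v <- rnorm(n, sd = 2)
  emp <- empirical_variogram(xy, v, n_lags = 10)
  plateau <- mean(emp$gamma[emp$lag > 200])
  expect_equal(plateau, 4, tolerance = 0.15)
})

test_that("variogram fitting recovers a noiseless spherical model", {
  truth <- list(family = "spherical", nugget = 0.2, psill = 0.8, range = 900)
  h <- seq(40, 1600, by = 40)
  emp <- data.frame(lag = h, gamma = variogram_values(h, truth), n = 50)
  fit <- fit_variogram(emp)
  expect_equal(fit$family, "spherical")
  expect_equal(fit$nugget, truth$nugget, tolerance = 0.1)
  expect_equal(fit$psill, truth$psill, tolerance = 0.1)
  expect_equal(fit$range, truth$range, tolerance = 0.1)
  # degenerate inputs
  expect_error(fit_variogram(emp[1:2, ]), class = "divgrad_insufficient_data")
  zero <- data.frame(lag = h[1:5], gamma = 0, n = 10)
  fz <- fit_variogram(zero)
  expect_equal(fz$nugget + fz$psill, 0)
})

test_that("ordinary kriging solves the hand-built system", {
  mod <- structure(list(family = "exponential", nugget = 0.1, psill = 1,
                        range = 500), class = "variogram_model")
  obs <- cbind(c(0, 1000, 0), c(0, 0, 800))
  v <- c(1, 3, 2)
  # both targets lie within the 2x-range neighbourhood of all three points
  tg <- rbind(c(300, 300), c(600, 200))
  kr <- krige(mod, obs, v, tg, return_weights = TRUE)
  for (t in 1:2) {
    G <- variogram_values(as.matrix(dist(obs)), mod)
    A <- rbind(cbind(G, 1), c(1, 1, 1, 0))
    g0 <- variogram_values(sqrt(rowSums(sweep(obs, 2, tg[t, ])^2)), mod)
    sol <- solve(A, c(g0, 1))
    expect_equal(kr$pred[t], sum(sol[1:3] * v), tolerance = 1e-10)
    expect_equal(sum(kr$weights[[t]]), 1, tolerance = 1e-8)
    expect_gte(kr$var[t], 0)
  }
})

test_that("kriging interpolates exactly with zero nugget and handles duplicates", {
  mod <- structure(list(family = "spherical", nugget = 0, psill = 2,
                        range = 600), class = "variogram_model")
  set.seed(2)
  obs <- cbind(runif(15, 0, 500), runif(15, 0, 500))
  v <- rnorm(15)
  kr <- krige(mod, obs, v, obs)
  expect_equal(kr$pred, v, tolerance = 1e-8)
  # constant field predicts the constant everywhere
  kr2 <- krige(mod, obs, rep(5, 15), cbind(c(100, 400), c(100, 300)))
  expect_equal(kr2$pred, c(5, 5), tolerance = 1e-8)
  # duplicated sites are averaged rather than crashing the solver
  obs3 <- rbind(obs, obs[1, ])
  v3 <- c(v, v[1] + 2)
  kr3 <- krige(mod, obs3, v3, cbind(250, 250))
  expect_true(is.finite(kr3$pred))
})

test_that("imputation fills only missing entries and respects bounds", {
  g <- tiny_grid(seed = 31)
  before <- g$grass_cover
  gi <- impute_covariates(g, covariates = "grass_cover",
                          bounds = list(grass_cover = c(0, 100)))
  obs <- !is.na(before)
  expect_identical(gi$grass_cover[obs], before[obs])
  expect_false(anyNA(gi$grass_cover))
  expect_true(all(gi$grass_cover >= 0 & gi$grass_cover <= 100))
  expect_identical(unique(gi$grass_cover_src[obs]), "observed")
  expect_identical(unique(gi$grass_cover_src[!obs]), "imputed")
})
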