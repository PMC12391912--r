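test_that("learner construction counts cells and drops constants", {
  set.seed(2)
  d <- data.frame(a = rnorm(40), b = rnorm(40),
                  flag = rep(0:1, 20),
                  cellvar = rep(c("x", "y"), each = 20))
  ln <- base_learners(d, c("a", "b"), grouping = "cellvar")
  # intercept + 2 metric predictors x 2 cells
  expect_length(ln, 1 + 4)
  expect_true(all(vapply(ln[-1], `[[`, character(1), "type") == "pspline"))
  ln2 <- base_learners(d, "flag")
  expect_equal(ln2[[2]]$type, "linear")
  d$const <- 1
  expect_warning(base_learners(d, c("a", "const")), "constant")
})

test_that("an offset-only model predicts the unconditional MLE", {
  set.seed(5)
  y <- rnbinom(200, mu = 4, size = 2)
  d <- data.frame(x = rnorm(200))
  fit <- boost_fit(y, d, fam_nb(), base_learners(d, "x"), n_iter = 0)
  p <- predict(fit, d)
  expect_equal(unname(p$pars$mu), rep(exp(fit$offset[["mu"]]), 200))
  expect_equal(length(fit$increments), 0)
})

test_that("the gaussian toy converges to the closed-form least-squares fit", {
  set.seed(42)
  n <- 200
  x <- rnorm(n)
  y <- 1.5 + 2 * x + rnorm(n)
  d <- data.frame(x = x)
  fit <- boost_fit(y, d, fam_gaussian(), base_learners(d, "x", types = "linear"),
                   n_iter = 2000, step = 0.1)
  ols <- unname(coef(lm(y ~ x)))
  cf <- fit$coef$mu[[2]]
  cf[1] <- cf[1] + fit$offset[["mu"]]
  expect_equal(unname(cf), ols, tolerance = 1e-4)
  # shrinkage: coefficients early in the path are strictly smaller
  fit_small <- boost_fit(y, d, fam_gaussian(),
                         base_learners(d, "x", types = "linear"),
                         n_iter = 5, step = 0.1)
  expect_lt(abs(fit_small$coef$mu[[2]][2]), abs(ols[2]))
})

test_that("training risk never increases, for every family", {
  set.seed(9)
  n <- 150
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  for (fn in c("gaussian", "nb", "zaga")) {
    fam <- family_by_name(fn)
    y <- switch(fn,
      gaussian = rnorm(n, d$x),
      nb = rnbinom(n, mu = exp(0.5 + 0.4 * d$x), size = 1.5),
      zaga = ifelse(runif(n) < 0.25, 0, rgamma(n, 2, 0.5)))
    fit <- boost_fit(y, d, fam, base_learners(d, c("x", "z")), n_iter = 80)
    expect_true(all(diff(c(fit$risk0, fit$path$risk)) <= 1e-9))
  }
})

test_that("informative predictors beat noise in selection frequency", {
  set.seed(3)
  n <- 500
  x <- rnorm(n)
  y <- x + rnorm(n)   # effect of one residual standard deviation
  d <- data.frame(inf = x, noise = rnorm(n))
  fit <- boost_fit(y, d, fam_gaussian(),
                   base_learners(d, c("inf", "noise"), types = "linear"),
                   n_iter = 50, step = 0.1)
  mu_sel <- fit$path$learner[fit$path$param == "mu" & !is.na(fit$path$learner)]
  frac <- mean(fit$learner_names[mu_sel] == "inf")
  expect_gt(frac, 0.8)
})

test_that("predictions on training data reproduce the fitted state", {
  set.seed(11)
  g <- tiny_grid(seed = 6)
  m <- community_summary(aggregate_blocks(g))
  rd <- divgrad:::response_data(m, "biomass_total", "dist_boundary_km")
  ln <- base_learners(rd$data, "dist_boundary_km", grouping = "year")
  fit <- boost_fit(rd$y, rd$data, rd$family, ln, n_iter = 60)
  p <- predict(fit, rd$data)
  risk_pred <- -sum(rd$family$loglik(rd$y, p$pars))
  expect_equal(risk_pred, tail(fit$path$risk, 1), tolerance = 1e-8)
})

test_that("grouped learners produce cell-specific effects", {
  set.seed(21)
  n <- 400
  cell <- rep(c("A", "B"), each = n / 2)
  x <- rnorm(n)
  y <- ifelse(cell == "A", 2 * x, -2 * x) + rnorm(n, sd = 0.5)
  d <- data.frame(x = x, cell = cell)
  ln <- base_learners(d, "x", grouping = "cell", types = "linear")
  fit <- boost_fit(y, d, fam_gaussian(), ln, n_iter = 400)
  nd <- data.frame(x = c(1, 1), cell = c("A", "B"))
  pr <- predict(fit, nd)$mean
  expect_gt(pr[1], 1)
  expect_lt(pr[2], -1)
})

test_that("cross-validated stopping is reproducible and honest about noise", {
  set.seed(7)
  n <- 300
  dn <- data.frame(a = rnorm(n), b = rnorm(n))
  yn <- rnorm(n)
  ln <- base_learners(dn, c("a", "b"), types = "linear")
  cv1 <- cv_tune(yn, dn, fam_gaussian(), ln, max_iter = 80, n_resamples = 8, seed = 5)
  cv2 <- cv_tune(yn, dn, fam_gaussian(), ln, max_iter = 80, n_resamples = 8, seed = 5)
  expect_identical(cv1$risk, cv2$risk)

  # pure noise: early stopping keeps the model at (or indistinguishable
  # from) the offset -- the typical mstop is near zero and whatever argmin
  # the near-flat held-out curve produces gains essentially nothing
  ms <- gain <- numeric(6)
  for (r in 1:6) {
    set.seed(700 + r)
    dz <- as.data.frame(matrix(rnorm(300 * 5), 300, 5))
    names(dz) <- paste0("x", 1:5)
    yz <- rnorm(300)
    lz <- base_learners(dz, names(dz), types = "linear")
    cvz <- cv_tune(yz, dz, fam_gaussian(), lz, max_iter = 60,
                   n_resamples = 6, seed = r,
                   param_learners = list(mu = 2:6, sigma = integer(0)))
    ms[r] <- cvz$mstop
    gain[r] <- (cvz$mean_risk[1] - min(cvz$mean_risk)) / 60  # per held-out row
  }
  expect_lte(median(ms), 3)          # 5% of max_iter
  expect_true(all(gain < 0.01))      # no real out-of-sample improvement

  ys <- 2 * dn$a + rnorm(n, sd = 0.5)
  cvs <- cv_tune(ys, dn, fam_gaussian(), ln, max_iter = 80, n_resamples = 8, seed = 5)
  expect_gt(cvs$mstop, 0)
  expect_lt(cvs$mean_risk[cvs$mstop + 1], cvs$mean_risk[1])
})
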