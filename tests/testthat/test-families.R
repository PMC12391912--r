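fd_gradient <- function(fam, y, eta, h = 1e-5) {
  np <- length(fam$params)
  g <- matrix(0, length(y), np)
  for (j in seq_len(np)) {
    e1 <- eta; e1[, j] <- e1[, j] + h
    e2 <- eta; e2[, j] <- e2[, j] - h
    g[, j] <- (fam$loglik(y, divgrad:::eta_to_pars(fam, e1)) -
                 fam$loglik(y, divgrad:::eta_to_pars(fam, e2))) / (2 * h)
  }
  g
}

test_that("count likelihoods normalize and truncate correctly", {
  fam <- fam_nb()
  for (mu in c(0.5, 5, 40)) {
    for (s in c(0.2, 1, 3)) {
      y <- 0:5000
      p <- exp(fam$loglik(y, list(mu = rep(mu, length(y)), sigma = rep(s, length(y)))))
      expect_equal(sum(p), 1, tolerance = 1e-10)
    }
  }
  # dispersion -> 0 approaches the Poisson limit
  p_nb <- exp(fam$loglik(0:50, list(mu = rep(3, 51), sigma = rep(1e-8, 51))))
  expect_equal(p_nb, dpois(0:50, 3), tolerance = 1e-6)

  tfam <- fam_truncnb()
  y <- 1:5000
  p <- exp(tfam$loglik(y, list(mu = rep(7, length(y)), sigma = rep(0.8, length(y)))))
  expect_equal(sum(p), 1, tolerance = 1e-10)
  # support y >= 1
  expect_error(tfam$check_y(c(1, 0, 2)), class = "divgrad_support_error")
  # truncation cancels in probability ratios
  for (mu in c(2, 9)) {
    nb2 <- fam$loglik(c(1, 2), list(mu = rep(mu, 2), sigma = c(0.7, 0.7)))
    t2 <- tfam$loglik(c(1, 2), list(mu = rep(mu, 2), sigma = c(0.7, 0.7)))
    expect_equal(t2[2] - t2[1], nb2[2] - nb2[1], tolerance = 1e-12)
  }
})

test_that("zero-adjusted gamma integrates to one and has mean (1 - nu) mu", {
  fam <- fam_zaga()
  nu <- 0.3; mu <- 2.5; s <- 0.8
  dens <- function(z) exp(fam$loglik(z, list(mu = rep(mu, length(z)),
                                             sigma = rep(s, length(z)),
                                             nu = rep(nu, length(z)))))
  total <- nu + integrate(dens, 0, Inf, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-8)
  # nu = 1: all mass at zero
  expect_equal(exp(fam$loglik(0, list(mu = 1, sigma = 1, nu = 1))), 1)
  # sampling mean
  set.seed(8)
  draws <- fam$rng(1e6, list(mu = rep(mu, 1e6), sigma = rep(s, 1e6),
                             nu = rep(nu, 1e6)))
  expect_equal(mean(draws), (1 - nu) * mu, tolerance = 0.01)
  expect_error(fam$check_y(-1), class = "divgrad_support_error")
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(12)
  for (fn in c("nb", "truncnb", "zaga", "gaussian")) {
    fam <- family_by_name(fn)
    n <- 100
    eta <- matrix(rnorm(n * length(fam$params), 0, 0.6), n,
                  dimnames = list(NULL, fam$params))
    if (fn == "gaussian") eta[, "mu"] <- rnorm(n, 1, 2)
    pars <- divgrad:::eta_to_pars(fam, eta)
    y <- fam$rng(n, pars)
    if (fn == "truncnb") y <- pmax(y, 1L)
    if (fn == "zaga") y[1] <- 0   # make sure the point mass is exercised
    expect_lt(max(abs(family_gradients(fam, y, pars) - fd_gradient(fam, y, eta))),
              1e-6)
  }
})

test_that("the mean score vanishes at the intercept-only MLE", {
  set.seed(3)
  for (fn in c("nb", "zaga", "gaussian")) {
    fam <- family_by_name(fn)
    pars0 <- switch(fn,
      nb = list(mu = 4, sigma = 0.8),
      zaga = list(mu = 3, sigma = 0.7, nu = 0.25),
      gaussian = list(mu = 1, sigma = 2))
    n <- 2000
    y <- fam$rng(n, lapply(pars0, rep, n))
    eta_hat <- fit_intercept_mle(fam, y)
    em <- matrix(rep(eta_hat, each = n), n, dimnames = list(NULL, fam$params))
    sc <- colMeans(fam$grad(y, divgrad:::eta_to_pars(fam, em)))
    expect_lt(max(abs(sc)), 1e-6)
  }
})

test_that("shift handling is an exact inverse and rejects impossible values", {
  fam <- fam_zaga(shift = 1)
  expect_equal(shift_response(1, fam), 0)
  d <- c(1, 1.4, 3.7)
  expect_equal(unshift_prediction(shift_response(d, fam), fam), d)
  expect_error(shift_response(0.5, fam), class = "divgrad_domain_error")
  expect_equal(family_by_name("zaga(shift=1)")$shift, 1)
})
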