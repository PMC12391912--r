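#' Distributional response families for boosted regression
#'
#' Constructors for the response families used throughout the package. Each
#' family models up to three distribution parameters, each with its own link:
#' a location `mu` (log link for the count and gamma families), a scale
#' `sigma` (log link), and -- for the zero-adjusted gamma -- a zero
#' probability `nu` (logit link). Families carry analytic log-likelihoods and
#' analytic gradients of the log-likelihood with respect to each *linked*
#' predictor, which is what component-wise gradient boosting consumes.
#'
#' Parameterizations follow the GAMLSS convention:
#' * negative binomial: mean `mu`, dispersion `sigma`, variance
#'   `mu + sigma * mu^2`;
#' * zero-truncated negative binomial: the same law renormalized to `y >= 1`;
#' * zero-adjusted gamma: point mass `nu` at zero and, with probability
#'   `1 - nu`, a gamma with mean `mu` and squared coefficient of variation
#'   `sigma^2` (shape `1/sigma^2`, scale `mu * sigma^2`);
#' * gaussian: mean `mu` (identity link), standard deviation `sigma`
#'   (log link); used for calibration exercises and as a fast null family.
#'
#' Diversity responses are bounded below by one, so they are modelled by
#' subtracting one on the way in (`shift = 1`) and adding it back to
#' predictions; biomass uses `shift = 0`. See [shift_response()].
#'
#' @param shift nonnegative constant subtracted from the response before
#'   fitting a zero-adjusted gamma and added back to predictions.
#' @return an object of class `divgrad_family`: a list with elements
#'   `family`, `params`, `links`, `shift`, and functions `loglik`,
#'   `grad`, `mean`, `init`, `rng`, `check_y`.
#' @examples
#' fam <- fam_nb()
#' fam$loglik(0:3, list(mu = rep(2, 4), sigma = rep(1, 4)))
#' @name families
NULL

linkfun <- function(link) {
  switch(link,
    log = log,
    logit = stats::qlogis,
    identity = identity,
    divgrad_error(paste("unknown link", link), "divgrad_bad_link")
  )
}

linkinv <- function(link) {
  switch(link,
    log = exp,
    logit = stats::plogis,
    identity = identity,
    divgrad_error(paste("unknown link", link), "divgrad_bad_link")
  )
}

new_family <- function(x) structure(x, class = "divgrad_family")

#' @export
print.divgrad_family <- function(x, ...) {
  cat("<divgrad_family>", x$family, "\n  parameters:",
      paste(sprintf("%s(%s)", x$params, unname(x$links[x$params])),
            collapse = ", "),
      if (x$shift != 0) sprintf("\n  response shift: %g", x$shift) else "",
      "\n")
  invisible(x)
}

check_pars <- function(pars, params) {
  for (p in params) {
    v <- pars[[p]]
    if (is.null(v) || any(!is.finite(v))) {
      divgrad_error(sprintf("parameter '%s' missing or non-finite", p),
                    "divgrad_domain_error")
    }
  }
  invisible(TRUE)
}

#' @rdname families
#' @export
fam_gaussian <- function() {
  new_family(list(
    family = "gaussian",
    params = c("mu", "sigma"),
    links = c(mu = "identity", sigma = "log"),
    shift = 0,
    check_y = function(y) {
      if (any(!is.finite(y))) divgrad_error("non-finite response", "divgrad_support_error")
      invisible(TRUE)
    },
    loglik = function(y, pars) stats::dnorm(y, pars$mu, pars$sigma, log = TRUE),
    grad = function(y, pars) {
      mu <- pars$mu; s <- pars$sigma
      cbind(mu = (y - mu) / s^2,
            sigma = (y - mu)^2 / s^2 - 1)
    },
    mean = function(pars) pars$mu,
    init = function(y) c(mu = mean(y), sigma = log(max(stats::sd(y), 1e-8))),
    rng = function(n, pars) stats::rnorm(n, pars$mu, pars$sigma)
  ))
}

nb_check <- function(y) {
  if (!is_count_vector(y)) {
    divgrad_error("negative binomial response must be nonnegative integers",
                  "divgrad_support_error")
  }
  invisible(TRUE)
}

# d log NB / d mu and d / d sigma (response-scale), mean-dispersion form.
nb_dldm <- function(y, mu, sigma) y / mu - (1 + sigma * y) / (1 + sigma * mu)
nb_dlds <- function(y, mu, sigma) {
  a <- 1 / sigma
  (-digamma(y + a) + digamma(a) + log1p(sigma * mu)) / sigma^2 -
    mu / (sigma * (1 + sigma * mu)) + y / sigma - y * mu / (1 + sigma * mu)
}

#' @rdname families
#' @export
fam_nb <- function() {
  new_family(list(
    family = "nb",
    params = c("mu", "sigma"),
    links = c(mu = "log", sigma = "log"),
    shift = 0,
    check_y = nb_check,
    loglik = function(y, pars) {
      stats::dnbinom(y, size = 1 / pars$sigma, mu = pars$mu, log = TRUE)
    },
    grad = function(y, pars) {
      mu <- pars$mu; s <- pars$sigma
      cbind(mu = mu * nb_dldm(y, mu, s),
            sigma = s * nb_dlds(y, mu, s))
    },
    mean = function(pars) pars$mu,
    init = function(y) {
      m <- max(mean(y), 1e-3)
      v <- max(stats::var(y), m * 1.0001)
      c(mu = log(m), sigma = log(max((v - m) / m^2, 1e-4)))
    },
    rng = function(n, pars) stats::rnbinom(n, size = 1 / pars$sigma, mu = pars$mu)
  ))
}

#' @rdname families
#' @export
fam_truncnb <- function() {
  new_family(list(
    family = "truncnb",
    params = c("mu", "sigma"),
    links = c(mu = "log", sigma = "log"),
    shift = 0,
    check_y = function(y) {
      nb_check(y)
      if (any(y < 1)) {
        divgrad_error("zero-truncated response must be >= 1", "divgrad_support_error")
      }
      invisible(TRUE)
    },
    loglik = function(y, pars) {
      p0 <- stats::dnbinom(0, size = 1 / pars$sigma, mu = pars$mu)
      stats::dnbinom(y, size = 1 / pars$sigma, mu = pars$mu, log = TRUE) -
        log1p(-p0)
    },
    grad = function(y, pars) {
      mu <- pars$mu; s <- pars$sigma
      p0 <- stats::dnbinom(0, size = 1 / s, mu = mu)
      # derivatives of log p0 = -(1/sigma) log(1 + sigma mu)
      dlp0_dm <- -1 / (1 + s * mu)
      dlp0_ds <- log1p(s * mu) / s^2 - mu / (s * (1 + s * mu))
      corr_m <- p0 * dlp0_dm / (1 - p0)   # d log(1-p0)/dmu = -p0 dlp0/dmu /(1-p0)
      corr_s <- p0 * dlp0_ds / (1 - p0)
      cbind(mu = mu * (nb_dldm(y, mu, s) + corr_m),
            sigma = s * (nb_dlds(y, mu, s) + corr_s))
    },
    mean = function(pars) {
      p0 <- stats::dnbinom(0, size = 1 / pars$sigma, mu = pars$mu)
      pars$mu / (1 - p0)
    },
    init = function(y) {
      m <- max(mean(y) - 0.5, 0.5)
      c(mu = log(m), sigma = log(0.5))
    },
    rng = function(n, pars) {
      p0 <- stats::dnbinom(0, size = 1 / pars$sigma, mu = pars$mu)
      u <- stats::runif(n, p0, 1)
      stats::qnbinom(u, size = 1 / pars$sigma, mu = pars$mu)
    }
  ))
}

#' @rdname families
#' @export
fam_zaga <- function(shift = 0) {
  if (!is.numeric(shift) || length(shift) != 1 || shift < 0) {
    divgrad_error("shift must be a single nonnegative number", "divgrad_domain_error")
  }
  new_family(list(
    family = "zaga",
    params = c("mu", "sigma", "nu"),
    links = c(mu = "log", sigma = "log", nu = "logit"),
    shift = shift,
    check_y = function(y) {
      if (any(!is.finite(y)) || any(y < 0)) {
        divgrad_error("zero-adjusted gamma response must be >= 0",
                      "divgrad_support_error")
      }
      invisible(TRUE)
    },
    loglik = function(y, pars) {
      mu <- pars$mu; s <- pars$sigma; nu <- pars$nu
      t <- 1 / s^2
      out <- numeric(length(y))
      z <- y == 0
      out[z] <- log(nu[z])
      if (any(!z)) {
        out[!z] <- log1p(-nu[!z]) +
          suppressWarnings(stats::dgamma(y[!z], shape = t[!z],
                                         scale = (mu * s^2)[!z], log = TRUE))
      }
      # parameter overflow in a trial step is a rejected move, not a warning
      out[is.nan(out)] <- -Inf
      out
    },
    grad = function(y, pars) {
      mu <- pars$mu; s <- pars$sigma; nu <- pars$nu
      t <- 1 / s^2
      z <- y == 0
      gmu <- numeric(length(y))
      gsi <- numeric(length(y))
      yy <- pmax(y, 1e-300)
      dlds <- (-2 / s^3) * (log(yy / (s^2 * mu)) - digamma(t)) -
        2 * t / s + 2 * y / (s^3 * mu)
      gmu[!z] <- ((y - mu) / (s^2 * mu))[!z]     # already on the log-mu scale
      gsi[!z] <- (s * dlds)[!z]
      gnu <- (as.numeric(z) - nu)                # logit scale
      cbind(mu = gmu, sigma = gsi, nu = gnu)
    },
    mean = function(pars) (1 - pars$nu) * pars$mu,
    init = function(y) {
      pos <- y[y > 0]
      p0 <- clamp(mean(y == 0), 1e-4, 1 - 1e-4)
      m <- if (length(pos)) mean(pos) else 1
      cv <- if (length(pos) > 1) stats::sd(pos) / m else 0.5
      c(mu = log(max(m, 1e-6)), sigma = log(clamp(cv, 0.05, 5)),
        nu = stats::qlogis(p0))
    },
    rng = function(n, pars) {
      z <- stats::rbinom(n, 1, pars$nu)
      g <- stats::rgamma(n, shape = 1 / pars$sigma^2, scale = pars$mu * pars$sigma^2)
      ifelse(z == 1, 0, g)
    }
  ))
}

#' Pick a family by config name
#'
#' Accepts `"nb"`, `"truncnb"`, `"gaussian"`, `"zaga"`, or `"zaga(shift=1)"`.
#'
#' @param name family name, optionally with a shift argument.
#' @return a [families] object.
#' @export
family_by_name <- function(name) {
  m <- regmatches(name, regexec("^zaga\\(shift=([0-9.]+)\\)$", name))[[1]]
  if (length(m) == 2) return(fam_zaga(shift = as.numeric(m[2])))
  switch(name,
    nb = fam_nb(),
    truncnb = fam_truncnb(),
    zaga = fam_zaga(),
    gaussian = fam_gaussian(),
    divgrad_error(paste("unknown family:", name), "divgrad_bad_family")
  )
}

#' Shift a response onto the model scale and back
#'
#' Diversity values of order one and above are bounded below by one; the
#' zero-adjusted gamma handles them after subtracting one (the point mass at
#' zero then absorbs blocks with a single effective species). Predictions are
#' shifted back by the same constant, so the composition is the identity.
#'
#' @param y response values (diversity or biomass).
#' @param family a [families] object carrying the shift constant.
#' @return shifted values.
#' @export
shift_response <- function(y, family) {
  s <- family$shift
  if (any(y < s - 1e-12, na.rm = TRUE)) {
    divgrad_error(sprintf("response below the shift constant %g", s),
                  "divgrad_domain_error")
  }
  pmax(y - s, 0)
}

#' @rdname shift_response
#' @param pred predictions on the shifted scale.
#' @export
unshift_prediction <- function(pred, family) pred + family$shift

#' Gradients of the log-likelihood on the link scale
#'
#' Returns the per-observation derivative of the log-likelihood with respect
#' to each linked predictor, the working response of component-wise boosting.
#'
#' @param family a [families] object.
#' @param y response vector (on the model scale, i.e. after any shift).
#' @param pars named list of parameter vectors on the response scale.
#' @return numeric matrix, one column per distribution parameter.
#' @export
family_gradients <- function(family, y, pars) {
  family$check_y(y)
  check_pars(pars, family$params)
  family$grad(y, pars)
}

# Transform a matrix of linked predictors to response-scale parameters.
eta_to_pars <- function(family, eta) {
  pars <- list()
  for (p in family$params) {
    pars[[p]] <- linkinv(family$links[[p]])(eta[, p])
  }
  pars
}

#' Intercept-only maximum likelihood fit
#'
#' Fits the family's parameters to an i.i.d. sample by maximizing the
#' log-likelihood over the linked intercepts. Used for boosting offsets and
#' for parameter-recovery checks.
#'
#' @inheritParams family_gradients
#' @param se if `TRUE`, also return standard errors from the numerically
#'   differentiated Hessian of the linked intercepts.
#' @return named vector of linked intercepts (attribute `"se"` if requested).
#' @export
fit_intercept_mle <- function(family, y, se = FALSE) {
  family$check_y(y)
  start <- family$init(y)
  n <- length(y)
  np <- length(family$params)
  negll <- function(eta) {
    em <- matrix(rep(eta, each = n), nrow = n,
                 dimnames = list(NULL, family$params))
    pars <- eta_to_pars(family, em)
    -sum(family$loglik(y, pars))
  }
  gr <- function(eta) {
    em <- matrix(rep(eta, each = n), nrow = n,
                 dimnames = list(NULL, family$params))
    pars <- eta_to_pars(family, em)
    -colSums(family$grad(y, pars))
  }
  fit <- stats::optim(start, negll, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  out <- fit$par
  names(out) <- family$params
  if (se) {
    h <- stats::optimHess(fit$par, negll, gr)
    attr(out, "se") <- sqrt(diag(solve(h)))
  }
  out
}
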