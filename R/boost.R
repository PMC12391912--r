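#' Base learner specifications
#'
#' Builds the candidate set for component-wise boosting: one P-spline learner
#' per metric predictor (20 interior knots, cubic basis, second-order
#' difference penalty, penalized to `df` effective degrees of freedom) and
#' one linear learner per binary predictor, optionally replicated per group
#' cell (variable coefficients, e.g. land use x census year), plus a global
#' intercept learner. Grouped learners apply only to rows of their cell.
#' Predictors constant within a cell are dropped with a warning.
#'
#' @param data training data frame.
#' @param predictors character vector of predictor columns.
#' @param grouping character vector of grouping columns (or `NULL`).
#' @param types optional named character vector forcing `"linear"` or
#'   `"pspline"` per predictor (default: splines for metric predictors,
#'   linear for binary ones).
#' @param df effective degrees of freedom per spline learner.
#' @param knots number of interior knots.
#' @param degree spline degree.
#' @param diff_order difference-penalty order.
#' @return list of learner specifications (class `base_learners`).
#' @export
base_learners <- function(data, predictors, grouping = NULL, types = NULL,
                          df = 4, knots = 20, degree = 3, diff_order = 2) {
  cells <- list(NULL)
  if (!is.null(grouping) && length(grouping)) {
    check_columns(data, grouping, "base_learners")
    key <- interaction(data[grouping], drop = TRUE, lex.order = TRUE)
    cells <- lapply(levels(key), function(lv) {
      row1 <- which(key == lv)[1]
      vapply(grouping, function(g) as.character(data[[g]][row1]), character(1))
    })
  }
  specs <- list(list(name = "(intercept)", predictor = NA_character_,
                     type = "intercept", cell = NULL, df = 1))
  for (pr in predictors) {
    v <- data[[pr]]
    if (is.null(v)) {
      divgrad_error(paste("predictor not in data:", pr), "divgrad_schema_error")
    }
    forced <- if (!is.null(types)) {
      if (is.null(names(types))) types[[1]] else unname(types[pr])
    } else NA_character_
    type <- if (!is.na(forced)) {
      match.arg(forced, c("linear", "pspline"))
    } else if (is.numeric(v) && length(unique(v[!is.na(v)])) > 6) {
      "pspline"
    } else {
      "linear"
    }
    for (cell in cells) {
      rows <- cell_rows(data, cell)
      vv <- v[rows]
      if (length(unique(vv[!is.na(vv)])) < 2) {
        warning(sprintf("dropping constant predictor '%s'%s", pr,
                        if (is.null(cell)) "" else paste0(" in cell ", cell_label(cell))))
        next
      }
      specs[[length(specs) + 1]] <- list(
        name = paste0(pr, if (is.null(cell)) "" else paste0("[", cell_label(cell), "]")),
        predictor = pr, type = type, cell = cell,
        df = df, knots = knots, degree = degree, diff_order = diff_order)
    }
  }
  structure(specs, class = "base_learners",
            grouping = grouping %||% character())
}

cell_label <- function(cell) paste(cell, collapse = ".")

cell_rows <- function(data, cell) {
  if (is.null(cell)) return(seq_len(nrow(data)))
  ok <- rep(TRUE, nrow(data))
  for (g in names(cell)) ok <- ok & as.character(data[[g]]) == cell[[g]]
  which(ok)
}

# P-spline machinery ---------------------------------------------------------

pspline_knots <- function(x, n_interior, degree) {
  r <- range(x)
  if (diff(r) <= 0) r <- r + c(-0.5, 0.5)
  inner <- seq(r[1], r[2], length.out = n_interior + 2)
  h <- inner[2] - inner[1]
  c(r[1] - (degree:1) * h, inner, r[2] + (1:degree) * h)
}

pspline_basis <- function(x, knots, degree) {
  lo <- knots[degree + 1]; hi <- knots[length(knots) - degree]
  splines::splineDesign(knots, clamp(x, lo, hi), ord = degree + 1)
}

# lambda such that the penalized smoother has the requested trace (df)
pspline_lambda <- function(BtB, P, df) {
  k <- nrow(BtB)
  ridge <- diag(1e-8 * (mean(diag(BtB)) + 1), k)
  trace_df <- function(loglam) {
    M <- BtB + 10^loglam * P + ridge
    sum(diag(solve(M, BtB)))
  }
  lo <- -8; hi <- 12
  if (trace_df(lo) <= df) return(10^lo)
  if (trace_df(hi) >= df) return(10^hi)
  10^stats::uniroot(function(l) trace_df(l) - df, c(lo, hi), tol = 1e-4)$root
}

build_learner <- function(spec, data) {
  rows <- cell_rows(data, spec$cell)
  if (spec$type == "intercept") {
    B <- matrix(1, length(rows), 1)
    P <- matrix(length(rows), 1, 1)   # 1/m * t(B): mean of the gradient
    return(c(spec, list(rows = rows, B = B,
                        proj = matrix(1 / length(rows), 1, length(rows)))))
  }
  x <- data[[spec$predictor]][rows]
  if (anyNA(x)) {
    divgrad_error(sprintf("predictor '%s' has missing values; impute first",
                          spec$predictor), "divgrad_schema_error")
  }
  if (spec$type == "linear") {
    B <- cbind(1, x)
    XtX <- crossprod(B)
    proj <- solve(XtX + diag(1e-10 * (diag(XtX) + 1))) %*% t(B)
    return(c(spec, list(rows = rows, B = B, proj = proj)))
  }
  kn <- pspline_knots(x, spec$knots, spec$degree)
  B <- pspline_basis(x, kn, spec$degree)
  D <- diff(diag(ncol(B)), differences = spec$diff_order)
  P <- crossprod(D)
  BtB <- crossprod(B)
  lam <- pspline_lambda(BtB, P, spec$df)
  ridge <- diag(1e-8 * (mean(diag(BtB)) + 1), ncol(B))
  proj <- solve(BtB + lam * P + ridge) %*% t(B)
  c(spec, list(rows = rows, B = B, proj = proj, knot_vec = kn))
}

learner_design <- function(L, newdata) {
  rows <- cell_rows(newdata, L$cell)
  if (!length(rows)) return(list(rows = rows, B = NULL))
  B <- switch(L$type,
    intercept = matrix(1, length(rows), 1),
    linear = cbind(1, newdata[[L$predictor]][rows]),
    pspline = pspline_basis(newdata[[L$predictor]][rows], L$knot_vec, L$degree))
  list(rows = rows, B = B)
}

default_param_learners <- function(family, n_learners) {
  pl <- list()
  for (p in family$params) {
    pl[[p]] <- if (p == "sigma") 1L else seq_len(n_learners)
  }
  pl
}

#' Component-wise gradient boosting for distributional regression
#'
#' Fits additive predictors for every distribution parameter of `family` by
#' non-cyclical component-wise functional gradient descent: in each
#' iteration, the gradient of the log-likelihood with respect to each linked
#' predictor is computed for every observation, every candidate base learner
#' is fit to its parameter's gradient by (penalized) least squares, and the
#' single (parameter, learner) pair whose tentative update most reduces the
#' empirical risk (the negative log-likelihood) is updated by `step` times
#' its fit. Offsets are the unconditional maximum-likelihood intercepts. Ties
#' in risk reduction go to the lowest learner index. If no update can lower
#' the risk even after step halving, the iteration records a null update, so
#' the training risk is nonincreasing by construction.
#'
#' @param y response vector (already on the model scale; see
#'   [shift_response()]).
#' @param data data frame of predictors.
#' @param family a [families] object.
#' @param learners a [base_learners()] specification.
#' @param n_iter number of boosting iterations.
#' @param step learning rate in (0, 1].
#' @param param_learners named list mapping each distribution parameter to
#'   the learner indices it may use; by default the scale parameter gets the
#'   intercept learner only (it is a nuisance parameter) and all other
#'   parameters get every learner.
#' @param stop_distinct optional early stop: halt once this many distinct
#'   non-intercept learners have been selected (used by stability selection).
#' @return a `boost_model`.
#' @export
boost_fit <- function(y, data, family, learners, n_iter = 100, step = 0.1,
                      param_learners = NULL, stop_distinct = NULL) {
  if (n_iter < 0) divgrad_error("n_iter must be >= 0", "divgrad_invalid_parameter")
  if (step <= 0 || step > 1) {
    divgrad_error("step must lie in (0, 1]", "divgrad_invalid_parameter")
  }
  family$check_y(y)
  n <- length(y)
  if (nrow(data) != n) {
    divgrad_error("data and response lengths differ", "divgrad_schema_error")
  }
  built <- lapply(learners, build_learner, data = data)
  np <- length(family$params)
  param_learners <- param_learners %||% default_param_learners(family, length(built))
  offset <- fit_intercept_mle(family, y)
  eta <- matrix(rep(offset, each = n), n, np,
                dimnames = list(NULL, family$params))
  coef <- lapply(family$params, function(p) vector("list", length(built)))
  names(coef) <- family$params
  risk0 <- -sum(family$loglik(y, eta_to_pars(family, eta)))
  if (!is.finite(risk0)) {
    divgrad_error("non-finite risk at the offset model", "divgrad_numeric_error")
  }
  path_param <- character(n_iter)
  path_learner <- rep(NA_integer_, n_iter)
  path_risk_v <- numeric(n_iter)
  increments <- vector("list", n_iter)
  risk <- risk0
  selected_set <- integer(0)
  it_done <- 0L
  for (it in seq_len(n_iter)) {
    pars <- eta_to_pars(family, eta)
    U <- family$grad(y, pars)
    cand <- NULL
    for (p in family$params) {
      u <- U[, p]
      best_red <- 1e-10; best <- NULL
      for (li in param_learners[[p]]) {
        L <- built[[li]]
        useg <- u[L$rows]
        cf <- as.vector(L$proj %*% useg)
        fit <- as.vector(L$B %*% cf)
        red <- sum(fit * (2 * useg - fit))
        if (red > best_red * (1 + 1e-9)) {
          best_red <- red
          best <- list(li = li, cf = cf, fit = fit)
        }
      }
      if (is.null(best)) next
      etry <- eta
      etry[built[[best$li]]$rows, p] <- etry[built[[best$li]]$rows, p] + step * best$fit
      rtry <- -sum(family$loglik(y, eta_to_pars(family, etry)))
      if (!is.finite(rtry)) next
      if (is.null(cand) || rtry < cand$risk - 1e-12) {
        cand <- list(param = p, li = best$li, cf = best$cf, fit = best$fit,
                     risk = rtry, step = step)
      }
    }
    # step halving if the best tentative update fails to reduce the risk
    if (!is.null(cand) && cand$risk > risk) {
      s <- step; fit <- cand$fit; cf <- cand$cf
      L <- built[[cand$li]]
      ok <- FALSE
      for (h in 1:30) {
        s <- s / 2
        etry <- eta
        etry[L$rows, cand$param] <- etry[L$rows, cand$param] + s * fit
        rtry <- -sum(family$loglik(y, eta_to_pars(family, etry)))
        if (is.finite(rtry) && rtry <= risk) {
          cand$risk <- rtry; cand$step <- s; ok <- TRUE; break
        }
      }
      if (!ok) cand <- NULL
    }
    if (is.null(cand)) {
      path_param[it] <- NA_character_
      path_risk_v[it] <- risk
      increments[it] <- list(NULL)
      it_done <- it
      next
    }
    L <- built[[cand$li]]
    delta <- cand$step * cand$cf
    eta[L$rows, cand$param] <- eta[L$rows, cand$param] + cand$step * cand$fit
    old <- coef[[cand$param]][[cand$li]]
    coef[[cand$param]][[cand$li]] <- if (is.null(old)) delta else old + delta
    risk <- cand$risk
    path_param[it] <- cand$param
    path_learner[it] <- cand$li
    path_risk_v[it] <- risk
    increments[[it]] <- list(param = cand$param, learner = cand$li, delta = delta)
    if (built[[cand$li]]$type != "intercept") {
      selected_set <- union(selected_set, cand$li)
    }
    it_done <- it
    if (!is.null(stop_distinct) && length(selected_set) >= stop_distinct) break
  }
  keep <- seq_len(it_done)
  path <- data.frame(iter = keep, param = path_param[keep],
                     learner = path_learner[keep], risk = path_risk_v[keep],
                     stringsAsFactors = FALSE)
  structure(list(
    family = family, learners = built, param_learners = param_learners,
    offset = offset, coef = coef, path = path,
    increments = increments[keep],
    risk0 = risk0, step = step, n_iter = it_done,
    selected = selected_set,
    learner_names = vapply(built, `[[`, character(1), "name")
  ), class = "boost_model")
}

#' @export
print.boost_model <- function(x, ...) {
  sel <- x$learner_names[x$selected]
  cat(sprintf("<boost_model> %s family, %d iterations, final risk %.4f\n",
              x$family$family, x$n_iter, utils::tail(c(x$risk0, x$path$risk), 1)))
  cat("  selected learners:", if (length(sel)) paste(sel, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Predict from a boosted distributional model
#'
#' Applies the accumulated base-learner coefficients (plus offsets) to new
#' data and inverts the links. The overall response-scale mean adds back any
#' response shift: for the zero-adjusted gamma it is
#' `(1 - nu) * mu + shift`.
#'
#' @param object a `boost_model`.
#' @param newdata data frame with every predictor the selected learners use.
#' @param ... unused.
#' @return list with `eta` (linked predictors), `pars` (response-scale
#'   parameters) and `mean` (response-scale prediction including the shift).
#' @export
predict.boost_model <- function(object, newdata, ...) {
  fam <- object$family
  n <- nrow(newdata)
  eta <- matrix(rep(object$offset, each = n), n, length(fam$params),
                dimnames = list(NULL, fam$params))
  for (p in fam$params) {
    for (li in seq_along(object$learners)) {
      cf <- object$coef[[p]][[li]]
      if (is.null(cf)) next
      L <- object$learners[[li]]
      if (!is.null(L$predictor) && !is.na(L$predictor) &&
          is.null(newdata[[L$predictor]])) {
        divgrad_error(paste("newdata lacks predictor", L$predictor),
                      "divgrad_schema_error")
      }
      des <- learner_design(L, newdata)
      if (length(des$rows)) {
        eta[des$rows, p] <- eta[des$rows, p] + as.vector(des$B %*% cf)
      }
    }
  }
  pars <- eta_to_pars(fam, eta)
  list(eta = eta, pars = pars,
       mean = unshift_prediction(fam$mean(pars), fam))
}

#' Risk curve of a boosting path on (new) data
#'
#' Replays the selection path iteration by iteration and evaluates the
#' negative log-likelihood on the supplied data after each update; index 1
#' is the offset-only model. This is the out-of-sample risk used for early
#' stopping.
#'
#' @param object a `boost_model`.
#' @param newdata data frame of predictors.
#' @param y response on the model scale.
#' @return numeric vector of length `n_iter + 1`.
#' @export
path_risk <- function(object, newdata, y) {
  fam <- object$family
  n <- nrow(newdata)
  eta <- matrix(rep(object$offset, each = n), n, length(fam$params),
                dimnames = list(NULL, fam$params))
  designs <- vector("list", length(object$learners))
  out <- numeric(length(object$increments) + 1)
  out[1] <- -sum(fam$loglik(y, eta_to_pars(fam, eta)))
  for (it in seq_along(object$increments)) {
    inc <- object$increments[[it]]
    if (!is.null(inc)) {
      li <- inc$learner
      if (is.null(designs[[li]])) {
        designs[[li]] <- learner_design(object$learners[[li]], newdata)
      }
      d <- designs[[li]]
      if (length(d$rows)) {
        eta[d$rows, inc$param] <- eta[d$rows, inc$param] + as.vector(d$B %*% inc$delta)
      }
    }
    out[it + 1] <- -sum(fam$loglik(y, eta_to_pars(fam, eta)))
  }
  out
}

#' Cross-validated early stopping
#'
#' Repeatedly splits the data into training and held-out parts (stratified
#' subsampling), fits the boosting path on the training part and records the
#' held-out negative log-likelihood after every iteration. The optimal
#' stopping iteration `mstop` is the minimizer of the mean out-of-sample
#' risk curve (iteration 0, the offset model, is a legal answer). Resamples
#' that lose an entire learner cell are redrawn.
#'
#' @inheritParams boost_fit
#' @param max_iter maximal number of boosting iterations.
#' @param n_resamples number of random subsamples.
#' @param train_frac fraction of rows used for training in each resample.
#' @param strata character vector of columns to stratify the subsampling on
#'   (typically the grouping factors).
#' @param seed integer seed controlling all resampling.
#' @return list of class `cv_result`: `risk` (resample x iteration matrix),
#'   `mstop`, `mean_risk`, `scheme`, `seed`.
#' @export
cv_tune <- function(y, data, family, learners, max_iter = 200, step = 0.1,
                    n_resamples = 25, train_frac = 0.8, strata = NULL,
                    param_learners = NULL, seed = 1) {
  if (max_iter < 1) divgrad_error("max_iter must be >= 1", "divgrad_invalid_parameter")
  n <- length(y)
  cells <- Filter(Negate(is.null), lapply(learners, `[[`, "cell"))
  with_seed(seed, {
    risk <- matrix(NA_real_, n_resamples, max_iter + 1)
    for (r in seq_len(n_resamples)) {
      for (attempt in 1:100) {
        tr <- stratified_sample(data, strata, train_frac)
        ok <- all(vapply(cells, function(cell) {
          length(cell_rows(data[tr, , drop = FALSE], cell)) >= 5
        }, logical(1)))
        if (ok) break
        if (attempt == 100) {
          divgrad_error("could not draw a resample covering every cell",
                        "divgrad_resample_error")
        }
      }
      fit <- boost_fit(y[tr], data[tr, , drop = FALSE], family, learners,
                       n_iter = max_iter, step = step,
                       param_learners = param_learners)
      rc <- path_risk(fit, data[-tr, , drop = FALSE], y[-tr])
      risk[r, seq_along(rc)] <- rc
    }
    mean_risk <- colMeans(risk)
    structure(list(risk = risk, mean_risk = mean_risk,
                   mstop = which.min(mean_risk) - 1L,
                   scheme = sprintf("%d subsamples, %.0f/%.0f split%s",
                                    n_resamples, 100 * train_frac,
                                    100 * (1 - train_frac),
                                    if (length(strata)) paste0(", stratified by ",
                                                               paste(strata, collapse = " x "))
                                    else ""),
                   seed = seed),
              class = "cv_result")
  })
}

stratified_sample <- function(data, strata, frac) {
  n <- nrow(data)
  if (is.null(strata) || !length(strata)) {
    return(sort(sample.int(n, max(2, round(frac * n)))))
  }
  key <- interaction(data[strata], drop = TRUE)
  idx <- unlist(lapply(split(seq_len(n), key), function(ii) {
    if (length(ii) == 1) return(ii)
    sample(ii, max(1, round(frac * length(ii))))
  }), use.names = FALSE)
  sort(idx)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s; mstop = %d (mean held-out risk %.4f)\n",
              x$scheme, x$mstop, x$mean_risk[x$mstop + 1]))
  invisible(x)
}
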