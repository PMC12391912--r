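#' Stability selection for boosted distributional models
#'
#' Complementary-pairs subsampling: the rows are repeatedly split into two
#' disjoint halves and the boosting algorithm is run on each half until
#' `q_sel` distinct (non-intercept) base learners have been selected. A
#' learner's selection frequency is the fraction of subsamples in which it
#' entered the model for a given distribution parameter; learners reaching
#' the threshold `pi_thr` on the location (`mu`) or zero-part (`nu`)
#' parameter form the stable set. The scale parameter's frequencies are
#' recorded but never confer stability (it is a nuisance parameter). The
#' analytic bound on the expected number of falsely stable learners,
#' `PFER <= q_sel^2 / ((2 pi_thr - 1) p)`, is reported alongside.
#'
#' @inheritParams boost_fit
#' @param B number of subsamples (even; `B/2` complementary pairs).
#' @param q_sel per-subsample budget of distinct selected learners.
#' @param pi_thr selection-frequency threshold in (0.5, 1].
#' @param max_iter iteration cap per subsample; subsamples that never reach
#'   `q_sel` are flagged and removed from the frequency denominators with a
#'   warning.
#' @param seed integer seed.
#' @return list of class `stability_result`: `freq` (learner x parameter
#'   matrix), `stable` (learner names), `B`, `q_sel`, `pi_thr`, `PFER`,
#'   `n_learners`, `flagged`.
#' @export
stabsel_boost <- function(y, data, family, learners, B = 50, q_sel = 6,
                          pi_thr = 0.7, max_iter = 500, step = 0.1,
                          param_learners = NULL, seed = 1) {
  if (B < 2 || B %% 2 != 0) {
    divgrad_error("B must be an even number >= 2", "divgrad_invalid_parameter")
  }
  if (pi_thr <= 0.5 || pi_thr > 1) {
    divgrad_error("pi_thr must lie in (0.5, 1]", "divgrad_invalid_parameter")
  }
  cand_names <- vapply(learners, `[[`, character(1), "name")
  covariate_idx <- which(cand_names != "(intercept)")
  p <- length(covariate_idx)
  if (q_sel < 1 || q_sel >= max(p, 2)) {
    divgrad_error("q_sel must satisfy 1 <= q_sel < number of learners",
                  "divgrad_invalid_parameter")
  }
  fam_params <- family$params
  track <- intersect(c("mu", "nu"), fam_params)
  n <- length(y)
  with_seed(seed, {
    counts <- matrix(0, length(cand_names), length(fam_params),
                     dimnames = list(cand_names, fam_params))
    used <- 0L
    flagged <- 0L
    for (pair in seq_len(B / 2)) {
      perm <- sample.int(n)
      half <- floor(n / 2)
      halves <- list(perm[seq_len(half)], perm[half + seq_len(half)])
      for (hs in halves) {
        hs <- sort(hs)
        fit <- boost_fit(y[hs], data[hs, , drop = FALSE], family, learners,
                         n_iter = max_iter, step = step,
                         param_learners = param_learners,
                         stop_distinct = q_sel)
        reached <- length(fit$selected) >= q_sel
        if (!reached) {
          flagged <- flagged + 1L
          next
        }
        used <- used + 1L
        sel <- unique(fit$path[!is.na(fit$path$learner),
                               c("learner", "param")])
        for (k in seq_len(nrow(sel))) {
          counts[sel$learner[k], sel$param[k]] <-
            counts[sel$learner[k], sel$param[k]] + 1
        }
      }
    }
    if (flagged > 0) {
      warning(sprintf("%d of %d subsamples never reached q_sel = %d; %s",
                      flagged, B, q_sel,
                      "frequencies use the remaining subsamples"))
    }
    if (used == 0) {
      divgrad_error("no subsample reached the selection budget", "divgrad_resample_error")
    }
    freq <- counts / used
    freq <- freq[covariate_idx, , drop = FALSE]
    stable <- rownames(freq)[apply(freq[, track, drop = FALSE], 1, max) >= pi_thr]
    structure(list(freq = freq, stable = stable, B = B, q_sel = q_sel,
                   pi_thr = pi_thr,
                   PFER = q_sel^2 / ((2 * pi_thr - 1) * p),
                   n_learners = p, flagged = flagged, seed = seed),
              class = "stability_result")
  })
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> B = %d, q = %d, threshold %.2f, PFER <= %.3f\n",
              x$B, x$q_sel, x$pi_thr, x$PFER))
  cat("  stable:", if (length(x$stable)) paste(x$stable, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Cross-tabulate stable predictors across analyses
#'
#' Combines stability results from several responses, land uses or census
#' years into one long table of selection frequencies, marking predictors
#' that reach the threshold on the location or zero-part parameter
#' (scale-parameter frequencies are reported for context but never make a
#' predictor consistent).
#'
#' @param results named list of `stability_result` objects (names label the
#'   analysis, e.g. response x land use x year).
#' @return data frame with one row per (analysis, learner): frequencies per
#'   parameter and a logical `consistent`.
#' @export
consistency_report <- function(results) {
  if (!length(results)) {
    divgrad_error("need at least one stability result", "divgrad_invalid_parameter")
  }
  if (is.null(names(results))) names(results) <- paste0("analysis", seq_along(results))
  rows <- lapply(names(results), function(nm) {
    x <- results[[nm]]
    f <- x$freq
    track <- intersect(c("mu", "nu"), colnames(f))
    data.frame(analysis = nm, learner = rownames(f),
               freq_mu = if ("mu" %in% colnames(f)) f[, "mu"] else NA_real_,
               freq_sigma = if ("sigma" %in% colnames(f)) f[, "sigma"] else NA_real_,
               freq_nu = if ("nu" %in% colnames(f)) f[, "nu"] else NA_real_,
               consistent = apply(f[, track, drop = FALSE], 1, max) >= x$pi_thr,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
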