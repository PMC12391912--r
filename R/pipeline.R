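PIPELINE_STAGES <- c("simulate", "impute", "aggregate", "metrics", "fit",
                     "stabsel", "gradient")

#' Response definitions for the regression stage
#'
#' Maps a response name to its metric column, distribution family and row
#' subset: raw species richness (zeros included) uses the negative binomial;
#' bias-adjusted richness, defined only for blocks with ungulates, uses the
#' zero-truncated negative binomial; Shannon, Simpson and order-10 diversity
#' are bounded below by one and use the shifted zero-adjusted gamma; biomass
#' responses use the zero-adjusted gamma without shift.
#'
#' @param name one of `richness`, `adj_richness`, `shannon`, `simpson`,
#'   `evenness`, `biomass_total`, `biomass_migratory`,
#'   `biomass_nonmigratory`.
#' @return list with `column`, `family`, `drop_na`.
#' @export
response_spec <- function(name) {
  switch(name,
    richness = list(column = "S_raw", family = fam_nb(), drop_na = FALSE),
    adj_richness = list(column = "D0", family = fam_truncnb(), drop_na = TRUE,
                        round = TRUE),
    shannon = list(column = "D1", family = fam_zaga(shift = 1), drop_na = TRUE),
    simpson = list(column = "D2", family = fam_zaga(shift = 1), drop_na = TRUE),
    evenness = list(column = "D10", family = fam_zaga(shift = 1), drop_na = TRUE),
    biomass_total = list(column = "biomass_total", family = fam_zaga(),
                         drop_na = FALSE),
    biomass_migratory = list(column = "biomass_migratory", family = fam_zaga(),
                             drop_na = FALSE),
    biomass_nonmigratory = list(column = "biomass_nonmigratory",
                                family = fam_zaga(), drop_na = FALSE),
    divgrad_error(paste("unknown response:", name), "divgrad_configuration_error")
  )
}

# Assemble (y, data) for one response from the metrics table.
response_data <- function(metrics, response, predictors) {
  spec <- response_spec(response)
  y <- metrics[[spec$column]]
  keep <- if (spec$drop_na) which(!is.na(y)) else seq_len(nrow(metrics))
  y <- y[keep]
  if (isTRUE(spec$round)) y <- as.integer(round_half_up(y))
  y <- shift_response(y, spec$family)
  if (spec$family$family %in% c("nb", "truncnb")) y <- as.integer(round_half_up(y))
  list(y = y, data = metrics[keep, , drop = FALSE], family = spec$family,
       spec = spec)
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = tempfile("divgrad_run_"),
    stages = PIPELINE_STAGES,
    scenario = list(),
    impute = list(covariates = NULL, max_neighbors = 32),
    fit = list(responses = c("shannon", "biomass_total"),
               predictors = NULL, grouping = "year",
               max_iter = 200L, step = 0.1,
               cv = list(n_resamples = 10L, train_frac = 0.8)),
    stabsel = list(response = "biomass_total", B = 20L, q_sel = 4L,
                   pi_thr = 0.7, max_iter = 300L),
    gradient = list(by = 0.5)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && !is.data.frame(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the census-to-gradient pipeline
#'
#' Chains the analysis stages -- simulate, impute, aggregate, metrics
#' (diversity and biomass), fit (boosted distributional regression with
#' cross-validated early stopping), stabsel (stability selection) and
#' gradient (distance-to-boundary prediction curves) -- writing each stage's
#' output CSV and a machine-readable JSON manifest to `out_dir`. A single
#' global seed deterministically derives per-stage seeds, so identical
#' configurations reproduce identical artifacts.
#'
#' @param config a (possibly partial) configuration list, or the path of a
#'   YAML file holding one. Defaults are used for everything unspecified;
#'   `stages` must be an in-order subset of the canonical stage list and
#'   every stage must be able to find its input (e.g. `fit` needs
#'   `metrics`).
#' @return invisibly, a list with the stage products (`grid`, `blocks`,
#'   `metrics`, `models`, `cv`, `stability`, `curves`) and the `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  stages <- cfg$stages
  pos <- match(stages, PIPELINE_STAGES)
  if (anyNA(pos) || any(diff(pos) <= 0)) {
    divgrad_error("stages must be an in-order subset of: simulate, impute, aggregate, metrics, fit, stabsel, gradient",
                  "divgrad_configuration_error")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed0 <- as.integer(cfg$seed)
  stage_seed <- function(stage) (seed0 * 131L + match(stage, PIPELINE_STAGES) * 7919L) %% 2147483629L

  state <- list()
  manifest <- list(package = "divgrad",
                   version = as.character(utils::packageVersion("divgrad")),
                   seed = seed0, stages = list())
  note <- function(stage, rows, outputs, elapsed) {
    manifest$stages[[length(manifest$stages) + 1]] <<-
      list(stage = stage, rows = rows, outputs = outputs,
           elapsed_s = round(elapsed, 3))
  }
  need <- function(what, stage) {
    if (is.null(state[[what]])) {
      divgrad_error(sprintf("stage '%s' needs '%s' from an earlier stage",
                            stage, what), "divgrad_configuration_error")
    }
    state[[what]]
  }

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    outs <- character()
    rows <- NA_integer_
    switch(stage,
      simulate = {
        sc <- do.call(scenario_config,
                      merge_config(cfg$scenario, list(seed = stage_seed("simulate"))))
        state$config <- sc
        state$grid <- simulate_landscape(sc)
        f <- file.path(cfg$out_dir, "grid.csv")
        write_subblock_csv(state$grid, f)
        ft <- file.path(cfg$out_dir, "truth.csv")
        write_csv_plain(write_truth(sc, state$grid), ft)
        rows <- nrow(state$grid); outs <- c(f, ft)
      },
      impute = {
        g <- need("grid", "impute")
        bounds <- list()
        if (!is.null(state$config)) {
          defs <- state$config$covariates
          bounds <- stats::setNames(lapply(seq_len(nrow(defs)), function(i)
            c(defs$lower[i], defs$upper[i])), defs$name)
        }
        state$grid <- impute_covariates(g, covariates = cfg$impute$covariates,
                                        bounds = bounds,
                                        max_neighbors = cfg$impute$max_neighbors)
        f <- file.path(cfg$out_dir, "grid_imputed.csv")
        write_csv_plain(as.data.frame(state$grid), f)
        rows <- nrow(state$grid); outs <- f
      },
      aggregate = {
        g <- need("grid", "aggregate")
        state$blocks <- aggregate_blocks(g)
        f <- file.path(cfg$out_dir, "blocks.csv")
        write_block_csv(as.data.frame(state$blocks), f)
        attr(state$blocks, "colmap") <- attr(g, "colmap")
        rows <- nrow(state$blocks); outs <- f
      },
      metrics = {
        b <- need("blocks", "metrics")
        state$metrics <- community_summary(b)
        f <- file.path(cfg$out_dir, "metrics.csv")
        write_block_csv(as.data.frame(state$metrics), f)
        rows <- nrow(state$metrics); outs <- f
      },
      fit = {
        m <- need("metrics", "fit")
        cm <- attr(m, "colmap")
        predictors <- cfg$fit$predictors %||% c("dist_boundary_km", cm$covariates, cm$flags)
        predictors <- predictors[vapply(predictors, function(pr)
          !is.null(m[[pr]]) && !anyNA(m[[pr]]), logical(1))]
        state$models <- list(); state$cv <- list()
        for (resp in cfg$fit$responses) {
          rd <- response_data(m, resp, predictors)
          ln <- base_learners(rd$data, predictors, grouping = cfg$fit$grouping)
          cv <- cv_tune(rd$y, rd$data, rd$family, ln,
                        max_iter = cfg$fit$max_iter, step = cfg$fit$step,
                        n_resamples = cfg$fit$cv$n_resamples,
                        train_frac = cfg$fit$cv$train_frac,
                        strata = cfg$fit$grouping,
                        seed = stage_seed("fit"))
          fit <- boost_fit(rd$y, rd$data, rd$family, ln,
                           n_iter = max(cv$mstop, 1L), step = cfg$fit$step)
          state$models[[resp]] <- fit
          state$cv[[resp]] <- cv
          f1 <- file.path(cfg$out_dir, sprintf("cv_risk_%s.csv", resp))
          write_csv_plain(data.frame(iter = seq_along(cv$mean_risk) - 1L,
                                     mean_risk = cv$mean_risk), f1)
          f2 <- file.path(cfg$out_dir, sprintf("path_%s.csv", resp))
          write_csv_plain(fit$path, f2)
          outs <- c(outs, f1, f2)
        }
        rows <- nrow(m)
      },
      stabsel = {
        m <- need("metrics", "stabsel")
        cm <- attr(m, "colmap")
        predictors <- cfg$fit$predictors %||% c("dist_boundary_km", cm$covariates, cm$flags)
        predictors <- predictors[vapply(predictors, function(pr)
          !is.null(m[[pr]]) && !anyNA(m[[pr]]), logical(1))]
        rd <- response_data(m, cfg$stabsel$response, predictors)
        ln <- base_learners(rd$data, predictors, grouping = cfg$fit$grouping)
        st <- stabsel_boost(rd$y, rd$data, rd$family, ln,
                            B = cfg$stabsel$B, q_sel = cfg$stabsel$q_sel,
                            pi_thr = cfg$stabsel$pi_thr,
                            max_iter = cfg$stabsel$max_iter,
                            step = cfg$fit$step,
                            seed = stage_seed("stabsel"))
        state$stability <- st
        f1 <- file.path(cfg$out_dir, "stabsel_freq.csv")
        write_csv_plain(data.frame(learner = rownames(st$freq), st$freq,
                                   row.names = NULL), f1)
        f2 <- file.path(cfg$out_dir, "stable_set.txt")
        writeLines(c(sprintf("# response: %s; PFER <= %.4f", cfg$stabsel$response, st$PFER),
                     st$stable), f2)
        rows <- st$n_learners; outs <- c(f1, f2)
      },
      gradient = {
        m <- need("metrics", "gradient")
        models <- need("models", "gradient")
        cond <- conditioning_record(m)
        state$curves <- list()
        for (resp in names(models)) {
          for (yr in sort(unique(m$year))) {
            cu <- gradient_curve(models[[resp]], m, cond = cond, year = yr,
                                 by = cfg$gradient$by)
            key <- sprintf("%s_%s", resp, yr)
            state$curves[[key]] <- cu
            f <- file.path(cfg$out_dir, sprintf("gradient_%s.csv", key))
            write_csv_plain(as.data.frame(cu), f)
            outs <- c(outs, f)
            rows <- nrow(cu)
          }
        }
      }
    )
    note(stage, rows, basename(outs), proc.time()[["elapsed"]] - t0)
  }
  mf <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  state$manifest <- manifest
  invisible(state)
}
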