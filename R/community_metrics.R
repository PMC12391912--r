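#' Hill number (effective number of species)
#'
#' `(sum(p^q))^(1/(1-q))` for order `q != 1` and the continuous limit
#' `exp(-sum(p log p))` at `q = 1`. Order 0 returns richness, order 2 the
#' reciprocal Simpson index, and `q = Inf` the reciprocal Berger--Parker
#' index (without the tie handling of [berger_parker()]).
#'
#' @param p relative abundances (any nonnegative vector; normalized
#'   internally, zeros dropped).
#' @param q diversity order, `>= 0` or `Inf`.
#' @return the effective number of species.
#' @examples
#' hill_number(c(0.8, 0.2), 1)
#' @export
hill_number <- function(p, q) {
  if (length(p) == 0 || all(is.na(p)) || sum(p, na.rm = TRUE) <= 0) {
    divgrad_error("diversity undefined for an empty abundance vector",
                  "divgrad_undefined_diversity")
  }
  if (any(p < 0, na.rm = TRUE)) {
    divgrad_error("abundances must be nonnegative", "divgrad_invalid_parameter")
  }
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q < 0) {
    divgrad_error("q must be a single nonnegative number", "divgrad_invalid_parameter")
  }
  p <- p[!is.na(p) & p > 0]
  p <- p / sum(p)
  hill_weighted(p, rep(1, length(p)), q)
}

# Hill number of a distribution given as (value, multiplicity) pairs;
# multiplicities may be fractional (used by the unseen-species adjustment).
hill_weighted <- function(p, w, q) {
  if (is.infinite(q)) return(1 / max(p))
  if (abs(q - 1) < 1e-12) return(exp(-sum(w * p * log(p))))
  sum(w * p^q)^(1 / (1 - q))
}

#' Reciprocal Berger--Parker index
#'
#' The order-infinity Hill number `1 / max(p)`. Undefined when several
#' species tie for top abundance: the return value is then `NA` with
#' attribute `tie = TRUE`.
#'
#' @inheritParams hill_number
#' @return numeric; `NA` with attribute `tie` on a tie.
#' @export
berger_parker <- function(p) {
  if (length(p) == 0 || all(is.na(p)) || sum(p, na.rm = TRUE) <= 0) {
    divgrad_error("diversity undefined for an empty abundance vector",
                  "divgrad_undefined_diversity")
  }
  p <- p[!is.na(p) & p > 0]
  p <- p / sum(p)
  m <- max(p)
  if (sum(abs(p - m) < 1e-12) > 1) {
    return(structure(NA_real_, tie = TRUE))
  }
  1 / m
}

# --- Burnham--Overton jackknife richness -----------------------------------

# Coefficient of f_i (species observed i times) in the order-k jackknife.
# Derived from the generalized leave-j-out construction: the order-k
# estimator is sum_j (-1)^j choose(k, j) (n - j)^k / k! times the expected
# richness of an (n - j)-subsample, and a species with i individuals
# survives subsampling with probability 1 - falling(j, i)/falling(n, i).
# The alternating sum is expanded as an exact integer polynomial in n before
# evaluation, so the massive cancellation for large n is handled exactly.
jack_coef <- function(k, n, imax) {
  a <- rep(1, imax)
  if (k == 0) return(a)
  for (i in seq_len(min(imax, k))) {
    # p(n) = sum_j (-1)^j C(k,j) j_(i) (n - j)^k  as integer coefficients
    coef <- numeric(k + 1)
    for (j in i:k) {
      jf <- prod(j - seq_len(i) + 1)               # falling factorial j_(i)
      for (t in 0:k) {
        coef[t + 1] <- coef[t + 1] +
          (-1)^j * choose(k, j) * jf * choose(k, t) * (-j)^(k - t)
      }
    }
    pn <- sum(coef * n^(0:k))
    nf <- prod(n - seq_len(i) + 1)                 # falling factorial n_(i)
    a[i] <- 1 - pn / (factorial(k) * nf)
  }
  a
}

#' Bias-adjusted species richness (interpolated jackknife)
#'
#' Species can be missed in tall grass or shrub; the jackknife family of
#' estimators corrects observed richness upward using the frequencies of
#' rarely seen species. The order is chosen by the sequential testing
#' procedure of the jackknife literature: starting at order 0, each step
#' tests whether the next-order estimate differs significantly from the
#' current one (normal test at `alpha`), and stops at the first
#' non-significant step. The returned estimate interpolates linearly between
#' the selected order and the next in the test statistic, which removes the
#' discontinuity order switching would otherwise cause. Orders are capped at
#' 5 and at the largest frequency class actually observed.
#'
#' @param counts integer abundance vector (zeros allowed and ignored).
#' @param alpha level of the sequential test.
#' @return list with `estimate` (always `>=` observed richness), `order`
#'   (selected integer order), and `jack` (the raw order-k estimates).
#' @examples
#' jackknife_richness(c(1, 1, 1))  # order 1: 3 + 3 * (2/3) = 5
#' @export
jackknife_richness <- function(counts, alpha = 0.05) {
  if (length(counts) == 0 || !is_count_vector(counts) || sum(counts) < 1) {
    divgrad_error("need a nonempty nonnegative integer abundance vector",
                  "divgrad_undefined_diversity")
  }
  counts <- counts[counts > 0]
  n <- sum(counts)
  S <- length(counts)
  fmax <- 6L
  f <- tabulate(pmin(counts, fmax + 1L), nbins = fmax + 1L)[seq_len(fmax)]
  Kmax <- max(c(0L, which(f[seq_len(5L)] > 0)))
  Kmax <- min(Kmax, max(n - 1L, 0L))
  if (Kmax == 0L) {
    return(list(estimate = as.numeric(S), order = 0L, jack = numeric(0)))
  }
  crit <- stats::qnorm(1 - alpha / 2)
  imax <- min(Kmax + 1L, 6L)
  A <- vapply(0:(Kmax), function(k) jack_coef(k, n, imax), numeric(imax))
  # A: imax x (Kmax+1); jack estimates for orders 0..Kmax
  jack <- as.vector(crossprod(A, f[seq_len(imax)])) + (S - sum(f[seq_len(imax)]))
  # sequential test over transitions k -> k+1 (k = 0..Kmax-1)
  Tstat <- rep(NA_real_, Kmax)
  for (k in seq_len(Kmax)) {       # transition (k-1) -> k
    b <- A[, k + 1] - A[, k]
    diff <- jack[k + 1] - jack[k]
    v <- sum(b^2 * f[seq_len(imax)]) - diff^2 / S
    if (v <= 1e-10) {
      Tstat[k] <- if (diff > 1e-10) Inf else 0
    } else {
      Tstat[k] <- diff / sqrt(v)
    }
  }
  m <- 0L
  while (m < Kmax && Tstat[m + 1] >= crit) m <- m + 1L
  if (m == Kmax) {
    est <- jack[Kmax + 1]
  } else {
    wt <- clamp(Tstat[m + 1] / crit, 0, 1)
    est <- jack[m + 1] + wt * (jack[m + 2] - jack[m + 1])
  }
  list(estimate = max(est, S), order = m, jack = jack[-1])
}

#' Diversity profile of a block
#'
#' Raw richness plus bias-adjusted effective species numbers at orders 0, 1,
#' 2 and 10, and the reciprocal Berger--Parker index (order infinity, subject
#' to its tie rule). Expected block totals are real-valued for incomplete
#' blocks; they are rounded half-up to integers for the jackknife (which
#' needs integer frequencies, and never below 1 for an observed species)
#' while relative abundances use the unrounded values.
#'
#' The bias adjustment spreads the estimated unseen-species complement over
#' the abundance distribution: observed proportions are scaled by the Turing
#' sample coverage `1 - f1/n` and the remaining mass is shared equally by
#' the `D0 - S` estimated unseen species. With no singletons the adjustment
#' is inactive and every order reduces to the raw Hill number.
#'
#' @param counts per-species expected block totals (nonnegative reals).
#' @param orders diversity orders beyond 0 to report.
#' @param alpha level of the jackknife sequential test.
#' @return list with `S_raw`, `D0`, `D` (named vector over `orders`),
#'   `D_inf`, `tie` and `jack_order`. Blocks with no ungulates report
#'   `S_raw = 0` and `NA` elsewhere.
#' @export
diversity_profile <- function(counts, orders = c(1, 2, 10), alpha = 0.05) {
  if (length(counts) == 0 || any(counts < 0, na.rm = TRUE)) {
    divgrad_error("expected counts must be a nonnegative vector",
                  "divgrad_invalid_parameter")
  }
  counts[is.na(counts)] <- 0
  S_raw <- sum(counts > 0)
  if (S_raw == 0) {
    return(list(S_raw = 0L, D0 = NA_real_,
                D = stats::setNames(rep(NA_real_, length(orders)),
                                    paste0("D", orders)),
                D_inf = NA_real_, tie = FALSE, jack_order = NA_integer_))
  }
  rounded <- ifelse(counts > 0, pmax(1, round_half_up(counts)), 0)
  jk <- jackknife_richness(rounded, alpha = alpha)
  p <- counts[counts > 0] / sum(counts)
  n_int <- sum(rounded)
  f1 <- sum(rounded == 1)
  cov <- 1 - f1 / n_int
  r <- jk$estimate - S_raw
  # coverage 0 (every species a singleton) carries no information to
  # redistribute mass; the adjustment is skipped for the positive orders
  if (r > 1e-9 && cov < 1 - 1e-12 && cov > 1e-12) {
    pv <- c(cov * p, (1 - cov) / r)
    wv <- c(rep(1, length(p)), r)
  } else {
    pv <- p
    wv <- rep(1, length(p))
  }
  D <- vapply(orders, function(q) hill_weighted(pv, wv, q), numeric(1))
  names(D) <- paste0("D", orders)
  bp <- berger_parker(p)
  list(S_raw = as.integer(S_raw), D0 = jk$estimate, D = D,
       D_inf = as.numeric(bp), tie = isTRUE(attr(bp, "tie")),
       jack_order = jk$order)
}

# --- biomass ----------------------------------------------------------------

#' Species attribute table
#'
#' Unit body masses (kg), migratory and domestic flags for the wild ungulate
#' pool. The shipped defaults are literature-typical unit weights for the
#' Mara--Serengeti assemblage; the table is a plain CSV so analyses can
#' substitute their own masses.
#'
#' @param path optional CSV with columns `species`, `mass_kg`, `migratory`,
#'   `domestic`; defaults to the packaged table.
#' @return data frame of species attributes.
#' @export
species_attributes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species_attributes.csv", package = "divgrad")
    if (path == "") path <- file.path("inst", "extdata", "species_attributes.csv")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "mass_kg", "migratory", "domestic")
  check_columns(df, need, "species attributes")
  if (any(df$mass_kg <= 0)) {
    divgrad_error("unit masses must be positive", "divgrad_configuration_error")
  }
  df$migratory <- as.logical(df$migratory)
  df$domestic <- as.logical(df$domestic)
  df
}

#' Block biomass from expected species totals
#'
#' Multiplies each species' expected block total by its unit weight and sums,
#' split into migratory (wildebeest and zebra by default) and nonmigratory
#' components.
#'
#' @param counts named vector of expected species totals.
#' @param attrs a [species_attributes()] table covering every species in
#'   `counts`.
#' @return list with `total`, `migratory`, `nonmigratory` (kg);
#'   `total = migratory + nonmigratory`.
#' @export
block_biomass <- function(counts, attrs) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    divgrad_error("counts must be named by species", "divgrad_configuration_error")
  }
  miss <- setdiff(names(counts), attrs$species)
  if (length(miss)) {
    divgrad_error(paste("species missing from the attribute table:",
                        paste(miss, collapse = ", ")),
                  "divgrad_configuration_error")
  }
  idx <- match(names(counts), attrs$species)
  w <- attrs$mass_kg[idx]
  mig <- attrs$migratory[idx]
  b <- as.numeric(counts) * w
  list(total = sum(b), migratory = sum(b[mig]), nonmigratory = sum(b[!mig]))
}

#' Diversity and biomass summary per block
#'
#' Convenience wrapper applying [diversity_profile()] and [block_biomass()]
#' to every row of a block table.
#'
#' @param blocks a `block_table` from [aggregate_blocks()].
#' @param attrs a [species_attributes()] table.
#' @param colmap column map; defaults to the table's own.
#' @return the block table with appended metric columns (`S_raw`, `D0`,
#'   `D1`, `D2`, `D10`, `D_inf`, `jack_order`, `biomass_total`,
#'   `biomass_migratory`, `biomass_nonmigratory`).
#' @export
community_summary <- function(blocks, attrs = species_attributes(),
                              colmap = attr(blocks, "colmap")) {
  if (is.null(colmap)) {
    divgrad_error("no column map attached to the block table", "divgrad_schema_error")
  }
  sp <- colmap$species
  cmat <- as.matrix(blocks[, sp, drop = FALSE])
  out <- blocks
  prof <- apply(cmat, 1, diversity_profile)
  out$S_raw <- vapply(prof, `[[`, integer(1), "S_raw")
  out$D0 <- vapply(prof, `[[`, numeric(1), "D0")
  dmat <- t(vapply(prof, `[[`, numeric(3), "D"))
  out$D1 <- dmat[, "D1"]; out$D2 <- dmat[, "D2"]; out$D10 <- dmat[, "D10"]
  out$D_inf <- vapply(prof, `[[`, numeric(1), "D_inf")
  out$jack_order <- vapply(prof, `[[`, integer(1), "jack_order")
  bm <- apply(cmat, 1, function(z) block_biomass(stats::setNames(z, sp), attrs))
  out$biomass_total <- vapply(bm, `[[`, numeric(1), "total")
  out$biomass_migratory <- vapply(bm, `[[`, numeric(1), "migratory")
  out$biomass_nonmigratory <- vapply(bm, `[[`, numeric(1), "nonmigratory")
  out
}
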