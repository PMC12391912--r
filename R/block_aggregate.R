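#' Expected block total from censused sub-blocks
#'
#' Blocks hold up to nine 333-m sub-blocks but edges and inaccessible ground
#' leave some blocks incomplete. To avoid underestimating block abundance,
#' the expected total for a species is the observed sum scaled up by the
#' fraction of the block censused: `sum(d) * 9 / Q` for `Q` censused
#' sub-blocks.
#'
#' @param subblock_counts nonnegative integer counts, one per censused
#'   sub-block.
#' @param Q_i number of censused sub-blocks (1--9); defaults to
#'   `length(subblock_counts)`.
#' @return the expected block total (real; integer whenever `Q_i = 9`).
#' @examples
#' expected_block_total(c(5, 5, 0, 0, 0, 0))  # 10 * 9/6 = 15
#' @export
expected_block_total <- function(subblock_counts, Q_i = length(subblock_counts)) {
  if (length(Q_i) != 1 || is.na(Q_i) || Q_i < 1 || Q_i > 9) {
    divgrad_error("Q_i must lie in 1..9", "divgrad_undefined_block")
  }
  if (length(subblock_counts) != Q_i) {
    divgrad_error("counts length must equal Q_i", "divgrad_undefined_block")
  }
  if (!is_count_vector(subblock_counts)) {
    divgrad_error("sub-block counts must be nonnegative integers",
                  "divgrad_invalid_parameter")
  }
  sum(subblock_counts) * 9 / Q_i
}

#' Aggregate sub-block records to block level
#'
#' Produces one record per (block, year): per-species expected totals via
#' [expected_block_total()], metric covariates averaged over non-missing
#' sub-blocks, presence flags OR-ed, the signed boundary distance averaged,
#' and the number of censused sub-blocks `Q` recorded.
#'
#' @param grid a `census_grid` (simulated or read from CSV).
#' @param colmap column map; defaults to the grid's own.
#' @return data frame of class `block_table` with attribute `colmap`.
#' @export
aggregate_blocks <- function(grid, colmap = attr(grid, "colmap")) {
  if (is.null(colmap)) {
    divgrad_error("no column map supplied or attached to the grid",
                  "divgrad_schema_error")
  }
  df <- as.data.frame(grid)
  check_columns(df, c(colmap$block, colmap$year, colmap$sub, colmap$land_use,
                      colmap$dist, colmap$species), "aggregate_blocks")
  key <- interaction(df[[colmap$year]], df[[colmap$block]], drop = TRUE, lex.order = TRUE)
  g <- as.integer(key)
  ng <- nlevels(key)

  # integrity: land use must be constant within a block-year
  lu_n <- tapply(df[[colmap$land_use]], g, function(z) length(unique(z)))
  if (any(lu_n > 1)) {
    divgrad_error("inconsistent land-use labels within a block", "divgrad_integrity_error")
  }
  sub_dup <- tapply(df[[colmap$sub]], g, anyDuplicated)
  if (any(sub_dup > 0)) {
    divgrad_error("duplicate sub-block indices within a block", "divgrad_integrity_error")
  }

  Q <- as.integer(tabulate(g, nbins = ng))
  if (any(Q < 1 | Q > 9)) {
    divgrad_error("each (block, year) must hold 1..9 sub-blocks", "divgrad_undefined_block")
  }
  first <- match(seq_len(ng), g)
  out <- data.frame(
    block_id = df[[colmap$block]][first],
    year = df[[colmap$year]][first],
    land_use = df[[colmap$land_use]][first],
    Q = Q,
    stringsAsFactors = FALSE
  )
  out$dist_boundary_km <- as.vector(rowsum(df[[colmap$dist]], g)) / Q

  cmat <- as.matrix(df[, colmap$species, drop = FALSE])
  if (any(cmat < 0) || any(cmat != floor(cmat))) {
    divgrad_error("species counts must be nonnegative integers",
                  "divgrad_invalid_parameter")
  }
  tot <- rowsum(cmat, g) * (9 / Q)
  colnames(tot) <- colmap$species
  out <- cbind(out, as.data.frame(tot))

  for (cc in colmap$covariates) {
    v <- df[[cc]]
    s <- rowsum(ifelse(is.na(v), 0, v), g)
    nn <- rowsum(as.numeric(!is.na(v)), g)
    m <- as.vector(s / nn)
    m[nn == 0] <- NA_real_
    out[[cc]] <- m
  }
  for (cc in colmap$flags) {
    out[[cc]] <- as.integer(as.vector(rowsum(df[[cc]], g)) > 0)
  }
  rownames(out) <- NULL
  structure(out, colmap = colmap, class = c("block_table", "data.frame"))
}
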