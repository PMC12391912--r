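#' Column maps for census CSV schemas
#'
#' A column map binds the semantic roles the pipeline needs (block id,
#' sub-block index, census year, land use, boundary distance, coordinates,
#' species count columns, covariate columns, presence-flag columns) to the
#' concrete column names of a CSV file, so no name is hard-coded and foreign
#' schemas can be read by supplying their own map.
#'
#' @param block,sub,year,land_use,dist,x,y single column names.
#' @param species,covariates,flags character vectors of column names.
#' @return a list of class `colmap`.
#' @export
default_colmap <- function(block = "block_id", sub = "sub_block",
                           year = "year", land_use = "land_use",
                           dist = "dist_boundary_km", x = "x_m", y = "y_m",
                           species = character(), covariates = character(),
                           flags = character()) {
  cm <- list(block = block, sub = sub, year = year, land_use = land_use,
             dist = dist, x = x, y = y,
             species = species, covariates = covariates, flags = flags)
  roles <- c(cm$block, cm$sub, cm$year, cm$land_use, cm$dist, cm$x, cm$y,
             cm$species, cm$covariates, cm$flags)
  if (anyDuplicated(roles)) {
    divgrad_error("column roles must be disjoint", "divgrad_schema_error")
  }
  structure(cm, class = "colmap")
}

check_columns <- function(df, wanted, where) {
  missing <- setdiff(wanted, names(df))
  if (length(missing)) {
    divgrad_error(sprintf("%s: missing mapped column(s): %s", where,
                          paste(missing, collapse = ", ")),
                  "divgrad_schema_error")
  }
}

parse_counts <- function(x, col) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !(x == "" | is.na(x)))
  if (length(bad) == 0) bad <- which(is.na(v))
  if (length(bad)) {
    divgrad_error(sprintf("column '%s': unparseable count at row %d", col, bad[1]),
                  "divgrad_parse_error")
  }
  bad <- which(v < 0 | v != floor(v))
  if (length(bad)) {
    divgrad_error(sprintf("column '%s': negative or non-integer count at row %d",
                          col, bad[1]), "divgrad_parse_error")
  }
  as.integer(v)
}

#' Read a sub-block census CSV
#'
#' Reads the sub-block schema (one row per sub-block and census year) into a
#' typed `census_grid`. Counts are validated as nonnegative integers with the
#' offending row reported on failure; empty fields become missing covariate
#' values.
#'
#' @param path CSV file path.
#' @param colmap a [default_colmap()]; if the file was written by
#'   [write_subblock_csv()] the default reconstruction from the header works.
#' @return a `census_grid` data frame.
#' @export
read_subblock_csv <- function(path, colmap) {
  if (!file.exists(path)) {
    divgrad_error(paste("file not found:", path), "divgrad_schema_error")
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  core <- c(colmap$block, colmap$sub, colmap$year, colmap$land_use,
            colmap$dist, colmap$x, colmap$y)
  check_columns(raw, c(core, colmap$species, colmap$covariates, colmap$flags),
                basename(path))
  n <- nrow(raw)
  out <- data.frame(row.names = seq_len(n))[, 0, drop = FALSE]
  out[[colmap$block]] <- raw[[colmap$block]]
  out[[colmap$sub]] <- as.integer(raw[[colmap$sub]])
  out[[colmap$year]] <- as.integer(raw[[colmap$year]])
  out[[colmap$land_use]] <- raw[[colmap$land_use]]
  for (cc in c(colmap$x, colmap$y, colmap$dist)) {
    out[[cc]] <- as.numeric(raw[[cc]])
  }
  for (cc in colmap$species) out[[cc]] <- parse_counts(raw[[cc]], cc)
  for (cc in colmap$covariates) {
    v <- raw[[cc]]
    v[v == ""] <- NA_character_
    out[[cc]] <- as.numeric(v)
  }
  for (cc in colmap$flags) out[[cc]] <- as.integer(raw[[cc]])
  if (n > 0) {
    key <- interaction(out[[colmap$block]], out[[colmap$year]], drop = TRUE)
    dup <- stats::ave(out[[colmap$sub]], key, FUN = anyDuplicated)
    if (any(dup > 0)) {
      divgrad_error("duplicate sub-block index within a (block, year)",
                    "divgrad_integrity_error")
    }
  }
  structure(out, colmap = colmap, class = c("census_grid", "data.frame"))
}

format_csv_frame <- function(df) {
  out <- df
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.double(v)) {
      out[[j]] <- format_num(v)
    } else if (is.integer(v) || is.logical(v)) {
      s <- as.character(as.integer(v))
      s[is.na(v)] <- ""
      out[[j]] <- s
    } else {
      s <- as.character(v)
      s[is.na(s)] <- ""
      out[[j]] <- s
    }
  }
  out
}

write_csv_plain <- function(df, path) {
  utils::write.table(format_csv_frame(df), path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "",
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a sub-block census CSV
#'
#' Serializes a `census_grid` with deterministic column order and formatting
#' (identical grids give byte-identical files); missing covariates become
#' empty fields, never sentinel numbers.
#'
#' @param grid a `census_grid`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_subblock_csv <- function(grid, path) {
  write_csv_plain(as.data.frame(grid), path)
}

#' Write / read block-level tables
#'
#' Block tables hold one row per (block, year): expected species totals,
#' covariate means, OR-ed presence flags and the number of censused
#' sub-blocks. Duplicate (block, year) keys are an integrity error.
#'
#' @param blocks block-level data frame (from [aggregate_blocks()]).
#' @param path file path.
#' @param block_col,year_col key column names.
#' @return the path (writer) or a data frame (reader).
#' @export
write_block_csv <- function(blocks, path, block_col = "block_id",
                            year_col = "year") {
  if (nrow(blocks) == 0) {
    divgrad_error("refusing to write an empty block table", "divgrad_integrity_error")
  }
  check_columns(blocks, c(block_col, year_col), "block table")
  key <- paste(blocks[[block_col]], blocks[[year_col]], sep = "\r")
  if (anyDuplicated(key)) {
    divgrad_error("duplicate (block, year) keys in block table",
                  "divgrad_integrity_error")
  }
  write_csv_plain(blocks, path)
}

#' @rdname write_block_csv
#' @export
read_block_csv <- function(path, block_col = "block_id", year_col = "year") {
  df <- utils::read.csv(path, check.names = FALSE)
  check_columns(df, c(block_col, year_col), basename(path))
  df[[block_col]] <- as.character(df[[block_col]])
  key <- paste(df[[block_col]], df[[year_col]], sep = "\r")
  if (anyDuplicated(key)) {
    divgrad_error("duplicate (block, year) keys in block table",
                  "divgrad_integrity_error")
  }
  df
}
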