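# Delimited-text I/O for the command-line workflows. All formats are plain
# CSV: a phenotype table (line_id, y, optional extra columns ignored by the
# model), a design/marker matrix (first column line_id), and a square
# relationship matrix whose header and first column hold the line ids.

#' Read an ordinal phenotype table
#'
#' Expects a CSV with at least the columns `line_id` and `y` (ordinal
#' categories coded 1..C); any further columns (replicate, environment
#' labels, ...) are carried along untouched.
#'
#' @param path CSV file path.
#' @return a tibble.
#' @export
read_phenotypes <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("line_id", "y") %in% names(tb))) {
    abort("phenotype file must contain columns `line_id` and `y`.")
  }
  tb
}

#' Read a design / marker matrix
#'
#' CSV whose first column is `line_id`; the remaining numeric columns form
#' the design matrix (one row per line).
#'
#' @param path CSV file path.
#' @return a tibble with `line_id` and numeric covariate columns.
#' @export
read_design <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  if (names(tb)[1] != "line_id") {
    abort("design file must have `line_id` as its first column.")
  }
  tb
}

#' Read a genomic relationship matrix
#'
#' Square CSV with the line ids both as header (after a leading `line_id`
#' column) and in the first column.
#'
#' @param path CSV file path.
#' @return a named square matrix.
#' @export
read_grm <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  ids <- as.character(tb[[1]])
  m <- as.matrix(tb[, -1])
  if (nrow(m) != ncol(m) || !identical(colnames(m), ids)) {
    abort("relationship-matrix file must be square with matching header and id column.")
  }
  rownames(m) <- ids
  m
}

# Join phenotypes with a per-line design into model inputs (y, X, line, G).
assemble_dataset <- function(pheno, design, G = NULL) {
  ids <- as.character(design$line_id)
  idx <- match(as.character(pheno$line_id), ids)
  if (anyNA(idx)) {
    abort(sprintf("%d phenotype line id(s) missing from the design file.",
                  sum(is.na(idx))))
  }
  X <- as.matrix(design[, -1])[idx, , drop = FALSE]
  if (!is.null(G)) {
    gidx <- match(ids, rownames(G))
    if (anyNA(gidx)) abort("design line id(s) missing from the relationship matrix.")
    G <- G[gidx, gidx, drop = FALSE]
  }
  list(y = as.integer(pheno$y), X = X, line = idx, G = G)
}

#' Write a posterior summary table
#'
#' Writes the [tidy()] posterior summary (parameter, mean, SD, interval
#' bounds) of a fit to CSV.
#'
#' @param fit a `blor_fit`.
#' @param path output CSV path.
#' @param conf.level credible level.
#' @return `path`, invisibly.
#' @export
write_posterior_summary <- function(fit, path, conf.level = 0.95) {
  readr::write_csv(tidy(fit, conf.level = conf.level), path)
  invisible(path)
}

# Reproducibility manifest written next to every CLI artifact.
write_manifest <- function(path, ...) {
  info <- list(..., written = format(Sys.time(), tz = "UTC"),
               package_version = as.character(utils::packageVersion("ordpg")))
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
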