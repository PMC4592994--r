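# Validation of the ordinal dataset fed to the Gibbs sampler and the MLE.
# Returns a normalized list: y (integer 1..C), X (numeric matrix), line
# (integer 1..I or NULL), G (matrix or NULL), C, n, I.
validate_ordinal_data <- function(y, X, line = NULL, G = NULL,
                                  require_all_categories = TRUE) {
  if (anyNA(y)) abort("`y` must not contain missing values.")
  yi <- as.integer(y)
  if (any(yi != y) || any(yi < 1)) {
    abort("`y` must contain ordinal categories coded as integers 1..C.")
  }
  C <- max(yi)
  if (C < 2) abort("`y` must contain at least two categories.")
  missing_cat <- setdiff(seq_len(C), unique(yi))
  if (require_all_categories && length(missing_cat) > 0) {
    abort(paste0(
      "Every category 1..C must be observed when thresholds are sampled; ",
      "missing: ", paste(missing_cat, collapse = ", "),
      ". Threshold intervals for unobserved categories are unbounded."
    ), class = "ordpg_category_coverage")
  }

  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != length(yi)) {
    abort("`X` must have one row per observation in `y`.")
  }
  if (anyNA(X) || any(!is.finite(X))) {
    abort(paste0(
      "`X` must be complete and finite; missing marker genotypes are not ",
      "imputed by this package."
    ), class = "ordpg_incomplete_design")
  }
  const_col <- apply(X, 2, function(col) diff(range(col)) == 0)
  if (any(const_col)) {
    abort(paste0(
      "`X` must not contain a constant (intercept) column when thresholds ",
      "are sampled: the thresholds absorb the intercept. Offending column(s): ",
      paste(which(const_col), collapse = ", ")
    ), class = "ordpg_intercept_column")
  }

  I <- NULL
  if (!is.null(line)) {
    if (anyNA(line)) abort("`line` must not contain missing values.")
    line <- as.integer(factor(line, levels = unique(line)))
    I <- max(line)
    if (length(line) != length(yi)) {
      abort("`line` must have one entry per observation.")
    }
  }
  if (!is.null(G)) {
    if (is.null(line)) {
      abort("a relationship matrix `G` requires line identifiers.")
    }
    G <- as.matrix(G)
    if (nrow(G) != I || ncol(G) != I) {
      abort(sprintf("`G` must be %d x %d (one row/column per line).", I, I))
    }
    if (max(abs(G - t(G))) > 1e-8 * max(1, max(abs(G)))) {
      abort("`G` must be symmetric.", class = "ordpg_matrix_conditioning")
    }
    ch <- tryCatch(chol(G), error = function(e) NULL)
    if (is.null(ch)) {
      abort("`G` must be positive definite (Cholesky failed).",
            class = "ordpg_matrix_conditioning")
    }
  }

  list(y = yi, X = X, line = line, G = G, C = C, n = length(yi), I = I)
}

# Build (y, X, line, G) from a data frame + formula, the tidy front door used
# by blor(), fit_cumulative_link() and cross_validate(). The intercept is
# dropped from the model matrix: thresholds play that role.
build_model_inputs <- function(data, formula, line_vec = NULL, G = NULL) {
  data <- as.data.frame(data)
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  mm <- model.matrix(attr(mf, "terms"), mf)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  c(validate_ordinal_data(y, mm, line_vec, G), list(formula = formula))
}

# Resolve a tidy-eval column selection (bare name, string, or NULL) against a
# data frame; returns the column vector or NULL.
resolve_column <- function(data, quo) {
  if (rlang::quo_is_null(quo)) return(NULL)
  nm <- rlang::as_name(quo)
  if (!nm %in% names(data)) {
    abort(sprintf("column `%s` not found in `data`.", nm))
  }
  data[[nm]]
}
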