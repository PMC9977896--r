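#' Subject-level dataset container
#'
#' Bundles an outcome vector, a design matrix (including an intercept column
#' if one is wanted) and optional nonnegative case weights into the container
#' used by all fitting functions.
#'
#' @param outcome Numeric vector of length n.
#' @param design Numeric matrix, n rows by m columns. Column names are kept
#'   and used to label coefficients.
#' @param case_weights Nonnegative numeric vector of length n; defaults to
#'   unit weights. Weights are interpreted as case (frequency-style) weights
#'   in the estimating equation.
#'
#' @return An object of class \code{resi_dataset}: a list with elements
#'   \code{outcome}, \code{design}, \code{case_weights}.
#' @export
resi_dataset <- function(outcome, design, case_weights = NULL) {
  outcome <- as.numeric(outcome)
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  n <- length(outcome)
  if (nrow(design) != n) {
    resi_error("nrow(design) must equal length(outcome)", "resi_input_error")
  }
  if (anyNA(outcome) || anyNA(design)) {
    resi_error("missing values are not supported; remove incomplete rows first",
               "resi_input_error")
  }
  if (is.null(case_weights)) {
    case_weights <- rep(1, n)
  } else {
    case_weights <- as.numeric(case_weights)
    if (length(case_weights) != n || anyNA(case_weights) ||
        any(case_weights < 0) || all(case_weights == 0)) {
      resi_error("case_weights must be nonnegative, length n, not all zero",
                 "resi_input_error")
    }
  }
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  structure(list(outcome = outcome, design = design,
                 case_weights = case_weights),
            class = "resi_dataset")
}

#' @export
print.resi_dataset <- function(x, ...) {
  cat("<resi_dataset> n =", length(x$outcome),
      " m =", ncol(x$design),
      " columns:", paste(colnames(x$design), collapse = ", "), "\n")
  invisible(x)
}

#' Read a delimited file into a model-ready dataset
#'
#' Reads a CSV/TSV file with a header row, expands character or factor
#' predictors to treatment-coded indicator columns (reference level = first
#' level in lexicographic order) and prepends an intercept column.
#'
#' @param path Path to a comma- or tab-separated file with a header row.
#'   Files ending in \code{.tsv} or \code{.txt} are read as tab-separated.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names.
#'
#' @return A \code{resi_dataset} with attributes \code{term_assign} (integer
#'   vector mapping design columns to predictors, 0 = intercept) and
#'   \code{term_labels} (the predictor names).
#' @export
read_dataset <- function(path, outcome, predictors) {
  if (!file.exists(path)) {
    resi_error(paste0("cannot read input file: ", path), "resi_input_error")
  }
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c(outcome, predictors), names(df))
  if (length(missing_cols)) {
    resi_error(paste0("columns not found in ", path, ": ",
                      paste(missing_cols, collapse = ", ")),
               "resi_input_error")
  }
  build_dataset(df, outcome, predictors)
}

# Shared by read_dataset() and resi(): treatment coding via model.matrix with
# lexicographic reference levels.
build_dataset <- function(df, outcome, predictors) {
  for (p in predictors) {
    if (is.character(df[[p]]) || is.logical(df[[p]]) || is.factor(df[[p]])) {
      df[[p]] <- factor(df[[p]], levels = sort(unique(as.character(df[[p]]))))
    }
  }
  fml <- stats::reformulate(sprintf("`%s`", predictors))
  mf <- stats::model.frame(fml, data = df)
  X <- stats::model.matrix(fml, data = mf)
  y <- df[[outcome]]
  if (!is.numeric(y)) {
    resi_error("outcome column must be numeric (code binary outcomes as 0/1)",
               "resi_input_error")
  }
  ds <- resi_dataset(y, X)
  attr(ds, "term_assign") <- attr(X, "assign")
  attr(ds, "term_labels") <- attr(stats::terms(mf), "term.labels")
  ds
}

# Classed conditions so callers (bootstrap layer, CLI) can react by type.
resi_error <- function(message, class) {
  stop(structure(class = c(class, "resi_error", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}
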