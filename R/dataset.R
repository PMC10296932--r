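#' Construct a binary-response dataset
#'
#' Bundles an `n x p` numeric design matrix with a 0/1 response vector,
#' the unit consumed by all screening and fitting functions.  Validation
#' enforces the contracts the screens rely on: a purely numeric design
#' with no missing values, a response containing only 0 and 1, and both
#' classes present.
#'
#' @param X Numeric matrix (or object coercible to one) with `n` rows
#'   (samples) and `p` columns (predictors).
#' @param y Response vector of length `n` with values in `{0, 1}`.
#'   A logical vector or a two-level factor is coerced, the second
#'   factor level mapping to 1.
#' @param feature_names Optional character vector of `p` predictor
#'   labels; defaults to the column names of `X` or `X1..Xp`.
#'
#' @return An object of class `binary_dataset`: a list with elements
#'   `X`, `y` and `feature_names`.
#' @examples
#' d <- binary_dataset(matrix(rnorm(40), 10, 4), rep(c(0, 1), 5))
#' d
#' @export
binary_dataset <- function(X, y, feature_names = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X)) {
    stop("'X' must be a numeric matrix", call. = FALSE)
  }
  if (is.factor(y)) {
    if (nlevels(y) != 2L) {
      stop("a factor response must have exactly two levels", call. = FALSE)
    }
    y <- as.integer(y) - 1L
  }
  if (is.logical(y)) y <- as.integer(y)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) {
    stop("length of 'y' (", length(y), ") does not match nrow(X) (",
         nrow(X), ")", call. = FALSE)
  }
  if (anyNA(X) || anyNA(y)) {
    stop("missing values are not supported", call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) {
    stop("'y' must contain only 0 and 1", call. = FALSE)
  }
  if (nrow(X) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names)) {
      feature_names <- paste0("X", seq_len(ncol(X)))
    }
  }
  if (length(feature_names) != ncol(X)) {
    stop("'feature_names' must have one entry per predictor", call. = FALSE)
  }
  colnames(X) <- feature_names
  structure(list(X = X, y = y, feature_names = feature_names),
            class = "binary_dataset")
}

#' @export
print.binary_dataset <- function(x, ...) {
  cat("binary_dataset: ", nrow(x$X), " samples x ", ncol(x$X),
      " predictors (n1 = ", sum(x$y == 1), ", n0 = ", sum(x$y == 0),
      ")\n", sep = "")
  invisible(x)
}

#' @export
dim.binary_dataset <- function(x) dim(x$X)

# Both classes present; screening and fitting require this.
check_two_classes <- function(data) {
  if (sum(data$y == 1) < 1L || sum(data$y == 0) < 1L) {
    stop("response is degenerate: both classes (0 and 1) must be present",
         call. = FALSE)
  }
  invisible(data)
}

#' Read a binary-response dataset from a delimited text file
#'
#' Reads a CSV or TSV file with one named response column; every other
#' numeric column becomes a predictor.  The response must either be
#' coded 0/1 already or take exactly two values, in which case
#' `positive_class` names the value mapped to 1.
#'
#' @param file Path to a CSV (default) or TSV file with a header row.
#' @param response Name of the response column.
#' @param positive_class Optional value of the response column mapped to
#'   1; required when the column is not already 0/1.
#' @param sep Field separator; `","` by default, use `"\t"` for TSV.
#'
#' @return A [binary_dataset].
#' @export
read_binary_dataset <- function(file, response, positive_class = NULL,
                                sep = ",") {
  df <- utils::read.delim(file, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!response %in% names(df)) {
    stop("response column '", response, "' not found in ", file,
         call. = FALSE)
  }
  yraw <- df[[response]]
  df[[response]] <- NULL
  if (!is.null(positive_class)) {
    vals <- unique(yraw)
    if (length(vals) != 2L) {
      stop("response column must take exactly two values, found ",
           length(vals), call. = FALSE)
    }
    if (!positive_class %in% vals) {
      stop("positive_class '", positive_class,
           "' does not occur in the response column", call. = FALSE)
    }
    y <- as.integer(yraw == positive_class)
  } else {
    y <- suppressWarnings(as.numeric(yraw))
    if (anyNA(y) || !all(y %in% c(0, 1))) {
      stop("response column is not 0/1 coded; supply 'positive_class'",
           call. = FALSE)
    }
  }
  numeric_cols <- vapply(df, is.numeric, logical(1))
  if (!all(numeric_cols)) {
    warning("dropping non-numeric columns: ",
            paste(names(df)[!numeric_cols], collapse = ", "))
    df <- df[numeric_cols]
  }
  if (ncol(df) < 1L) stop("no numeric predictor columns found", call. = FALSE)
  binary_dataset(as.matrix(df), y, feature_names = names(df))
}
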