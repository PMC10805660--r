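#' Load a rectangular indicator table
#'
#' Reads a comma-delimited file with a header row.  An optional first column
#' named \code{unit} (case-insensitive) supplies unit identifiers; every
#' other cell must be numeric.  Columns with missing values or zero variance
#' are rejected with an error naming the column.
#'
#' @param path path to a CSV file.
#' @return a data frame of numeric indicator columns; unit identifiers (when
#'   present) become row names.
#' @export
read_indicator_data <- function(path) {
  if (!file.exists(path)) stop("data file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(d) == 0L || ncol(d) == 0L) stop("empty data file: ", path)
  if (tolower(names(d)[1]) == "unit") {
    ids <- as.character(d[[1]])
    d <- d[, -1, drop = FALSE]
    if (ncol(d) == 0L) stop("data file has no indicator columns: ", path)
    rownames(d) <- make.unique(ids)
  }
  validate_indicators(d)
}

#' Validate an indicator table
#'
#' @param d data frame or matrix of indicator columns.
#' @return the validated data, unchanged, as a data frame.
#' @export
validate_indicators <- function(d) {
  d <- as.data.frame(d)
  for (nm in names(d)) {
    col <- d[[nm]]
    if (!is.numeric(col)) stop("non-numeric values in column '", nm, "'")
    if (anyNA(col)) stop("missing values in column '", nm, "'")
    if (stats::sd(col) < .Machine$double.eps^0.5)
      stop("zero-variance column '", nm, "'")
  }
  d
}

#' Column-wise standardization
#'
#' Centres every column to mean zero and scales it to unit sample
#' (\eqn{n-1}) standard deviation.  Idempotent up to floating point; the
#' centring and scaling constants are attached as attributes so the
#' transform is invertible.
#'
#' @param d numeric data frame or matrix.
#' @return numeric matrix with attributes \code{center}, \code{scale} and
#'   \code{standardized = TRUE}.
#' @export
standardize <- function(d) {
  x <- as.matrix(validate_indicators(d))
  z <- .zscore(x)
  out <- z$values
  attr(out, "center") <- z$center
  attr(out, "scale") <- z$scale
  attr(out, "standardized") <- TRUE
  out
}

# Coerce data to a numeric matrix whose columns are exactly the model's
# indicators, in model order; errors name the offending column.
.as_indicator_matrix <- function(data, model) {
  d <- as.data.frame(data)
  need <- unlist(model$blocks, use.names = FALSE)
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("data is missing indicator column(s): ",
         paste(missing, collapse = ", "))
  d <- validate_indicators(d[need])
  x <- as.matrix(d)
  if (!is.null(rownames(d))) rownames(x) <- rownames(d)
  x
}
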