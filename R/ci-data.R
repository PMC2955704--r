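#' Dataset container for conditional-independence testing
#'
#' Wraps a fully observed data frame into the internal representation used
#' by the CI tests and learners: discrete columns are encoded as 1-based
#' integer category codes with a recorded arity, continuous columns as
#' doubles.  Columns are classified as discrete when they are factors,
#' characters, logicals or integer-valued numerics, unless a schema says
#' otherwise.  Missing values are rejected (the learners assume fully
#' observed data).
#'
#' @param x a data frame, or an existing `"ci_data"` (returned unchanged).
#' @param schema optional named list declaring column types: each entry is
#'   `"continuous"`, `"discrete"`, or `list(discrete = arity)`.
#' @return An object of class `"ci_data"`: list with `names`, `n`, `type`
#'   (per-column `"discrete"`/`"continuous"`), `codes` (integer matrix),
#'   `arities` (named integer vector) and `values` (numeric matrix for
#'   continuous columns).
#' @export
ci_data <- function(x, schema = NULL) {
  if (inherits(x, "ci_data")) return(x)
  if (!is.data.frame(x)) stop_input("expected a data frame")
  if (nrow(x) < 1) stop_input("dataset has no rows")
  if (anyNA(x)) stop_input("dataset contains missing values")
  nm <- colnames(x)
  type <- character(ncol(x))
  codes <- matrix(NA_integer_, nrow(x), ncol(x), dimnames = list(NULL, nm))
  values <- matrix(NA_real_, nrow(x), ncol(x), dimnames = list(NULL, nm))
  arities <- setNames(rep(NA_integer_, ncol(x)), nm)
  for (j in seq_along(nm)) {
    col <- x[[j]]
    decl <- schema[[nm[j]]]
    discrete <- if (!is.null(decl)) {
      if (identical(decl, "continuous")) FALSE else TRUE
    } else {
      is.factor(col) || is.character(col) || is.logical(col) ||
        is.integer(col) || (is.numeric(col) && all(col == round(col)))
    }
    if (discrete) {
      f <- if (is.factor(col)) col else factor(col)
      ar <- nlevels(f)
      if (is.list(decl) && !is.null(decl$discrete)) {
        if (decl$discrete < ar) stop_input("declared arity below observed: ", nm[j])
        ar <- as.integer(decl$discrete)
      }
      type[j] <- "discrete"
      codes[, j] <- as.integer(f)
      arities[j] <- ar
    } else {
      if (!is.numeric(col)) stop_input("continuous column is not numeric: ", nm[j])
      type[j] <- "continuous"
      values[, j] <- as.double(col)
    }
  }
  structure(list(names = nm, n = nrow(x), type = setNames(type, nm),
                 codes = codes, arities = arities, values = values),
            class = "ci_data")
}

#' @export
print.ci_data <- function(x, ...) {
  cat("ci_data:", x$n, "rows,", length(x$names), "columns (",
      sum(x$type == "discrete"), "discrete,",
      sum(x$type == "continuous"), "continuous )\n")
  invisible(x)
}

#' Read a dataset from a headered CSV file
#'
#' @param path CSV file with a header row.
#' @param schema optional column-type schema as in [ci_data()], or a path
#'   to a YAML file holding one (requires the `yaml` package).
#' @return A `"ci_data"`.
#' @export
read_ci_csv <- function(path, schema = NULL) {
  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_input("reading a YAML schema requires the 'yaml' package")
    schema <- yaml::read_yaml(schema)
  }
  ci_data(read.csv(path, stringsAsFactors = FALSE), schema = schema)
}

ci_columns <- function(data, cols, kind) {
  bad <- setdiff(cols, data$names)
  if (length(bad)) stop_input("unknown column(s): ", paste(bad, collapse = ", "))
  wrong <- cols[data$type[cols] != kind]
  if (length(wrong))
    stop(sprintf("column(s) not %s: %s", kind, paste(wrong, collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

# 1-based stratum index over the z columns (all discrete), plus the number
# of configurations.
z_index <- function(data, z) {
  if (!length(z)) return(list(idx = rep(1L, data$n), nz = 1L))
  ar <- data$arities[z]
  idx <- rep(0L, data$n)
  stride <- 1L
  for (j in seq_along(z)) {
    idx <- idx + (data$codes[, z[j]] - 1L) * stride
    stride <- stride * ar[[j]]
  }
  list(idx = idx + 1L, nz = as.integer(prod(ar)))
}
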