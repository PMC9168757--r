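#' Expression matrix container
#'
#' A genes-by-observations expression matrix with string identifiers. Values
#' are log2-normalized expression unless `is_counts = TRUE`, in which case
#' they must be non-negative integers (raw UMI counts). This is the container
#' every pipeline stage consumes; observations are bulk samples, single cells
#' or pseudocells depending on the stage.
#'
#' @param values Numeric matrix, rows = genes, columns = observations. Must
#'   carry unique row and column names and contain only finite values.
#' @param is_counts Logical; `TRUE` marks raw count data (non-negative,
#'   integral values required).
#'
#' @return An object of class `expr_matrix`: the validated matrix with the
#'   `is_counts` flag attached.
#' @export
#'
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' x <- expr_matrix(m)
#' gene_ids(x)
expr_matrix <- function(values, is_counts = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene row names and observation column names", call. = FALSE)
  }
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g) > 0) {
    stop("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "), call. = FALSE)
  }
  dup_o <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_o) > 0) {
    stop("duplicate observation id(s): ", paste(unique(dup_o), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-finite value at gene '%s', observation '%s' (missing values are not permitted)",
      rownames(values)[bad[1]], colnames(values)[bad[2]]
    ), call. = FALSE)
  }
  if (is_counts && (any(values < 0) || any(values != round(values)))) {
    stop("count matrices must be non-negative and integral", call. = FALSE)
  }
  structure(values, is_counts = is_counts, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
gene_ids <- function(x) rownames(x)

#' @rdname expr_matrix
#' @export
obs_ids <- function(x) colnames(x)

#' @rdname expr_matrix
#' @export
is_counts <- function(x) isTRUE(attr(x, "is_counts"))

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d observations (%s)\n",
    nrow(x), ncol(x), if (is_counts(x)) "raw counts" else "log2-normalized"
  ))
  invisible(x)
}

# Subsetting keeps the class and flag when the result is still a matrix.
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    structure(out,
      is_counts = attr(x, "is_counts"),
      class = c("expr_matrix", "matrix", "array")
    )
  } else {
    out
  }
}

#' Shift a matrix to be non-negative
#'
#' NMF requires entrywise non-negative input. Log-scale expression can dip
#' below zero, so the whole matrix is shifted by its global minimum when any
#' entry is negative; between-observation contrasts are preserved.
#'
#' @param x An `expr_matrix` or numeric matrix.
#' @return Matrix of the same shape with all entries >= 0.
#' @export
shift_nonneg <- function(x) {
  mn <- min(x)
  if (mn < 0) x <- x - mn
  x
}
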