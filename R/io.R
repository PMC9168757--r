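# Readers and writers for the package's plain-text interchange formats:
# TSV matrices (first column = gene id, header = observation ids),
# MatrixMarket MTX with genes.txt / barcodes.txt sidecars, GMT gene sets,
# and TSV sample / cell annotation tables. All readers are deterministic and
# fail hard on malformed input rather than guessing.

#' Read an expression matrix
#'
#' @param path Path to the matrix file. For `format = "tsv"`, a UTF-8
#'   tab-separated file whose first row holds observation ids and first column
#'   gene ids, with no quoting. For `format = "mtx"`, a 1-based coordinate
#'   MatrixMarket file with sidecar `genes.txt` and `barcodes.txt` (one id per
#'   line) in the same directory.
#' @param format Either `"tsv"` or `"mtx"`.
#' @param is_counts Logical; mark the result as raw counts.
#'
#' @return An [expr_matrix()] with gene and observation order preserved from
#'   the file.
#' @export
read_expression_matrix <- function(path, format = c("tsv", "mtx"), is_counts = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    read_expression_tsv(path, is_counts)
  } else {
    read_expression_mtx(path, is_counts)
  }
}

read_expression_tsv <- function(path, is_counts) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2) stop("matrix file has no data rows: ", path, call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  obs <- header[-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  genes <- vapply(rows, `[[`, character(1), 1L)
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) {
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(obs),
                 dimnames = list(genes, obs))
  for (i in seq_along(rows)) {
    fields <- rows[[i]][-1]
    if (length(fields) != length(obs)) {
      stop(sprintf("row %d ('%s') has %d values, expected %d",
                   i, genes[i], length(fields), length(obs)), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(fields))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("non-numeric value '%s' at gene '%s', column '%s'",
                   fields[j], genes[i], obs[j]), call. = FALSE)
    }
    vals[i, ] <- v
  }
  expr_matrix(vals, is_counts = is_counts)
}

read_expression_mtx <- function(path, is_counts) {
  dir <- dirname(path)
  gene_file <- file.path(dir, "genes.txt")
  bc_file <- file.path(dir, "barcodes.txt")
  if (!file.exists(gene_file) || !file.exists(bc_file)) {
    stop("MTX sidecar files genes.txt / barcodes.txt not found in ", dir, call. = FALSE)
  }
  m <- as.matrix(Matrix::readMM(path))
  genes <- readLines(gene_file)
  bcs <- readLines(bc_file)
  if (nrow(m) != length(genes) || ncol(m) != length(bcs)) {
    stop("MTX dimensions do not match sidecar id files", call. = FALSE)
  }
  dimnames(m) <- list(genes, bcs)
  expr_matrix(m, is_counts = is_counts)
}

#' Write an expression matrix as TSV
#'
#' Values are written with full round-trip precision so write-then-read
#' reproduces the matrix exactly.
#'
#' @param x An [expr_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- tibble::as_tibble(as.matrix(unclass(x)), rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write an expression matrix as MatrixMarket MTX
#'
#' Writes `<name>.mtx` plus `genes.txt` and `barcodes.txt` sidecars.
#'
#' @param x An [expr_matrix()].
#' @param path Output path for the `.mtx` file.
#' @return `path`, invisibly.
#' @export
write_expression_mtx <- function(x, path) {
  Matrix::writeMM(Matrix::Matrix(as.matrix(unclass(x)), sparse = TRUE), path)
  dir <- dirname(path)
  writeLines(gene_ids(x), file.path(dir, "genes.txt"))
  writeLines(obs_ids(x), file.path(dir, "barcodes.txt"))
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes
#' within a line are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (one gene set per line, file order
#'   preserved).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line needs >= 3 tab-separated fields: ", substr(ln, 1, 40), call. = FALSE)
    }
    name <- fields[1]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", name, "' deduplicated", call. = FALSE)
      genes <- unique(genes)
    }
    if (length(genes) == 0) {
      stop("gene set '", name, "' is empty after deduplication", call. = FALSE)
    }
    sets[[name]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional per-set description (recycled).
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample or cell annotation table
#'
#' Sample tables require a `sample_id` column; optional columns are
#' `subtype_label`, `time` (survival time in days, positive) and `event`
#' (0/1/true/false). `time` and `event` must be present together. Cell tables
#' require `cell_id`, `sample_id` and `cell_type`; `group_label` is optional.
#'
#' @param path Path to a TSV file with a header row.
#' @param kind `"sample"` or `"cell"`.
#' @return A tibble with validated, typed columns.
#' @export
read_annotation <- function(path, kind = c("sample", "cell")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- if (kind == "sample") "sample_id" else c("cell_id", "sample_id", "cell_type")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  id_col <- if (kind == "sample") "sample_id" else "cell_id"
  ids <- df[[id_col]]
  if (anyDuplicated(ids)) {
    stop("duplicate ", id_col, ": ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (kind == "sample") {
    has_time <- "time" %in% names(df)
    has_event <- "event" %in% names(df)
    if (has_time != has_event) {
      stop("`time` and `event` must be present together", call. = FALSE)
    }
    if (has_time) {
      time <- suppressWarnings(as.numeric(df$time))
      if (anyNA(time) || any(time <= 0)) {
        stop("`time` must be positive numeric survival time", call. = FALSE)
      }
      df$time <- time
      df$event <- parse_event(df$event)
    }
    df
  } else {
    df
  }
}

parse_event <- function(x) {
  lx <- tolower(trimws(x))
  ok <- lx %in% c("0", "1", "true", "false")
  if (!all(ok)) {
    stop("`event` must be 0/1/true/false; got '", x[!ok][1], "'", call. = FALSE)
  }
  lx %in% c("1", "true")
}
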