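#' Build an expression table
#'
#' The central input container: a non-negative numeric matrix with variables
#' (genes or cells) in rows and samples in columns, plus per-column metadata
#' assigning each sample to a unit (embryo or cell) and a group (cell type,
#' phase, or stage).
#'
#' @param data A data frame whose first column holds row identifiers and whose
#'   remaining columns are numeric sample columns, or a numeric matrix with
#'   rownames.
#' @param col_meta Optional tibble with columns `sample_id` and any of
#'   `unit_id`, `group_label`, `stage`. Rows must cover every sample column.
#' @return An object of class `expr_table`: a list with elements `values`
#'   (matrix), `row_ids`, `col_ids` and `col_meta` (tibble).
#' @examples
#' tab <- expression_table(
#'   tibble::tibble(gene = c("g1", "g2"), s1 = c(1, 3), s2 = c(2, 4))
#' )
#' expression_index(tab, axis = "per_sample")
#' @export
expression_table <- function(data, col_meta = NULL) {
  if (is.matrix(data)) {
    values <- data
    row_ids <- rownames(data) %||% paste0("v", seq_len(nrow(data)))
    col_ids <- colnames(data) %||% paste0("s", seq_len(ncol(data)))
  } else {
    data <- tibble::as_tibble(data)
    assert_that(ncol(data) >= 2L, "`data` needs an id column plus sample columns")
    row_ids <- as.character(data[[1L]])
    values <- as.matrix(data[, -1L, drop = FALSE])
    storage.mode(values) <- "double"
    col_ids <- colnames(data)[-1L]
  }
  assert_that(all(is.finite(values)), "expression values must be finite")
  assert_that(all(values >= 0), "expression values must be non-negative")
  assert_that(!anyDuplicated(row_ids), "row identifiers must be unique")
  assert_that(!anyDuplicated(col_ids), "column identifiers must be unique")
  dimnames(values) <- list(row_ids, col_ids)
  if (is.null(col_meta)) {
    col_meta <- tibble::tibble(sample_id = col_ids, unit_id = col_ids,
                               group_label = "group1")
  } else {
    col_meta <- tibble::as_tibble(col_meta)
    assert_that("sample_id" %in% names(col_meta),
                "col_meta needs a sample_id column")
    assert_that(all(col_ids %in% col_meta$sample_id),
                "col_meta must cover every sample column")
    col_meta <- col_meta[match(col_ids, col_meta$sample_id), , drop = FALSE]
    if (is.null(col_meta$unit_id)) col_meta$unit_id <- col_ids
    if (is.null(col_meta$group_label)) col_meta$group_label <- "group1"
  }
  structure(
    list(values = values, row_ids = row_ids, col_ids = col_ids,
         col_meta = col_meta),
    class = "expr_table"
  )
}

#' @export
print.expr_table <- function(x, ...) {
  cat("<expr_table> ", nrow(x$values), " variables x ", ncol(x$values),
      " samples; groups: ",
      paste(unique(x$col_meta$group_label), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_table <- function(x) dim(x$values)

#' Read a dense expression table from CSV/TSV
#'
#' Expects variables in rows (first column = identifiers) and samples in
#' columns with a header of sample ids.
#'
#' @param file Path to a CSV or TSV file (delimiter inferred from extension).
#' @param meta_file Optional path to a sample-metadata CSV with columns
#'   `sample_id`, `unit_id`, `group_label` and optionally `stage`.
#' @return An [expression_table()].
#' @export
read_expression <- function(file, meta_file = NULL) {
  delim <- if (grepl("\\.tsv$|\\.txt$", file)) "\t" else ","
  df <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  meta <- if (!is.null(meta_file)) {
    readr::read_csv(meta_file, show_col_types = FALSE, progress = FALSE)
  }
  expression_table(df, col_meta = meta)
}

#' Read an expression table from MatrixMarket triplet files
#'
#' @param mtx_file Path to the `.mtx` triplet file.
#' @param row_file,col_file Sidecar files with one identifier per line.
#' @inheritParams read_expression
#' @return An [expression_table()].
#' @export
read_expression_mtx <- function(mtx_file, row_file, col_file,
                                meta_file = NULL) {
  m <- as.matrix(Matrix::readMM(mtx_file))
  rownames(m) <- readr::read_lines(row_file, progress = FALSE)
  colnames(m) <- readr::read_lines(col_file, progress = FALSE)
  meta <- if (!is.null(meta_file)) {
    readr::read_csv(meta_file, show_col_types = FALSE, progress = FALSE)
  }
  expression_table(m, col_meta = meta)
}
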