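#' Niche index of paired expression
#'
#' The niche index (NI) of a gene in a unit (embryo) is the sum of its
#' expression over the two interacting cell types. It serves as the
#' quasi-time axis along which the paired qdODE system evolves.
#'
#' @param g1,g2 Equal-length non-negative expression vectors, one per cell
#'   type.
#' @return The element-wise sum `g1 + g2`.
#' @examples
#' niche_index(c(1, 2), c(4, 1))
#' @export
niche_index <- function(g1, g2) {
  assert_that(length(g1) == length(g2), "g1 and g2 must have equal length")
  assert_that(all(g1 >= 0) && all(g2 >= 0),
              "expression values must be non-negative")
  g1 + g2
}

#' Expression index of a table
#'
#' Per-sample: the total expression over all variables in a sample (the EI of
#' the sample, used as the quasi-time axis for gene networks). Per-row: the
#' total of one variable over all samples (the EI of a gene over cells, used
#' for cell-cell networks).
#'
#' @param table An [expression_table()].
#' @param axis `"per_sample"` (column sums) or `"per_row"` (row sums).
#' @return A named numeric vector.
#' @export
expression_index <- function(table, axis = c("per_sample", "per_row")) {
  axis <- match.arg(axis)
  assert_that(inherits(table, "expr_table"), "`table` must be an expr_table")
  assert_that(length(table$values) > 0L, "empty expression table")
  out <- if (axis == "per_sample") colSums(table$values) else rowSums(table$values)
  if (any(out == 0)) {
    warning("expression index is zero for: ",
            paste(names(out)[out == 0], collapse = ", "), call. = FALSE)
  }
  out
}

#' Serialize observations along an ascending index
#'
#' Sorts an index vector ascending (stable, ties broken by original position)
#' and co-sorts the values. Tied index values are separated by a minimal
#' jitter, `1e-9 * (max - min)`, added to later duplicates so the resulting
#' grid is strictly increasing (distinct grid points are required by the ODE
#' integrator).
#'
#' @param values Numeric vector of observations.
#' @param index Numeric vector of index (NI or EI) values, same length.
#' @return A list of class `indexed_series` with ascending `index`, co-sorted
#'   `values`, and the sorting permutation `order`.
#' @export
serialize_by_index <- function(values, index) {
  assert_that(length(values) == length(index),
              "values and index must have equal length")
  ord <- order(index)  # stable radix/shell sort: ties keep original order
  idx <- index[ord]
  eps <- 1e-9 * (max(idx) - min(idx))
  if (eps == 0) eps <- 1e-9
  for (i in seq_along(idx)[-1]) {
    if (idx[i] <= idx[i - 1]) idx[i] <- idx[i - 1] + eps
  }
  structure(list(index = idx, values = values[ord], order = ord),
            class = "indexed_series")
}

#' Paired gene profiles across units
#'
#' Collapses an expression table with two group labels into per-gene paired
#' profiles: the gene's expression in each cell type per unit (averaging
#' samples mapping to the same unit and group, unweighted) together with its
#' niche index. Units in which the gene is silent in both cell types (NI = 0)
#' are dropped with a warning, since a power law with a negative exponent is
#' undefined at zero.
#'
#' @param table An [expression_table()] whose `col_meta` contains exactly two
#'   `group_label` values; the first level (alphabetically, or as a factor) is
#'   cell type 1.
#' @param genes Optional character vector restricting the genes.
#' @return A tibble with columns `gene_id`, `unit_id`, `g1`, `g2`, `N`.
#' @export
paired_profiles <- function(table, genes = NULL) {
  assert_that(inherits(table, "expr_table"), "`table` must be an expr_table")
  meta <- table$col_meta
  groups <- sort(unique(as.character(meta$group_label)))
  assert_that(length(groups) == 2L,
              "paired profiles need exactly two group labels")
  genes <- genes %||% table$row_ids
  long <- tibble::as_tibble(table$values[genes, , drop = FALSE],
                            rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "value") |>
    dplyr::left_join(meta, by = "sample_id")
  out <- long |>
    dplyr::group_by(.data$gene_id, .data$unit_id, .data$group_label) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(side = ifelse(.data$group_label == groups[1], "g1", "g2")) |>
    dplyr::select(-"group_label") |>
    tidyr::pivot_wider(names_from = "side", values_from = "value") |>
    tidyr::drop_na("g1", "g2") |>
    dplyr::mutate(N = .data$g1 + .data$g2)
  out
}

#' Single-gene paired profile
#'
#' Builds the per-gene profile object consumed by [fit_pairwise()]: vectors
#' `g1`, `g2` and niche index `N`, serialized in ascending NI order. Zero-NI
#' units are dropped (see [paired_profiles()]).
#'
#' @param g1,g2 Expression of the gene in cell types 1 and 2 across units.
#' @param gene_id Identifier carried through to results.
#' @param unit_id Optional unit identifiers.
#' @return A list of class `pair_profile`.
#' @export
pair_profile <- function(g1, g2, gene_id = "gene", unit_id = NULL) {
  assert_that(length(g1) == length(g2), "g1 and g2 must have equal length")
  N <- g1 + g2
  unit_id <- unit_id %||% seq_along(g1)
  drop <- N <= 0
  if (any(drop)) {
    warning(sum(drop), " unit(s) with zero niche index dropped for ", gene_id,
            call. = FALSE)
    g1 <- g1[!drop]; g2 <- g2[!drop]; N <- N[!drop]; unit_id <- unit_id[!drop]
  }
  ser <- serialize_by_index(seq_along(N), N)
  ord <- ser$order
  structure(
    list(gene_id = gene_id, g1 = g1[ord], g2 = g2[ord], N = ser$index,
         unit_id = unit_id[ord], order = ord),
    class = "pair_profile"
  )
}

#' @export
print.pair_profile <- function(x, ...) {
  cat("<pair_profile> ", x$gene_id, ": n = ", length(x$N),
      ", NI range [", signif(min(x$N), 4), ", ", signif(max(x$N), 4), "]\n",
      sep = "")
  invisible(x)
}
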