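#' Transpose an embryo's expression table to the cell view
#'
#' For cell-cell networks within one embryo, cells become the variables and
#' genes the observations: each gene's expression index (its total over all
#' cells, E_j) is the quasi-time axis, and genes are serialized in ascending
#' E_j. Genes with zero total expression carry no index information and are
#' dropped.
#'
#' @param table An [expression_table()] with rows = genes and columns = cells
#'   of one embryo (at least 5 genes).
#' @return An [expression_table()] with rows = cells, columns = genes ordered
#'   by ascending gene EI, and the (jitter-separated) index stored in
#'   attribute `"index"`.
#' @export
cell_view <- function(table) {
  assert_that(inherits(table, "expr_table"), "`table` must be an expr_table")
  assert_that(nrow(table$values) >= 5L, "need at least 5 genes")
  Ej <- rowSums(table$values)
  keep <- Ej > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-expression gene(s) dropped", call. = FALSE)
  }
  vals <- table$values[keep, , drop = FALSE]
  Ej <- Ej[keep]
  ser <- serialize_by_index(seq_along(Ej), Ej)
  tv <- t(vals[ser$order, , drop = FALSE])
  out <- expression_table(tv)
  attr(out, "index") <- ser$index
  out
}

#' Reconstruct a cell-cell interaction network within one embryo
#'
#' Applies the sparse-network machinery ([fit_network()]) to the transposed
#' cell view: cells are nodes, genes (ordered by their expression index) are
#' the observations. Phase labels, when given, annotate the nodes and the
#' per-phase interaction summary; they never influence the fit itself.
#'
#' @param table An [expression_table()]: genes x cells of one embryo.
#' @param phase_labels Optional character vector of cell phases (e.g.
#'   mitotic / RA-responsive / meiotic / oogenesis), one per cell column.
#' @inheritParams fit_network
#' @return A `qd_network` whose `nodes` carry a `phase` column and with an
#'   attribute `phase_summary`: per phase, the number of outgoing activating
#'   (directional synergism) and inhibiting (directional antagonism) edges
#'   and the summed outgoing hubness.
#' @export
fit_cell_network <- function(table, phase_labels = NULL, max_predictors = 5L,
                             lop_order = 3L, seed = 1L, tau = 0.05,
                             starts = 3L) {
  cv <- cell_view(table)
  net <- fit_network(cv, attr(cv, "index"), max_predictors = max_predictors,
                     lop_order = lop_order, seed = seed, tau = tau,
                     starts = starts)
  phases <- tibble::tibble(
    node = table$col_ids,
    phase = phase_labels %||% rep("unknown", length(table$col_ids))
  )
  net$nodes <- dplyr::left_join(net$nodes, phases, by = "node")
  out_sign <- net$edges |>
    dplyr::left_join(phases, by = c(from = "node")) |>
    dplyr::count(.data$phase, .data$sign) |>
    tidyr::pivot_wider(names_from = "sign", values_from = "n",
                       values_fill = 0L)
  summ <- net$nodes |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     total_hubness = sum(.data$hubness), .groups = "drop") |>
    dplyr::left_join(out_sign, by = "phase")
  if (!"+" %in% names(summ)) summ$`+` <- 0L
  if (!"-" %in% names(summ)) summ$`-` <- 0L
  summ <- dplyr::rename(summ, out_synergism = "+", out_antagonism = "-")
  summ[is.na(summ)] <- 0L
  attr(net, "phase_summary") <- summ
  net
}

#' Write the per-phase interaction summary of a cell network
#' @param network A `qd_network` from [fit_cell_network()].
#' @param file Output CSV path.
#' @export
write_phase_summary <- function(network, file) {
  summ <- attr(network, "phase_summary")
  assert_that(!is.null(summ), "network has no phase summary")
  readr::write_csv(summ, file)
  invisible(network)
}
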