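make_cell_table <- function(seed = 4, cells = 8, genes = 30) {
  sim <- simulate_network(m = cells, regulators_per_node = 2,
                          coupling_scale = 1.5, n = genes, seed = seed,
                          noise_sd = 0.05)
  # rows = genes, columns = cells of one embryo
  vals <- t(pmax(sim$values, 1e-6))
  rownames(vals) <- sprintf("g%03d", seq_len(genes))
  colnames(vals) <- sprintf("cell%02d", seq_len(cells))
  list(table = expression_table(vals), sim = sim)
}

test_that("the cell view transposes and orders genes by their index", {
  vals <- matrix(c(2, 3, 1, 2, 5, 2), 3, byrow = TRUE,
                 dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  tab <- expression_table(vals)
  expect_error(cell_view(tab), "at least 5")
  vals5 <- rbind(vals, g4 = c(1, 1), g5 = c(4, 4))
  cv <- cell_view(expression_table(vals5))
  Ej <- rowSums(vals5)
  expect_equal(colnames(cv$values), names(sort(Ej)))
  # gene EI equals the column sums of the transposed view
  expect_equal(unname(colSums(cv$values)), unname(sort(Ej)))
  # transposing twice restores row/column identities (square-enough table)
  big <- matrix(runif(36, 1, 3), 6,
                dimnames = list(paste0("g", 1:6), paste0("c", 1:6)))
  cv2 <- cell_view(expression_table(big))
  back <- cell_view(cv2)
  expect_setequal(rownames(back$values), colnames(cv2$values))
})

test_that("zero-expression genes are dropped from the cell view", {
  vals <- matrix(runif(12, 1, 2), 6,
                 dimnames = list(paste0("g", 1:6), c("c1", "c2")))
  vals[3, ] <- 0
  expect_warning(cv <- cell_view(expression_table(vals)), "dropped")
  expect_equal(ncol(cv$values), 5L)
})

test_that("the cell network is the gene machinery on the transposed table", {
  x <- make_cell_table()
  net_cells <- fit_cell_network(x$table, seed = 2, starts = 1)
  cv <- cell_view(x$table)
  net_direct <- fit_network(cv, attr(cv, "index"), seed = 2, starts = 1)
  expect_equal(net_cells$edges[, c("from", "to", "sign", "weight")],
               net_direct$edges[, c("from", "to", "sign", "weight")])
})

test_that("phase labels annotate nodes and summaries without affecting fits", {
  x <- make_cell_table(seed = 6)
  phases <- rep(c("mitotic", "meiotic"), length.out = ncol(x$table$values))
  net1 <- fit_cell_network(x$table, phases, seed = 3, starts = 1)
  net2 <- fit_cell_network(x$table, rev(phases), seed = 3, starts = 1)
  expect_equal(net1$edges, net2$edges)  # labels never influence the fit
  expect_true("phase" %in% names(net1$nodes))
  summ <- attr(net1, "phase_summary")
  expect_true(all(c("phase", "n_cells", "total_hubness", "out_synergism",
                    "out_antagonism") %in% names(summ)))
  expect_equal(sum(summ$n_cells), ncol(x$table$values))
  # annotations follow the cells under a label permutation
  expect_equal(sort(net1$nodes$phase), sort(net2$nodes$phase))
  # hubness ranking is invariant to cell relabeling through the shared core
  expect_equal(sort(net1$nodes$hubness), sort(net2$nodes$hubness))
})
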