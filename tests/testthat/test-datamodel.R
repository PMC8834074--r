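test_that("niche index is the element-wise pair sum with validation", {
  expect_equal(niche_index(3, 2), 5)
  expect_equal(niche_index(c(0, 0), c(0, 0)), c(0, 0))
  expect_equal(niche_index(c(1, 2), c(4, 1)), c(5, 3))
  expect_equal(order(niche_index(c(1, 2), c(4, 1))), c(2L, 1L))
  expect_error(niche_index(1:3, 1:2), "equal length")
  expect_error(niche_index(c(-1, 0), c(0, 0)), "non-negative")
})

test_that("niche index is linear and symmetric in its arguments", {
  set.seed(11)
  for (i in 1:20) {
    g1 <- runif(8); g2 <- runif(8); a <- runif(1); b <- runif(1)
    expect_equal(niche_index(g1, g2), niche_index(g2, g1))
    expect_equal(niche_index(a * g1, a * g2), a * niche_index(g1, g2))
  }
})

test_that("expression index sums per sample or per row", {
  tab <- expression_table(matrix(c(1, 3, 2, 4), 2,
                                 dimnames = list(c("g1", "g2"),
                                                 c("s1", "s2"))))
  expect_equal(unname(expression_index(tab, "per_sample")), c(4, 6))
  expect_equal(unname(expression_index(tab, "per_row")), c(3, 7))
  tab0 <- expression_table(matrix(c(1, 3, 0, 0), 2,
                                  dimnames = list(c("g1", "g2"),
                                                  c("s1", "s2"))))
  expect_warning(ei <- expression_index(tab0, "per_sample"), "zero")
  expect_equal(unname(ei), c(4, 0))
  expect_error(expression_index(list(), "per_sample"), "expr_table")
})

test_that("serialization sorts ascending, jitters ties, preserves values", {
  s <- serialize_by_index(c(10, 20), c(5, 3))
  expect_equal(s$index, c(3, 5))
  expect_equal(s$values, c(20, 10))
  s2 <- serialize_by_index(1:4, c(1, 2, 3, 4))
  expect_equal(s2$values, 1:4)
  sdup <- serialize_by_index(c(7, 8, 9), c(3, 3, 1))
  expect_true(all(diff(sdup$index) > 0))
  expect_setequal(sdup$values, c(7, 8, 9))
  set.seed(2)
  for (i in 1:10) {
    v <- rnorm(12)
    idx <- sample(rep(1:4, 3))
    out <- serialize_by_index(v, idx)
    expect_true(all(diff(out$index) > 0))
    expect_equal(sort(out$values), sort(v))
  }
})

test_that("expression table validates its invariants", {
  expect_error(expression_table(matrix(c(1, -1), 1)), "non-negative")
  expect_error(expression_table(matrix(c(1, NA), 1)), "finite")
  m <- matrix(1:4, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(expression_table(m), "unique")
})

test_that("paired profiles average within unit and pair the two types", {
  vals <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 2,
                 dimnames = list(c("gA", "gB"),
                                 c("u1_t1", "u1_t2", "u2_t1", "u2_t2")))
  meta <- tibble::tibble(
    sample_id = colnames(vals),
    unit_id = rep(c("u1", "u2"), each = 2),
    group_label = rep(c("type1", "type2"), 2)
  )
  tab <- expression_table(vals, meta)
  pp <- paired_profiles(tab)
  row <- pp[pp$gene_id == "gA" & pp$unit_id == "u1", ]
  expect_equal(row$g1, 1)
  expect_equal(row$g2, 3)
  expect_equal(row$N, 4)
})

test_that("zero-NI units are dropped from a profile with a warning", {
  expect_warning(p <- pair_profile(c(0, 1, 2), c(0, 1, 1)), "zero niche")
  expect_equal(length(p$N), 2L)
  expect_true(all(diff(p$N) > 0))
})

test_that("CSV and MTX readers round-trip an expression table", {
  dir <- withr::local_tempdir()
  vals <- matrix(round(runif(12), 3), 3,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  readr::write_csv(tibble::as_tibble(vals, rownames = "gene_id"),
                   file.path(dir, "e.csv"))
  tab <- read_expression(file.path(dir, "e.csv"))
  expect_equal(tab$values, vals)

  mm <- Matrix::Matrix(vals, sparse = TRUE)
  Matrix::writeMM(mm, file.path(dir, "e.mtx"))
  writeLines(rownames(vals), file.path(dir, "rows.txt"))
  writeLines(colnames(vals), file.path(dir, "cols.txt"))
  tab2 <- read_expression_mtx(file.path(dir, "e.mtx"),
                              file.path(dir, "rows.txt"),
                              file.path(dir, "cols.txt"))
  expect_equal(tab2$values, vals)
})
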