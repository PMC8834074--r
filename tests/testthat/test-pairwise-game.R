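test_that("directional signs follow the significance and magnitude rules", {
  expect_equal(sign_of_dependence(0.5, 1, TRUE), "+")
  expect_equal(sign_of_dependence(-0.5, 1, TRUE), "-")
  expect_equal(sign_of_dependence(5, 1, FALSE), "0")
  expect_equal(sign_of_dependence(-0.03, 1, TRUE, tau = 0.05), "0")
  expect_error(sign_of_dependence(1, 0, TRUE), "> 0")
})

test_that("the eleven interaction classes map as in the qualitative table", {
  expect_equal(classify_table1("+", "+", 1, 1), "symmetric synergism")
  expect_equal(classify_table1("+", "+", 1, 0.5), "asymmetric synergism")
  expect_equal(classify_table1("+", "0"), "directional synergism toward k")
  expect_equal(classify_table1("0", "+"), "directional synergism toward k'")
  expect_equal(classify_table1("+", "-", 1, -1), "altruism toward k")
  expect_equal(classify_table1("-", "+", -1, 1), "altruism toward k'")
  expect_equal(classify_table1("-", "-", -1, -1), "symmetric antagonism")
  expect_equal(classify_table1("-", "-", -1, -0.2), "asymmetric antagonism")
  expect_equal(classify_table1("-", "0"), "directional antagonism toward k")
  expect_equal(classify_table1("0", "-"), "directional antagonism toward k'")
  expect_equal(classify_table1("0", "0"), "coexistence")
  # within 10% relative magnitude counts as symmetric
  expect_equal(classify_table1("+", "+", 1, 0.95), "symmetric synergism")
})

test_that("classification is total over all sign patterns and aggregates", {
  combos <- expand.grid(s12 = c("+", "0", "-"), s21 = c("+", "0", "-"),
                        stringsAsFactors = FALSE)
  cats <- apply(combos, 1, function(r) {
    d12 <- switch(r[["s12"]], "+" = 1, "0" = 0, "-" = -1)
    d21 <- switch(r[["s21"]], "+" = 0.5, "0" = 0, "-" = -0.5)
    aggregate_category(classify_table1(r[["s12"]], r[["s21"]], d12, d21))
  })
  expect_true(all(cats %in% c("synergistic", "directional_synergistic",
                              "altruistic", "antagonistic",
                              "directional_antagonistic", "none")))
  expect_equal(cats[combos$s12 == "0" & combos$s21 == "0"], "none")
  expect_equal(aggregate_category("symmetric synergism"), "synergistic")
  expect_equal(aggregate_category("directional antagonism toward k'"),
               "directional_antagonistic")
  expect_error(aggregate_category("nonsense"), "unknown")
})

test_that("swapping the cell-type labels mirrors the directional classes", {
  swap_sign <- function(s) s
  for (s12 in c("+", "0", "-")) {
    for (s21 in c("+", "0", "-")) {
      d12 <- switch(s12, "+" = 1, "0" = 0, "-" = -1)
      d21 <- switch(s21, "+" = 0.6, "0" = 0, "-" = -0.6)
      a <- classify_table1(s12, s21, d12, d21)
      b <- classify_table1(s21, s12, d21, d12)
      a_sw <- sub("toward k'", "toward_KP", a)
      a_sw <- sub("toward k", "toward k'", a_sw)
      a_sw <- sub("toward_KP", "toward k", a_sw)
      expect_equal(b, a_sw)
    }
  }
})

test_that("gene screening produces one classified row per gene", {
  # three genes: one with directional coupling, two without
  set.seed(42)
  n <- 15
  sims <- list(
    simulate_pairwise(directional_spec(0.5), ar_low(0.02), n, seed = 101,
                      mode = "independent"),
    simulate_null(ar = ar_low(0.02), n = n, seed = 102),
    simulate_null(ar = ar_low(0.02), n = n, seed = 103)
  )
  vals <- do.call(rbind, lapply(sims, function(s)
    pmax(c(s$data$g1, s$data$g2), 1e-6)))
  rownames(vals) <- c("coupled", "null_a", "null_b")
  colnames(vals) <- c(paste0("u", 1:n, "_t1"), paste0("u", 1:n, "_t2"))
  meta <- tibble::tibble(sample_id = colnames(vals),
                         unit_id = rep(paste0("u", 1:n), 2),
                         group_label = rep(c("type1", "type2"), each = n))
  tab <- expression_table(vals, meta)
  sc <- screen_genes(tab, n_perm = 60, seed = 1, starts = 1)
  expect_s3_class(sc, "qd_screen")
  expect_equal(nrow(sc), 3L)
  expect_true(all(c("gene_id", "dep_12", "dep_21", "table1_class",
                    "category5", "LR", "significant") %in% names(sc)))
  counts <- attr(sc, "category_counts")
  expect_equal(sum(counts$n_genes), 3L)
  expect_true(is.finite(attr(sc, "threshold")))
})
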