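test_that("paired simulation is reproducible and respects the noise limit", {
  sp <- directional_spec()
  a <- simulate_pairwise(sp, ar_low(0.05), 12, seed = 7)
  b <- simulate_pairwise(sp, ar_low(0.05), 12, seed = 7)
  expect_identical(a$data, b$data)
  tiny <- simulate_pairwise(sp, ar_low(1e-9), 12, seed = 7)
  expect_lt(max(abs(tiny$data$g1 - tiny$data$g1_true)), 1e-6)
})

test_that("consistent mode reports a niche index equal to the pair sum", {
  sp <- pairwise_spec(c12 = c(0.2, 0.05, 0), c21 = c(0.15, 0.02, 0))
  sim <- simulate_pairwise(sp, ar_low(0.02), 20, seed = 3,
                           mode = "consistent")
  if (sim$truth$mode == "consistent") {
    expect_equal(sim$data$N_true,
                 sim$data$g1_true + sim$data$g2_true, tolerance = 1e-10)
    expect_lt(sim$truth$gap, 1e-3 * 9)
  }
  ind <- simulate_pairwise(sp, ar_low(0.02), 20, seed = 3,
                           mode = "independent")
  expect_equal(ind$truth$mode, "independent")
})

test_that("noisy data recompute the niche index as the noisy sum", {
  sim <- simulate_null(ar = ar_low(0.05), n = 15, seed = 9)
  expect_equal(sim$data$N_obs, sim$data$g1 + sim$data$g2)
  expect_true(all(diff(sim$profile$N) > 0))
})

test_that("simulated residuals reproduce the target AR(1) covariance", {
  ar <- ar1_params(sigma1 = 0.3, sigma2 = 0.25, rho1 = 0.5, rho2 = 0.4,
                   rho12 = 0.3)
  n <- 6
  sp <- pairwise_spec()
  set.seed(1)
  res <- matrix(0, 2000, 2 * n)
  for (b in seq_len(2000)) {
    sim <- simulate_pairwise(sp, ar, n, seed = b, mode = "independent")
    res[b, ] <- c(sim$data$g1 - sim$data$g1_true,
                  sim$data$g2 - sim$data$g2_true)
  }
  emp <- crossprod(res) / nrow(res)
  target <- build_ar1_covariance(ar, n)
  # the covariance is stationary within each block, so Monte-Carlo noise is
  # averaged over entries that share a theoretical value before comparing
  avg_by_value <- function(M) {
    vapply(split(M, round(target, 10)), mean, 0)
  }
  rel <- abs(avg_by_value(emp) - avg_by_value(target)) /
    max(abs(target))
  expect_lt(max(rel), 0.05)
})

test_that("network simulation honours sparsity, scale and determinism", {
  sim0 <- simulate_network(m = 6, regulators_per_node = 0,
                           coupling_scale = 0, n = 20, seed = 2)
  expect_equal(nrow(sim0$truth$edges), 0L)
  sim <- simulate_network(m = 6, regulators_per_node = 2, coupling_scale = 1,
                          n = 20, seed = 2)
  expect_equal(nrow(sim$truth$edges), 12L)
  expect_equal(as.integer(table(sim$truth$edges$target)), rep(2L, 6))
  sim_b <- simulate_network(m = 6, regulators_per_node = 2,
                            coupling_scale = 1, n = 20, seed = 2)
  expect_identical(sim$values, sim_b$values)
})

test_that("module simulation produces the requested design", {
  sm <- simulate_modules(3, genes_per_module = 5, n_per_group = 8, seed = 1)
  expect_equal(dim(sm$table$values), c(15L, 16L))
  expect_equal(as.integer(table(sm$labels)), rep(5L, 3))
  expect_equal(length(sm$index), 16L)
})

test_that("simulations round-trip through the CSV writers and readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_pairwise(directional_spec(), ar_low(0.02), 10, seed = 5)
  write_simulation(sim, dir)
  tab <- read_expression(file.path(dir, "expression.csv"),
                         file.path(dir, "metadata.csv"))
  expect_equal(nrow(tab$values), 1L)
  expect_equal(ncol(tab$values), 20L)
  pp <- paired_profiles(tab)
  expect_equal(nrow(pp), 10L)
})
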