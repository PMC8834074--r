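test_that("partner selection finds a planted basis-driven dependence", {
  set.seed(17)
  grid <- sort(runif(60, 1, 10))
  ab <- cbind(runif(8, 0.3, 1), runif(8, 0.3, 1.1))
  cands <- lapply(1:8, function(i)
    ab[i, 1] * grid^ab[i, 2] + rnorm(60, sd = ifelse(i == 3, 0.3, 0.05)))
  names(cands) <- paste0("c", 1:8)
  # focal generated from candidate 3's Legendre basis integrals plus its own
  # power trend; the source's fluctuations are the identifying signature
  B3 <- qdgame:::node_basis_cpp(grid, matrix(cands[[3]], 1),
                                matrix(range(cands[[3]]), 1), 3L, 100L)
  focal <- 0.8 * grid^0.6 + B3 %*% c(2, -0.5, 0.2) + rnorm(60, sd = 0.02)
  sel <- lasso_select(as.numeric(focal), cands, max_predictors = 3,
                      seed = 1, index = grid)
  expect_true("c3" %in% sel)
  # best-subset oracle over single candidates agrees on the top partner
  sses <- vapply(seq_along(cands), function(i) {
    B <- qdgame:::node_basis_cpp(grid, matrix(cands[[i]], 1),
                                 matrix(range(cands[[i]]), 1), 3L, 100L)
    X <- cbind(grid^0.6, B)
    sum(stats::lm.fit(X, as.numeric(focal))$residuals^2)
  }, 0)
  expect_equal(which.min(sses), 3L)
  expect_true("c3" %in% lasso_select(as.numeric(focal), cands, 1L, seed = 2,
                                     index = grid))
  # the cap is respected
  expect_lte(length(lasso_select(as.numeric(focal), cands, 1L, seed = 1,
                                 index = grid)), 1L)
  expect_error(lasso_select(rep(1, 60), cands, index = grid), "constant")
})

test_that("a single node yields a power fit and no edges", {
  set.seed(5)
  grid <- sort(runif(30, 1, 10))
  vals <- matrix(0.7 * grid^0.6 + rnorm(30, sd = 0.02), 1,
                 dimnames = list("solo", NULL))
  net <- fit_network(vals, grid, seed = 1)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(net$nodes$role, "subordinate")
  fitted_curve <- net$nodes$alpha * grid^net$nodes$beta
  expect_lt(max(abs(sort(fitted_curve) - 0.7 * sort(grid)^0.6)), 0.2)
  expect_equal(unname(net$nodes$hubness), 0)
})

test_that("network fitting is equivariant under node relabeling", {
  sim <- simulate_network(m = 6, regulators_per_node = 2, coupling_scale = 1.5,
                          n = 40, seed = 5, noise_sd = 0.05)
  net1 <- fit_network(sim$values, sim$index, seed = 2)
  perm <- c(4, 2, 6, 1, 3, 5)
  vals2 <- sim$values[perm, ]
  net2 <- fit_network(vals2, sim$index, seed = 2)
  e1 <- sort(paste(net1$edges$from, net1$edges$to, net1$edges$sign))
  e2 <- sort(paste(net2$edges$from, net2$edges$to, net2$edges$sign))
  expect_equal(e1, e2)
})

test_that("per-node incoming edges never exceed the predictor cap", {
  sim <- simulate_network(m = 8, regulators_per_node = 3, coupling_scale = 1.5,
                          n = 40, seed = 9, noise_sd = 0.05)
  net <- fit_network(sim$values, sim$index, max_predictors = 2, seed = 1)
  if (nrow(net$edges) > 0) {
    expect_lte(max(table(net$edges$to)), 2L)
  }
  # decomposition consistency for every fitted node
  for (v in names(net$curves)) {
    cv <- net$curves[[v]]
    if (all(is.finite(cv$mean))) {
      dep_sum <- cv$mean - cv$indep
      incoming <- net$edges[net$edges$to == v, ]
      expect_true(all(is.finite(dep_sum)))
    }
  }
})

test_that("hubness follows the outgoing dependent-to-independent ratio", {
  grid <- seq(1, 5, length.out = 101)
  # hand-built two-node network: one edge a -> b with a known dep curve
  dep_b <- 0.5 * (grid - 1)  # |integral| = 4
  indep_b <- grid             # integral = 12
  net <- structure(list(
    nodes = tibble::tibble(node = c("a", "b")),
    edges = tibble::tibble(from = "a", to = "b", sign = "+",
                           weight = qdgame:::trapz(grid, dep_b),
                           net_dep = dep_b[101],
                           abs_area = qdgame:::trapz(grid, abs(dep_b))),
    grid = grid,
    curves = list(a = list(indep = 0.5 * grid),
                  b = list(indep = indep_b))
  ), class = "qd_network")
  expect_equal(hubness(net, "a"),
               qdgame:::trapz(grid, abs(dep_b)) / qdgame:::trapz(grid, indep_b))
  expect_equal(hubness(net, "b"), 0)
  # exact analytic oracle: both curves are linear, so the ratio is 4 / 12
  expect_equal(hubness(net, "a"), 4 / 12, tolerance = 1e-12)
})

test_that("network roles follow in/out degree patterns", {
  net <- structure(list(
    nodes = tibble::tibble(node = c("hub", "mid", "leaf", "iso")),
    edges = tibble::tibble(from = c("hub", "hub", "mid"),
                           to = c("mid", "leaf", "leaf"))
  ), class = "qd_network")
  roles <- classify_network_roles(net)
  expect_equal(roles$role[roles$node == "hub"], "primary_hub")
  expect_equal(roles$role[roles$node == "mid"], "secondary_hub")
  expect_equal(roles$role[roles$node == "leaf"], "subordinate")
  expect_equal(roles$role[roles$node == "iso"], "subordinate")
})

test_that("module networks are fitted per stage and group", {
  sm <- simulate_modules(2, genes_per_module = 8, n_per_group = 12,
                         noise_sd = 0.1, seed = 6)
  asg <- functional_cluster(sm$table, sm$index, 2, seed = 1, restarts = 1)
  out <- module_network(sm$table, asg, seed = 1, starts = 1)
  expect_equal(nrow(out), 2L)  # one stage x two groups
  nets <- out$network[!vapply(out$network, is.null, TRUE)]
  expect_true(length(nets) >= 1L)
  expect_true(all(vapply(nets, function(nw) nrow(nw$nodes), 0L) == 2L))
  # undersized strata are skipped with a warning
  expect_warning(
    module_network(sm$table, asg,
                   stage_labels = rep(c("a", "b"),
                                      c(3, ncol(sm$table$values) - 3)),
                   seed = 1, starts = 1),
    "fewer than 5")
})

test_that("network writers produce edge CSV and GraphML", {
  sim <- simulate_network(m = 5, regulators_per_node = 1, coupling_scale = 1.5,
                          n = 30, seed = 3, noise_sd = 0.05)
  net <- fit_network(sim$values, sim$index, seed = 1, starts = 1)
  dir <- withr::local_tempdir()
  write_edge_csv(net, file.path(dir, "edges.csv"))
  expect_true(file.exists(file.path(dir, "edges.csv")))
  write_graphml(net, file.path(dir, "net.graphml"))
  g <- igraph::read_graph(file.path(dir, "net.graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), 5)
})
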