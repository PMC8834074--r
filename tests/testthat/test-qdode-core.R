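test_that("Legendre polynomial values match closed forms", {
  expect_equal(lop_evaluate(0, c(-0.7, 0.2, 1)), rep(1, 3))
  expect_equal(lop_evaluate(1, 0.3), 0.3)
  expect_equal(lop_evaluate(2, 0.5), -0.125)
  x <- seq(-1, 1, by = 0.25)
  expect_equal(lop_evaluate(3, x), (5 * x^3 - 3 * x) / 2)
  expect_equal(lop_evaluate(4, x), (35 * x^4 - 30 * x^2 + 3) / 8)
  expect_error(lop_evaluate(2, 1.5), "\\[-1, 1\\]")
})

test_that("independent rate is the derivative of the power curve", {
  expect_equal(independent_rate(2, 0.5, 4), 0.5)
  expect_equal(independent_rate(3, 1, c(1, 5, 9)), rep(3, 3))
  # central finite-difference oracle
  h <- 1e-6
  for (p in list(c(2, 0.5, 4), c(0.7, 1.6, 2.5), c(1.2, -0.4, 7))) {
    fd <- (p[1] * (p[3] + h)^p[2] - p[1] * (p[3] - h)^p[2]) / (2 * h)
    expect_equal(independent_rate(p[1], p[2], p[3]), fd, tolerance = 1e-6)
  }
  expect_error(independent_rate(1, 1, -2), "> 0")
})

test_that("dependent rate equals direct polynomial summation", {
  b <- lop_basis(3, 0, 10)
  expect_equal(dependent_rate(c(0, 0, 0), 3.7, b), 0)
  expect_equal(dependent_rate(c(2, 0, 0), 5, b), 0)  # P1 at the midpoint
  # brute-force oracle with explicit polynomial formulas
  set.seed(3)
  for (i in 1:10) {
    cf <- rnorm(3)
    x <- runif(1, 0, 10)
    u <- 2 * (x - 0) / 10 - 1
    direct <- cf[1] * u + cf[2] * (3 * u^2 - 1) / 2 +
      cf[3] * (5 * u^3 - 3 * u) / 2
    expect_equal(dependent_rate(cf, x, b), direct, tolerance = 1e-12)
  }
  expect_error(dependent_rate(numeric(0), 1, b), "non-empty")
})

test_that("uncoupled systems integrate to the closed-form power curve", {
  spec <- qdode_spec("v", 2, 0.5)
  grid <- seq(1, 10, length.out = 50)
  tr <- solve_qdode(spec, grid)
  expect_lt(max(abs(tr[, 1] - 2 * grid^0.5)), 1e-6)
  # beta = 0 gives a constant trajectory equal to the initial value
  spec0 <- qdode_spec("v", 2, 0, initial = 3.3)
  expect_equal(unname(solve_qdode(spec0, grid)[, 1]), rep(3.3, 50))
})

test_that("RK4 integration has fourth-order convergence", {
  spec <- qdode_spec("v", 2, 0.5)
  grid <- seq(1, 10, length.out = 50)
  # nsub chosen so halving the sub-step size exactly doubles the step count
  e1 <- max(abs(solve_qdode(spec, grid, nsub = 98)[, 1] - 2 * grid^0.5))
  e2 <- max(abs(solve_qdode(spec, grid, nsub = 196)[, 1] - 2 * grid^0.5))
  expect_gte(e1 / e2, 8)
})

test_that("solutions are stable under interior grid refinement", {
  spec <- pairwise_spec(c12 = c(0.3, 0.1, 0), c21 = c(-0.2, 0, 0.05))
  spec <- qdgame:::anchor_domains(spec, seq(1, 10, length.out = 30))
  g1 <- seq(1, 10, length.out = 30)
  g2 <- sort(unique(c(g1, seq(1.2, 9.7, length.out = 41))))
  s1 <- solve_qdode(spec, g1, nsub = 400)
  s2 <- solve_qdode(spec, g2, nsub = 400)
  expect_lt(max(abs(s2[match(g1, g2), ] - s1)), 1e-6)
})

test_that("mirror-symmetric systems give identical trajectories", {
  cc <- c(0.25, 0.1, 0)
  spec <- pairwise_spec(alpha = c(0.6, 0.6), beta = c(0.8, 0.8),
                        c12 = cc, c21 = cc)
  tr <- solve_qdode(spec, seq(1, 8, length.out = 25))
  expect_equal(tr[, 1], tr[, 2], tolerance = 1e-10)
})

test_that("decomposition components sum to the trajectory", {
  spec <- pairwise_spec(c12 = c(0.4, 0.1, 0), c21 = c(-0.3, 0.05, 0))
  grid <- seq(1, 10, length.out = 40)
  spec <- qdgame:::anchor_domains(spec, grid)
  dec <- decompose_qdode(spec, grid)
  tr <- solve_qdode(spec, grid)
  recon <- dec$indep
  for (e in seq_len(nrow(dec$edges))) {
    v <- match(dec$edges$target[e], spec$node_ids)
    recon[, v] <- recon[, v] + dec$dep[, e]
  }
  expect_lt(max(abs(dec$mean - recon)), 1e-12)
  expect_lt(max(abs(dec$mean - tr)), 1e-8)
  # no edges: dependent curves are identically zero
  dec0 <- decompose_qdode(qdode_spec(c("a", "b"), c(1, 1), c(0.5, 0.7)),
                          grid)
  expect_equal(dec0$mean, dec0$indep)
})

test_that("negating a pinned edge's coefficients negates its component", {
  ed <- tibble::tibble(target = "a", source = "b",
                       coefs = list(c(0.4, -0.2, 0.1)), lo = 0.5, hi = 6,
                       pinned = 1L, src_alpha = 0.5, src_beta = 0.9)
  grid <- seq(1, 9, length.out = 30)
  sp1 <- qdode_spec(c("a", "b"), c(1, 0.5), c(0.6, 0.9), ed)
  ed2 <- ed
  ed2$coefs <- list(-c(0.4, -0.2, 0.1))
  sp2 <- qdode_spec(c("a", "b"), c(1, 0.5), c(0.6, 0.9), ed2)
  d1 <- decompose_qdode(sp1, grid)
  d2 <- decompose_qdode(sp2, grid)
  expect_equal(d1$dep[, 1], -d2$dep[, 1], tolerance = 1e-12)
})

test_that("invalid system specifications are rejected", {
  expect_error(qdode_spec("a", -1, 0.5), "alpha")
  expect_error(
    qdode_spec(c("a", "b"), c(1, 1), c(1, 1),
               tibble::tibble(target = "a", source = "a",
                              coefs = list(1:3), lo = 0, hi = 1)),
    "self-edges")
  spec <- qdode_spec("a", 1, 0.5)
  expect_error(solve_qdode(spec, c(2, 1)), "increasing")
  expect_error(solve_qdode(spec, c(0, 1)), "positive")
})
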