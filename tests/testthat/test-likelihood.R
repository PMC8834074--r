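test_that("bivariate AR(1) covariance has the prescribed block structure", {
  S <- build_ar1_covariance(ar1_params(1, 1, 0, 0, 0), 2)
  expect_equal(S, diag(4))
  S3 <- build_ar1_covariance(ar1_params(1, 1, 0.5, 0.5, 0), 3)
  expect_equal(S3[1:3, 1:3],
               matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3))
  expect_error(ar1_params(1, 1, 1.2), "rho")
})

test_that("the Cholesky PD check agrees with an eigenvalue oracle", {
  # positive definiteness is a checked invariant: for admissible parameters
  # the factorization succeeds, and when it refuses (rho12 too large for the
  # serial correlations) the smallest eigenvalue is indeed non-positive
  set.seed(8)
  n_pd <- 0L
  for (i in 1:100) {
    p <- ar1_params(sigma1 = runif(1, 0.1, 2), sigma2 = runif(1, 0.1, 2),
                    rho1 = runif(1, -0.8, 0.8), rho2 = runif(1, -0.8, 0.8),
                    rho12 = runif(1, -0.4, 0.4))
    S <- build_ar1_covariance(p, 6, check = FALSE)
    expect_equal(S, t(S))
    lam_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    accepted <- tryCatch({ build_ar1_covariance(p, 6); TRUE },
                         error = function(e) FALSE)
    if (accepted) {
      n_pd <- n_pd + 1L
      expect_gt(lam_min, 0)
    } else {
      expect_lte(lam_min, 1e-8)
    }
  }
  expect_gt(n_pd, 50L)  # most of the moderate box is admissible
})

test_that("gaussian log-likelihood matches dense brute-force evaluation", {
  expect_equal(gaussian_loglik(rep(0, 5), diag(5)), -5 / 2 * log(2 * pi))
  set.seed(13)
  for (i in 1:20) {
    p <- ar1_params(runif(1, .5, 2), runif(1, .5, 2), runif(1, -.7, .7),
                    runif(1, -.7, .7), runif(1, -.3, .3))
    S <- build_ar1_covariance(p, 3)
    r <- rnorm(6)
    brute <- -0.5 * (6 * log(2 * pi) + log(det(S)) +
                       drop(t(r) %*% solve(S) %*% r))
    expect_equal(gaussian_loglik(r, S), brute, tolerance = 1e-10)
    # compiled path agrees with the R path (dual route)
    expect_equal(-qdgame:::ar1_negll2_cpp(r[1:3], r[4:6], p$sigma1, p$sigma2,
                                          p$rho1, p$rho2, p$rho12),
                 brute, tolerance = 1e-8)
  }
  # scaling the covariance by c shifts the log-density by -(d/2) log c
  S <- build_ar1_covariance(ar1_params(1, 1, 0.3, 0.3, 0.1), 4)
  expect_equal(gaussian_loglik(rep(0, 8), 2 * S),
               gaussian_loglik(rep(0, 8), S) - 4 * log(2))
})

test_that("univariate AR(1) analytic likelihood matches the dense one", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    s <- runif(1, 0.3, 2)
    rho <- runif(1, -0.8, 0.8)
    r <- rnorm(n)
    S <- s^2 * rho^abs(outer(1:n, 1:n, "-"))
    expect_equal(-qdgame:::ar1_negll1_cpp(r, s, rho), gaussian_loglik(r, S),
                 tolerance = 1e-10)
  }
})

test_that("full fit dominates the null fit on any dataset", {
  sp <- directional_spec()
  for (s in 1:5) {
    sim <- simulate_pairwise(sp, ar_low(0.03), 20, seed = s,
                             mode = "independent")
    fit <- fit_pairwise(sim$profile, seed = 1, starts = 2, maxit = 800)
    expect_gte(fit$loglik, fit$null_fit$loglik - 1e-6)
    expect_equal(fit$n_params - fit$null_fit$n_params, 2L * 3L)
  }
})

test_that("the optimizer attains at least the generating-parameter likelihood", {
  # on no-interaction data the null model's own generating parameters are a
  # feasible point; the fitted likelihood must not fall below it
  ar <- ar_low(0.05)
  sim <- simulate_null(ar = ar, n = 30, seed = 7)
  prof <- sim$profile
  fit0 <- fit_pairwise_null(prof, seed = 1, starts = 3)
  tp <- qdgame:::pair_par_pack(c(0.6, 0.5), c(0.7, 0.8), rep(0, 3), rep(0, 3),
                               ar, 3L, TRUE)
  ll_truth <- -qdgame:::pair_negll_cpp(tp, prof$N, prof$g1, prof$g2, 3L, TRUE,
                                       range(prof$g2), range(prof$g1), 100L)
  expect_gte(fit0$loglik, ll_truth - 1e-6)
})

test_that("null fit recovers the marginal power laws on null data", {
  sim <- simulate_null(ar = ar_low(0.01), n = 50, seed = 3)
  fit0 <- fit_pairwise_null(sim$profile, seed = 1, starts = 3)
  expect_lt(fit_rmse(fit0, sim), 0.05)
})

test_that("the permutation LR test is deterministic and non-negative", {
  sim <- simulate_null(ar = ar_low(0.05), n = 15, seed = 2)
  t1 <- lr_interaction_test(sim$profile, n_perm = 19, seed = 4, starts = 0,
                            maxit = 300, cycles = 1, polish = FALSE,
                            return_perms = TRUE)
  t2 <- lr_interaction_test(sim$profile, n_perm = 19, seed = 4, starts = 0,
                            maxit = 300, cycles = 1, polish = FALSE,
                            return_perms = TRUE)
  expect_gte(t1$LR, 0)
  expect_identical(t1$LR, t2$LR)
  expect_identical(t1$perm_LR, t2$perm_LR)
  expect_error(lr_interaction_test(sim$profile, n_perm = 5), ">= 19")
})

test_that("profiles that are too short are rejected", {
  expect_error(fit_pairwise(list(g1 = 1:3, g2 = 1:3, N = 2 * (1:3))),
               "at least 5")
})
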