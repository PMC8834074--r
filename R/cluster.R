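#' Power-equation-based functional clustering of genes
#'
#' Fits a K-component mixture whose component means are power curves in the
#' expression index (one curve per cell-type group per module) with
#' independent Gaussian residuals (one residual variance per module), by EM.
#' Hard module labels are the maximum-posterior assignments. The full AR(1)
#' residual structure is reserved for the qdODE likelihoods; clustering is a
#' screening step.
#'
#' EM details: initialization by k-means on per-gene log-log slope/intercept
#' features; convergence when the change in mixture log-likelihood falls
#' below `1e-6`; at most 200 iterations; `restarts` random restarts keeping
#' the best log-likelihood. The M-step profiles out `alpha` in closed form
#' and maximizes over `beta` by Brent search, so the mixture log-likelihood
#' is non-decreasing across iterations.
#'
#' @param table An [expression_table()]; rows are genes.
#' @param index Numeric vector of expression-index values, one per sample
#'   column (typically `expression_index(table, "per_sample")` computed on
#'   the full gene complement).
#' @param K Number of modules (>= 1).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param restarts Number of EM restarts (default 5).
#' @return A list of class `module_assignment` with `K`, `labels` (named
#'   integer vector), `module_fits` (tibble: module, group, alpha, beta),
#'   `sigma`, `pi`, `loglik`, `aic`, `n_params`, `converged`, `ll_trace`.
#' @export
functional_cluster <- function(table, index, K, seed = 1L, restarts = 5L) {
  assert_that(inherits(table, "expr_table"), "`table` must be an expr_table")
  assert_that(K >= 1L, "K must be >= 1")
  m <- nrow(table$values)
  assert_that(K <= m, "K exceeds the number of genes")
  assert_that(length(index) == ncol(table$values),
              "`index` must have one entry per sample column")

  groups <- sort(unique(as.character(table$col_meta$group_label)))
  G <- length(groups)
  # per-group data: genes x samples value matrix and ascending index
  dat <- lapply(groups, function(g) {
    cols <- which(table$col_meta$group_label == g)
    ser <- serialize_by_index(cols, index[cols])
    list(x = ser$index, y = table$values[, cols[ser$order], drop = FALSE])
  })
  n_tot <- sum(vapply(dat, function(d) length(d$x), 0L))

  # per-gene log-log features for initialization
  feats <- do.call(cbind, lapply(dat, function(d) {
    ylog <- d$y
    ylog[ylog <= 0] <- min(ylog[ylog > 0], 1) / 2
    t(apply(ylog, 1L, function(yy) coef(lm(log(yy) ~ log(d$x)))))
  }))
  feats[!is.finite(feats)] <- 0

  fit_curve <- function(x, y_mat, w, wyy_tot) {
    # weighted power fit over stacked gene rows: profile alpha in closed
    # form, Brent on beta; sufficient statistics make each objective
    # evaluation O(n)
    sw <- sum(w)
    if (sw <= 0) return(c(alpha = 1, beta = 0, rss = 0))
    wy <- as.numeric(w %*% y_mat)  # weighted sums per sample point
    sse_b <- function(b) {
      xb <- x^b
      denom <- sw * sum(xb * xb)
      a <- max(sum(wy * xb) / denom, 1e-12)
      wyy_tot - 2 * a * sum(wy * xb) + a^2 * sw * sum(xb * xb)
    }
    br <- stats::optimize(sse_b, lower = -5, upper = 5, tol = 1e-9)
    b <- br$minimum
    xb <- x^b
    a <- max(sum(wy * xb) / (sw * sum(xb * xb)), 1e-12)
    c(alpha = a, beta = b,
      rss = wyy_tot - 2 * a * sum(wy * xb) + a^2 * sw * sum(xb * xb))
  }

  wyy_rows <- lapply(dat, function(d) rowSums(d$y^2))

  run_em <- function(labels0) {
    ab <- array(NA_real_, c(K, G, 2L))
    sig2 <- rep(1, K)
    pi_k <- rep(1 / K, K)
    resp <- matrix(0, m, K)
    for (k in seq_len(K)) resp[labels0 == k, k] <- 1
    resp <- resp + 1e-6
    resp <- resp / rowSums(resp)
    ll_old <- -Inf
    ll_trace <- numeric(0)
    converged <- FALSE
    for (iter in seq_len(200L)) {
      # M-step
      for (k in seq_len(K)) {
        w <- resp[, k]
        rss_k <- 0
        for (g in seq_len(G)) {
          cf <- fit_curve(dat[[g]]$x, dat[[g]]$y, w, sum(w * wyy_rows[[g]]))
          ab[k, g, ] <- cf[1:2]
          rss_k <- rss_k + cf[[3L]]
        }
        sig2[k] <- max(rss_k / (sum(w) * n_tot), 1e-10)
        pi_k[k] <- sum(w) / m
      }
      # E-step: per-gene component log-densities
      logd <- matrix(0, m, K)
      for (k in seq_len(K)) {
        for (g in seq_len(G)) {
          mu <- ab[k, g, 1L] * dat[[g]]$x^ab[k, g, 2L]
          res2 <- rowSums(sweep(dat[[g]]$y, 2L, mu)^2)
          nk <- length(dat[[g]]$x)
          logd[, k] <- logd[, k] -
            0.5 * (nk * log(2 * pi * sig2[k]) + res2 / sig2[k])
        }
        logd[, k] <- logd[, k] + log(pi_k[k])
      }
      mx <- apply(logd, 1L, max)
      ll <- sum(mx + log(rowSums(exp(logd - mx))))
      resp <- exp(logd - mx)
      resp <- resp / rowSums(resp)
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) < 1e-6) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    list(ab = ab, sig2 = sig2, pi = pi_k, resp = resp, ll = ll,
         ll_trace = ll_trace, converged = converged)
  }

  best <- NULL
  for (rs in seq_len(max(1L, restarts))) {
    set.seed(child_seed(seed, rs))
    labels0 <- if (K == 1L) rep(1L, m) else {
      km <- tryCatch(kmeans(feats, centers = K, nstart = 5L),
                     error = function(e) NULL)
      if (is.null(km)) sample(rep_len(seq_len(K), m)) else km$cluster
    }
    em <- run_em(labels0)
    if (is.null(best) || em$ll > best$ll) best <- em
  }
  if (!best$converged) {
    warning("EM did not converge within 200 iterations; best iterate returned",
            call. = FALSE)
  }

  labels <- max.col(best$resp, ties.method = "first")
  n_params <- K * 2L * G + K + (K - 1L)
  fits <- tidyr::expand_grid(module = seq_len(K), group = groups) |>
    dplyr::mutate(
      alpha = purrr::map2_dbl(.data$module, .data$group,
                              ~ best$ab[.x, match(.y, groups), 1L]),
      beta = purrr::map2_dbl(.data$module, .data$group,
                             ~ best$ab[.x, match(.y, groups), 2L])
    )
  structure(
    list(K = K, labels = setNames(labels, table$row_ids),
         module_fits = fits, sigma = sqrt(best$sig2), pi = best$pi,
         loglik = best$ll, aic = -2 * best$ll + 2 * n_params,
         n_params = n_params, converged = best$converged,
         ll_trace = best$ll_trace, groups = groups),
    class = "module_assignment"
  )
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("<module_assignment> K = ", x$K, ", loglik = ", signif(x$loglik, 6),
      ", AIC = ", signif(x$aic, 6), "\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' @method tidy module_assignment
#' @export
tidy.module_assignment <- function(x, ...) {
  tibble::tibble(gene_id = names(x$labels), module = unname(x$labels))
}

#' @method glance module_assignment
#' @export
glance.module_assignment <- function(x, ...) {
  tibble::tibble(K = x$K, loglik = x$loglik, aic = x$aic,
                 n_params = x$n_params, converged = x$converged)
}

#' Select the number of modules by AIC
#'
#' Runs [functional_cluster()] over a range of K and returns the
#' minimum-AIC assignment.
#'
#' @inheritParams functional_cluster
#' @param K_range Integer vector of candidate module counts.
#' @return The selected `module_assignment`, with an `aic_table` attribute
#'   (tibble of K, loglik, aic).
#' @export
select_module_count <- function(table, index, K_range, seed = 1L,
                                restarts = 5L) {
  assert_that(length(K_range) >= 1L, "K_range must be non-empty")
  fits <- lapply(K_range, function(K)
    functional_cluster(table, index, K, seed = seed, restarts = restarts))
  aics <- vapply(fits, function(f) f$aic, 0)
  best <- fits[[which.min(aics)]]
  attr(best, "aic_table") <- tibble::tibble(
    K = as.integer(K_range),
    loglik = vapply(fits, function(f) f$loglik, 0),
    aic = aics
  )
  best
}
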