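# Shared simulation scenarios and metric helpers.

# Default residual model for simulation studies: low measurement noise on
# averaged expression profiles, mild serial and cross-type correlation.
ar_low <- function(sigma = 0.01) {
  ar1_params(sigma1 = sigma, rho1 = 0.3, rho12 = 0.2)
}

# One-sided directional coupling used for the recovery studies: cell type 2
# activates type 1, type 1 is neutral to type 2.
directional_spec <- function(strength = 0.5) {
  pairwise_spec(c12 = c(strength, 0.12 * strength / 0.5, 0), c21 = NULL)
}

# Symmetric coupling for the power study.
symmetric_spec <- function(strength = 0.5) {
  cc <- c(strength, 0.12 * strength / 0.5, 0)
  pairwise_spec(c12 = cc, c21 = cc)
}

# RMSE of fitted mean curves against the generating (noise-free) means,
# matched per unit through the observed-NI ordering.
fit_rmse <- function(fit, sim) {
  keep <- sim$data$N_obs > 0
  ot <- order(sim$data$N_obs[keep])
  truth <- cbind(sim$data$g1_true[keep][ot], sim$data$g2_true[keep][ot])
  sqrt(mean((fit$decomposition$mean - truth)^2))
}

# Directed-edge support metrics of a fitted network against a simulated one.
edge_metrics <- function(net, sim) {
  te <- paste(sim$truth$edges$source, sim$truth$edges$target)
  fe <- paste(net$edges$from, net$edges$to)
  tp <- length(intersect(te, fe))
  prec <- tp / max(length(fe), 1L)
  rec <- tp / max(length(te), 1L)
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  m <- match(fe, te)
  ok <- !is.na(m)
  sign_acc <- if (any(ok)) {
    mean(net$edges$sign[ok] == sim$truth$edges$sign[m[ok]])
  } else NA_real_
  list(precision = prec, recall = rec, f1 = f1, sign_acc = sign_acc,
       n_edges = length(fe), n_true = length(te))
}

# Adjusted Rand index between two labelings (independent of mclust).
adj_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}
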