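# Internal numerical helpers.

# Trapezoidal quadrature on an (ascending) grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Derive a child seed (< 2^31) from a base seed and a stream label.
# Double-precision arithmetic: the product exceeds 32-bit integer range but
# stays exact below 2^53.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 1009) %%
               2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_qd <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_qd(msg)
  invisible(TRUE)
}

# Lean power-law seed (alpha, beta) without inference: log-log least squares
# then one profiled Brent refinement. Used by internal seeding paths.
power_seed <- function(x, y) {
  keep <- is.finite(x) & is.finite(y) & x > 0
  x <- x[keep]; y <- y[keep]
  ylog <- y
  if (any(y <= 0)) {
    pos <- y[y > 0]
    if (length(pos) == 0L) return(c(alpha = 1e-8, beta = 0))
    ylog[y <= 0] <- min(pos) / 2
  }
  lx <- log(x)
  cf <- stats::.lm.fit(cbind(1, lx), log(ylog))$coefficients
  b <- cf[2L]
  sse_b <- function(bb) {
    xb <- x^bb
    a <- sum(y * xb) / sum(xb * xb)
    s <- sum((y - a * xb)^2)
    if (is.finite(s)) s else 1e300
  }
  b <- stats::optimize(sse_b, lower = b - 2, upper = b + 2, tol = 1e-10)$minimum
  a <- sum(y * x^b) / sum(x^(2 * b))
  if (!is.finite(a) || a <= 0) a <- exp(cf[1L])
  c(alpha = a, beta = b)
}
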