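#' Fit an allometric power law
#'
#' Fits `y = alpha * x^beta` by least squares on the original scale,
#' initialized by ordinary least squares on `(log x, log y)`. Allometric
#' part-whole scaling of a gene's expression in one cell type against the
#' niche index (or of one gene against the expression index) is the
#' independent-component model of every qdODE in this package.
#'
#' Zeros in `y` are handled at the log-log initialization stage only, by
#' offsetting them with half the smallest positive value of the series; the
#' final fit minimizes untransformed SSE so the estimate is insensitive to
#' the offset.
#'
#' @param series An `indexed_series` (see [serialize_by_index()]), or anything
#'   with elements `index` and `values`; alternatively a data frame with
#'   columns `index` and `values`.
#' @return A list of class `power_fit` with `alpha` (> 0), `beta`, `sse`,
#'   `r2`, and `p_value` (slope test of the log-log regression).
#' @examples
#' s <- serialize_by_index(2 * c(1, 4, 9)^0.5, c(1, 4, 9))
#' fit_power_law(s)
#' @export
fit_power_law <- function(series) {
  if (is.data.frame(series)) series <- list(index = series$index,
                                            values = series$values)
  x <- as.numeric(series$index)
  y <- as.numeric(series$values)
  keep <- is.finite(x) & is.finite(y) & x > 0
  x <- x[keep]; y <- y[keep]
  assert_that(length(x) >= 3L, "need at least 3 usable points")
  assert_that(diff(range(x)) > 0, "index is constant")

  ylog <- y
  if (any(y <= 0)) {
    pos <- y[y > 0]
    assert_that(length(pos) >= 1L, "all values are zero")
    ylog[y <= 0] <- min(pos) / 2
  }
  ll <- lm(log(ylog) ~ log(x))
  a0 <- exp(coef(ll)[[1L]])
  b0 <- coef(ll)[[2L]]
  p_value <- summary(ll)$coefficients[2L, 4L]

  # alpha is profiled out in closed form; beta by iterated Brent search
  # re-centered on the previous optimum (bracket +/- 2, then +/- 0.25)
  beta_sse <- function(b) {
    xb <- x^b
    if (!all(is.finite(xb))) return(1e300)
    a <- sum(y * xb) / sum(xb * xb)
    sum((y - a * xb)^2)
  }
  beta <- b0
  for (half in c(2, 0.25)) {
    br <- stats::optimize(beta_sse, lower = beta - half, upper = beta + half,
                          tol = 1e-12)
    beta <- br$minimum
  }
  alpha <- sum(y * x^beta) / sum(x^(2 * beta))
  if (!is.finite(alpha) || alpha <= 0) {
    alpha <- a0
    beta <- b0
  }
  sse <- sum((y - alpha * x^beta)^2)
  sst <- sum((y - mean(y))^2)
  structure(
    list(alpha = alpha, beta = beta, sse = sse,
         r2 = if (sst > 0) 1 - sse / sst else NA_real_,
         p_value = p_value, n = length(x)),
    class = "power_fit"
  )
}

#' @export
print.power_fit <- function(x, ...) {
  cat("<power_fit> y = ", signif(x$alpha, 5), " * x^", signif(x$beta, 5),
      "  (sse ", signif(x$sse, 4), ", r2 ", signif(x$r2, 3), ", p ",
      signif(x$p_value, 3), ")\n", sep = "")
  invisible(x)
}

#' @method tidy power_fit
#' @export
tidy.power_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "beta"),
                 estimate = c(x$alpha, x$beta))
}

#' @method glance power_fit
#' @export
glance.power_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, r2 = x$r2, p_value = x$p_value, n = x$n)
}
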