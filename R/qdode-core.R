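#' Legendre orthogonal polynomial value
#'
#' Evaluates the Legendre polynomial of a given order on `[-1, 1]` by the
#' Bonnet recurrence. These polynomials are the nonparametric basis for the
#' dependent (interaction) rate functions.
#'
#' @param order_index Polynomial order (0 = constant, 1 = identity, ...).
#' @param x Evaluation points in `[-1, 1]` (vectorized).
#' @return Numeric vector of polynomial values.
#' @examples
#' lop_evaluate(2, 0.5) # (3 * 0.25 - 1) / 2
#' @export
lop_evaluate <- function(order_index, x) {
  assert_that(order_index >= 0L, "order_index must be >= 0")
  assert_that(all(abs(x) <= 1 + 1e-12), "x must lie in [-1, 1]")
  lop_eval_cpp(as.integer(order_index), pmin(pmax(as.numeric(x), -1), 1))
}

#' Legendre basis descriptor
#'
#' @param order Basis order (number of non-constant polynomials used).
#' @param lo,hi Domain endpoints mapped affinely onto `[-1, 1]`.
#' @return A list of class `lop_basis`.
#' @export
lop_basis <- function(order, lo, hi) {
  assert_that(order >= 1L, "order must be >= 1")
  assert_that(lo < hi, "need lo < hi")
  structure(list(order = as.integer(order), lo = lo, hi = hi),
            class = "lop_basis")
}

#' Independent expression rate
#'
#' The index-derivative of the allometric power curve `alpha * N^beta`,
#' i.e. `alpha * beta * N^(beta - 1)`: the rate at which a node's expression
#' changes with the index when it is unaffected by any other node.
#'
#' @param alpha,beta Power-curve parameters.
#' @param N Index value(s), strictly positive.
#' @export
independent_rate <- function(alpha, beta, N) {
  assert_that(all(N > 0), "N must be > 0")
  alpha * beta * N^(beta - 1)
}

#' Dependent expression rate
#'
#' The Legendre-polynomial expansion of the directed influence of a source
#' node on a target, evaluated at the source's current value. The constant
#' term is excluded (orders run 1..length(coeffs)): a constant dependent rate
#' is not identifiable against the independent power term. Source values
#' outside the basis domain are clamped to the boundary.
#'
#' @param coeffs Coefficient vector (order r = length).
#' @param source_value Source-node value(s).
#' @param basis A [lop_basis()] whose `order` equals `length(coeffs)`.
#' @export
dependent_rate <- function(coeffs, source_value, basis) {
  assert_that(length(coeffs) >= 1L, "coeffs must be non-empty")
  assert_that(inherits(basis, "lop_basis"), "`basis` must be a lop_basis")
  assert_that(length(coeffs) == basis$order,
              "length(coeffs) must equal basis$order")
  u <- 2 * (source_value - basis$lo) / (basis$hi - basis$lo) - 1
  u <- pmin(pmax(u, -1), 1)
  out <- 0
  for (r in seq_along(coeffs)) out <- out + coeffs[r] * lop_eval_cpp(r, u)
  out
}

#' Construct a qdODE system specification
#'
#' Parameterizes a quasi-dynamic ODE system: per node the `(alpha, beta)` of
#' the power curve whose index-derivative is its independent rate, and per
#' directed edge (`target <- source`) a Legendre coefficient vector together
#' with the basis domain of the source values.
#'
#' @param node_ids Character vector of node names.
#' @param alpha,beta Numeric vectors, one entry per node (`alpha > 0`).
#' @param edges A tibble/data.frame with columns `target`, `source` (node
#'   ids), `coefs` (list-column of length-`lop_order` numeric vectors), and
#'   optionally `lo`, `hi` (basis domains; required for solving). May be
#'   `NULL` for a system with no interactions.
#' @param lop_order Legendre basis order shared by all edges (default 3).
#' @param initial Optional per-node values at the smallest index point; if
#'   `NULL`, the power-curve values at the first grid point are used when
#'   solving.
#' @return A list of class `qdode_spec`.
#' @export
qdode_spec <- function(node_ids, alpha, beta, edges = NULL, lop_order = 3L,
                       initial = NULL) {
  m <- length(node_ids)
  assert_that(length(alpha) == m && length(beta) == m,
              "alpha and beta need one entry per node")
  assert_that(all(alpha > 0), "alpha must be > 0")
  if (is.null(edges)) {
    edges <- tibble::tibble(target = character(), source = character(),
                            coefs = list(), lo = numeric(), hi = numeric())
  } else {
    edges <- tibble::as_tibble(edges)
    assert_that(all(c("target", "source", "coefs") %in% names(edges)),
                "edges needs target, source, coefs columns")
    assert_that(all(edges$target %in% node_ids) &&
                all(edges$source %in% node_ids), "edge endpoints must be nodes")
    assert_that(!any(edges$target == edges$source), "self-edges not allowed")
    assert_that(all(lengths(edges$coefs) == lop_order),
                "each coefficient vector must have length lop_order")
  }
  structure(
    list(node_ids = node_ids, alpha = setNames(alpha, node_ids),
         beta = setNames(beta, node_ids), edges = edges,
         lop_order = as.integer(lop_order), initial = initial),
    class = "qdode_spec"
  )
}

#' @export
print.qdode_spec <- function(x, ...) {
  cat("<qdode_spec> ", length(x$node_ids), " node(s), ", nrow(x$edges),
      " edge(s), LOP order ", x$lop_order, "\n", sep = "")
  invisible(x)
}

# Shared marshalling of a qdode_spec (plus optional pinned smoothers) into
# the C++ decomposition kernel. Edge rows with a `pinned` logical column and
# `src_alpha`/`src_beta` columns evaluate the source as a power curve of the
# index instead of the coupled model state.
qd_decompose_call <- function(spec, grid, nsub = 100L) {
  m <- length(spec$node_ids)
  E <- nrow(spec$edges)
  init <- spec$initial %||% (spec$alpha * grid[1]^spec$beta)
  init <- as.numeric(init)
  ed <- spec$edges
  n <- length(grid)
  if (E > 0L) {
    coefs <- vapply(ed$coefs, as.numeric, numeric(spec$lop_order))
    coefs <- matrix(coefs, nrow = spec$lop_order)
    assert_that(all(c("lo", "hi") %in% names(ed)) && all(ed$lo < ed$hi),
                "edges need valid lo < hi basis domains for solving")
    dom <- rbind(ed$lo, ed$hi)
    pinned <- if ("pinned" %in% names(ed)) as.integer(ed$pinned) else
      rep(0L, E)
    sa <- if ("src_alpha" %in% names(ed)) as.numeric(ed$src_alpha) else
      rep(0, E)
    sb <- if ("src_beta" %in% names(ed)) as.numeric(ed$src_beta) else
      rep(0, E)
    series <- matrix(0, n, E)
    if ("series" %in% names(ed)) {
      for (e in seq_len(E)) {
        if (pinned[e] == 2L) {
          assert_that(length(ed$series[[e]]) == n,
                      "pinned source series must match the grid length")
          series[, e] <- ed$series[[e]]
        }
      }
    }
  } else {
    coefs <- matrix(0, spec$lop_order, 0)
    dom <- matrix(0, 2, 0)
    pinned <- integer(0)
    sa <- sb <- numeric(0)
    series <- matrix(0, n, 0)
  }
  res <- qd_decompose_cpp(
    as.numeric(grid), init, as.numeric(spec$alpha), as.numeric(spec$beta),
    match(ed$target, spec$node_ids) - 1L, match(ed$source, spec$node_ids) - 1L,
    pinned, sa, sb, series, coefs, dom, as.integer(nsub)
  )
  if (!res$ok) {
    stop_qd("non-finite state encountered during qdODE integration")
  }
  res$init <- init
  res
}

#' Solve a qdODE system on an index grid
#'
#' Coupled fourth-order Runge-Kutta integration of
#' `dg_v/dN = independent_rate_v(N) + sum dependent_rate(coefs, g_source)`
#' from the initial values across the grid. Each inter-observation interval
#' is sub-stepped so the maximum step is `(grid span)/nsub`.
#'
#' @param spec A [qdode_spec()].
#' @param grid Strictly increasing index vector with `grid[1] > 0`.
#' @param nsub Sub-step denominator (default 100).
#' @return A numeric matrix (length(grid) x nodes) of trajectories.
#' @export
solve_qdode <- function(spec, grid, nsub = 100L) {
  assert_that(inherits(spec, "qdode_spec"), "`spec` must be a qdode_spec")
  assert_that(all(diff(grid) > 0), "grid must be strictly increasing")
  assert_that(grid[1] > 0, "grid must be positive")
  res <- qd_decompose_call(spec, grid, nsub)
  out <- res$mean
  dimnames(out) <- list(NULL, spec$node_ids)
  out
}

#' Decompose qdODE trajectories into independent and dependent components
#'
#' Accumulates each rate term's own integral during the same RK4 pass that
#' solves the system, so that `mean = indep + sum(incoming dep)` holds at
#' every grid point by construction. The independent curve starts at the
#' initial value; each dependent curve starts at 0. `net_dep` summarizes each
#' edge by the value of its dependent curve at the largest index point.
#'
#' @inheritParams solve_qdode
#' @return A list of class `qd_decomp`: `grid`, `mean`, `indep` (matrices
#'   n x m), `dep` (n x E), `edges` (tibble with `net_dep` added), `initial`.
#' @export
decompose_qdode <- function(spec, grid, nsub = 100L) {
  assert_that(inherits(spec, "qdode_spec"), "`spec` must be a qdode_spec")
  assert_that(all(diff(grid) > 0), "grid must be strictly increasing")
  assert_that(grid[1] > 0, "grid must be positive")
  res <- qd_decompose_call(spec, grid, nsub)
  E <- nrow(spec$edges)
  dep <- res$dep[, seq_len(E), drop = FALSE]
  edges <- spec$edges
  edges$net_dep <- if (E > 0L) dep[length(grid), ] else numeric(0)
  dimnames(res$mean) <- dimnames(res$indep) <- list(NULL, spec$node_ids)
  structure(
    list(grid = as.numeric(grid), mean = res$mean, indep = res$indep,
         dep = dep, edges = edges, initial = res$init,
         node_ids = spec$node_ids),
    class = "qd_decomp"
  )
}

#' @method tidy qd_decomp
#' @export
tidy.qd_decomp <- function(x, ...) {
  n <- length(x$grid)
  indep <- tibble::as_tibble(x$indep) |>
    dplyr::mutate(index = x$grid) |>
    tidyr::pivot_longer(-"index", names_to = "node", values_to = "value") |>
    dplyr::mutate(component = "independent", edge = NA_character_)
  mean_ <- tibble::as_tibble(x$mean) |>
    dplyr::mutate(index = x$grid) |>
    tidyr::pivot_longer(-"index", names_to = "node", values_to = "value") |>
    dplyr::mutate(component = "mean", edge = NA_character_)
  out <- dplyr::bind_rows(mean_, indep)
  if (nrow(x$edges) > 0L) {
    dep <- purrr::map_dfr(seq_len(nrow(x$edges)), function(e) {
      tibble::tibble(
        index = x$grid, node = x$edges$target[e], value = x$dep[, e],
        component = "dependent",
        edge = paste0(x$edges$target[e], "<-", x$edges$source[e])
      )
    })
    out <- dplyr::bind_rows(out, dep)
  }
  out
}

#' @method autoplot qd_decomp
#' @export
autoplot.qd_decomp <- function(object, ...) {
  df <- tidy(object)
  df$edge[is.na(df$edge)] <- ""
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value,
                                   linetype = .data$component,
                                   colour = .data$node,
                                   group = interaction(.data$component,
                                                       .data$edge,
                                                       .data$node))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~node, scales = "free_y") +
    ggplot2::labs(x = "index", y = "expression",
                  linetype = "component") +
    ggplot2::theme_minimal()
}
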