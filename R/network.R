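#' LASSO-based selection of interacting partners for a focal variable
#'
#' Selects the candidate variables whose directed influence best explains the
#' focal series, by L1-penalized regression of the focal values on the
#' candidates' Legendre basis-integral transforms (the design implied by the
#' reduced qdODE regression): each candidate contributes `lop_order` columns,
#' the cumulative integrals of the Legendre polynomials of its affinely
#' mapped observed series, while the focal's own power trend enters as an
#' unpenalized column. The penalty is chosen by cross-validation, followed by
#' an adaptive reweighting pass (weights `1/|coef|`); a candidate's columns
#' are combined by their joint L2 norm so it is selected or dropped as a
#' whole, and the selection is truncated to the `max_predictors` largest
#' groups. When a candidate contributes series from both cell types, the
#' group spans all of its columns.
#'
#' @param focal Numeric vector of the focal variable's values along the
#'   shared ascending grid, or an `indexed_series`.
#' @param candidates A named list of numeric vectors (or matrices with one
#'   column per cell-type series) sharing the focal grid.
#' @param max_predictors Cap on the number of selected partners.
#' @param seed Integer seed controlling the cross-validation folds.
#' @param index Ascending index grid (taken from `focal` when it is an
#'   `indexed_series`).
#' @param lop_order Legendre order of the basis transform (default 3).
#' @return Character vector of selected candidate names (possibly empty).
#' @export
lasso_select <- function(focal, candidates, max_predictors = 5L, seed = 1L,
                         index = NULL, lop_order = 3L) {
  if (is.list(focal) && !is.null(focal$values)) {
    index <- index %||% focal$index
    focal <- focal$values
  }
  y <- as.numeric(focal)
  n <- length(y)
  assert_that(!is.null(index) && length(index) == n,
              "an ascending `index` grid matching the focal series is needed")
  assert_that(sd(y) > 0, "focal series is constant")
  if (is.matrix(candidates)) candidates <- as.list(as.data.frame(candidates))
  assert_that(length(candidates) >= 1L, "need at least one candidate")
  nm <- names(candidates) %||% paste0("c", seq_along(candidates))

  # basis-integral columns per candidate series
  cols <- list()
  group <- character(0)
  for (i in seq_along(candidates)) {
    ser <- as.matrix(candidates[[i]])
    for (k in seq_len(ncol(ser))) {
      v <- ser[, k]
      if (sd(v) == 0) next
      B <- node_basis_cpp(index, matrix(v, 1L), matrix(range(v), 1L),
                          lop_order, 100L)
      cols[[length(cols) + 1L]] <- B
      group <- c(group, rep(nm[i], lop_order))
    }
  }
  if (length(cols) == 0L) return(character(0))
  X <- do.call(cbind, cols)
  # unpenalized own power trend absorbs the focal's independent component
  pf <- power_seed(index, y)
  trend <- index^pf[["beta"]]
  X <- cbind(trend, X)
  pen <- c(0, rep(1, length(group)))

  set.seed(child_seed(seed, 3L))
  nfolds <- max(3L, min(5L, floor(n / 3)))
  foldid <- sample(rep_len(seq_len(nfolds), n))
  cv1 <- glmnet::cv.glmnet(X, y, foldid = foldid, standardize = TRUE,
                           penalty.factor = pen)
  b1 <- as.numeric(coef(cv1, s = "lambda.min"))[-(1:2)]
  if (all(b1 == 0)) return(character(0))
  w <- 1 / pmax(abs(b1), 1e-8)
  w <- w / min(w)
  w[b1 == 0] <- 1e8
  cv2 <- glmnet::cv.glmnet(X, y, foldid = foldid, standardize = TRUE,
                           penalty.factor = c(0, w))
  b2 <- as.numeric(coef(cv2, s = "lambda.1se"))[-(1:2)]
  if (all(b2 == 0)) return(character(0))
  norms <- tapply(b2^2, group, function(v) sqrt(sum(v)))
  norms <- norms[norms > 0]
  sel <- names(sort(norms, decreasing = TRUE))
  utils::head(sel, max_predictors)
}

# ---------------------------------------------------------------------------
# Decoupled per-node qdODE fit
# ---------------------------------------------------------------------------

# Fit one node's reduced qdODE conditioning on the observed series of its
# selected sources (linear interpolants on the grid), by Nelder-Mead MLE
# with univariate AR(1) errors.
fit_node <- function(grid, y, sources, seed = 1L, lop_order = 3L,
                     starts = 3L, maxit = 2000L, reltol = 1e-8,
                     nsub = 100L) {
  q <- length(sources)
  pf <- power_seed(grid, y)
  pf <- list(alpha = pf[["alpha"]], beta = pf[["beta"]])
  resid <- y - pf$alpha * grid^pf$beta
  lag1 <- if (length(resid) >= 3L && sd(resid) > 0) {
    a <- acf(resid, lag.max = 1L, plot = FALSE)$acf[2L]
    if (is.finite(a)) min(max(a, -0.9), 0.9) else 0
  } else 0
  src_series <- if (q > 0L) {
    do.call(rbind, lapply(sources, function(s) s$series))
  } else matrix(0, 0L, length(grid))
  doms <- if (q > 0L) {
    do.call(rbind, lapply(sources, function(s) s$dom))
  } else matrix(0, 0L, 2L)
  # regression seed: the mean is linear in the basis coefficients
  creg <- rep(0, q * lop_order)
  if (q > 0L) {
    B <- node_basis_cpp(grid, src_series, doms, lop_order, nsub)
    X <- cbind(grid^pf$beta - grid[1L]^pf$beta, B)
    lam <- 1e-3 * mean(colSums(X^2))
    cf <- tryCatch(
      solve(crossprod(X) + diag(lam, ncol(X)), crossprod(X, y - y[1L]))[, 1L],
      error = function(e) rep(0, ncol(X)))
    cf[!is.finite(cf)] <- 0
    creg <- cf[-1L]
    m <- max(abs(creg))
    if (m > 5) creg <- creg * 5 / m
  }
  base <- c(log(max(pf$alpha, 1e-8)), pf$beta, creg,
            log(max(sd(resid), 1e-4)), atanh(lag1 / 0.95))
  p <- length(base)
  sm <- matrix(base, nrow = p, ncol = starts)
  if (starts > 1L) {
    set.seed(child_seed(seed, 11L))
    sm[, -1L] <- sm[, -1L] + matrix(rnorm(p * (starts - 1L), sd = 0.3),
                                    nrow = p)
  }
  cppfit <- fit_node_cpp(grid, y, src_series, doms, lop_order, sm, maxit,
                         reltol, nsub, 8L, TRUE)
  co <- cppfit$par
  list(
    alpha = exp(co[1L]), beta = co[2L],
    coefs = if (q > 0L) {
      lapply(seq_len(q), function(e)
        co[(3L + (e - 1L) * lop_order):(2L + e * lop_order)])
    } else list(),
    sigma = exp(co[3L + q * lop_order]),
    rho = 0.95 * tanh(co[4L + q * lop_order]),
    loglik = -cppfit$negll, converged = cppfit$fail == 0L, mu = cppfit$mu,
    n_params = p
  )
}

#' Reconstruct a sparse signed gene network from indexed expression
#'
#' Per focal variable: select interacting partners by adaptive LASSO
#' ([lasso_select()]), then fit the node's reduced qdODE in decoupled mode -
#' each selected source pinned to the linear interpolant of its own observed
#' series, whose per-sample fluctuations identify the direction of influence
#' - by Nelder-Mead MLE with AR(1) errors. An incoming edge is
#' retained when its net dependent integral exceeds `tau` times the range of
#' the target's independent curve. Edge weight is the absolute net area of
#' the dependent curve over the grid, its sign the sign of that area.
#'
#' @param table An [expression_table()] (rows = variables), or a plain
#'   numeric matrix.
#' @param index Numeric index (EI) vector, one entry per column.
#' @param max_predictors Cap on incoming edges per node (default 5).
#' @param lop_order Legendre order of dependent rates (default 3).
#' @param seed Integer seed.
#' @param tau Relative magnitude threshold for retaining an edge.
#' @param starts Nelder-Mead multi-starts per node fit.
#' @return A list of class `qd_network`: `nodes` (tibble: node, alpha, beta,
#'   hubness, role, in/out degree), `edges` (tibble: from, to, sign, weight,
#'   net_dep, sign_change), `grid`, `curves` (per-node decomposition), and
#'   `loglik` per node.
#' @export
fit_network <- function(table, index, max_predictors = 5L, lop_order = 3L,
                        seed = 1L, tau = 0.05, starts = 3L) {
  values <- if (inherits(table, "expr_table")) table$values else as.matrix(table)
  ids <- rownames(values) %||% paste0("v", seq_len(nrow(values)))
  assert_that(length(index) == ncol(values),
              "`index` must have one entry per column")
  ser <- serialize_by_index(seq_len(ncol(values)), index)
  grid <- ser$index
  vals <- values[, ser$order, drop = FALSE]
  m <- nrow(vals)

  edges <- list()
  node_rows <- vector("list", m)
  curves <- vector("list", m)
  for (j in seq_len(m)) {
    y <- vals[j, ]
    # per-node randomness keyed by the node's name, so relabeling the rows
    # relabels the network (permutation equivariance)
    nseed <- child_seed(seed, sum(utf8ToInt(ids[j])))
    res <- tryCatch({
      cand_ids <- setdiff(which(apply(vals, 1L, sd) > 0), j)
      sel <- if (length(cand_ids) > 0L && sd(y) > 0 && m > 1L) {
        cand <- lapply(cand_ids, function(i) vals[i, ])
        names(cand) <- ids[cand_ids]
        lasso_select(y, cand, max_predictors, nseed,
                     index = grid, lop_order = lop_order)
      } else character(0)
      sel_idx <- match(sel, ids)
      sources <- lapply(sel_idx, function(i)
        list(series = vals[i, ], dom = range(vals[i, ])))
      nf <- fit_node(grid, y, sources, seed = nseed,
                     lop_order = lop_order, starts = starts)
      # decomposition curves from the fitted reduced system, sources pinned
      # to their observed series
      sp_edges <- if (length(sel) > 0L) tibble::tibble(
        target = ids[j], source = sel,
        coefs = nf$coefs,
        lo = vapply(sources, function(s) s$dom[1L], 0),
        hi = vapply(sources, function(s) s$dom[2L], 0),
        pinned = 2L,
        series = lapply(sources, function(s) s$series)
      ) else NULL
      spec <- qdode_spec(unique(c(ids[j], sel)),
                         alpha = c(nf$alpha, rep(1, length(sel))),
                         beta = c(nf$beta, rep(1, length(sel))),
                         edges = sp_edges, lop_order = lop_order,
                         initial = c(y[1L],
                                     vapply(sel_idx, function(i)
                                       vals[i, 1L], 0)))
      dec <- decompose_qdode(spec, grid)
      indep_j <- dec$indep[, 1L]
      ir <- max(diff(range(indep_j)), 1e-12)
      kept <- list()
      if (length(sel) > 0L) {
        for (e in seq_along(sel)) {
          depc <- dec$dep[, e]
          nd <- depc[length(grid)]
          if (abs(nd) >= tau * ir) {
            area <- trapz(grid, depc)
            kept[[length(kept) + 1L]] <- tibble::tibble(
              from = sel[e], to = ids[j],
              sign = if (area >= 0) "+" else "-",
              weight = abs(area), net_dep = nd,
              sign_change = min(depc) < 0 && max(depc) > 0,
              abs_area = trapz(grid, abs(depc))
            )
          }
        }
      }
      list(node = tibble::tibble(node = ids[j], alpha = nf$alpha,
                                 beta = nf$beta, sigma = nf$sigma,
                                 rho = nf$rho, loglik = nf$loglik,
                                 converged = nf$converged),
           edges = kept,
           curve = list(indep = indep_j, mean = dec$mean[, 1L]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("node ", ids[j], " failed (", conditionMessage(res),
              "); retained with no incoming edges", call. = FALSE)
      node_rows[[j]] <- tibble::tibble(node = ids[j], alpha = NA_real_,
                                       beta = NA_real_, sigma = NA_real_,
                                       rho = NA_real_, loglik = NA_real_,
                                       converged = FALSE)
      curves[[j]] <- list(indep = rep(NA_real_, length(grid)),
                          mean = rep(NA_real_, length(grid)))
    } else {
      node_rows[[j]] <- res$node
      curves[[j]] <- res$curve
      edges <- c(edges, res$edges)
    }
  }
  nodes <- dplyr::bind_rows(node_rows)
  edges <- if (length(edges) > 0L) dplyr::bind_rows(edges) else tibble::tibble(
    from = character(), to = character(), sign = character(),
    weight = numeric(), net_dep = numeric(), sign_change = logical(),
    abs_area = numeric()
  )
  names(curves) <- ids
  net <- structure(
    list(nodes = nodes, edges = edges, grid = grid, curves = curves),
    class = "qd_network"
  )
  net$nodes$hubness <- vapply(net$nodes$node, function(v) hubness(net, v), 0)
  net$nodes <- dplyr::left_join(net$nodes, classify_network_roles(net),
                                by = "node")
  net
}

#' @export
print.qd_network <- function(x, ...) {
  cat("<qd_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " directed edges (",
      sum(x$edges$sign == "+"), " activating, ",
      sum(x$edges$sign == "-"), " inhibiting)\n", sep = "")
  invisible(x)
}

#' @method tidy qd_network
#' @export
tidy.qd_network <- function(x, ...) x$edges

#' @method glance qd_network
#' @export
glance.qd_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_activating = sum(x$edges$sign == "+"),
    n_inhibiting = sum(x$edges$sign == "-"),
    n_primary_hubs = sum(x$nodes$role == "primary_hub", na.rm = TRUE),
    n_secondary_hubs = sum(x$nodes$role == "secondary_hub", na.rm = TRUE)
  )
}

#' Outgoing hubness of a node
#'
#' The hubness of node j is the sum, over the targets j' it regulates, of
#' the ratio between the integral of the absolute dependent curve j' <- j
#' and the integral of the target's independent curve (trapezoidal
#' quadrature on the network grid). A node with no outgoing edges has
#' hubness 0. Targets whose independent integral is not positive are skipped
#' with a warning.
#'
#' @param network A `qd_network`.
#' @param node Node identifier.
#' @return Non-negative hubness score.
#' @export
hubness <- function(network, node) {
  assert_that(node %in% network$nodes$node, "unknown node")
  out <- network$edges[network$edges$from == node, , drop = FALSE]
  if (nrow(out) == 0L) return(0)
  h <- 0
  for (e in seq_len(nrow(out))) {
    tgt <- out$to[e]
    indep <- network$curves[[tgt]]$indep
    denom <- trapz(network$grid, indep)
    if (!is.finite(denom) || denom <= 0) {
      warning("target ", tgt, " has non-positive independent integral; ",
              "term skipped", call. = FALSE)
      next
    }
    h <- h + out$abs_area[e] / denom
  }
  h
}

#' Classify nodes into hub roles
#'
#' Primary hubs regulate without being regulated (out-degree > 0, in-degree
#' 0); secondary hubs both regulate and are regulated; the remaining
#' (out-degree 0) nodes are subordinates.
#'
#' @param network A `qd_network`.
#' @return A tibble with columns `node`, `out_degree`, `in_degree`, `role`.
#' @export
classify_network_roles <- function(network) {
  nodes <- network$nodes$node
  outd <- vapply(nodes, function(v) sum(network$edges$from == v), 0L)
  ind <- vapply(nodes, function(v) sum(network$edges$to == v), 0L)
  tibble::tibble(
    node = nodes, out_degree = outd, in_degree = ind,
    role = dplyr::case_when(
      outd > 0L & ind == 0L ~ "primary_hub",
      outd > 0L & ind > 0L ~ "secondary_hub",
      TRUE ~ "subordinate"
    )
  )
}

#' Stage-specific module-level networks
#'
#' Collapses genes to module-mean series per sample and fits one sparse
#' network within each (stage x group) stratum. Strata with fewer than five
#' samples are skipped with a warning.
#'
#' @param table An [expression_table()].
#' @param assignment A `module_assignment` covering all genes of `table`.
#' @param stage_labels Character vector of stages, one per sample column; if
#'   `NULL`, the `stage` column of `col_meta` is used, or a single stage.
#' @inheritParams fit_network
#' @return A tibble with columns `stage`, `group`, `network` (list-column of
#'   `qd_network`).
#' @export
module_network <- function(table, assignment, stage_labels = NULL,
                           lop_order = 3L, seed = 1L, max_predictors = 5L,
                           tau = 0.05, starts = 3L) {
  assert_that(inherits(assignment, "module_assignment"),
              "`assignment` must be a module_assignment")
  labels <- assignment$labels[table$row_ids]
  assert_that(!anyNA(labels), "assignment must cover all genes")
  meta <- table$col_meta
  stage_labels <- stage_labels %||% meta$stage %||% rep("all", ncol(table$values))
  strata <- tidyr::expand_grid(
    stage = unique(stage_labels),
    group = unique(as.character(meta$group_label))
  )
  strata$network <- purrr::pmap(strata, function(stage, group) {
    cols <- which(stage_labels == stage & meta$group_label == group)
    if (length(cols) < 5L) {
      warning("stratum (", stage, ", ", group, ") has fewer than 5 samples; ",
              "skipped", call. = FALSE)
      return(NULL)
    }
    sub <- table$values[, cols, drop = FALSE]
    idx <- colSums(sub)
    mod_means <- rowsum(sub, labels) / as.vector(table(labels))
    rownames(mod_means) <- paste0("M", rownames(mod_means))
    fit_network(mod_means, idx, max_predictors = max_predictors,
                lop_order = lop_order, seed = seed, tau = tau,
                starts = starts)
  })
  strata
}

#' Write a network as an edge-list CSV
#' @param network A `qd_network`.
#' @param file Output path.
#' @export
write_edge_csv <- function(network, file) {
  readr::write_csv(
    dplyr::select(network$edges, "from", "to", "sign", "weight"), file)
  invisible(network)
}

#' Write a network as GraphML with node attributes
#' @inheritParams write_edge_csv
#' @export
write_graphml <- function(network, file) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to", "sign", "weight")],
    directed = TRUE,
    vertices = dplyr::select(network$nodes, "node", "alpha", "beta",
                             "hubness", "role")
  )
  igraph::write_graph(g, file, format = "graphml")
  invisible(network)
}

#' @method autoplot qd_network
#' @export
autoplot.qd_network <- function(object, ...) {
  g <- igraph::graph_from_data_frame(
    object$edges[, c("from", "to", "sign", "weight")], directed = TRUE,
    vertices = object$nodes$node
  )
  set.seed(1L)
  lay <- igraph::layout_with_fr(g)
  nodes_df <- tibble::tibble(
    node = igraph::V(g)$name, x = lay[, 1L], y = lay[, 2L]
  ) |> dplyr::left_join(object$nodes, by = "node")
  ed <- object$edges |>
    dplyr::left_join(nodes_df[, c("node", "x", "y")],
                     by = c(from = "node")) |>
    dplyr::left_join(nodes_df[, c("node", "x", "y")],
                     by = c(to = "node"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$sign,
                   linewidth = .data$weight),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(data = nodes_df,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$hubness)) +
    ggplot2::geom_text(data = nodes_df,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$node),
                       vjust = -1, size = 3) +
    ggplot2::scale_colour_manual(values = c("+" = "#D55E00",
                                            "-" = "#0072B2")) +
    ggplot2::theme_void()
}
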