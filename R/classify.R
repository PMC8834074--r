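# Qualitative classification of two-player interactions.
#
# The two dependent-component integrals (net_dep of each direction) carry the
# interaction: positive = activation, negative = inhibition, zero = neutral.
# Neutrality is operationalized as EITHER a non-significant global test OR a
# net dependent effect smaller than a fraction tau of the partner's
# independent-expression range.

#' Sign of a directed dependent effect
#'
#' Returns `"+"`, `"0"` or `"-"` for one direction of the interaction:
#' `"0"` when the global interaction test is not significant or when
#' `|net_dep| < tau * indep_range`; otherwise the sign of `net_dep`.
#'
#' @param net_dep Signed net dependent integral (dependent curve at the
#'   largest index point).
#' @param indep_range Range (max - min) of the target's independent curve
#'   (> 0).
#' @param test_significant Logical: did the interaction test reject?
#' @param tau Relative-magnitude threshold for neutrality (default 0.05).
#' @return One of `"+"`, `"0"`, `"-"`.
#' @export
sign_of_dependence <- function(net_dep, indep_range, test_significant,
                               tau = 0.05) {
  assert_that(indep_range > 0, "indep_range must be > 0")
  if (!isTRUE(test_significant) || abs(net_dep) < tau * indep_range) return("0")
  if (net_dep > 0) "+" else "-"
}

table1_classes <- c(
  "symmetric synergism",              # 1  (+, +), |.| equal
  "asymmetric synergism",             # 2  (+, +), |.| unequal
  "directional synergism toward k",   # 3  (+, 0)
  "directional synergism toward k'",  # 4  (0, +)
  "altruism toward k",                # 5  (+, -)
  "altruism toward k'",               # 6  (-, +)
  "symmetric antagonism",             # 7  (-, -), |.| equal
  "asymmetric antagonism",            # 8  (-, -), |.| unequal
  "directional antagonism toward k",  # 9  (-, 0)
  "directional antagonism toward k'", # 10 (0, -)
  "coexistence"                       # 11 (0, 0)
)

#' Classify a sign pattern into the eleven interaction classes
#'
#' Maps the signs of the two directed dependent integrals (`sign_12`: effect
#' of cell type k' on k; `sign_21`: effect of k on k') onto the eleven
#' qualitative classes: symmetric/asymmetric synergism and antagonism,
#' directional synergism/antagonism toward either type, altruism (one type
#' activates the other, which inhibits it back; equivalently exploitation),
#' and coexistence (mutual neutrality). Symmetric versus asymmetric is
#' decided by whether `|dep_12|` and `|dep_21|` agree within a relative
#' tolerance (default 10%).
#'
#' @param sign_12,sign_21 Signs from [sign_of_dependence()].
#' @param dep_12,dep_21 The signed net dependent integrals.
#' @param sym_tol Relative tolerance distinguishing "=" from "!=" magnitudes.
#' @return The class label (character).
#' @export
classify_table1 <- function(sign_12, sign_21, dep_12 = 0, dep_21 = 0,
                            sym_tol = 0.1) {
  key <- paste0(sign_12, sign_21)
  symmetric <- {
    m <- max(abs(dep_12), abs(dep_21))
    m == 0 || abs(abs(dep_12) - abs(dep_21)) / m <= sym_tol
  }
  switch(key,
    "++" = if (symmetric) table1_classes[1] else table1_classes[2],
    "+0" = table1_classes[3],
    "0+" = table1_classes[4],
    "+-" = table1_classes[5],
    "-+" = table1_classes[6],
    "--" = if (symmetric) table1_classes[7] else table1_classes[8],
    "-0" = table1_classes[9],
    "0-" = table1_classes[10],
    "00" = table1_classes[11],
    stop_qd("invalid sign pattern: ", key)
  )
}

#' Aggregate the eleven classes into five regulator categories
#'
#' Synergistic (classes 1-2), directional synergistic (3-4), altruistic
#' (5-6), antagonistic (7-8), directional antagonistic (9-10), and none
#' (coexistence, class 11).
#'
#' @param table1_class A label produced by [classify_table1()].
#' @return One of `"synergistic"`, `"directional_synergistic"`,
#'   `"altruistic"`, `"antagonistic"`, `"directional_antagonistic"`,
#'   `"none"`.
#' @export
aggregate_category <- function(table1_class) {
  i <- match(table1_class, table1_classes)
  assert_that(!is.na(i), "unknown class label")
  c("synergistic", "synergistic",
    "directional_synergistic", "directional_synergistic",
    "altruistic", "altruistic",
    "antagonistic", "antagonistic",
    "directional_antagonistic", "directional_antagonistic",
    "none")[i]
}

# Build one interaction call from a full fit + significance flag.
interaction_call <- function(fit_full, LR, threshold, significant, tau = 0.05,
                             sym_tol = 0.1) {
  dec <- fit_full$decomposition
  net <- dec$edges$net_dep
  # edge 1: type1 <- type2 (effect on k), edge 2: type2 <- type1
  ir1 <- diff(range(dec$indep[, 1L]))
  ir2 <- diff(range(dec$indep[, 2L]))
  s12 <- sign_of_dependence(net[1L], max(ir1, 1e-12), significant, tau)
  s21 <- sign_of_dependence(net[2L], max(ir2, 1e-12), significant, tau)
  cls <- classify_table1(s12, s21, net[1L], net[2L], sym_tol)
  tibble::tibble(
    gene_id = fit_full$gene_id,
    dep_12 = net[1L], dep_21 = net[2L],
    sign_12 = s12, sign_21 = s21,
    table1_class = cls, category5 = aggregate_category(cls),
    LR = LR, threshold = threshold, significant = significant
  )
}

#' Screen genes for cell-cell interactions
#'
#' Runs the full per-gene pipeline over an expression table with two cell
#' types: paired profile, game and non-game fits, LR statistic, permutation
#' threshold, sign classification, and the five-way category. Following the
#' single genome-wide threshold of the analysis design, permutation LR values
#' are pooled across genes (each gene contributes roughly `n_perm / n_genes`
#' replicates, at least 2) and the shared threshold is the pooled 95th
#' percentile; set `pool_permutations = FALSE` for per-gene thresholds.
#'
#' @param table An [expression_table()] with two `group_label`s in
#'   `col_meta`.
#' @param n_perm Total number of permutation replicates in the pooled null
#'   (or per gene when not pooling).
#' @param seed Integer seed.
#' @param lop_order,starts,tau,sym_tol,level Passed to the per-gene machinery.
#' @param pool_permutations Pool permutation replicates across genes
#'   (default TRUE).
#' @return A tibble of class `qd_screen` with one row per gene (the
#'   interaction call columns) plus attributes `category_counts` and
#'   `threshold`.
#' @export
screen_genes <- function(table, n_perm = 1000L, seed = 1L, lop_order = 3L,
                         starts = 5L, tau = 0.05, sym_tol = 0.1,
                         level = 0.05, pool_permutations = TRUE) {
  profs <- paired_profiles(table)
  genes <- unique(profs$gene_id)
  if (length(genes) == 0L) {
    out <- tibble::tibble()
    class(out) <- c("qd_screen", class(out))
    return(out)
  }
  per_gene <- max(2L, ceiling(n_perm / length(genes)))

  results <- vector("list", length(genes))
  pooled <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    rows <- profs[profs$gene_id == g, ]
    res <- tryCatch({
      prof <- pair_profile(rows$g1, rows$g2, gene_id = g,
                           unit_id = rows$unit_id)
      gseed <- child_seed(seed, gi)
      if (pool_permutations) {
        tst <- lr_interaction_test(prof, n_perm = max(per_gene, 19L),
                                   seed = gseed, lop_order = lop_order,
                                   starts = starts, level = level,
                                   return_perms = TRUE)
        pooled[[gi]] <- utils::head(tst$perm_LR, per_gene)
        list(fit = tst$fit_full, LR = tst$LR)
      } else {
        tst <- lr_interaction_test(prof, n_perm = n_perm, seed = gseed,
                                   lop_order = lop_order, starts = starts,
                                   level = level)
        list(fit = tst$fit_full, LR = tst$LR, threshold = tst$threshold,
             significant = tst$significant)
      }
    }, error = function(e) e)
    results[[gi]] <- res
  }

  threshold <- if (pool_permutations) {
    quantile(unlist(pooled), probs = 1 - level, names = FALSE)
  } else NA_real_

  calls <- purrr::map2_dfr(results, genes, function(res, g) {
    if (inherits(res, "error")) {
      warning("gene ", g, " failed: ", conditionMessage(res), call. = FALSE)
      return(tibble::tibble(
        gene_id = g, dep_12 = NA_real_, dep_21 = NA_real_,
        sign_12 = NA_character_, sign_21 = NA_character_,
        table1_class = "unclassified", category5 = "unclassified",
        LR = NA_real_, threshold = NA_real_, significant = NA
      ))
    }
    thr <- if (pool_permutations) threshold else res$threshold
    sig <- if (pool_permutations) res$LR > thr else res$significant
    interaction_call(res$fit, res$LR, thr, sig, tau, sym_tol)
  })
  counts <- calls |>
    dplyr::count(.data$category5, name = "n_genes")
  class(calls) <- c("qd_screen", class(calls))
  attr(calls, "category_counts") <- counts
  attr(calls, "threshold") <- threshold
  calls
}

#' @method autoplot qd_screen
#' @export
autoplot.qd_screen <- function(object, ...) {
  counts <- attr(object, "category_counts")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$category5,
                                       y = .data$n_genes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Write a screen report to CSV and a category summary to JSON
#'
#' @param screen A `qd_screen` tibble from [screen_genes()].
#' @param csv_file,json_file Output paths (either may be `NULL`).
#' @return Invisibly, the screen.
#' @export
write_screen_report <- function(screen, csv_file = NULL, json_file = NULL) {
  if (!is.null(csv_file)) readr::write_csv(screen, csv_file)
  if (!is.null(json_file)) {
    counts <- attr(screen, "category_counts")
    jsonlite::write_json(
      list(threshold = attr(screen, "threshold"),
           categories = setNames(as.list(counts$n_genes),
                                 counts$category5)),
      json_file, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(screen)
}
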