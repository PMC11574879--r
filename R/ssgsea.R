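#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' Per cell (row), genes are ranked by expression with mid-ranks for ties
#' (pervasive under single-cell dropout). Walking the genes in decreasing
#' expression order (ties broken by column position, deterministic), the
#' running sum accumulates rank^alpha-weighted in-set hits against uniform
#' out-of-set misses; the score is the sum over all steps of the running-sum
#' difference. Because only ranks enter, the score is exactly invariant
#' under any strictly increasing per-cell transform of expression. With
#' alpha = 0 the weighting reduces to the unweighted Kolmogorov-Smirnov-sum
#' statistic.
#'
#' @param expr non-negative cells x genes matrix with unique gene column
#'   names
#' @param genes character vector of gene-set symbols (or a single-set list)
#' @param alpha rank-weight exponent (ssGSEA convention 0.25)
#' @param normalize if TRUE, min-max normalize scores across cells
#' @return named numeric vector of per-cell scores; attribute
#'   \code{missing_genes} lists set genes absent from the matrix
#' @export
ssgsea <- function(expr, genes, alpha = 0.25, normalize = FALSE) {
  if (is.list(genes)) genes <- genes[[1]]
  expr <- as.matrix(expr)
  if (any(expr < 0)) tq_value_error("expression matrix has negative values")
  if (is.null(colnames(expr)) || anyDuplicated(colnames(expr))) {
    tq_value_error("expression matrix needs unique gene column names")
  }
  present <- intersect(genes, colnames(expr))
  absent <- setdiff(genes, colnames(expr))
  if (!length(present)) tq_value_error("gene set disjoint from the matrix")
  if (length(absent)) {
    warning(sprintf("ssgsea: %d set gene(s) absent from matrix: %s",
                    length(absent), paste(absent, collapse = ", ")))
  }
  N <- ncol(expr)
  m <- length(present)
  if (N - m < 1) tq_value_error("gene set covers the whole matrix")
  in_set <- colnames(expr) %in% present

  scores <- vapply(seq_len(nrow(expr)), function(i) {
    v <- expr[i, ]
    r <- rank(v)                                   # mid-ranks, ascending
    ord <- order(v, decreasing = TRUE)             # stable: ties by position
    hit <- in_set[ord]
    w <- r[ord]^alpha
    w[!hit] <- 0
    p_hit <- cumsum(w) / sum(w)
    p_miss <- cumsum(!hit) / (N - m)
    sum(p_hit - p_miss)
  }, numeric(1))
  names(scores) <- rownames(expr)
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- (scores - rng[1]) / diff(rng)
  }
  attr(scores, "missing_genes") <- absent
  scores
}

#' Correlation of an anchor gene with signature scores
#'
#' Spearman correlation (mid-rank Pearson) between the anchor gene's
#' expression and a per-cell score vector; used to check that a marker gene
#' tracks (or anti-tracks) a signature.
#'
#' @param expr cells x genes matrix
#' @param anchor_gene gene symbol present in \code{expr}
#' @param scores per-cell score vector aligned with \code{expr} rows
#' @return list \code{(rho, p, n)}; \code{rho = NA} for a constant anchor
#' @export
anchor_correlation <- function(expr, anchor_gene, scores) {
  if (!anchor_gene %in% colnames(expr)) {
    tq_config_error(sprintf("anchor gene %s absent from matrix", anchor_gene))
  }
  spearman_rho(expr[, anchor_gene], as.numeric(scores))
}

#' Compare signature scores across anchor-expression tertiles
#'
#' Cells are split into tertiles by anchor rank (T1 = lowest expression);
#' per-tertile mean and median scores are reported with Holm-adjusted
#' pairwise rank tests between tertiles.
#'
#' @param anchor per-cell anchor expression
#' @param scores per-cell score vector
#' @return list with \code{summary} (data.table: tertile, n, mean, median)
#'   and \code{tests} (data.table: tertile_a, tertile_b, p_raw, p_holm)
#' @export
tertile_compare <- function(anchor, scores) {
  anchor <- as.numeric(anchor); scores <- as.numeric(scores)
  if (length(anchor) < 3) tq_value_error("need >= 3 cells")
  tert <- dichotomize(anchor, "tertiles")
  summ <- data.table::data.table(
    tertile = levels(tert),
    n = as.integer(table(tert)),
    mean = vapply(split(scores, tert), mean, 0),
    median = vapply(split(scores, tert), median, 0))
  pairs <- combn(levels(tert), 2)
  tests <- data.table::data.table(
    tertile_a = pairs[1, ], tertile_b = pairs[2, ],
    p_raw = vapply(seq_len(ncol(pairs)), function(k) {
      mann_whitney_pratt(scores[tert == pairs[1, k]],
                         scores[tert == pairs[2, k]])$p_raw
    }, 0))
  tests$p_holm <- adjust_pvalues(tests$p_raw, "holm")
  list(summary = summ, tests = tests)
}
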