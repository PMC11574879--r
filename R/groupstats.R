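#' Mann-Whitney U test with zero/tie-retaining ranking
#'
#' Two-sample rank test suited to zero-inflated density data: zero
#' observations are retained in the pooled mid-ranking (never dropped) and
#' the variance is tie-corrected. For pooled size N <= \code{exact_limit}
#' the two-sided p-value comes from exhaustive enumeration of all
#' \code{choose(N, n1)} group labelings of the pooled values (exact under
#' ties and zeros); otherwise from the normal approximation with the
#' tie-corrected variance
#' \eqn{\sigma^2 = (n_1 n_2/12)[(N+1) - \sum(t^3-t)/(N(N-1))]}
#' and a 0.5 continuity correction. The exact two-sided p is
#' \eqn{P(|U - n_1 n_2/2| \ge |u_{obs} - n_1 n_2/2|)} over the permutation
#' distribution, which is symmetric about \eqn{n_1 n_2 / 2}.
#'
#' @param x,y numeric density vectors for the two groups
#' @param exact_limit largest pooled N for the exact-enumeration branch
#' @return \code{tq_test}: list with \code{U} (U statistic of \code{x}),
#'   \code{z_value}, \code{p_raw}, \code{n1}, \code{n2}, \code{method}
#'   (exact/normal), \code{tie_correction_applied}, \code{degenerate},
#'   \code{summary} (per-group median/mean/IQR)
#' @export
mann_whitney_pratt <- function(x, y, exact_limit = 10L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (any(!is.finite(c(x, y)))) tq_value_error("non-finite values in test input")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 < 1 || n2 < 1) tq_value_error("both groups need at least one value")
  pooled <- c(x, y)
  r <- rank(pooled)                       # mid-ranks; zeros kept
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_corr <- any(ties > 1)
  summ <- list(
    group1 = c(median = median(x), mean = mean(x), IQR = IQR_(x)),
    group2 = c(median = median(y), mean = mean(y), IQR = IQR_(y)))

  if (length(ties) == 1L) {               # all pooled values identical
    return(tq_test(U, 0, 1, n1, n2, "degenerate", tie_corr, TRUE, summ))
  }
  if (N <= exact_limit) {
    idx <- combn(N, n1)
    Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    return(tq_test(U, NA_real_, p, n1, n2, "exact", tie_corr, FALSE, summ))
  }
  tsum <- sum(ties^3 - ties)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - tsum / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(tq_test(U, 0, 1, n1, n2, "degenerate", tie_corr, TRUE, summ))
  }
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  if (U == mu) z <- 0
  p <- min(1, 2 * pnorm(-abs(z)))
  tq_test(U, z, p, n1, n2, "normal", tie_corr, FALSE, summ)
}

IQR_ <- function(v) unname(diff(quantile(v, c(0.25, 0.75))))

tq_test <- function(U, z, p, n1, n2, method, tie, degen, summ) {
  structure(list(U = U, z_value = z, p_raw = p, n1 = n1, n2 = n2,
                 method = method, tie_correction_applied = tie,
                 degenerate = degen, summary = summ),
            class = "tq_test")
}

#' Adjust p-values for multiple testing
#'
#' \code{holm}: step-down Holm-Bonferroni with running maximum, capped at
#' 1. \code{bh}: Benjamini-Hochberg step-up with running minimum from the
#' largest rank, capped at 1. Input order is preserved.
#'
#' @param p numeric vector of raw p-values in \code{[0, 1]}
#' @param method \code{"holm"} or \code{"bh"}
#' @return adjusted p-values, same order as input
#' @export
adjust_pvalues <- function(p, method = c("holm", "bh")) {
  method <- match.arg(method)
  assert_prob(p)
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- if (method == "holm") {
    pmin(1, cummax((n - seq_len(n) + 1) * ps))
  } else {
    rev(pmin(1, cummin(rev(n / seq_len(n) * ps))))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Spearman rank correlation with missing-pair handling
#'
#' rho is the Pearson correlation of mid-ranks over pairwise-complete
#' observations; the p-value uses the t approximation with n - 2 degrees of
#' freedom. Constant input yields a missing rho.
#'
#' @param x,y numeric vectors
#' @return list \code{(rho, p, n)}
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), n - 2), n = n)
}

#' Phenotype-by-phenotype Spearman co-infiltration matrix
#'
#' Correlates per-sample densities of every phenotype pair within one group
#' and demarcation scope, pairwise-complete.
#'
#' @param dm \code{density_matrix}
#' @param clinical clinical table (for the group filter)
#' @param group \code{"dHGP"}, \code{"non_dHGP"} or \code{NULL} for all
#' @param scope demarcation, e.g. \code{"total_excluding_liver"} or
#'   \code{"stroma"}
#' @return list with matrices \code{rho} and \code{p} plus the long-format
#'   data.table \code{long} \code{(group, scope, pheno_a, pheno_b, rho, p)}
#' @export
spearman_matrix <- function(dm, clinical, group = NULL,
                            scope = "total_excluding_liver") {
  sub <- dm[dm$demarcation == scope, ]
  if (!is.null(group)) {
    keep <- clinical$sample_id[clinical$hgp == group]
    if (length(keep) < 3) tq_value_error("need >= 3 samples in group")
    sub <- sub[sub$sample_id %in% keep, ]
  }
  wide <- data.table::dcast(sub, sample_id ~ phenotype, value.var = "density")
  phenos <- setdiff(names(wide), "sample_id")
  k <- length(phenos)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(phenos, phenos))
  for (i in seq_len(k)) {
    rho[i, i] <- 1; p[i, i] <- 0
    for (j in seq_len(i - 1L)) {
      s <- spearman_rho(wide[[phenos[i]]], wide[[phenos[j]]])
      rho[i, j] <- rho[j, i] <- s$rho
      p[i, j] <- p[j, i] <- s$p
    }
  }
  long <- data.table::data.table(
    group = group %||% "all", scope = scope,
    pheno_a = rep(phenos, each = k), pheno_b = rep(phenos, k),
    rho = as.vector(rho), p = as.vector(p))
  list(rho = rho, p = p, long = long)
}

#' Compare growth-pattern groups over a density matrix and ratio table
#'
#' Runs \code{\link{mann_whitney_pratt}} for every phenotype x demarcation
#' cell of the density matrix (and each ratio metric), then adjusts within
#' statistical families: by default one family per (panel, demarcation),
#' with ratios forming their own family. Both Holm and BH-FDR columns are
#' always reported. The direction column names the group with the larger
#' rank-sum tendency.
#'
#' @param dm \code{density_matrix}
#' @param clinical clinical table with \code{sample_id, hgp}
#' @param ratios optional \code{ratio_table}
#' @param family_of optional function \code{(phenotype, demarcation) ->
#'   family label}; default uses the panel lookup in \code{panel_map}
#'   crossed with demarcation
#' @param panel_map optional named character vector phenotype -> panel name
#' @return \code{comparison_report}: data.table with columns
#'   \code{phenotype, demarcation, family, n1, n2, U, z_value, p_raw,
#'   p_holm, p_fdr, direction, median_dHGP, median_non_dHGP}
#' @export
compare_hgp <- function(dm, clinical, ratios = NULL, family_of = NULL,
                        panel_map = NULL) {
  gx <- clinical$sample_id[clinical$hgp == "dHGP"]
  gy <- clinical$sample_id[clinical$hgp == "non_dHGP"]
  if (length(gx) < 2 || length(gy) < 2) {
    tq_value_error("each growth-pattern group needs >= 2 samples")
  }
  fam <- family_of %||% function(phenotype, demarcation) {
    pnl <- if (!is.null(panel_map) && phenotype %in% names(panel_map)) {
      panel_map[[phenotype]]
    } else "default"
    paste(pnl, demarcation, sep = ":")
  }

  rows <- list()
  run_one <- function(phenotype, demarcation, values, ids, family) {
    x <- values[ids %in% gx]; y <- values[ids %in% gy]
    ok <- is.finite(x); x <- x[ok]
    ok <- is.finite(y); y <- y[ok]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    t <- mann_whitney_pratt(x, y)
    dir <- if (t$degenerate || t$U == t$n1 * t$n2 / 2) "none" else
      if (t$U > t$n1 * t$n2 / 2) "dHGP" else "non_dHGP"
    data.table::data.table(
      phenotype = phenotype, demarcation = demarcation, family = family,
      n1 = t$n1, n2 = t$n2, U = t$U, z_value = t$z_value, p_raw = t$p_raw,
      direction = dir,
      median_dHGP = t$summary$group1[["median"]],
      median_non_dHGP = t$summary$group2[["median"]])
  }
  combos <- unique(dm[, c("phenotype", "demarcation")])
  for (i in seq_len(nrow(combos))) {
    ph <- combos$phenotype[i]; de <- combos$demarcation[i]
    sub <- dm[dm$phenotype == ph & dm$demarcation == de, ]
    rows[[length(rows) + 1L]] <- run_one(ph, de, sub$density, sub$sample_id,
                                         fam(ph, de))
  }
  if (!is.null(ratios)) {
    for (rn in unique(ratios$ratio_name)) {
      sub <- ratios[ratios$ratio_name == rn, ]
      rows[[length(rows) + 1L]] <- run_one(rn, "ratio", sub$value,
                                           sub$sample_id, "ratios")
    }
  }
  rep <- data.table::rbindlist(rows)
  if (!nrow(rep)) tq_value_error("no testable phenotype/demarcation cells")
  rep[, "p_holm" := adjust_pvalues(p_raw, "holm"), by = "family"]
  rep[, "p_fdr" := adjust_pvalues(p_raw, "bh"), by = "family"]
  data.table::setattr(rep, "class", c("comparison_report", class(rep)))
  rep[]
}
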