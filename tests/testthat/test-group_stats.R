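test_that("exact branch reproduces enumeration on canonical examples", {
  # complete separation: U = 0, exact two-sided p = 2/20
  t <- mann_whitney_pratt(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t$method, "exact")
  expect_equal(t$U, 0)
  expect_equal(t$p_raw, 0.1)

  # identical multisets: symmetric, p = 1
  t <- mann_whitney_pratt(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_equal(t$p_raw, 1)
  expect_equal(t$U, t$n1 * t$n2 / 2)

  # zero-inflated: matches full permutation enumeration to 1e-9
  x <- c(0, 0, 0, 5); y <- c(0, 0, 7, 9)
  t <- mann_whitney_pratt(x, y)
  expect_equal(t$p_raw, mw_perm_oracle(x, y), tolerance = 1e-9)
  expect_true(t$tie_correction_applied)

  # all pooled values identical: degenerate, p = 1
  t <- mann_whitney_pratt(c(0, 0), c(0, 0, 0))
  expect_true(t$degenerate)
  expect_equal(t$p_raw, 1)
})

test_that("exact branch matches the permutation oracle over random tied/zero-inflated cases", {
  set.seed(47)
  for (rep in 1:40) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    vals <- sample(c(0, 0, 0, 1, 1, 2, 3, 5), n1 + n2, replace = TRUE)
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    t <- mann_whitney_pratt(x, y)
    if (t$degenerate) {
      expect_equal(t$p_raw, 1)
    } else {
      expect_equal(t$p_raw, mw_perm_oracle(x, y), tolerance = 1e-9,
                   info = sprintf("x=%s y=%s", paste(x, collapse = ","),
                                  paste(y, collapse = ",")))
    }
  }
})

test_that("normal approximation tracks the exact p for balanced untied N = 10", {
  # the 0.02 bound holds in the approximation's intended regime (no ties,
  # balanced groups); with heavy ties the exact branch is the one in use
  set.seed(53)
  for (rep in 1:25) {
    vals <- sample(seq_len(500), 10)      # distinct values
    x <- vals[1:5]; y <- vals[6:10]
    ex <- mann_whitney_pratt(x, y, exact_limit = 10)
    ap <- mann_whitney_pratt(x, y, exact_limit = 0)
    expect_lt(abs(ap$p_raw - ex$p_raw), 0.02)
  }
  # with ties the approximation stays usable though coarser
  t_ap <- mann_whitney_pratt(c(0, 0, 1, 2, 3), c(0, 1, 1, 4, 8),
                             exact_limit = 0)
  t_ex <- mann_whitney_pratt(c(0, 0, 1, 2, 3), c(0, 1, 1, 4, 8))
  expect_lt(abs(t_ap$p_raw - t_ex$p_raw), 0.15)
})

test_that("p-value adjustment reproduces hand-applied Holm and BH", {
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "holm"),
               c(0.03, 0.06, 0.06))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bh"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.2, "holm"), 0.2)
  expect_equal(adjust_pvalues(0.2, "bh"), 0.2)
  expect_error(adjust_pvalues(c(0.1, 1.2), "holm"), class = "tq_value_error")
})

test_that("adjustment is monotone, capped, order-preserving and matches stats::p.adjust", {
  set.seed(59)
  for (rep in 1:20) {
    p <- runif(sample(2:12, 1))
    for (m in c("holm", "bh")) {
      adj <- adjust_pvalues(p, m)
      expect_true(all(adj >= p - 1e-15))
      expect_true(all(adj <= 1))
      # reordering inputs reorders outputs identically
      o <- sample(length(p))
      expect_equal(adjust_pvalues(p[o], m), adj[o])
      # independent oracle
      expect_equal(adj, stats::p.adjust(p, if (m == "bh") "BH" else "holm"),
                   tolerance = 1e-12)
    }
  }
})

test_that("spearman_rho handles monotone, anti-monotone, tied and constant input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_rho(x, exp(x))$rho, 1)
  expect_equal(spearman_rho(x, -x^3)$rho, -1)
  expect_true(is.na(spearman_rho(rep(1, 5), x)$rho))

  set.seed(61)
  a <- sample(0:5, 200, replace = TRUE)   # heavy ties
  b <- a + sample(0:3, 200, replace = TRUE)
  expect_equal(spearman_rho(a, b)$rho, spearman_oracle(a, b),
               tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(spearman_rho(exp(a), log1p(b))$rho, spearman_rho(a, b)$rho,
               tolerance = 1e-12)
})

test_that("spearman_matrix is symmetric with unit diagonal and respects scope", {
  b <- generate_cohort(sim_config(n_per_group = 6, cells_per_core = 150,
                                  seed = 67))
  th <- fit_thresholds(b$cells)
  calls <- apply_thresholds(b$cells, th)
  dm <- compute_densities(calls, b$cells, b$areas)
  cm <- spearman_matrix(dm, b$clinical, "dHGP", "stroma")
  expect_equal(cm$rho, t(cm$rho))
  expect_true(all(diag(cm$rho) == 1))
  expect_true(all(cm$rho >= -1 & cm$rho <= 1, na.rm = TRUE))
  expect_error(spearman_matrix(dm, b$clinical[1:2, ], "dHGP"),
               class = "tq_value_error")
})

test_that("compare_hgp orchestrates tests with per-family adjustment", {
  b <- generate_cohort(sim_config(n_per_group = 10, cells_per_core = 150,
                                  seed = 71))
  th <- fit_thresholds(b$cells)
  calls <- apply_thresholds(b$cells, th)
  dm <- compute_densities(calls, b$cells, b$areas, c("tumor_nest", "stroma"))

  rep <- compare_hgp(dm, b$clinical)
  expect_true(all(rep$p_holm >= rep$p_raw - 1e-15))
  expect_true(all(rep$p_fdr >= rep$p_raw - 1e-15))
  expect_true(all(rep$p_holm <= 1 & rep$p_fdr <= 1))

  # single phenotype, single demarcation -> adjustment is identity
  one <- dm[dm$phenotype == "CD8" & dm$demarcation == "stroma", ]
  rep1 <- compare_hgp(one, b$clinical)
  expect_equal(rep1$p_holm, rep1$p_raw)
  expect_equal(rep1$p_fdr, rep1$p_raw)

  # group with < 2 samples errors
  clin <- data.table::copy(b$clinical)
  clin$hgp <- c("dHGP", rep("non_dHGP", nrow(clin) - 1))
  expect_error(compare_hgp(dm, clin), class = "tq_value_error")
})

test_that("compare_hgp direction column follows the rank tendency", {
  dm <- data.table::data.table(
    sample_id = paste0("S", 1:8),
    phenotype = "X", demarcation = "stroma",
    density = c(10, 12, 14, 16, 1, 2, 3, 4))
  clin <- data.table::data.table(
    sample_id = paste0("S", 1:8),
    hgp = rep(c("dHGP", "non_dHGP"), each = 4),
    os_months = 10, event = 1L)
  rep <- compare_hgp(dm, clin)
  expect_equal(rep$direction, "dHGP")
  dm$density <- rev(dm$density)
  expect_equal(compare_hgp(dm, clin)$direction, "non_dHGP")
})
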