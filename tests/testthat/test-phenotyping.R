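make_calls <- function(df) {
  structure(data.table::as.data.table(df),
            class = c("marker_calls", "data.table", "data.frame"))
}

test_that("packaged panels load and encode the expected marker rules", {
  panels <- lapply(default_panel_paths(), read_panel)
  expect_setequal(names(panels), c("lymphoid", "myeloid", "caf"))
  expect_setequal(panels$myeloid$markers,
                  c("CD68", "CD163", "Calprotectin", "MARCO"))
  expect_equal(panels$caf$tiered_markers, "aSMA")
  expect_true(panels$caf$denominator$match_any)
  m2 <- panels$myeloid$phenotypes$M2
  expect_setequal(m2$positive, c("CD68", "CD163"))
})

test_that("macrophage polarization rules are definitional", {
  panel <- read_panel(default_panel_paths()["myeloid"])
  calls <- make_calls(list(CD68 = c(TRUE, TRUE, FALSE, FALSE),
                           CD163 = c(TRUE, FALSE, TRUE, FALSE),
                           Calprotectin = FALSE, MARCO = FALSE))
  pc <- assign_phenotypes(calls, panel)
  # CD68+CD163+ is M2 and CD68_total, never M1
  expect_true(pc$matrix[1, "M2"])
  expect_true(pc$matrix[1, "CD68_total"])
  expect_false(pc$matrix[1, "M1"])
  # CD68+CD163- is M1
  expect_true(pc$matrix[2, "M1"])
  # CD68-CD163+ is the myeloid nonmacrophage population
  expect_true(pc$matrix[3, "myeloid_nonmacrophage"])
  expect_false(pc$matrix[3, "CD68_total"])
  # all-negative cell matches nothing
  expect_false(any(pc$matrix[4, ]))
})

test_that("phenotype counts equal a brute-force rule evaluator on random calls", {
  set.seed(13)
  panel <- read_panel(default_panel_paths()["myeloid"])
  n <- 1000
  calls <- make_calls(list(CD68 = runif(n) < 0.3, CD163 = runif(n) < 0.3,
                           Calprotectin = runif(n) < 0.2,
                           MARCO = runif(n) < 0.1))
  pc <- assign_phenotypes(calls, panel)
  for (nm in names(panel$phenotypes)) {
    def <- panel$phenotypes[[nm]]
    brute <- brute_pheno(calls, def$positive, def$negative,
                         panel$markers, def$exclusive_single)
    expect_equal(unname(pc$matrix[, nm]), brute, info = nm)
  }
})

test_that("_single phenotypes are contained in their totals and partitions reconcile", {
  b <- generate_cohort(sim_config(n_per_group = 5, cells_per_core = 200,
                                  seed = 17))
  th <- fit_thresholds(b$cells)
  calls <- apply_thresholds(b$cells, th)
  panel <- read_panel(default_panel_paths()["lymphoid"])
  pc <- assign_phenotypes(calls, panel)
  expect_true(all(pc$matrix[, "CD8_total"] | !pc$matrix[, "CD8_single"]))

  dm <- compute_densities(pc, b$cells, b$areas)
  # exclusive partition: CD8_memory + CD8_nonmemory = CD8_total everywhere
  for (d in unique(dm$demarcation)) {
    tot <- dm[dm$phenotype == "CD8_total" & dm$demarcation == d, ]
    mem <- dm[dm$phenotype == "CD8_memory" & dm$demarcation == d, ]
    non <- dm[dm$phenotype == "CD8_nonmemory" & dm$demarcation == d, ]
    expect_equal(mem$density + non$density, tot$density, tolerance = 1e-9)
  }
  # _single densities never exceed totals
  s <- dm[dm$phenotype == "CD8_single", ]
  t <- dm[dm$phenotype == "CD8_total", ]
  expect_true(all(s$density <= t$density + 1e-12))
})

test_that("missing marker in calls raises a named error", {
  panel <- read_panel(default_panel_paths()["myeloid"])
  calls <- make_calls(list(CD68 = TRUE))
  expect_error(assign_phenotypes(calls, panel), "CD163",
               class = "tq_config_error")
})

test_that("combination enumeration partitions the denominator exactly", {
  # 2 markers, 4 cells, one of each signature -> four fractions of 0.25
  calls <- make_calls(list(A = c(TRUE, TRUE, FALSE, FALSE),
                           B = c(TRUE, FALSE, TRUE, FALSE)))
  denom <- phenotype_def("all", positive = character())
  tab <- enumerate_combinations(calls, rep("S1", 4), c("A", "B"), denom)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$fraction == 0.25))

  # fractions sum to 1 per sample on random data, incl. a tiered marker
  set.seed(19)
  n <- 400
  calls <- make_calls(list(aSMA = runif(n) < 0.5, FAP = runif(n) < 0.3,
                           COL1A1 = runif(n) < 0.4))
  tiers <- list(aSMA = ifelse(runif(n) < 0.5, "high", "low"))
  tiers$aSMA[!calls$aSMA] <- "negative"
  sample_id <- sample(c("S1", "S2"), n, replace = TRUE)
  denom <- phenotype_def("fib", positive = c("aSMA", "FAP", "COL1A1"),
                         match_any = TRUE)
  tab <- enumerate_combinations(calls, sample_id, c("aSMA", "FAP", "COL1A1"),
                                denom, tiers = tiers)
  sums <- tapply(tab$fraction, tab$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # brute-force tally of one signature
  sig <- "aSMA:high|FAP:+|COL1A1:-"
  in_denom <- calls$aSMA | calls$FAP | calls$COL1A1
  brute <- sum(in_denom & sample_id == "S1" & calls$aSMA &
                 tiers$aSMA == "high" & calls$FAP & !calls$COL1A1) /
    sum(in_denom & sample_id == "S1")
  got <- tab$fraction[tab$sample_id == "S1" & tab$signature == sig]
  expect_equal(if (length(got)) got else 0, brute)

  expect_error(
    enumerate_combinations(calls, sample_id, paste0("M", 1:13), denom),
    class = "tq_config_error")
})

test_that("the 15% retention rule keeps exactly the right signatures", {
  tab <- data.table::data.table(
    sample_id = rep(c("P1", "P2", "P3"), times = 3),
    signature = rep(c("sigA", "sigB", "sigC"), each = 3),
    n = 1L,
    fraction = c(0.10, 0.16, 0.02,    # sigA: max 0.16 -> retained
                 0.14, 0.14, 0.14,    # sigB: never above 0.15 -> dropped
                 0.50, 0.60, 0.70))   # sigC: retained, ranks first
  kept <- filter_combinations(tab, 0.15)
  expect_equal(kept$signature, c("sigC", "sigA"))

  # min_fraction = 0 retains every observed signature
  expect_setequal(filter_combinations(tab, 0)$signature,
                  c("sigA", "sigB", "sigC"))

  # random table vs one-line oracle
  set.seed(23)
  rt <- data.table::data.table(
    sample_id = rep(paste0("P", 1:5), 8),
    signature = rep(paste0("sig", 1:8), each = 5),
    n = 1L, fraction = runif(40, 0, 0.3))
  kept <- filter_combinations(rt, 0.15)
  oracle <- names(which(tapply(rt$fraction, rt$signature, max) > 0.15))
  expect_setequal(kept$signature, oracle)
})
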