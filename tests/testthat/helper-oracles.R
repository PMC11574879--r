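# Independent oracles used across the suite. Each re-derives the expected
# quantity by a different route than the package implementation.

# Exact two-sided Mann-Whitney p by enumeration of all group labelings.
# U is computed by pair counting (not rank sums) for independence.
mw_perm_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); N <- length(pooled)
  u_of <- function(a, b) {
    s <- 0
    for (ai in a) for (bi in b) {
      s <- s + (ai > bi) + 0.5 * (ai == bi)
    }
    s
  }
  mu <- n1 * (N - n1) / 2
  uobs <- u_of(x, y)
  sets <- utils::combn(N, n1)
  us <- apply(sets, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  mean(abs(us - mu) >= abs(uobs - mu) - 1e-12)
}

# Brute-force phenotype rule evaluation, cell by cell.
brute_pheno <- function(calls_df, positive, negative = character(),
                        panel_markers = NULL, exclusive_single = FALSE,
                        tiers_df = NULL, tier_req = NULL) {
  n <- nrow(calls_df)
  out <- logical(n)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (m in positive) ok <- ok && isTRUE(calls_df[[m]][i])
    for (m in negative) ok <- ok && !isTRUE(calls_df[[m]][i])
    if (exclusive_single) {
      for (m in setdiff(panel_markers, positive)) {
        ok <- ok && !isTRUE(calls_df[[m]][i])
      }
    }
    if (!is.null(tier_req)) {
      for (m in names(tier_req)) ok <- ok && tiers_df[[m]][i] == tier_req[[m]]
    }
    out[i] <- ok
  }
  out
}

# Brute-force density per (sample, phenotype, demarcation): loop over cores.
brute_density <- function(cells, mask, areas, demarcation) {
  members <- demarcation_members()[[demarcation]]
  cores <- unique(cells[, c("sample_id", "core_id")])
  vals <- numeric(0)
  for (i in seq_len(nrow(cores))) {
    s <- cores$sample_id[i]; co <- cores$core_id[i]
    sel <- cells$sample_id == s & cells$core_id == co &
      cells$compartment %in% members
    n <- sum(mask[sel])
    a <- sum(areas$area_mm2[areas$sample_id == s & areas$core_id == co &
                              areas$demarcation %in% members])
    vals <- c(vals, setNames(n / a, s))
  }
  tapply(vals, names(vals), mean)
}

# Efron-tie Cox partial log-likelihood, written independently of survival::
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sumD <- sum(x[D] * beta)
    rs <- sum(exp(beta * x[R]))
    ds <- sum(exp(beta * x[D]))
    ll <- ll + sumD
    for (l in seq_len(d) - 1) {
      ll <- ll - log(rs - (l / d) * ds)
    }
  }
  ll
}

# Log-rank observed-minus-expected with hypergeometric variance, two groups.
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O - E)^2 / V
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# Spearman rho as explicit mid-rank Pearson with loops (independent route).
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# Small hand-built cohort fixture: 1 sample, 1 core, explicit cells.
toy_bundle <- function() {
  cells <- data.table::data.table(
    sample_id = "S1", core_id = "c1",
    cell_id = c("a", "b", "c"),
    x_um = c(10, 20, 30), y_um = c(5, 6, 7),
    compartment = c("tumor_nest", "stroma", "liver"),
    CD8_int = c(30, 1, 2), CD68_int = c(1, 25, 1))
  areas <- data.table::data.table(
    sample_id = "S1", core_id = "c1",
    demarcation = c("tumor_nest", "stroma", "liver"),
    area_mm2 = c(0.3, 0.25, 0.25))
  clinical <- data.table::data.table(
    sample_id = "S1", hgp = "dHGP", os_months = 24, event = 1L)
  cohort_bundle(cells, areas, clinical)
}

# Reduced null-generator config for calibration runs.
null_sim_config <- function(seed, n_per_group = 30, cells_per_core = 100) {
  sim_config(
    n_per_group = n_per_group, cells_per_core = cells_per_core,
    marker_models = default_marker_models(c("CD8", "CD68", "Calprotectin")),
    effect_table = NULL,
    survival = list(hgp_hazard_ratio = 1),
    seed = seed)
}
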