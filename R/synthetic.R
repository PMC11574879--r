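#' Default intensity models for the three staining panels
#'
#' One row per marker with the two-component log-normal intensity mixture
#' (negative and positive modes, common log-sd) and the baseline fraction of
#' positive cells. Fluorescence intensities are right-skewed and strictly
#' positive, hence the log-normal modes; the mixture weight — not the mode
#' location — carries group effects, matching how density differences arise
#' in tissue. Baseline positive fractions are order-of-magnitude realistic
#' for liver-metastasis TMA cores (abundant stromal markers like collagen I
#' and smooth-muscle actin around 25%, rare populations like NGFR+ or CD20+
#' cells a few percent).
#'
#' @param markers optional character vector restricting the panel
#' @return data.table with columns \code{marker, neg_mean, pos_mean, sdlog,
#'   pos_frac}
#' @export
default_marker_models <- function(markers = NULL) {
  mm <- data.table::data.table(
    marker = c("CD8", "CD4", "CD45R0", "CD20", "FoxP3",
               "CD68", "CD163", "Calprotectin", "MARCO",
               "aSMA", "FAP", "CD90", "NGFR", "COL1A1"),
    pos_frac = c(0.10, 0.12, 0.15, 0.03, 0.04,
                 0.20, 0.15, 0.10, 0.05,
                 0.25, 0.10, 0.10, 0.05, 0.25))
  mm$neg_mean <- 1
  mm$pos_mean <- 20
  mm$sdlog <- 0.4
  if (!is.null(markers)) {
    bad <- setdiff(markers, mm$marker)
    if (length(bad)) tq_config_error(sprintf(
      "no default intensity model for marker(s): %s",
      paste(bad, collapse = ", ")))
    mm <- mm[mm$marker %in% markers, ]
  }
  mm[]
}

#' Default group effects on positive-cell fractions
#'
#' Multiplicative effect of the desmoplastic (dHGP) group on the positive
#' fraction per marker and base compartment, relative to the
#' non-desmoplastic group. Defaults encode the directions the analysis is
#' expected to recover: cytotoxic CD8+ cells enriched inside tumor nests of
#' dHGP lesions, and the myelophagocytic markers (CD68, CD163, Calprotectin)
#' enriched in the stroma of non-dHGP lesions.
#'
#' @return data.table with columns \code{marker, compartment, effect}
#' @export
default_effect_table <- function() {
  data.table::data.table(
    marker      = c("CD8", "CD68", "CD163", "Calprotectin"),
    compartment = c("tumor_nest", "stroma", "stroma", "stroma"),
    effect      = c(2.5, 0.4, 0.4, 0.4))
}

#' Simulation configuration for the synthetic cohort generator
#'
#' @param n_per_group samples per growth-pattern group (default 50, i.e. a
#'   100-patient cohort)
#' @param cores_per_sample TMA cores per patient (default 2)
#' @param cells_per_core mean total segmented cells per core
#' @param compartment_area_means named vector of mean areas (mm2) for the
#'   three base compartments; defaults sum to ~0.8 mm2, a 1-mm TMA core
#' @param marker_models as \code{\link{default_marker_models}}
#' @param effect_table as \code{\link{default_effect_table}}; \code{NULL}
#'   means no group effects (null cohort)
#' @param survival list with \code{baseline_median_months} (median overall
#'   survival of the reference dHGP group), \code{hgp_hazard_ratio} (hazard
#'   of non-dHGP relative to dHGP; default 2.83) and \code{censor_fraction}
#'   (expected fraction administratively censored)
#' @param interaction list with \code{calprotectin_protective_hr}: hazard
#'   multiplier applied only to samples that are simultaneously
#'   Calprotectin-high and macrophage(CD68)-high in the latent abundance
#'   scale; 1 disables the interaction
#' @param sample_sd log-sd of the per-sample, per-marker latent abundance
#'   multiplier (biological between-patient variability)
#' @param area_sdlog log-sd of per-core compartment area variability
#' @param seed integer seed; every draw in \code{\link{generate_cohort}}
#'   flows from it
#' @return object of class \code{sim_config}
#' @export
sim_config <- function(n_per_group = 50,
                       cores_per_sample = 2,
                       cells_per_core = 600,
                       compartment_area_means = c(tumor_nest = 0.30,
                                                  stroma = 0.25,
                                                  liver = 0.25),
                       marker_models = default_marker_models(),
                       effect_table = default_effect_table(),
                       survival = list(baseline_median_months = 40,
                                       hgp_hazard_ratio = 2.83,
                                       censor_fraction = 0.3),
                       interaction = list(calprotectin_protective_hr = 1),
                       sample_sd = 0.5,
                       area_sdlog = 0.1,
                       seed = 1L) {
  survival <- modifyList(list(baseline_median_months = 40,
                              hgp_hazard_ratio = 2.83,
                              censor_fraction = 0.3), survival)
  interaction <- modifyList(list(calprotectin_protective_hr = 1), interaction)
  cfg <- list(n_per_group = as.integer(n_per_group),
              cores_per_sample = as.integer(cores_per_sample),
              cells_per_core = cells_per_core,
              compartment_area_means = compartment_area_means,
              marker_models = data.table::as.data.table(marker_models),
              effect_table = if (is.null(effect_table)) NULL else
                data.table::as.data.table(effect_table),
              survival = survival, interaction = interaction,
              sample_sd = sample_sd, area_sdlog = area_sdlog,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_per_group < 1 || cfg$cores_per_sample < 1 ||
      cfg$cells_per_core <= 0) {
    tq_config_error("n_per_group, cores_per_sample, cells_per_core must be positive")
  }
  if (!setequal(names(cfg$compartment_area_means), base_compartments()) ||
      any(cfg$compartment_area_means <= 0)) {
    tq_config_error("compartment_area_means must name the three base compartments with positive values")
  }
  mm <- cfg$marker_models
  if (any(mm$pos_mean <= mm$neg_mean)) {
    tq_config_error(sprintf(
      "degenerate intensity model (pos_mean <= neg_mean) for marker %s",
      mm$marker[which(mm$pos_mean <= mm$neg_mean)[1]]))
  }
  if (any(mm$pos_frac <= 0 | mm$pos_frac >= 1) || any(mm$sdlog <= 0)) {
    tq_config_error("marker_models: pos_frac must be in (0,1) and sdlog > 0")
  }
  if (cfg$survival$hgp_hazard_ratio <= 0 ||
      cfg$interaction$calprotectin_protective_hr <= 0) {
    tq_config_error("hazard ratios must be > 0")
  }
  cf <- cfg$survival$censor_fraction
  if (cf < 0 || cf >= 1) tq_config_error("censor_fraction must be in [0, 1)")
  if (!is.null(cfg$effect_table)) {
    bad <- setdiff(cfg$effect_table$marker, mm$marker)
    if (length(bad)) tq_config_error(sprintf(
      "effect_table names marker(s) without an intensity model: %s",
      paste(bad, collapse = ", ")))
    bad <- setdiff(cfg$effect_table$compartment, base_compartments())
    if (length(bad)) tq_config_error(sprintf(
      "effect_table names unknown compartment(s): %s",
      paste(bad, collapse = ", ")))
    if (any(cfg$effect_table$effect <= 0)) {
      tq_config_error("effects must be > 0")
    }
  }
  invisible(cfg)
}

# administrative censoring horizon giving the requested expected censoring
# fraction under uniform(0, cmax) censoring and per-subject exponential rates
censor_horizon <- function(rates, censor_fraction) {
  if (censor_fraction <= 0) return(Inf)
  pfun <- function(cmax) {
    mean((1 - exp(-rates * cmax)) / (rates * cmax)) - censor_fraction
  }
  stats::uniroot(pfun, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

# exponential event times + uniform administrative censoring for given
# per-subject hazard rates; caller owns the RNG state
draw_survival <- function(rates, censor_fraction) {
  t_event <- rexp(length(rates), rate = rates)
  if (censor_fraction <= 0) {
    return(list(os_months = t_event, event = rep(1L, length(rates))))
  }
  cmax <- censor_horizon(rates, censor_fraction)
  t_cens <- runif(length(rates), 0, cmax)
  list(os_months = pmin(t_event, t_cens),
       event = as.integer(t_event <= t_cens))
}

#' Simulate two-group exponential survival data
#'
#' Event times are exponential with a proportional-hazards group effect;
#' censoring is uniform administrative, calibrated to the requested expected
#' censoring fraction. Group 1 carries the elevated hazard (the non-dHGP
#' analog). Set the RNG seed before calling.
#'
#' @param n_per_group subjects per group
#' @param hazard_ratio hazard of group 1 relative to group 0 (default 2.83)
#' @param baseline_median_months median survival of group 0
#' @param censor_fraction expected censored fraction in \code{[0, 1)}
#' @return data.table with columns \code{group} (0/1), \code{os_months},
#'   \code{event}
#' @export
simulate_survival <- function(n_per_group, hazard_ratio = 2.83,
                              baseline_median_months = 40,
                              censor_fraction = 0.3) {
  if (hazard_ratio <= 0 || baseline_median_months <= 0) {
    tq_config_error("hazard_ratio and baseline_median_months must be > 0")
  }
  lam0 <- log(2) / baseline_median_months
  group <- rep(c(0L, 1L), each = n_per_group)
  rates <- lam0 * hazard_ratio^group
  s <- draw_survival(rates, censor_fraction)
  data.table::data.table(group = group, os_months = s$os_months,
                         event = s$event)
}

#' Generate a synthetic cohort bundle
#'
#' Produces a full \code{\link{cohort_bundle}} with the statistical
#' structure the analysis assumes: two growth-pattern groups, per-core base
#' compartment areas, cell counts from a thinned homogeneous point process
#' per compartment, per-cell marker intensities from two-component
#' log-normal mixtures whose positive-mode weight is scaled per
#' marker/compartment/group and by a per-sample latent abundance multiplier,
#' and exponential survival with the configured group hazard ratio. When the
#' interaction hazard multiplier differs from 1 it is applied only to
#' samples that are latently both Calprotectin-high and CD68-high (above the
#' cohort mean latent abundance, matching the mean-cutoff convention the
#' survival analysis uses), emulating a protective marker effect confined to
#' a macrophage-enriched stratum. Deterministic given
#' \code{config$seed}.
#'
#' @param config a \code{\link{sim_config}}
#' @return a \code{cohort_bundle}; \code{provenance$truth} records the
#'   per-sample group, latent multipliers and interaction stratum flags
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  mm <- config$marker_models
  n_samp <- 2L * config$n_per_group
  sample_id <- sprintf("S%03d", seq_len(n_samp))
  hgp <- rep(c("dHGP", "non_dHGP"), each = config$n_per_group)

  # per-sample latent abundance multipliers, one per marker
  L <- matrix(exp(rnorm(n_samp * nrow(mm), 0, config$sample_sd)),
              nrow = n_samp, dimnames = list(sample_id, mm$marker))

  # survival with optional calprotectin-within-macrophage-high interaction
  lam0 <- log(2) / config$survival$baseline_median_months
  rates <- lam0 * config$survival$hgp_hazard_ratio^(hgp == "non_dHGP")
  cal_hr <- config$interaction$calprotectin_protective_hr
  cal_high <- mac_high <- rep(NA, n_samp)
  if (all(c("Calprotectin", "CD68") %in% mm$marker)) {
    # "high" at the cohort mean of the latent abundance, matching the
    # mean-cutoff dichotomization convention used in the analysis
    cal_high <- L[, "Calprotectin"] > mean(L[, "Calprotectin"])
    mac_high <- L[, "CD68"] > mean(L[, "CD68"])
    if (cal_hr != 1) rates <- rates * cal_hr^(cal_high & mac_high)
  }
  s <- draw_survival(rates, config$survival$censor_fraction)
  clinical <- data.table::data.table(sample_id = sample_id, hgp = hgp,
                                     os_months = s$os_months,
                                     event = s$event)

  # per-core base compartment areas and cell counts
  am <- config$compartment_area_means[base_compartments()]
  cores <- data.table::CJ(sample_id = sample_id,
                          core_id = sprintf("core%d",
                                            seq_len(config$cores_per_sample)),
                          compartment = base_compartments(), sorted = FALSE)
  data.table::setorder(cores, sample_id, core_id, compartment)
  mu <- am[cores$compartment]
  cores$area_mm2 <- rlnorm(nrow(cores),
                           meanlog = log(mu) - config$area_sdlog^2 / 2,
                           sdlog = config$area_sdlog)
  dens0 <- config$cells_per_core / sum(am)   # base cells per mm2
  cores$n <- rpois(nrow(cores), dens0 * cores$area_mm2)

  cells <- cores[rep(seq_len(nrow(cores)), cores$n),
                 c("sample_id", "core_id", "compartment")]
  # positions uniform over a square core of the summed base area
  core_area <- cores[, list(tot = sum(area_mm2)),
                     by = c("sample_id", "core_id")]
  side <- 1000 * sqrt(core_area$tot)
  names(side) <- paste(core_area$sample_id, core_area$core_id, sep = "\r")
  sd_key <- paste(cells$sample_id, cells$core_id, sep = "\r")
  cells$x_um <- runif(nrow(cells)) * side[sd_key]
  cells$y_um <- runif(nrow(cells)) * side[sd_key]
  cells[, "cell_id" := sprintf("c%05d", seq_len(.N)),
        by = c("sample_id", "core_id")]

  # intensities: mixture weight = baseline x group effect x sample latent
  grp_dhgp <- clinical$hgp[match(cells$sample_id, clinical$sample_id)] == "dHGP"
  for (k in seq_len(nrow(mm))) {
    m <- mm$marker[k]
    p <- rep(mm$pos_frac[k], nrow(cells))
    if (!is.null(config$effect_table)) {
      et <- config$effect_table[config$effect_table$marker == m, ]
      for (j in seq_len(nrow(et))) {
        sel <- grp_dhgp & cells$compartment == et$compartment[j]
        p[sel] <- p[sel] * et$effect[j]
      }
    }
    p <- pmin(pmax(p * L[cells$sample_id, m], 0.001), 0.95)
    pos <- rbinom(nrow(cells), 1L, p) == 1L
    meanlog <- ifelse(pos, log(mm$pos_mean[k]), log(mm$neg_mean[k]))
    data.table::set(cells, j = intensity_col(m),
                    value = rlnorm(nrow(cells), meanlog, mm$sdlog))
  }

  areas <- cores[, c("sample_id", "core_id", "compartment", "area_mm2")]
  data.table::setnames(areas, "compartment", "demarcation")

  truth <- data.table::data.table(sample_id = sample_id, hgp = hgp,
                                  cal_high = cal_high, mac_high = mac_high)
  cohort_bundle(cells, areas, clinical,
                provenance = list(seed = config$seed, generator = "tmeQuant",
                                  truth = truth,
                                  latent = L))
}

#' Configuration for the synthetic expression generator
#'
#' @param n_cells number of cells (rows)
#' @param n_genes total gene universe size; filler genes named
#'   \code{GENE0001...} are appended beyond the signature/anchor genes
#' @param signature_genes character vector of signature gene symbols
#'   (default: the shipped inflammatory-fibroblast placeholder list)
#' @param anchor_gene symbol whose expression is anti-correlated with the
#'   signature (default ACTA2, the smooth-muscle actin gene)
#' @param anti_correlation_strength in \code{[0, 1]}; 0 makes the anchor
#'   independent of the signature
#' @param noise_sd log-scale residual noise sd
#' @param dropout expected zero fraction per gene; zeros are assigned with
#'   expression-dependent probability \code{exp(-lambda x^2)} (ZIFA-style),
#'   emulating single-cell dropout and making rank ties pervasive
#' @param seed integer seed
#' @return object of class \code{expr_config}
#' @export
expr_config <- function(n_cells = 3000, n_genes = 200,
                        signature_genes = NULL,
                        anchor_gene = "ACTA2",
                        anti_correlation_strength = 0.8,
                        noise_sd = 0.5, dropout = 0.2, seed = 1L) {
  if (is.null(signature_genes)) {
    signature_genes <- default_gene_sets()$iCAF
  }
  signature_genes <- unique(signature_genes)
  if (!length(signature_genes)) tq_config_error("signature_genes is empty")
  if (anchor_gene %in% signature_genes) {
    tq_config_error("anchor_gene must not be part of signature_genes (confound)")
  }
  s <- anti_correlation_strength
  if (s < 0 || s > 1) {
    tq_config_error("anti_correlation_strength must be in [0, 1]")
  }
  if (dropout < 0 || dropout >= 1) tq_config_error("dropout must be in [0, 1)")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 signature_genes = signature_genes, anchor_gene = anchor_gene,
                 anti_correlation_strength = s, noise_sd = noise_sd,
                 dropout = dropout, seed = as.integer(seed)),
            class = "expr_config")
}

#' Generate a synthetic cells-by-genes expression matrix
#'
#' Each cell carries a latent inflammatory-fibroblast activity
#' \code{a ~ N(0,1)}. Signature genes load positively on \code{a}
#' (log-normal expression), the anchor gene loads negatively with the
#' configured strength, and filler genes carry no loading. A dropout mask
#' zeroes a fraction of entries. Deterministic given \code{config$seed}.
#'
#' @param config an \code{\link{expr_config}}
#' @return list with \code{expr} (non-negative cells x genes matrix),
#'   \code{anchor} (the anchor gene's column), \code{activity} (the latent
#'   per-cell activity, for calibration checks) and \code{config}
#' @export
generate_expression <- function(config = expr_config()) {
  set.seed(config$seed)
  sig <- config$signature_genes
  genes <- c(sig, config$anchor_gene)
  n_fill <- config$n_genes - length(genes)
  if (n_fill < 0) tq_config_error("n_genes smaller than signature + anchor")
  if (n_fill > 0) genes <- c(genes, sprintf("GENE%04d", seq_len(n_fill)))

  n <- config$n_cells
  a <- rnorm(n)
  mu <- rnorm(length(genes), log(5), 0.5)
  load <- numeric(length(genes))
  names(load) <- genes
  load[sig] <- 1
  load[config$anchor_gene] <- -config$anti_correlation_strength

  logx <- outer(a, load) +
    matrix(mu, n, length(genes), byrow = TRUE) +
    matrix(rnorm(n * length(genes), 0, config$noise_sd), n, length(genes))
  x <- exp(logx)
  if (config$dropout > 0) {
    # expression-dependent dropout (ZIFA-style p = exp(-lambda x^2)), with
    # lambda calibrated per gene so the expected zero fraction matches the
    # configured rate; low-expressed entries drop out preferentially
    for (j in seq_along(genes)) {
      xj <- x[, j]
      f <- function(lam) mean(exp(-lam * xj^2)) - config$dropout
      lam <- tryCatch(stats::uniroot(f, c(1e-12, 1e6), tol = 1e-10)$root,
                      error = function(e) NA_real_)
      if (is.finite(lam)) {
        x[runif(n) < exp(-lam * xj^2), j] <- 0
      }
    }
  }
  dimnames(x) <- list(sprintf("cell%05d", seq_len(n)), genes)
  list(expr = x, anchor = x[, config$anchor_gene], activity = a,
       config = config)
}

#' Shipped placeholder fibroblast signature gene lists
#'
#' Literature-derived inflammatory (iCAF) and myofibroblastic (myCAF)
#' fibroblast marker lists, shipped as a stand-in because the study-specific
#' signatures are not reproduced here; replace via any GMT file for real
#' analyses. The same lists back the packaged
#' \code{inst/extdata/genesets/caf_signatures_synthetic.gmt}.
#'
#' @return named list of character vectors
#' @export
default_gene_sets <- function() {
  list(
    iCAF = c("IL6", "CXCL1", "CXCL2", "CXCL12", "CCL2", "CFD", "PDGFRA",
             "HAS1", "HAS2", "LMNA", "DPT", "IGF1", "C3", "C7", "CLU",
             "EFEMP1", "MGP", "OGN", "APOD", "GSN"),
    myCAF = c("TAGLN", "MYL9", "TPM1", "TPM2", "MYH11", "POSTN", "COL12A1",
              "CALD1", "CNN1", "ACTG2", "PDGFRB", "THY1", "COL5A1",
              "COL6A3", "LUM", "VCAN", "CTHRC1", "SPARC", "MMP11", "FN1"))
}
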