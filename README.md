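# tmeQuant

Quantitative profiling of the tumor microenvironment (TME) from multiplex
immunohistochemistry (mIHC) cell tables, built around the comparison of
histologic growth patterns (HGPs) in colorectal liver metastases:
desmoplastic/encapsulated lesions (dHGP) versus non-desmoplastic ones
(non-dHGP), two morphologies with markedly different prognosis and immune
contexture.

The package starts where image segmentation ends — a flat table with one
row per cell (position, tissue compartment, one intensity column per
marker), a per-core compartment area table (mm²) and a clinical table — and
provides every downstream stage as tested, reusable building blocks:

- **Gating** (`fit_threshold`, `apply_thresholds`): per-marker positivity
  cutoffs from the valley between the modes of a kernel density estimate of
  log-intensities (or quantile/fixed rules), plus high/low intensity tiers
  at the mean over positive cells (`split_intensity_tiers`, used for
  αSMA^high/low^ fibroblast splits).
- **Phenotyping** (`assign_phenotypes`): declarative marker-combination
  rules read from YAML panel files (lymphoid, myeloid, CAF panels ship with
  the package), including `_single` phenotypes (negative for all other
  panel markers), full combination enumeration over a fibroblast
  denominator (`enumerate_combinations`) and the ≥15 % per-sample retention
  rule (`filter_combinations`).
- **Density metrics** (`compute_densities`, `compute_ratios`): cells/mm²
  per compartment demarcation (tumor nests, stroma, adjacent liver, and the
  derived tumor-area / total-tissue views), per-core then averaged per
  sample; ratio metrics including the SIA (signature of immune activation,
  CD8⁺ density over an immunosuppressive myeloid population) and the
  CD8^tumor^/CD8^stroma^ exclusion ratio.
- **Group statistics** (`mann_whitney_pratt`, `adjust_pvalues`,
  `compare_hgp`, `spearman_matrix`): two-sample rank tests that retain zero
  observations in the pooled mid-ranking with tie-corrected variance
  \(σ² = (n₁n₂/12)[(N+1) − Σ(t³−t)/(N(N−1))]\), exact permutation
  enumeration for pooled N ≤ 10, Holm and Benjamini–Hochberg adjustment per
  statistical family, and Spearman co-infiltration matrices.
- **Survival** (`km_estimate`, `logrank_test`, `cox_univariate`,
  `dichotomize`, `stratified_prognosis`): Kaplan–Meier curves, log-rank
  tests, univariate Cox fits (Efron ties, Wald CIs), mean/tertile biomarker
  dichotomization and the interaction workflow that tests a marker's
  prognosis within strata of a second marker (e.g. Calprotectin within
  macrophage-high vs -low patients).
- **Signature scoring** (`ssgsea`, `anchor_correlation`,
  `tertile_compare`): per-cell single-sample gene-set enrichment (rank^α
  weighted running sum, α = 0.25), anchor-gene correlation and
  anchor-tertile comparisons for fibroblast signatures (placeholder
  iCAF/myCAF gene lists ship as a GMT; swap in your own).
- **Synthetic cohort generator** (`sim_config`, `generate_cohort`,
  `generate_expression`): a seeded simulator with two HGP groups, per-core
  compartment areas, log-normal intensity mixtures whose positive-mode
  weight carries group effects, exponential survival with a configurable
  group hazard ratio (default 2.83) and an optional protective interaction
  confined to macrophage-enriched samples — so the entire pipeline is
  testable with no patient data.
- **Pipeline** (`run_pipeline`, `inst/cli/tmequant`): configuration-driven
  orchestration writing thresholds, densities, ratios, comparison reports,
  correlation matrices, survival JSON and a reproducibility manifest.

## Worked example

```r
library(tmeQuant)

cfg <- sim_config(n_per_group = 25, cells_per_core = 400, seed = 42)
bundle <- generate_cohort(cfg)
bundle
#> <cohort_bundle> 39993 cells | 50 samples | 100 cores | markers: CD8, CD4,
#>   CD45R0, CD20, FoxP3, CD68, CD163, Calprotectin, MARCO, aSMA, FAP, CD90,
#>   NGFR, COL1A1

thresholds <- fit_thresholds(bundle$cells)            # KDE valley per marker
calls <- apply_thresholds(bundle$cells, thresholds)   # positive/negative calls
panel <- read_panel(default_panel_paths()["myeloid"])
pheno <- assign_phenotypes(calls, panel)
dm <- compute_densities(pheno, bundle$cells, bundle$areas,
                        c("tumor_nest", "stroma"))
report <- compare_hgp(dm, bundle$clinical)
report[order(report$p_holm)][1:4, c("phenotype", "demarcation", "p_raw",
                                    "p_holm", "direction",
                                    "median_dHGP", "median_non_dHGP")]
#>             phenotype demarcation    p_raw   p_holm direction median_dHGP median_non_dHGP
#> 1:         CD68_total      stroma 1.99e-07 1.59e-06  non_dHGP       38.72           112.2
#> 2:                 M1      stroma 7.51e-07 3.84e-06  non_dHGP       36.81            89.5
#> 3:                 M2      stroma 5.49e-07 3.84e-06  non_dHGP        3.98            17.8
#> 4: Calprotectin_total      stroma 6.15e-07 3.84e-06  non_dHGP       20.20            48.5
```

The report reads: stromal macrophage and Calprotectin⁺ densities (cells/mm²,
medians shown per group) are higher in the non-desmoplastic group, with
Holm-adjusted rank-test p-values from the zero/tie-retaining Mann–Whitney
test — the direction the generator's defaults encode.

```r
fit <- cox_univariate(bundle$clinical$os_months, bundle$clinical$event,
                      as.integer(bundle$clinical$hgp == "non_dHGP"))
sprintf("Cox HR (non-dHGP vs dHGP) = %.2f [%.2f, %.2f]", fit$hr,
        fit$ci[1], fit$ci[2])
#> "Cox HR (non-dHGP vs dHGP) = 5.02 [2.31, 10.95]"
```

At 25 patients per group the estimated hazard ratio is noisy (true
generator value 2.83, inside the Wald interval); the acceptance script
below averages 200 replicates at n = 300 per group.

## Command line

```sh
tmequant=$(Rscript -e 'cat(system.file("cli", "tmequant", package = "tmeQuant"))')
Rscript "$tmequant" simulate --outdir sim --seed 3 --n-per-group 10
Rscript "$tmequant" run --config analysis.yaml --outdir out
```

See `vignettes/tme-quantification-methods.Rmd` for the statistical model,
conventions (boundary rules, family definitions, tie handling) and the
limits of what the synthetic generator establishes.
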