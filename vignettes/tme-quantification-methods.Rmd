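---
title: "Methods: quantitative TME profiling from mIHC cell tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative TME profiling from mIHC cell tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmeQuant)
```

## The problem

Liver metastases of colorectal cancer grow with distinct histologic growth
patterns (HGPs): desmoplastic/encapsulated lesions (dHGP) build a fibrotic
rim between tumor and liver, while non-desmoplastic lesions (non-dHGP)
replace hepatocytes directly and carry a worse prognosis. Multiplexed
immunohistochemistry on tissue microarray (TMA) cores yields, after
segmentation, one record per cell with a tissue compartment label and a
fluorescence intensity per marker. The scientific questions downstream are
always the same shape: which immune and fibroblast populations differ
between HGP groups, in which tissue compartment, and which marker densities
carry prognostic information? tmeQuant packages that analysis chain with
explicit, frozen conventions.

## Compartments and demarcations

Cells carry one of three **base compartments**: `tumor_nest` (PanCK⁺
epithelial nests), `stroma`, `liver` (adjacent parenchyma). The five
reporting **demarcations** are views over these labels: the three base
labels, `tumor_area` = tumor_nest + stroma, `total_tissue` = tumor_area +
liver, and `total_excluding_liver` as an alias of tumor_area. Storing only
base labels makes inconsistency impossible; derived areas and counts are
aggregated *before* dividing, so a tumor-area density is
\((n_{nest}+n_{stroma})/(a_{nest}+a_{stroma})\), never a mean of
compartment densities. Regions excluded during image review (artifacts,
portal tracts, necrosis) are simply absent from the cell table; no
"excluded" label is modelled.

Two TMA cores per patient are combined by the **unweighted mean of core
densities**. The common alternative — pooling counts and areas across cores
— weights cores by area; the unweighted mean is the usual TMA convention
and is what `compute_densities` implements (the per-core table is kept as
an attribute so either can be recovered).

## Gating

Positivity thresholds are fitted **per marker over the whole cohort**
(mirroring one trained classifier per staining panel), from the kernel
density estimate of log-intensities: Gaussian kernel, Silverman bandwidth,
512 grid points; the threshold is the density minimum between the two
largest modes. Local maxima below 5 % of the main mode's height are not
counted as modes — without that prominence rule, tail wiggles of a plainly
unimodal sample register as second modes and a meaningless "valley" is
returned. A unimodal distribution raises a typed error
(`tq_no_valley_error`) so the caller can fall back to a quantile or fixed
threshold; `fit_thresholds` does this automatically and records the method
used. Thresholds serialize to TSV and re-load as `fixed`, making a run
exactly reproducible.

Frozen boundary conventions:

* a cell is **positive iff intensity ≥ threshold**;
* intensity tiers split positives at the **arithmetic mean intensity of all
  positive cells, cohort-wide**; *high* is strictly above the mean, so a
  cell exactly at the mean — and a lone positive cell — is *low*.

The cohort-wide tier cutoff (rather than per-sample) keeps "αSMA-high"
comparable across samples; a per-sample cutoff would re-center every sample
and absorb exactly the between-sample differences the analysis is after.

## Phenotyping

Panels are **data, not code**: YAML files list markers, tiered markers,
phenotype rules (required-positive, required-negative, tier constraints),
optional exclusive partitions and an optional denominator population. The
shipped panels encode the conventional subsets — e.g. M1 = CD68⁺CD163⁻,
M2 = CD68⁺CD163⁺, myeloid nonmacrophage = CD68⁻CD163⁺ — and the
`_single` convention: `exclusive_single: true` implicitly requires
negativity for every panel marker outside the rule's positive set. The
exact negative-marker scope of each published `_single` subset is not fully
enumerated anywhere, so the panel files *are* the documented assumption:
`_single` always means "within this panel".

Fibroblast combination analysis enumerates all marker combinations (αSMA
expanded to high/low/negative, other markers ±) over a denominator
population of "any CAF marker positive" cells; each denominator cell maps
to exactly one signature, so per-sample fractions partition to 1. The
retention rule keeps a signature iff its **maximum fraction across samples
is strictly greater than 0.15**. The number retained is a property of the
data, not a constant of the method.

## Group comparison

Density data per phenotype×demarcation are zero-inflated and heavily tied.
The two-sample test used throughout (`mann_whitney_pratt`) therefore:

* retains zero observations in the pooled mid-ranking (they are data, not
  missing values — the "zeros and ties" correction);
* uses the tie-corrected variance
  \(\sigma^2 = \frac{n_1 n_2}{12}\Big[(N+1) - \frac{\sum(t^3-t)}{N(N-1)}\Big]\)
  with a 0.5 continuity correction in the normal approximation, two-sided
  \(p = \min(1, 2 p_{one})\);
* switches to **exact enumeration of all \(\binom{N}{n_1}\) labelings** for
  pooled \(N \le 10\), with the two-sided p defined by the symmetric tail
  \(P(|U - n_1n_2/2| \ge |u_{obs} - n_1n_2/2|)\). The permutation
  distribution is symmetric about \(n_1n_2/2\) under label exchange, ties
  included, so this is well defined.

A caveat worth stating: for tied or strongly unbalanced small samples the
normal approximation can sit far from the exact p (a degenerate example:
one non-zero value among ten zeros has exact p = 1, approximation ≈ 0.42).
That is why the exact branch is the default for \(N \le 10\); the 0.02
approximation-accuracy check in the acceptance suite is run on the balanced
untied regime where the approximation is actually used as advertised.

Multiple testing: one statistical **family per (panel, demarcation)**, with
ratio metrics forming their own family; this matches adjusting within a
figure's marker family and is configurable via `family_of`. Both Holm
(step-down, running maximum) and Benjamini–Hochberg FDR (step-up, running
minimum) columns are always reported. Spearman co-infiltration matrices use
mid-rank Pearson correlation with the t-approximation and pairwise-complete
handling; constant densities yield a missing ρ rather than a fabricated
value.

## Survival

Kaplan–Meier, log-rank and univariate Cox regression wrap the mature
`survival` package (the test suite verifies them against independent
oracles: hand product-limit arithmetic, an observed-minus-expected /
hypergeometric-variance loop, and a from-scratch Efron partial likelihood
maximized by grid search). Conventions:

* **Efron tie handling** (more accurate than Breslow where event times tie);
* Wald 95 % CIs, \(\exp(\hat\beta \pm 1.96\,\mathrm{se})\);
* a constant covariate returns β = 0, HR = 1 with a degenerate flag instead
  of an error — no information is not a failure;
* mean-cutoff dichotomization assigns a subject **exactly at the mean to
  "low"**, consistent with the gating boundary; tertiles split by rank with
  ties broken by position (deterministic equal thirds).

`stratified_prognosis` implements the interaction workflow: the stratifier
(e.g. CD68 density) is dichotomized at the **cohort-wide** mean; within
each stratum the marker of interest is dichotomized at the within-stratum
mean and a log-rank test run, alongside the unstratified analysis. Strata
that cannot support a test (constant marker, < 2 subjects per group) are
reported as not evaluable rather than raising.

Dichotomizing a noisily measured density before testing attenuates a true
interaction substantially — roughly halving the log hazard ratio in the
synthetic calibration — which is worth remembering when reading borderline
stratified p-values on modest cohorts. A dominant global prognostic factor
(such as the HGP effect itself) further masks within-stratum effects; run
the stratified analysis within one prognostic subset when such a factor is
present, which is how the reference workflow handles it.

## Signature scoring

`ssgsea` implements the per-cell single-sample enrichment score: genes are
mid-ranked by expression within each cell, walked in decreasing order (ties
broken by column position, deterministic), accumulating
rank^α-weighted in-set hits against uniform out-of-set misses; the score is
the sum of the running-sum differences, with α = 0.25 by convention.
Because only ranks enter, the score is exactly invariant under any strictly
increasing per-cell transform — the acceptance suite asserts bit-level
equality under `log1p`. With α = 0 it reduces to the unweighted
Kolmogorov–Smirnov-sum statistic. Mid-ranks matter because single-cell
matrices are full of tied zeros.

The shipped iCAF/myCAF gene lists are **literature-derived placeholders**
(the study-specific signature lists are not public); the GMT file is named
`caf_signatures_synthetic.gmt` to make the substitution visible, and any
GMT can be supplied instead. Scores are reported unnormalized by default
(`normalize = TRUE` applies min–max across cells); every shipped analysis
is rank-based downstream, so the choice does not affect conclusions.

## The synthetic cohort: what it states and what it does not

The generator is a stated world, fixed once:

| parameter | default | rationale |
|---|---|---|
| samples per group | 50 | a 100-patient TMA cohort |
| cores per sample | 2 | standard TMA design |
| cells per core (mean) | 600 | ~750 cells/mm² over a 0.8 mm² core |
| base areas (mm²) | 0.30 / 0.25 / 0.25 | 1-mm core split into nest/stroma/liver |
| intensity mixture | log-normal modes at 1 and 20, log-sd 0.4 | right-skewed, strictly positive fluorescence |
| baseline positive fractions | 3–25 % per marker | rare (CD20, NGFR) to abundant (COL1A1, αSMA) populations |
| group effects | CD8 ×2.5 in tumor nests (dHGP); CD68/CD163/Calprotectin ×0.4 (dHGP stroma) | the effect directions the analysis should recover |
| per-sample latent abundance | log-normal, sd 0.5 | between-patient biological variability |
| survival | exponential, median 40 months, group HR 2.83, 30 % uniform censoring | closed-form parameter-recovery truth |
| interaction | protective HR (default off) applied iff latently Calprotectin-high **and** CD68-high | marker effect confined to a macrophage-enriched stratum |
| expression dropout | 20 % zeros, \(p = e^{-\lambda x^2}\) per gene | expression-dependent dropout; uniform zeroing is both less realistic and destroys anchor-gene rank information |

Group effects act on the **mixture weight** (the fraction of positive
cells), not on mode locations — density differences in tissue arise from
how many cells express a marker, not from brighter staining. Latent "high"
flags for the interaction use the cohort **mean** of the latent abundance,
matching the mean-cutoff convention of the analysis; defining truth at the
median while analyzing at the mean would build a systematic ~10 %
misclassification into the world (log-normal latents have mean > median).

Deliberately **not** emulated: spatial clustering and neighborhood
structure (positions are uniform plumbing), correlations between markers
beyond co-occurrence on shared cells, slide/batch effects, cross-slide
intensity drift, segmentation errors, and cell-shape features. A green test
on this generator therefore establishes that the *statistical machinery*
recovers known structure at realistic sizes and noise — it says nothing
about robustness to segmentation artifacts or batch confounding, which real
studies must address upstream.

## Numerical choices and degenerate inputs

* Area additivity is validated to relative tolerance 1e-6; partition
  reconciliation to 1e-9 relative.
* Zero-denominator ratios are missing, never ∞ and never pseudocounted —
  a pseudocount would manufacture an ordering among true zeros.
* Zero area with a nonzero cell count is a hard data error.
* All randomness flows from a single seed; the pipeline derives a named
  sub-seed per stage, so removing one stage never shifts another stage's
  draws.
* Exact rank-test enumeration is capped at pooled N ≤ 10
  (\(\binom{10}{5} = 252\) labelings); combination enumeration is capped at
  12 markers.

## Known limitations

Core-level pseudo-replication is averaged, not modelled (no mixed models);
FDR is plain Benjamini–Hochberg, not permutation-based; Cox is univariate
by design — the package stratifies rather than adjusts; the CLI exposes
`simulate` and `run` (with stage selection) rather than one subcommand per
stage; and the shipped signature lists are placeholders as noted above.
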