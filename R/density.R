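#' Compute compartment-stratified cell densities
#'
#' Per core and demarcation, density = (cells matching the phenotype whose
#' base compartment belongs to the demarcation) / (summed base-compartment
#' area in mm2). Derived demarcations aggregate counts and areas before
#' dividing, so e.g. the tumor_area density equals
#' (n_tumor_nest + n_stroma) / (a_tumor_nest + a_stroma), not the mean of
#' the two compartment densities. The sample-level value is the unweighted
#' mean across that sample's cores (the common TMA convention).
#'
#' @param pheno \code{phenotype_calls} (or a bare logical matrix/data.table
#'   with named columns, e.g. \code{marker_calls} for per-marker totals)
#' @param cells cell data.table row-aligned with the calls
#' @param areas area table (\code{sample_id, core_id, demarcation,
#'   area_mm2}; base compartments suffice)
#' @param demarcations demarcation names to compute (default: all five plus
#'   the three base labels)
#' @return \code{density_matrix}: data.table \code{(sample_id, phenotype,
#'   demarcation, density)} with the per-core table in attribute
#'   \code{cores}
#' @export
compute_densities <- function(pheno, cells, areas,
                              demarcations = names(demarcation_members())) {
  mat <- if (inherits(pheno, "phenotype_calls")) pheno$matrix else
    as.matrix(as.data.frame(pheno))
  if (nrow(mat) != nrow(cells)) {
    tq_data_error("calls and cells are not row-aligned")
  }
  dm <- demarcation_members()
  bad <- setdiff(demarcations, names(dm))
  if (length(bad)) tq_config_error(sprintf("unknown demarcation(s): %s",
                                           paste(bad, collapse = ", ")))
  areas <- data.table::as.data.table(areas)
  base_areas <- areas[areas$demarcation %in% base_compartments(), ]

  # per core x base compartment phenotype counts
  cdt <- data.table::data.table(sample_id = cells$sample_id,
                                core_id = cells$core_id,
                                compartment = cells$compartment)
  counts <- cbind(cdt, data.table::as.data.table(mat))
  counts <- counts[, lapply(.SD, sum),
                   by = c("sample_id", "core_id", "compartment"),
                   .SDcols = colnames(mat)]

  core_rows <- list()
  for (d in demarcations) {
    members <- dm[[d]]
    a <- base_areas[base_areas$demarcation %in% members,
                    list(area_mm2 = sum(area_mm2)),
                    by = c("sample_id", "core_id")]
    n <- counts[counts$compartment %in% members,
                lapply(.SD, sum), by = c("sample_id", "core_id"),
                .SDcols = colnames(mat)]
    mg <- merge(a, n, by = c("sample_id", "core_id"), all.x = TRUE)
    for (ph in colnames(mat)) {
      data.table::set(mg, which(is.na(mg[[ph]])), ph, 0)
    }
    if (any(mg$area_mm2 <= 0 &
            rowSums(mg[, colnames(mat), with = FALSE]) > 0)) {
      tq_data_error(sprintf("zero area with nonzero cell count in %s", d))
    }
    long <- data.table::melt(mg, id.vars = c("sample_id", "core_id", "area_mm2"),
                             variable.name = "phenotype", value.name = "n",
                             variable.factor = FALSE)
    long$demarcation <- d
    long$density <- ifelse(long$area_mm2 > 0, long$n / long$area_mm2, 0)
    core_rows[[d]] <- long
  }
  core_tab <- data.table::rbindlist(core_rows)
  samp <- core_tab[, list(density = mean(density)),
                   by = c("sample_id", "phenotype", "demarcation")]
  data.table::setattr(samp, "cores", core_tab)
  data.table::setattr(samp, "class", c("density_matrix", class(samp)))
  samp[]
}

#' Standard ratio metric specifications
#'
#' The shipped ratio list: the three immune-activation (SIA) ratios of CD8+
#' density to an immunosuppressive myeloid population in the stroma, the
#' tumor-exclusion ratio CD8(tumor_nest)/CD8(stroma), the intraepithelial
#' CD8 to stromal CD4 ratio, and CD8/CD4 within each demarcation.
#'
#' @param demarcations demarcations for the per-compartment CD8/CD4 ratios
#' @return data.table \code{(ratio_name, num_phenotype, num_demarcation,
#'   den_phenotype, den_demarcation)}
#' @export
default_ratio_specs <- function(demarcations = c("tumor_nest", "stroma",
                                                 "total_excluding_liver")) {
  base <- data.table::data.table(
    ratio_name = c("SIA_M2", "SIA_myeloid_nonmac", "SIA_calprotectin",
                   "CD8tumor_over_CD8stroma", "CD8tumor_over_CD4stroma"),
    num_phenotype = c("CD8_total", "CD8_total", "CD8_total",
                      "CD8_total", "CD8_total"),
    num_demarcation = c("stroma", "stroma", "stroma",
                        "tumor_nest", "tumor_nest"),
    den_phenotype = c("M2", "myeloid_nonmacrophage", "Calprotectin_total",
                      "CD8_total", "CD4_total"),
    den_demarcation = c("stroma", "stroma", "stroma", "stroma", "stroma"))
  cd84 <- data.table::data.table(
    ratio_name = paste0("CD8_over_CD4_", demarcations),
    num_phenotype = "CD8_total", num_demarcation = demarcations,
    den_phenotype = "CD4_total", den_demarcation = demarcations)
  data.table::rbindlist(list(base, cd84))
}

#' Compute per-sample ratio metrics from a density matrix
#'
#' Ratio = numerator density / denominator density per sample. A zero
#' denominator yields a missing value (never infinity): pseudocounts would
#' manufacture an ordering among true zeros.
#'
#' @param dm \code{density_matrix} from \code{\link{compute_densities}}
#' @param specs ratio specification table as
#'   \code{\link{default_ratio_specs}}
#' @return \code{ratio_table}: data.table \code{(sample_id, ratio_name,
#'   value)}, \code{value = NA} where the denominator is zero
#' @export
compute_ratios <- function(dm, specs = default_ratio_specs()) {
  out <- list()
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    num <- dm[dm$phenotype == s$num_phenotype &
                dm$demarcation == s$num_demarcation, ]
    den <- dm[dm$phenotype == s$den_phenotype &
                dm$demarcation == s$den_demarcation, ]
    if (!nrow(num)) tq_config_error(sprintf(
      "ratio %s: phenotype %s / demarcation %s absent from density matrix",
      s$ratio_name, s$num_phenotype, s$num_demarcation))
    if (!nrow(den)) tq_config_error(sprintf(
      "ratio %s: phenotype %s / demarcation %s absent from density matrix",
      s$ratio_name, s$den_phenotype, s$den_demarcation))
    mg <- merge(num[, c("sample_id", "density")],
                den[, c("sample_id", "density")],
                by = "sample_id", suffixes = c("_num", "_den"))
    out[[i]] <- data.table::data.table(
      sample_id = mg$sample_id, ratio_name = s$ratio_name,
      value = ifelse(mg$density_den > 0, mg$density_num / mg$density_den,
                     NA_real_))
  }
  rt <- data.table::rbindlist(out)
  data.table::setattr(rt, "class", c("ratio_table", class(rt)))
  rt[]
}
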