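#' Base tissue compartments and derived demarcations
#'
#' Cells carry exactly one of three base compartment labels assigned during
#' image segmentation: \code{tumor_nest} (PanCK+ epithelial nests),
#' \code{stroma} (intratumoral stroma including the fibrous capsule) and
#' \code{liver} (adjacent normal liver parenchyma). The five analysis
#' demarcations used for density reporting are views over these labels and
#' are never stored redundantly:
#' \describe{
#'   \item{tumor_nest, stroma, liver}{the base labels themselves}
#'   \item{tumor_area}{tumor_nest + stroma (the malignant lesion)}
#'   \item{total_excluding_liver}{alias of tumor_area}
#'   \item{total_tissue}{tumor_area + liver (the whole core)}
#' }
#'
#' @return \code{base_compartments}: character vector of the three base
#'   labels. \code{demarcation_members}: named list mapping each demarcation
#'   to the base compartments it aggregates.
#' @export
base_compartments <- function() c("tumor_nest", "stroma", "liver")

#' @rdname base_compartments
#' @export
demarcation_members <- function() {
  list(
    tumor_nest            = "tumor_nest",
    stroma                = "stroma",
    liver                 = "liver",
    tumor_area            = c("tumor_nest", "stroma"),
    total_excluding_liver = c("tumor_nest", "stroma"),
    total_tissue          = c("tumor_nest", "stroma", "liver")
  )
}

#' Marker columns of a cell table
#'
#' Marker intensity columns are identified by the \code{_int} suffix
#' (inForm-export-like convention); names are case-sensitive.
#'
#' @param cells cell data.table
#' @return character vector of marker names (suffix stripped)
#' @export
marker_names <- function(cells) {
  sub("_int$", "", grep("_int$", names(cells), value = TRUE))
}

intensity_col <- function(marker) paste0(marker, "_int")

#' Construct a cohort bundle
#'
#' A cohort bundle holds the three linked tables the pipeline consumes: the
#' per-cell table (one row per segmented cell with identifiers, position,
#' base compartment and one \code{<MARKER>_int} column per marker), the
#' per-core compartment area table (mm2), and the per-sample clinical table
#' (growth-pattern class, overall survival, event flag).
#'
#' @param cells data.table with columns \code{sample_id, core_id, cell_id,
#'   x_um, y_um, compartment} plus \code{<MARKER>_int} columns
#' @param areas data.table with columns \code{sample_id, core_id,
#'   demarcation, area_mm2}; base compartments suffice, derived demarcations
#'   are computed on demand
#' @param clinical data.table with columns \code{sample_id, hgp, os_months,
#'   event}; \code{hgp} is \code{dHGP} or \code{non_dHGP}
#' @param provenance free-text list (seed, generator config, file paths)
#' @return object of class \code{cohort_bundle}
#' @export
cohort_bundle <- function(cells, areas, clinical, provenance = list()) {
  cells <- data.table::as.data.table(cells)
  areas <- data.table::as.data.table(areas)
  clinical <- data.table::as.data.table(clinical)

  need <- c("sample_id", "core_id", "cell_id", "x_um", "y_um", "compartment")
  miss <- setdiff(need, names(cells))
  if (length(miss)) {
    tq_schema_error(sprintf("cell table missing required column(s): %s",
                            paste(miss, collapse = ", ")))
  }
  miss <- setdiff(c("sample_id", "core_id", "demarcation", "area_mm2"),
                  names(areas))
  if (length(miss)) {
    tq_schema_error(sprintf("area table missing required column(s): %s",
                            paste(miss, collapse = ", ")))
  }
  miss <- setdiff(c("sample_id", "hgp", "os_months", "event"), names(clinical))
  if (length(miss)) {
    tq_schema_error(sprintf("clinical table missing required column(s): %s",
                            paste(miss, collapse = ", ")))
  }

  bad <- setdiff(unique(cells$compartment), base_compartments())
  if (length(bad)) {
    tq_value_error(sprintf("unknown compartment label(s): %s",
                           paste(bad, collapse = ", ")))
  }
  for (m in marker_names(cells)) {
    v <- cells[[intensity_col(m)]]
    if (any(!is.finite(v) | v < 0)) {
      tq_value_error(sprintf(
        "negative or non-finite intensity for marker %s at row %d",
        m, which(!is.finite(v) | v < 0)[1]))
    }
  }
  if (any(!is.finite(areas$area_mm2) | areas$area_mm2 < 0)) {
    tq_value_error(sprintf("negative or non-finite area at row %d",
                           which(!is.finite(areas$area_mm2) |
                                   areas$area_mm2 < 0)[1]))
  }
  orphans <- setdiff(unique(cells$sample_id), unique(clinical$sample_id))
  if (length(orphans)) {
    tq_linkage_error(sprintf(
      "sample(s) present in cells but absent from clinical: %s",
      paste(orphans, collapse = ", ")))
  }
  orphans <- setdiff(unique(cells$sample_id), unique(areas$sample_id))
  if (length(orphans)) {
    tq_linkage_error(sprintf(
      "sample(s) present in cells but absent from areas: %s",
      paste(orphans, collapse = ", ")))
  }

  structure(list(cells = cells, areas = areas, clinical = clinical,
                 provenance = provenance),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "<cohort_bundle> %d cells | %d samples | %d cores | markers: %s\n",
    nrow(x$cells), length(unique(x$cells$sample_id)),
    nrow(unique(x$cells[, c("sample_id", "core_id")])),
    paste(marker_names(x$cells), collapse = ", ")))
  invisible(x)
}

#' Read a cohort from delimited text files
#'
#' Reads the cell, area and clinical tables (TSV or CSV, auto-detected by
#' \code{data.table::fread}) and returns a validated \code{\link{cohort_bundle}}.
#' Marker columns are auto-detected by the \code{_int} suffix.
#'
#' @param cell_path,area_path,clinical_path paths to the three tables
#' @return a \code{cohort_bundle}
#' @export
read_cohort <- function(cell_path, area_path, clinical_path) {
  for (p in c(cell_path, area_path, clinical_path)) {
    if (!file.exists(p)) tq_schema_error(sprintf("file not found: %s", p))
  }
  cells <- data.table::fread(cell_path)
  areas <- data.table::fread(area_path)
  clinical <- data.table::fread(clinical_path)
  cohort_bundle(cells, areas, clinical,
                provenance = list(cell_path = cell_path,
                                  area_path = area_path,
                                  clinical_path = clinical_path))
}

#' Write a cohort bundle to delimited text files
#'
#' @param bundle a \code{cohort_bundle}
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return named character vector of the three written paths, invisibly
#' @export
write_cohort <- function(bundle, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cells    = file.path(dir, paste0(prefix, "_cells.tsv")),
    areas    = file.path(dir, paste0(prefix, "_areas.tsv")),
    clinical = file.path(dir, paste0(prefix, "_clinical.tsv")))
  data.table::fwrite(bundle$cells, paths["cells"], sep = "\t")
  data.table::fwrite(bundle$areas, paths["areas"], sep = "\t")
  data.table::fwrite(bundle$clinical, paths["clinical"], sep = "\t")
  invisible(paths)
}

#' Validate a cohort bundle
#'
#' Checks every structural invariant and returns all violations as a table
#' rather than throwing: non-finite or negative intensities, unknown
#' compartment labels, duplicate cell identifiers, cells whose sample is
#' missing from the clinical or area tables, non-positive areas where cells
#' exist, area additivity (tumor_nest + stroma = tumor_area, tumor_area +
#' liver = total_tissue, checked at relative tolerance \code{tol} where the
#' derived rows are present), and clinical invariants (non-negative survival
#' time, binary event flag, non-missing growth-pattern class). An empty
#' report means the bundle passes.
#'
#' @param bundle a \code{cohort_bundle}
#' @param tol relative tolerance for area additivity
#' @return data.table with columns \code{check, location, message}; zero
#'   rows iff the bundle is valid
#' @export
validate_bundle <- function(bundle, tol = 1e-6) {
  f <- list()
  add <- function(check, location, message) {
    f[[length(f) + 1L]] <<- data.table::data.table(
      check = check, location = location, message = message)
  }
  cells <- bundle$cells; areas <- bundle$areas; clin <- bundle$clinical

  bad <- which(!cells$compartment %in% base_compartments())
  for (i in bad) add("compartment", sprintf("cells row %d", i),
                     sprintf("unknown compartment '%s'", cells$compartment[i]))
  for (m in marker_names(cells)) {
    v <- cells[[intensity_col(m)]]
    idx <- which(!is.finite(v) | v < 0)
    for (i in idx) add("intensity", sprintf("cells row %d", i),
                       sprintf("non-finite or negative %s intensity", m))
  }
  key <- paste(cells$sample_id, cells$core_id, cells$cell_id, sep = "\r")
  dup <- which(duplicated(key))
  for (i in dup) add("cell_id", sprintf("cells row %d", i),
                     "duplicate (sample_id, core_id, cell_id)")
  for (s in setdiff(unique(cells$sample_id), unique(clin$sample_id))) {
    add("linkage", s, "sample in cells but not in clinical")
  }
  for (s in setdiff(unique(cells$sample_id), unique(areas$sample_id))) {
    add("linkage", s, "sample in cells but not in areas")
  }

  # areas must be positive wherever cells exist
  n_by_core <- cells[, list(n = .N),
                     by = c("sample_id", "core_id", "compartment")]
  aw <- data.table::dcast(areas, sample_id + core_id ~ demarcation,
                          value.var = "area_mm2", fun.aggregate = sum,
                          fill = NA_real_)
  mg <- merge(n_by_core, areas,
              by.x = c("sample_id", "core_id", "compartment"),
              by.y = c("sample_id", "core_id", "demarcation"),
              all.x = TRUE)
  bad <- which(mg$n > 0 & (is.na(mg$area_mm2) | mg$area_mm2 <= 0))
  for (i in bad) add("area", sprintf("%s/%s/%s", mg$sample_id[i],
                                     mg$core_id[i], mg$compartment[i]),
                     "cells present but compartment area missing or <= 0")

  rel_ne <- function(a, b) is.finite(a) & is.finite(b) &
    abs(a - b) > tol * pmax(abs(a), abs(b), 1e-12)
  chk_add <- function(lhs_cols, rhs_col, label) {
    if (all(c(lhs_cols, rhs_col) %in% names(aw))) {
      lhs <- Reduce(`+`, lapply(lhs_cols, function(cc) aw[[cc]]))
      idx <- which(rel_ne(lhs, aw[[rhs_col]]))
      for (i in idx) add("area_additivity",
                         sprintf("%s/%s", aw$sample_id[i], aw$core_id[i]),
                         label)
    }
  }
  chk_add(c("tumor_nest", "stroma"), "tumor_area",
          "tumor_nest + stroma != tumor_area")
  chk_add(c("tumor_area", "liver"), "total_tissue",
          "tumor_area + liver != total_tissue")
  chk_add("tumor_area", "total_excluding_liver",
          "total_excluding_liver != tumor_area")

  idx <- which(!is.finite(clin$os_months) | clin$os_months < 0)
  for (i in idx) add("clinical", sprintf("clinical row %d", i),
                     "os_months negative or non-finite")
  idx <- which(!clin$event %in% c(0, 1))
  for (i in idx) add("clinical", sprintf("clinical row %d", i),
                     "event flag not in {0, 1}")
  idx <- which(is.na(clin$hgp) | !nzchar(as.character(clin$hgp)))
  for (i in idx) add("clinical", sprintf("clinical row %d", i),
                     "missing hgp class")

  if (length(f)) data.table::rbindlist(f) else
    data.table::data.table(check = character(), location = character(),
                           message = character())
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated \code{name, description,
#' gene1, gene2, ...}. Duplicate symbols within a set are dropped.
#'
#' @param path GMT file path
#' @return named list of character vectors of gene symbols
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) tq_schema_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      tq_schema_error("GMT line has fewer than 3 tab-separated fields")
    }
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) tq_schema_error(sprintf("empty gene set '%s'", parts[1]))
    out[[parts[1]]] <- genes
  }
  out
}
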