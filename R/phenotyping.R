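#' Declarative phenotype definition
#'
#' A phenotype is a boolean rule over marker calls: all \code{positive}
#' markers must be called positive, all \code{negative} markers negative,
#' tier constraints must hold, and if \code{exclusive_single} is set every
#' panel marker outside \code{positive} is implicitly required negative (the
#' \code{_single} convention). \code{match_any} relaxes \code{positive} to
#' at-least-one (used for umbrella denominators such as "any fibroblast
#' marker positive").
#'
#' @param name phenotype name
#' @param positive,negative character vectors of marker names
#' @param tiers named list/character: marker -> required tier (\code{high}
#'   or \code{low})
#' @param exclusive_single logical
#' @param match_any logical
#' @return object of class \code{phenotype_def}
#' @export
phenotype_def <- function(name, positive, negative = character(),
                          tiers = NULL, exclusive_single = FALSE,
                          match_any = FALSE) {
  positive <- as.character(positive %||% character())
  negative <- as.character(negative %||% character())
  if (length(intersect(positive, negative))) {
    tq_config_error(sprintf("phenotype %s: positive and negative overlap", name))
  }
  structure(list(name = name, positive = positive, negative = negative,
                 tiers = as.list(tiers %||% list()),
                 exclusive_single = isTRUE(exclusive_single),
                 match_any = isTRUE(match_any)),
            class = "phenotype_def")
}

#' Read a staining panel from YAML
#'
#' Panels are data, not code: a YAML file lists the panel's markers, which
#' markers are intensity-tiered, the phenotype definitions, optional
#' mutually-exclusive partitions used for density reconciliation checks, and
#' an optional denominator definition for combination enumeration. The
#' packaged panels live under \code{inst/extdata/panels/}.
#'
#' @param path YAML file path
#' @return object of class \code{tq_panel}: list with \code{name},
#'   \code{markers}, \code{tiered_markers}, \code{phenotypes} (named list of
#'   \code{\link{phenotype_def}}), \code{partitions}, \code{denominator}
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) tq_schema_error(sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$markers) || is.null(y$phenotypes)) {
    tq_schema_error("panel file needs 'markers' and 'phenotypes'")
  }
  phenos <- lapply(y$phenotypes, function(p) {
    phenotype_def(p$name, p$positive, p$negative, p$tiers,
                  p$exclusive_single %||% FALSE, p$match_any %||% FALSE)
  })
  names(phenos) <- vapply(phenos, `[[`, "", "name")
  denom <- if (!is.null(y$denominator)) {
    phenotype_def(y$denominator$name, y$denominator$positive,
                  y$denominator$negative, y$denominator$tiers,
                  y$denominator$exclusive_single %||% FALSE,
                  y$denominator$match_any %||% FALSE)
  }
  structure(list(name = y$name %||% basename(path),
                 markers = as.character(y$markers),
                 tiered_markers = as.character(y$tiered_markers %||% character()),
                 phenotypes = phenos,
                 partitions = y$partitions %||% list(),
                 denominator = denom),
            class = "tq_panel")
}

#' Paths of the packaged panel files
#'
#' @return named character vector (lymphoid, myeloid, caf)
#' @export
default_panel_paths <- function() {
  dir <- system.file("extdata", "panels", package = "tmeQuant")
  c(lymphoid = file.path(dir, "lymphoid.yaml"),
    myeloid = file.path(dir, "myeloid.yaml"),
    caf = file.path(dir, "caf.yaml"))
}

# evaluate one definition against calls (+ tiers) -> logical vector
match_phenotype <- function(def, calls, tiers, panel_markers) {
  n <- nrow(calls)
  for (m in c(def$positive, def$negative, names(def$tiers))) {
    if (is.null(calls[[m]])) {
      tq_config_error(sprintf(
        "phenotype %s references marker %s absent from calls", def$name, m))
    }
  }
  ok <- rep(TRUE, n)
  if (length(def$positive)) {
    pos <- as.matrix(calls[, def$positive, with = FALSE])
    ok <- ok & if (def$match_any) rowSums(pos) > 0 else rowSums(pos) == ncol(pos)
  }
  for (m in def$negative) ok <- ok & !calls[[m]]
  if (def$exclusive_single) {
    for (m in setdiff(panel_markers, def$positive)) ok <- ok & !calls[[m]]
  }
  for (m in names(def$tiers)) {
    tv <- tiers[[m]]
    if (is.null(tv)) {
      tq_config_error(sprintf("phenotype %s needs tiers for marker %s",
                              def$name, m))
    }
    ok <- ok & tv == def$tiers[[m]]
  }
  ok
}

#' Assign cells to panel phenotypes
#'
#' Evaluates every phenotype rule of a panel against per-cell marker calls
#' (and tier calls for tiered markers). A cell may match several
#' non-exclusive definitions; declared partitions are checked downstream via
#' density reconciliation.
#'
#' @param calls \code{marker_calls} from \code{\link{apply_thresholds}}
#' @param panel \code{tq_panel} from \code{\link{read_panel}}
#' @param tiers named list marker -> tier vector (from
#'   \code{\link{split_intensity_tiers}})
#' @return \code{phenotype_calls}: list with \code{matrix} (cells x
#'   phenotypes logical) and \code{panel}
#' @export
assign_phenotypes <- function(calls, panel, tiers = NULL) {
  mat <- vapply(panel$phenotypes, match_phenotype, logical(nrow(calls)),
                calls = calls, tiers = tiers, panel_markers = panel$markers)
  if (nrow(calls) == 1L) mat <- matrix(mat, nrow = 1,
                                       dimnames = list(NULL, names(panel$phenotypes)))
  if (nrow(calls) == 0L) mat <- matrix(logical(), 0, length(panel$phenotypes),
                                       dimnames = list(NULL, names(panel$phenotypes)))
  structure(list(matrix = mat, panel = panel), class = "phenotype_calls")
}

#' Enumerate all marker-combination signatures within a denominator population
#'
#' Every cell of the denominator population maps to exactly one signature
#' over the ordered marker set; tiered markers contribute three levels
#' (\code{high}, \code{low}, \code{-}), others two (\code{+}, \code{-}).
#' Fractions are computed per sample over the denominator count; samples
#' with an empty denominator are recorded as missing.
#'
#' @param calls \code{marker_calls}
#' @param sample_id character vector row-aligned with \code{calls}
#' @param markers ordered marker set to combine (max 12)
#' @param denominator \code{\link{phenotype_def}} of the denominator
#'   population (e.g. all fibroblasts)
#' @param panel panel the denominator belongs to (for
#'   \code{exclusive_single} scope); defaults to the marker set itself
#' @param tiers named list marker -> tier vector for tiered markers
#' @return \code{combination_fractions}: data.table \code{(sample_id,
#'   signature, n, fraction)}; attribute \code{empty_samples} lists samples
#'   with no denominator cells
#' @export
enumerate_combinations <- function(calls, sample_id, markers, denominator,
                                   panel = NULL, tiers = NULL) {
  if (length(markers) > 12) {
    tq_config_error("more than 12 markers: combinatorial guard tripped")
  }
  panel_markers <- if (is.null(panel)) markers else panel$markers
  in_denom <- match_phenotype(denominator, calls, tiers, panel_markers)

  parts <- lapply(markers, function(m) {
    if (!is.null(tiers[[m]])) {
      paste0(m, ":", ifelse(calls[[m]],
                            ifelse(tiers[[m]] == "high", "high", "low"), "-"))
    } else {
      paste0(m, ":", ifelse(calls[[m]], "+", "-"))
    }
  })
  sig <- do.call(paste, c(parts, sep = "|"))

  all_samples <- unique(sample_id)
  dt <- data.table::data.table(sample_id = sample_id[in_denom],
                               signature = sig[in_denom])
  tab <- dt[, list(n = .N), by = c("sample_id", "signature")]
  tab[, "fraction" := n / sum(n), by = "sample_id"]
  empty <- setdiff(all_samples, unique(tab$sample_id))
  data.table::setattr(tab, "empty_samples", empty)
  data.table::setattr(tab, "markers", markers)
  data.table::setattr(tab, "class",
                      c("combination_fractions", class(tab)))
  tab[]
}

#' Retain combination signatures exceeding a per-sample fraction cutoff
#'
#' A signature is retained iff its maximum fraction over samples is strictly
#' greater than \code{min_fraction} (default 0.15: present above 15% of the
#' denominator population in at least one sample). Output is sorted by
#' maximum fraction, descending.
#'
#' @param table \code{combination_fractions} from
#'   \code{\link{enumerate_combinations}}
#' @param min_fraction retention cutoff
#' @return data.table \code{(signature, max_fraction)} of retained signatures
#' @export
filter_combinations <- function(table, min_fraction = 0.15) {
  if (!nrow(table)) tq_value_error("empty combination table")
  mx <- table[, list(max_fraction = max(fraction)), by = "signature"]
  keep <- mx[mx$max_fraction > min_fraction, ]
  data.table::setorder(keep, -max_fraction)
  keep[]
}
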