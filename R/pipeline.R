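#' Load and validate a pipeline configuration
#'
#' The configuration is a single YAML (or JSON) document with either a
#' \code{simulate:} block (forwarded to \code{\link{sim_config}}) or an
#' \code{inputs:} block naming the three cohort files; optional blocks
#' select panels, demarcations, threshold method, ratio specs, survival
#' analyses and the signature stage. Defaults are filled in so a minimal
#' config is just \code{simulate: {}}.
#'
#' @param path config file path
#' @return validated config list
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) tq_config_error(sprintf("config not found: %s", path))
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path) else
    yaml::read_yaml(path)
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    tq_config_error("config needs either a 'simulate' or an 'inputs' block")
  }
  if (!is.null(cfg$inputs)) {
    for (k in c("cells", "areas", "clinical")) {
      if (is.null(cfg$inputs[[k]]) || !file.exists(cfg$inputs[[k]])) {
        tq_config_error(sprintf("inputs$%s missing or not found", k))
      }
    }
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$demarcations <- unlist(cfg$demarcations) %||% names(demarcation_members())
  cfg$threshold <- modifyList(list(method = "kde_valley", fallback = 0.9),
                              cfg$threshold %||% list())
  cfg$panels <- unlist(cfg$panels) %||% unname(default_panel_paths())
  cfg
}

write_tsv <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t")
  path
}

#' Run the full profiling pipeline
#'
#' Executes the stages in dependency order: simulate/read, gate, phenotype,
#' density + ratios, group comparison + co-infiltration correlation,
#' survival analyses, and (if configured) signature scoring. Any stage
#' failure aborts with the stage name; outputs written by earlier stages
#' are left intact. All randomness flows from the config seed via a named
#' substream per stage.
#'
#' @param config path to a config file, or a pre-parsed config list
#' @param outdir output directory (overrides the config's
#'   \code{output_dir})
#' @return \code{result_bundle}: list of in-memory results plus
#'   \code{paths} of the written files and the run \code{manifest}
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  outdir <- outdir %||% cfg$output_dir %||% "tmequant_out"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- "init"
  log <- function(...) message(sprintf("[%s] ", stage), sprintf(...))

  res <- tryCatch({
    # ---- cohort ----
    stage <- "cohort"
    bundle <- if (!is.null(cfg$simulate)) {
      sc <- do.call(sim_config, modifyList(
        cfg$simulate, list(seed = stage_seed(cfg$seed, "simulate"))))
      generate_cohort(sc)
    } else {
      read_cohort(cfg$inputs$cells, cfg$inputs$areas, cfg$inputs$clinical)
    }
    log("%d cells, %d samples", nrow(bundle$cells),
        length(unique(bundle$cells$sample_id)))

    # ---- gating ----
    stage <- "gate"
    thresholds <- fit_thresholds(bundle$cells,
                                 method = cfg$threshold$method,
                                 params = cfg$threshold$params %||% list(),
                                 fallback = cfg$threshold$fallback)
    calls <- apply_thresholds(bundle$cells, thresholds)
    paths$thresholds <- write_thresholds(thresholds,
                                         file.path(outdir, "thresholds.tsv"))
    log("%d markers gated", length(thresholds))

    # ---- phenotyping ----
    stage <- "phenotype"
    panels <- lapply(cfg$panels, read_panel)
    tiers <- list()
    pheno_mats <- list()
    panel_map <- character()
    for (pnl in panels) {
      for (tm in intersect(pnl$tiered_markers, names(calls))) {
        if (is.null(tiers[[tm]])) {
          tiers[[tm]] <- split_intensity_tiers(bundle$cells, tm, calls)$tier
        }
      }
      avail <- intersect(pnl$markers, names(calls))
      if (length(avail) < length(pnl$markers)) next   # panel not stained
      pc <- assign_phenotypes(calls, pnl, tiers)
      pheno_mats[[pnl$name]] <- pc$matrix
      panel_map[colnames(pc$matrix)] <- pnl$name
    }
    pheno_mat <- do.call(cbind, pheno_mats)
    log("%d phenotypes over %d panels", ncol(pheno_mat), length(pheno_mats))

    # ---- densities & ratios ----
    stage <- "density"
    dm <- compute_densities(pheno_mat, bundle$cells, bundle$areas,
                            cfg$demarcations)
    paths$densities <- write_tsv(dm, file.path(outdir, "densities.tsv"))
    specs <- default_ratio_specs()
    specs <- specs[specs$num_phenotype %in% colnames(pheno_mat) &
                     specs$den_phenotype %in% colnames(pheno_mat), ]
    ratios <- if (nrow(specs)) compute_ratios(dm, specs)
    if (!is.null(ratios)) {
      paths$ratios <- write_tsv(ratios, file.path(outdir, "ratios.tsv"))
    }

    # ---- group comparison & correlation ----
    stage <- "compare"
    report <- compare_hgp(dm, bundle$clinical, ratios, panel_map = panel_map)
    paths$comparison <- write_tsv(report, file.path(outdir, "comparison.tsv"))
    corr_long <- list()
    for (scope in intersect(cfg$spearman %||%
                              c("total_excluding_liver", "stroma"),
                            cfg$demarcations)) {
      for (grp in c("dHGP", "non_dHGP")) {
        cm <- spearman_matrix(dm, bundle$clinical, grp, scope)
        corr_long[[paste(grp, scope)]] <- cm$long
      }
    }
    corr <- data.table::rbindlist(corr_long)
    paths$spearman <- write_tsv(corr, file.path(outdir, "spearman.tsv"))

    # ---- survival ----
    stage <- "survive"
    surv_out <- list(
      hgp = {
        cl <- bundle$clinical
        fit <- cox_univariate(cl$os_months, cl$event,
                              as.integer(cl$hgp == "non_dHGP"))
        list(hr = fit$hr, ci = fit$ci, p = fit$p, n = fit$n,
             events = fit$events)
      })
    for (an in cfg$survival_analyses %||% list()) {
      if (!all(c(an$marker, an$stratifier) %in% colnames(pheno_mat))) next
      sp <- stratified_prognosis(dm, bundle$clinical, an$marker,
                                 an$stratifier,
                                 an$demarcation %||% "stroma",
                                 an$rule %||% "mean")
      surv_out[[paste(an$marker, an$stratifier, sep = "_by_")]] <-
        lapply(sp, function(e) {
          if (isTRUE(e$evaluable)) {
            list(label = e$label, n = e$n,
                 groups = as.list(e$groups),
                 logrank_p = e$logrank$p,
                 logrank_stat = e$logrank$statistic)
          } else list(label = e$label, n = e$n, evaluable = FALSE,
                      reason = e$reason)
        })
    }
    paths$survival <- file.path(outdir, "survival.json")
    jsonlite::write_json(surv_out, paths$survival, auto_unbox = TRUE,
                         digits = NA)

    # ---- signature scoring (optional) ----
    sig_out <- NULL
    if (!is.null(cfg$signature)) {
      stage <- "ssgsea"
      sg <- cfg$signature
      ex <- if (!is.null(sg$simulate)) {
        ec <- do.call(expr_config, modifyList(
          sg$simulate, list(seed = stage_seed(cfg$seed, "expression"))))
        generate_expression(ec)
      } else {
        mat <- as.matrix(data.table::fread(sg$expr), rownames = 1)
        list(expr = mat, anchor = mat[, sg$anchor %||% "ACTA2"])
      }
      gmt_path <- sg$gmt %||% system.file(
        "extdata", "genesets", "caf_signatures_synthetic.gmt",
        package = "tmeQuant")
      sets <- read_gmt(gmt_path)
      set_name <- sg$set %||% names(sets)[1]
      scores <- ssgsea(ex$expr, sets[[set_name]],
                       alpha = sg$alpha %||% 0.25)
      ac <- anchor_correlation(ex$expr, sg$anchor %||% "ACTA2", scores)
      tc <- tertile_compare(ex$anchor, scores)
      sig_out <- list(set = set_name, scores = scores, anchor = ac,
                      tertiles = tc)
      paths$signature <- write_tsv(
        data.table::data.table(cell = names(scores), score = scores),
        file.path(outdir, "signature_scores.tsv"))
      log("set %s: rho(anchor, score) = %.3f", set_name, ac$rho)
    }

    stage <- "manifest"
    manifest <- list(package = "tmeQuant",
                     version = as.character(utils::packageVersion("tmeQuant")),
                     seed = cfg$seed,
                     config = cfg[setdiff(names(cfg), "inputs_data")],
                     outputs = lapply(paths, as.character))
    paths$manifest <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA)

    structure(list(bundle = bundle, thresholds = thresholds,
                   calls = calls, tiers = tiers, phenotypes = pheno_mat,
                   densities = dm, ratios = ratios, comparison = report,
                   spearman = corr, survival = surv_out,
                   signature = sig_out, paths = paths, manifest = manifest),
              class = "result_bundle")
  }, tq_error = function(e) {
    tq_error(sprintf("pipeline stage '%s' failed: %s", stage,
                     conditionMessage(e)), "tq_pipeline_error")
  })
  res
}
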