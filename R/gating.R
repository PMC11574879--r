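#' Fit a positivity threshold for one marker
#'
#' Reproduces threshold setting from per-marker intensity density plots.
#' \code{kde_valley} fits a Gaussian kernel density (Silverman bandwidth,
#' 512-point grid) to log-intensities, locates the two largest modes
#' (ignoring bumps below 5% of the main mode's height) and returns the
#' minimum-density point between them, back-transformed to the intensity
#' scale. \code{quantile} returns the stated quantile of the raw
#' intensities; \code{fixed} echoes a user value (the serialization format,
#' so a run is exactly reproducible).
#'
#' @param values numeric vector of non-negative intensities
#' @param method one of \code{"kde_valley"}, \code{"quantile"}, \code{"fixed"}
#' @param params list: \code{bw} pins the kde bandwidth (log scale),
#'   \code{q} the quantile, \code{value} the fixed threshold
#' @param marker marker name recorded in the result
#' @return object of class \code{tq_threshold}: list with \code{marker},
#'   \code{value}, \code{method}, \code{diagnostics}
#' @export
fit_threshold <- function(values, method = c("kde_valley", "quantile", "fixed"),
                          params = list(), marker = NA_character_) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (method != "fixed") {
    if (!length(values)) tq_value_error("no finite intensity values")
    if (max(values) == min(values)) {
      tq_value_error("constant intensities: threshold undefined")
    }
  }
  diagnostics <- list(n_cells = length(values), modes_found = NA_integer_)
  value <- switch(method,
    fixed = {
      if (is.null(params$value)) tq_config_error("fixed method needs params$value")
      params$value
    },
    quantile = {
      q <- params$q %||% 0.75
      assert_prob(q, "quantile q")
      unname(quantile(values, q, type = 7))
    },
    kde_valley = {
      if (length(values) < 50) {
        tq_value_error("kde_valley needs at least 50 values")
      }
      lx <- log(pmax(values, .Machine$double.xmin))
      d <- if (is.null(params$bw)) density(lx, n = 512) else
        density(lx, bw = params$bw, n = 512)
      y <- d$y
      # interior local maxima of the density grid; negligible tail bumps
      # (< 5% of the main mode's height) do not count as modes
      peaks <- which(diff(sign(diff(y))) == -2) + 1L
      peaks <- peaks[y[peaks] >= 0.05 * max(y[peaks])]
      diagnostics$modes_found <- length(peaks)
      if (length(peaks) < 2) {
        tq_error("unimodal intensity distribution: no valley between modes",
                 "tq_no_valley_error")
      }
      top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
      valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
      exp(d$x[valley])
    })
  structure(list(marker = marker, value = value, method = method,
                 params = params, diagnostics = diagnostics),
            class = "tq_threshold")
}

#' Fit thresholds for every marker of a cell table
#'
#' One threshold per marker, fitted cohort-wide (one trained gate per
#' panel). Markers where the valley search fails fall back to the
#' \code{fallback} quantile, with the method recorded.
#'
#' @param cells cell data.table with \code{<MARKER>_int} columns
#' @param method,params forwarded to \code{\link{fit_threshold}}
#' @param markers subset of markers (default: all detected)
#' @param fallback quantile used when \code{kde_valley} finds no valley
#' @return named list of \code{tq_threshold} objects
#' @export
fit_thresholds <- function(cells, method = "kde_valley", params = list(),
                           markers = NULL, fallback = 0.9) {
  markers <- markers %||% marker_names(cells)
  out <- list()
  for (m in markers) {
    v <- cells[[intensity_col(m)]]
    if (is.null(v)) tq_schema_error(sprintf("no intensity column for %s", m))
    out[[m]] <- tryCatch(
      fit_threshold(v, method, params, marker = m),
      tq_no_valley_error = function(e) {
        fit_threshold(v, "quantile", list(q = fallback), marker = m)
      })
  }
  out
}

#' Apply positivity thresholds to a cell table
#'
#' A cell is positive for a marker iff its intensity is greater than or
#' equal to the marker's threshold (boundary convention: at-threshold is
#' positive).
#'
#' @param cells cell data.table
#' @param thresholds named list of \code{tq_threshold} (or bare numerics)
#' @return \code{marker_calls}: logical data.table, one column per marker,
#'   row-aligned with \code{cells}
#' @export
apply_thresholds <- function(cells, thresholds) {
  markers <- marker_names(cells)
  miss <- setdiff(markers, names(thresholds))
  if (length(miss)) {
    tq_config_error(sprintf("no threshold for marker(s): %s",
                            paste(miss, collapse = ", ")))
  }
  out <- data.table::data.table(row = seq_len(nrow(cells)))[, "row" := NULL]
  for (m in markers) {
    th <- thresholds[[m]]
    tv <- if (inherits(th, "tq_threshold")) th$value else th
    data.table::set(out, j = m, value = cells[[intensity_col(m)]] >= tv)
  }
  if (nrow(cells) == 0) out <- out[0L]
  structure(out, class = c("marker_calls", class(out)))
}

#' Split positive cells of a tiered marker into high/low intensity tiers
#'
#' The cutoff is the arithmetic mean intensity over all marker-positive
#' cells, computed cohort-wide so the high/low semantics are comparable
#' across samples. A positive cell is \code{high} iff its intensity is
#' strictly greater than the mean (a cell exactly at the mean is
#' \code{low}); negative cells stay \code{negative}.
#'
#' @param cells cell data.table
#' @param marker tiered marker name (e.g. \code{"aSMA"})
#' @param calls \code{marker_calls} from \code{\link{apply_thresholds}}
#' @return list with \code{tier} (character vector row-aligned with
#'   \code{cells}, values \code{high/low/negative}) and \code{cutoff}
#' @export
split_intensity_tiers <- function(cells, marker, calls) {
  pos <- calls[[marker]]
  if (is.null(pos)) tq_config_error(sprintf("no calls for marker %s", marker))
  if (!any(pos)) tq_value_error(sprintf("no positive cells for %s", marker))
  v <- cells[[intensity_col(marker)]]
  cutoff <- mean(v[pos])
  tier <- rep("negative", nrow(cells))
  tier[pos] <- ifelse(v[pos] > cutoff, "high", "low")
  list(tier = tier, cutoff = cutoff, marker = marker)
}

#' Serialize / read thresholds as TSV
#'
#' @param thresholds named list of \code{tq_threshold}
#' @param path TSV path
#' @return (write) the path invisibly; (read) a named list of
#'   \code{tq_threshold} with method \code{fixed}
#' @export
write_thresholds <- function(thresholds, path) {
  dt <- data.table::rbindlist(lapply(thresholds, function(t) {
    data.table::data.table(marker = t$marker, value = t$value,
                           method = t$method,
                           params = jsonlite::toJSON(t$params,
                                                     auto_unbox = TRUE))
  }))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  dt <- data.table::fread(path)
  out <- lapply(seq_len(nrow(dt)), function(i) {
    structure(list(marker = dt$marker[i], value = dt$value[i],
                   method = "fixed", params = list(value = dt$value[i]),
                   diagnostics = list()),
              class = "tq_threshold")
  })
  names(out) <- dt$marker
  out
}
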