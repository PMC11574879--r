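#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over \code{survival::survfit} returning the curve as a
#' plain table. Censored subjects leave the risk set after their time; with
#' no censoring the curve equals the empirical survival function.
#'
#' @param times non-negative follow-up times
#' @param events binary event indicators (1 = death observed)
#' @return \code{survival_curve}: data.table \code{(time, n_risk, n_event,
#'   n_censor, S)}
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) tq_value_error("empty survival input")
  if (any(times < 0) || any(!events %in% c(0, 1))) {
    tq_value_error("times must be >= 0 and events binary")
  }
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.table::data.table(time = fit$time, n_risk = fit$n.risk,
                                n_event = fit$n.event,
                                n_censor = fit$n.censor, S = fit$surv)
  data.table::setattr(out, "class", c("survival_curve", class(out)))
  out[]
}

#' Log-rank test
#'
#' Observed-minus-expected chi-square with hypergeometric variance across
#' event times; p from the chi-square distribution with k - 1 degrees of
#' freedom.
#'
#' @param times,events as in \code{\link{km_estimate}}
#' @param groups group labels (>= 2 levels, each non-empty)
#' @return list \code{(statistic, df, p)}
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    tq_value_error("log-rank needs >= 2 non-empty groups")
  }
  if (sum(events) < 1) tq_value_error("log-rank needs >= 1 event")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1
  list(statistic = sd$chisq, df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling; Wald 95%
#' confidence interval and p-value. A constant covariate carries no
#' information and returns beta = 0, HR = 1 with a degenerate flag.
#'
#' @param times,events as in \code{\link{km_estimate}}
#' @param covariate numeric or binary covariate
#' @return \code{cox_fit}: list with \code{beta}, \code{hr}, \code{ci}
#'   (length-2), \code{se}, \code{p}, \code{n}, \code{events},
#'   \code{converged}, \code{degenerate}
#' @export
cox_univariate <- function(times, events, covariate) {
  if (sum(events) < 1) tq_value_error("Cox fit needs >= 1 event")
  covariate <- as.numeric(covariate)
  if (length(unique(covariate)) < 2) {
    return(structure(list(beta = 0, hr = 1, ci = c(1, 1), se = NA_real_,
                          p = 1, n = length(times), events = sum(events),
                          converged = TRUE, degenerate = TRUE),
                     class = "cox_fit"))
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(times, events) ~ covariate,
                    ties = "efron", control = survival::coxph.control(
                      iter.max = 100)),
    error = function(e) tq_error(paste("Cox fit failed:", conditionMessage(e)),
                                 "tq_cox_error"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        tq_error("monotone partial likelihood (separation) or non-convergence",
                 "tq_cox_error")
      }
      suppressWarnings(
        survival::coxph(survival::Surv(times, events) ~ covariate,
                        ties = "efron"))
    })
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se)) {
    tq_error("Cox fit did not yield finite estimates", "tq_cox_error")
  }
  structure(list(beta = beta, hr = exp(beta),
                 ci = exp(beta + c(-1, 1) * 1.96 * se), se = se,
                 p = 2 * pnorm(-abs(beta / se)), n = length(times),
                 events = sum(events), converged = TRUE, degenerate = FALSE),
            class = "cox_fit")
}

#' @importFrom stats coef
NULL

#' Dichotomize a biomarker by mean or tertiles
#'
#' \code{mean}: low = value <= mean, high = value > mean (a subject exactly
#' at the mean is low, consistent with the gating boundary convention); the
#' mean is computed over the supplied values, i.e. the caller fixes the
#' scope (whole cohort by default in the stratified workflow).
#' \code{tertiles}: three groups (T1 lowest) by ranked thirds, ties broken
#' by position for a deterministic equal split.
#'
#' @param values numeric vector
#' @param rule \code{"mean"} or \code{"tertiles"}
#' @return factor of labels (\code{low/high} or \code{T1/T2/T3})
#' @export
dichotomize <- function(values, rule = c("mean", "tertiles")) {
  rule <- match.arg(rule)
  v <- as.numeric(values)
  if (any(!is.finite(v))) tq_value_error("non-finite biomarker values")
  if (length(unique(v)) < 2) tq_value_error("constant biomarker: no cutpoint")
  if (rule == "mean") {
    factor(ifelse(v > mean(v), "high", "low"), levels = c("low", "high"))
  } else {
    if (length(v) < 3) tq_value_error("tertiles need >= 3 values")
    r <- rank(v, ties.method = "first")
    factor(paste0("T", ceiling(3 * r / length(v))),
           levels = c("T1", "T2", "T3"))
  }
}

#' Marker prognosis stratified by a second marker
#'
#' Implements the interaction subgroup workflow: the stratifier's
#' per-sample density is dichotomized at the cohort-wide mean; within each
#' stratum the marker of interest is dichotomized (within-stratum mean) and
#' a two-group log-rank test is run. The unstratified analysis is reported
#' alongside. Strata that cannot support the test (fewer than 2 subjects in
#' either marker group, or a constant marker) are reported as not evaluable
#' rather than raising.
#'
#' @param dm \code{density_matrix}
#' @param clinical clinical table with \code{sample_id, os_months, event}
#' @param marker phenotype whose prognostic value is tested
#' @param stratifier phenotype defining the strata
#' @param demarcation demarcation whose densities are used (default stroma)
#' @param rule dichotomization rule for the marker
#' @return \code{stratified_report}: list of per-analysis entries
#'   (\code{unstratified}, \code{<stratifier>_high}, \code{<stratifier>_low}),
#'   each with \code{n}, \code{groups}, \code{logrank} (or
#'   \code{evaluable = FALSE} with a reason) and per-group KM curves
#' @export
stratified_prognosis <- function(dm, clinical, marker, stratifier,
                                 demarcation = "stroma", rule = "mean") {
  getdens <- function(ph) {
    sub <- dm[dm$phenotype == ph & dm$demarcation == demarcation, ]
    if (!nrow(sub)) tq_config_error(sprintf(
      "phenotype %s not present for demarcation %s", ph, demarcation))
    setNames(sub$density, sub$sample_id)
  }
  mv <- getdens(marker)
  sv <- getdens(stratifier)
  ids <- intersect(names(mv), clinical$sample_id)
  clin <- clinical[match(ids, clinical$sample_id), ]
  mv <- mv[ids]; sv <- sv[ids]

  analyse <- function(sel, label) {
    res <- list(label = label, n = sum(sel))
    out <- tryCatch({
      grp <- dichotomize(mv[sel], rule)
      if (min(table(grp)) < 2) {
        tq_value_error("a marker group has fewer than 2 subjects")
      }
      lr <- logrank_test(clin$os_months[sel], clin$event[sel], grp)
      curves <- lapply(split(seq_len(sum(sel)), grp), function(ii) {
        km_estimate(clin$os_months[sel][ii], clin$event[sel][ii])
      })
      c(res, list(evaluable = TRUE, groups = table(grp), logrank = lr,
                  curves = curves))
    }, tq_error = function(e) {
      c(res, list(evaluable = FALSE, reason = conditionMessage(e)))
    })
    out
  }

  strata <- dichotomize(sv, "mean")      # cohort-wide mean for stratifier
  out <- list(
    unstratified = analyse(rep(TRUE, length(ids)), "unstratified"))
  out[[paste0(stratifier, "_high")]] <-
    analyse(strata == "high", paste0(stratifier, "_high"))
  out[[paste0(stratifier, "_low")]] <-
    analyse(strata == "low", paste0(stratifier, "_low"))
  structure(out, class = "stratified_report",
            marker = marker, stratifier = stratifier,
            demarcation = demarcation)
}
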