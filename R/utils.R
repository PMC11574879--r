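# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

tq_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "tq_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

tq_schema_error  <- function(msg) tq_error(msg, "tq_schema_error")
tq_value_error   <- function(msg) tq_error(msg, "tq_value_error")
tq_linkage_error <- function(msg) tq_error(msg, "tq_linkage_error")
tq_config_error  <- function(msg) tq_error(msg, "tq_config_error")
tq_data_error    <- function(msg) tq_error(msg, "tq_data_error")

#' @importFrom stats median quantile rnorm rlnorm rpois runif rexp rbinom
#'   pnorm pt pchisq density sd setNames complete.cases
#' @importFrom utils combn head modifyList
#' @import data.table
NULL

# deterministic child seed for a named stage, kept below 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 7919L + as.integer(h %% 104729L)) %% 2147483647L
}

assert_prob <- function(p, what = "p") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    tq_value_error(sprintf("%s values must lie in [0, 1]", what))
  }
  invisible(p)
}
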