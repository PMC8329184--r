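## Internal helpers shared across modules.

#' @importFrom stats pnorm pchisq pt qnorm plogis qlogis rnorm rbinom rpois
#'   runif sd var cor complete.cases setNames p.adjust
#' @importFrom utils read.delim read.csv write.csv write.table head
NULL

## Condition constructors: every user-facing error carries a class so the
## command-line front-end can map it to an exit code.
.configError <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("phewasMR_config_error", "error", "condition"),
                 list(message = msg, call = call)))
}

.validationError <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("phewasMR_validation_error", "error", "condition"),
                 list(message = msg, call = call)))
}

.dataError <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("phewasMR_data_error", "error", "condition"),
                 list(message = msg, call = call)))
}

## Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG afterwards so library code never disturbs user simulations.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## Derive a per-stage seed from a master seed; keeps all derived seeds within
## 32-bit integer range.
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647L)
}

.isString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
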