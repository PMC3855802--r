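# Internal helpers shared across the package.

.SENTINEL <- "Unknown/Missing"

#' Sentinel label used for explicitly modelled missing values
#'
#' Null observations are not imputed: they are recoded as a real category so
#' that missingness itself can carry predictive information. This returns the
#' reserved label appended (always last) to the state list of any variable
#' that contains nulls.
#'
#' @return A character scalar.
#' @export
missing_sentinel <- function() .SENTINEL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix.
row_log_sum_exp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

stop_usage <- function(...) stop(..., call. = FALSE)
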