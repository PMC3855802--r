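#' Declare a categorical clinical variable
#'
#' A variable specification carries the ordered state labels, the temporal
#' tier the variable belongs to (pre-treatment characteristics, the treatment
#' decision, or post-treatment outcome), and whether the explicit
#' `"Unknown/Missing"` sentinel state has been appended.
#'
#' @param name Variable identifier (single string).
#' @param states Ordered, unique character vector of category labels.
#' @param tier One of `"pre_treatment"`, `"treatment"`, `"post_treatment"`.
#' @param has_missing_state Logical; if `TRUE` the sentinel label must appear
#'   exactly once, as the last state.
#' @return An object of class `bn_variable`.
#' @seealso [add_missing_state()], [bn_dataset()]
#' @export
variable_spec <- function(name, states,
                          tier = c("pre_treatment", "treatment", "post_treatment"),
                          has_missing_state = FALSE) {
  tier <- match.arg(tier)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_usage("variable name must be a single non-empty string")
  states <- as.character(states)
  if (length(states) == 0L) stop_usage("'", name, "': states must be non-empty")
  if (anyDuplicated(states)) stop_usage("'", name, "': states must be unique")
  if (has_missing_state) {
    if (sum(states == .SENTINEL) != 1L || states[length(states)] != .SENTINEL)
      stop_usage("'", name, "': sentinel state must appear exactly once, last")
  } else if (.SENTINEL %in% states) {
    stop_usage("'", name, "': sentinel present but has_missing_state is FALSE")
  }
  structure(
    list(name = name, states = states, tier = tier,
         has_missing_state = has_missing_state),
    class = "bn_variable")
}

#' Append the explicit missing-value state to a variable
#'
#' @param spec A [variable_spec()] object.
#' @return The specification with the sentinel appended (idempotent).
#' @export
add_missing_state <- function(spec) {
  stopifnot(inherits(spec, "bn_variable"))
  if (spec$has_missing_state) return(spec)
  variable_spec(spec$name, c(spec$states, .SENTINEL), spec$tier,
                has_missing_state = TRUE)
}

#' @export
print.bn_variable <- function(x, ...) {
  cat(sprintf("<variable> %s [%s]: %s\n", x$name, x$tier,
              paste(x$states, collapse = "; ")))
  invisible(x)
}

#' Construct a categorical patient dataset
#'
#' Records are stored as integer state indices (1-based, per the variable's
#' state list) together with an observedness mask: `mask == 1` means the cell
#' was recorded, `mask == 0` means it was originally null and now holds the
#' sentinel state index.
#'
#' @param variables List of [variable_spec()] objects, one per column.
#' @param x Integer matrix, `n` rows by `length(variables)` columns.
#' @param mask Optional 0/1 integer matrix of the same shape; defaults to all
#'   observed.
#' @return An object of class `bn_dataset`.
#' @export
bn_dataset <- function(variables, x, mask = NULL) {
  if (!is.list(variables) || !all(vapply(variables, inherits, TRUE, "bn_variable")))
    stop_usage("variables must be a list of variable_spec() objects")
  nm <- unname(vapply(variables, `[[`, "", "name"))
  if (anyDuplicated(nm)) stop_usage("duplicate variable names")
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (ncol(x) != length(variables))
    stop_usage("record table has ", ncol(x), " columns but ", length(variables),
               " variables are declared")
  if (nrow(x) < 1L) stop_usage("dataset must contain at least one record")
  colnames(x) <- nm
  cards <- vapply(variables, function(v) length(v$states), 0L)
  for (j in seq_along(nm)) {
    cj <- x[, j]
    if (anyNA(cj) || any(cj < 1L) || any(cj > cards[j]))
      stop_usage("column '", nm[j], "' contains invalid state indices")
  }
  if (is.null(mask)) {
    mask <- matrix(1L, nrow(x), ncol(x))
  } else {
    mask <- as.matrix(mask)
    storage.mode(mask) <- "integer"
    if (!all(dim(mask) == dim(x))) stop_usage("mask shape must match records")
    if (!all(mask %in% c(0L, 1L))) stop_usage("mask must be 0/1")
  }
  colnames(mask) <- nm
  names(variables) <- nm
  structure(list(variables = variables, x = x, mask = mask),
            class = "bn_dataset")
}

#' @export
print.bn_dataset <- function(x, ...) {
  cat(sprintf("<bn_dataset> %d records x %d variables (%.1f%% cells missing)\n",
              nrow(x$x), ncol(x$x), 100 * mean(x$mask == 0L)))
  invisible(x)
}

#' @export
dim.bn_dataset <- function(x) dim(x$x)

var_names <- function(data) names(data$variables)

cards <- function(data) {
  vapply(data$variables, function(v) length(v$states), 0L)
}

tiers_of <- function(data) {
  vapply(data$variables, `[[`, "", "tier")
}

#' Variable names of a dataset
#' @param data A [bn_dataset()].
#' @return Character vector of column names.
#' @export
dataset_variables <- function(data) var_names(data)

#' Convert a dataset back to labelled factors
#'
#' @param x A [bn_dataset()].
#' @param row.names,optional,... Passed through for S3 compatibility.
#' @return A `data.frame` of factor columns with the declared state levels.
#' @export
as.data.frame.bn_dataset <- function(x, row.names = NULL, optional = FALSE, ...) {
  cols <- lapply(seq_along(x$variables), function(j) {
    v <- x$variables[[j]]
    factor(v$states[x$x[, j]], levels = v$states)
  })
  names(cols) <- var_names(x)
  as.data.frame(cols, row.names = row.names, optional = optional,
                stringsAsFactors = FALSE)
}

#' Build a dataset from a labelled data frame
#'
#' Cells must match the declared state labels case-sensitively; `NA` is only
#' accepted when the variable declares the sentinel state, in which case the
#' cell is encoded as the sentinel with `mask = 0`.
#'
#' @param df A data frame of character/factor columns.
#' @param variables List of [variable_spec()]s covering every column of `df`.
#' @return A [bn_dataset()].
#' @export
dataset_from_frame <- function(df, variables) {
  nm <- vapply(variables, `[[`, "", "name")
  if (!all(nm %in% names(df)))
    stop_usage("data frame is missing columns: ",
               paste(setdiff(nm, names(df)), collapse = ", "))
  n <- nrow(df)
  x <- matrix(0L, n, length(nm))
  mask <- matrix(1L, n, length(nm))
  for (j in seq_along(nm)) {
    v <- variables[[j]]
    vals <- as.character(df[[nm[j]]])
    idx <- match(vals, v$states)
    isna <- is.na(vals)
    if (any(isna)) {
      if (!v$has_missing_state)
        stop_usage("column '", nm[j], "' has nulls; run encode_missing() first")
      idx[isna] <- length(v$states)
      mask[isna, j] <- 0L
    }
    bad <- is.na(idx) & !isna
    if (any(bad))
      stop_usage("column '", nm[j], "': unknown state label '",
                 vals[which(bad)[1L]], "'")
    x[, j] <- idx
  }
  bn_dataset(variables, x, mask)
}

# Subset rows of a dataset (keeps variables/metadata).
dataset_rows <- function(data, idx) {
  bn_dataset(data$variables, data$x[idx, , drop = FALSE],
             data$mask[idx, , drop = FALSE])
}
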