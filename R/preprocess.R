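# Record filtering, manual discretisation and explicit missing-state
# encoding.

#' Manual discretisation rule for a continuous field
#'
#' Intervals are left-closed/right-open: with cut points `c(50, 60, 70, 80)`
#' a value of exactly 60 falls in the `"60-70"` bin. Labels must be one more
#' than the cut points and partition the real line.
#'
#' @param variable Name of the field.
#' @param cut_points Strictly increasing numeric cut points.
#' @param labels Interval labels, `length(cut_points) + 1` of them.
#' @return An object of class `bn_discretisation`.
#' @export
discretisation_rule <- function(variable, cut_points, labels) {
  cut_points <- as.numeric(cut_points)
  if (length(cut_points) == 0L || any(!is.finite(cut_points)))
    stop_usage("cut points must be finite")
  if (is.unsorted(cut_points, strictly = TRUE))
    stop_usage("cut points must be strictly increasing")
  labels <- as.character(labels)
  if (length(labels) != length(cut_points) + 1L)
    stop_usage("need exactly ", length(cut_points) + 1L, " labels")
  if (anyDuplicated(labels)) stop_usage("labels must be unique")
  structure(list(variable = variable, cut_points = cut_points,
                 labels = labels),
            class = "bn_discretisation")
}

#' Discretise continuous values into labelled intervals
#'
#' @param values Numeric vector; `NA` maps to the `"Unknown/Missing"`
#'   sentinel label.
#' @param rule A [discretisation_rule()].
#' @return Character vector of interval labels.
#' @export
discretise <- function(values, rule) {
  stopifnot(inherits(rule, "bn_discretisation"))
  if (any(!is.finite(values) & !is.na(values)))
    stop_usage("non-finite values cannot be discretised")
  bin <- findInterval(values, rule$cut_points, left.open = FALSE) + 1L
  out <- rule$labels[bin]
  out[is.na(values)] <- .SENTINEL
  out
}

#' Exclusion rule for record filtering
#'
#' Declarative analogue of the registry clean-up (e.g. drop a diagnosis
#' category, drop a rare treatment, drop records with a null outcome), kept
#' as configuration so synthetic cohorts can exercise the same path.
#'
#' @param column Column the rule applies to.
#' @param states Drop records whose value (label) is in this set; `NULL` to
#'   skip the state test.
#' @param drop_null If `TRUE`, drop records where this column was originally
#'   null (mask 0).
#' @param name Optional label used in the removal log.
#' @return An object of class `bn_exclusion`.
#' @export
exclusion_rule <- function(column, states = NULL, drop_null = FALSE,
                           name = NULL) {
  structure(list(column = column, states = states,
                 drop_null = isTRUE(drop_null),
                 name = name %||% column),
            class = "bn_exclusion")
}

#' Filter records against a set of exclusion rules
#'
#' @param data A [bn_dataset()].
#' @param rules List of [exclusion_rule()]s.
#' @return The retained records, with a `"removal_log"` attribute giving the
#'   per-rule removal counts (counted in rule order, without
#'   double-counting).
#' @export
filter_records <- function(data, rules) {
  stopifnot(inherits(data, "bn_dataset"))
  nm <- var_names(data)
  drop <- rep(FALSE, nrow(data$x))
  log <- data.frame(rule = character(0), removed = integer(0))
  for (rule in rules) {
    if (!rule$column %in% nm)
      stop_usage("exclusion rule on unknown column '", rule$column, "'")
    j <- match(rule$column, nm)
    hit <- rep(FALSE, nrow(data$x))
    if (!is.null(rule$states)) {
      states <- data$variables[[j]]$states
      idx <- match(rule$states, states)
      if (anyNA(idx))
        stop_usage("rule '", rule$name, "': unknown state '",
                   rule$states[which(is.na(idx))[1L]], "'")
      hit <- hit | data$x[, j] %in% idx
    }
    if (rule$drop_null) hit <- hit | data$mask[, j] == 0L
    new_hits <- hit & !drop
    log <- rbind(log, data.frame(rule = rule$name,
                                 removed = sum(new_hits)))
    drop <- drop | hit
  }
  if (all(drop)) stop_usage("all records excluded by the filtering rules")
  out <- dataset_rows(data, !drop)
  attr(out, "removal_log") <- log
  out
}

#' Recode nulls as the explicit "Unknown/Missing" state
#'
#' Takes a raw labelled data frame (with `NA` for null cells) and the
#' variable declarations *without* sentinel states. Columns containing nulls
#' get the sentinel appended as a real last state and the null cells encoded
#' to it; fully observed columns are left unchanged and unflagged. The
#' returned mask records original observedness.
#'
#' @param df Data frame of character/factor columns.
#' @param variables List of [variable_spec()]s for the columns of interest.
#' @return A [bn_dataset()].
#' @export
encode_missing <- function(df, variables) {
  specs <- lapply(variables, function(v) {
    if (any(is.na(df[[v$name]])) && !v$has_missing_state)
      add_missing_state(v) else v
  })
  dataset_from_frame(df, specs)
}

#' Binary observedness indicators for the predictor columns
#'
#' Rebuilds the missingness experiment's design: every predictor column is
#' replaced by a two-state variable (`"Missing"`/`"Observed"`, from the
#' mask) while the outcome column is passed through untouched. The outcome
#' must be fully observed.
#'
#' @param data A [bn_dataset()] with a non-trivial mask.
#' @param outcome Name of the outcome column.
#' @return A [bn_dataset()] of indicator variables plus the outcome.
#' @export
indicator_matrix <- function(data, outcome) {
  nm <- var_names(data)
  if (!outcome %in% nm) stop_usage("unknown outcome column: ", outcome)
  oj <- match(outcome, nm)
  if (any(data$mask[, oj] == 0L))
    stop_usage("outcome column contains nulls; filter those records first")
  pred <- setdiff(nm, outcome)
  specs <- c(lapply(pred, function(v)
               variable_spec(v, c("Missing", "Observed"),
                             tier = data$variables[[v]]$tier)),
             list(data$variables[[outcome]]))
  x <- cbind(data$mask[, pred, drop = FALSE] + 1L,
             data$x[, oj, drop = FALSE])
  bn_dataset(specs, x)
}

# ---- dataset CSV + JSON schema sidecar ------------------------------------

#' Write a dataset as CSV with a JSON schema sidecar
#'
#' The CSV holds state labels (UTF-8, comma separated, quoted); originally
#' null cells are written empty. The sidecar declares, per variable, the
#' states (without the sentinel), the temporal tier and whether the sentinel
#' was in use.
#'
#' @param data A [bn_dataset()].
#' @param csv,schema Output paths.
#' @export
write_dataset <- function(data, csv, schema) {
  df <- as.data.frame(data)
  for (j in seq_along(df)) {
    v <- as.character(df[[j]])
    v[data$mask[, j] == 0L] <- NA_character_
    df[[j]] <- v
  }
  utils::write.csv(df, csv, row.names = FALSE, na = "")
  spec_list <- lapply(data$variables, function(v) {
    states <- v$states
    if (v$has_missing_state) states <- states[-length(states)]
    list(name = v$name, states = states, tier = v$tier,
         has_missing_state = v$has_missing_state)
  })
  jsonlite::write_json(unname(spec_list), schema, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(csv)
}

#' Read a dataset from CSV + JSON schema
#'
#' @param csv,schema Paths written by [write_dataset()] (or hand-authored in
#'   the same layout).
#' @return A [bn_dataset()]; empty cells become the sentinel state with
#'   `mask = 0`.
#' @export
read_dataset <- function(csv, schema) {
  spec_list <- jsonlite::read_json(schema, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE)
  variables <- lapply(spec_list, function(s) {
    v <- variable_spec(s$name, unlist(s$states), s$tier)
    if (isTRUE(s$has_missing_state)) add_missing_state(v) else v
  })
  df <- utils::read.csv(csv, colClasses = "character", check.names = FALSE,
                        na.strings = "")
  encode_missing(df, variables)
}
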