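# Trial-table CSV schema, run configuration JSON, and draws serialization.
# All indices in files are 1-based, matching trial numbering 1..120;
# correct and dual_task are 0/1 integers for cross-language CSV safety.

.TRIAL_COLS <- c("participant_id", "condition", "block", "trial_in_block",
                 "trial_overall", "set_size", "item_position", "correct",
                 "shape_family", "dual_task")

#' Validate a trial-record table
#'
#' Checks the disaggregated trial-table schema: required columns, field
#' domains, the trial-index arithmetic
#' `trial_overall == 30 * (block - 1) + trial_in_block`, and that every
#' presented trial carries exactly `set_size` item rows with positions
#' `1..set_size`. Violations raise errors naming the offending rows and rule.
#'
#' @param records Data frame to validate.
#' @param complete_trials Require every trial to carry its full complement of
#'   `set_size` items (default). Cross-validation refits legitimately hold
#'   out single items and relax this.
#' @return `records`, invisibly, if valid.
#' @export
validate_trial_table <- function(records, complete_trials = TRUE) {
  missing_cols <- setdiff(.TRIAL_COLS, names(records))
  if (length(missing_cols))
    stop("trial table is missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- function(rows, rule) {
    if (any(rows))
      stop("trial table rows ", paste(utils::head(which(rows), 5), collapse = ", "),
           if (sum(rows) > 5) sprintf(" (and %d more)", sum(rows) - 5),
           ": ", rule)
  }
  bad(!records$condition %in% CONDITIONS,
      paste("condition must be one of", paste(CONDITIONS, collapse = "/")))
  bad(!records$block %in% 1:4, "block must be in 1..4")
  bad(!records$trial_in_block %in% 1:30, "trial_in_block must be in 1..30")
  bad(records$trial_overall !=
        30L * (records$block - 1L) + records$trial_in_block,
      "trial_overall must equal 30*(block-1) + trial_in_block")
  bad(!records$set_size %in% 2:6, "set_size must be in 2..6")
  bad(!records$correct %in% c(0L, 1L), "correct must be 0 or 1")
  bad(!records$item_position %in% 1:6 |
        records$item_position > records$set_size,
      "item_position must be in 1..set_size")
  if (complete_trials) {
    key <- paste(records$participant_id, records$trial_overall)
    n_items <- tapply(records$item_position, key, length)
    ss <- tapply(records$set_size, key, function(x) x[1])
    if (any(n_items != ss))
      stop("trials with item count != set_size: ",
           paste(utils::head(names(n_items)[n_items != ss], 5),
                 collapse = ", "))
    pos_ok <- tapply(records$item_position, key,
                     function(x) identical(sort(x), seq_along(x)))
    if (!all(pos_ok))
      stop("trials with item positions not 1..set_size: ",
           paste(utils::head(names(pos_ok)[!pos_ok], 5), collapse = ", "))
  }
  invisible(records)
}

#' Write a trial-record table to CSV
#' @param records Trial-record data frame (validated before writing).
#' @param path Output CSV path.
#' @export
write_trial_table <- function(records, path) {
  validate_trial_table(records)
  out <- records[, intersect(c(.TRIAL_COLS, "rotation_deg", "button"),
                             names(records))]
  out$correct <- as.integer(out$correct)
  out$dual_task <- as.integer(out$dual_task)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a trial-record table from CSV
#' @param path CSV path written by [write_trial_table()] (or matching its
#'   schema).
#' @return Validated trial-record data frame (`dual_task` as logical).
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("dual_task" %in% names(df)) df$dual_task <- as.logical(df$dual_task)
  validate_trial_table(df)
  df
}

#' Read a run configuration from JSON
#'
#' A run configuration holds the master seed, cohort parameters, model
#' specification and sampler settings; it round-trips read -> write -> read
#' identically.
#' @param path JSON path.
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a run configuration to JSON
#' @param config Named list.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize posterior draws as tidy CSV plus a diagnostics JSON sidecar
#' @param fit A `posterior_draws` object from [fit_learning_model()].
#' @param path Output CSV path; diagnostics go to `<path>.diag.json`.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "posterior_draws"))
  dr <- fit$draws
  tidy <- data.frame(
    chain = rep(rep(seq_len(dim(dr)[2]), each = dim(dr)[1]), dim(dr)[3]),
    draw = rep(seq_len(dim(dr)[1]), dim(dr)[2] * dim(dr)[3]),
    parameter = rep(dimnames(dr)[[3]], each = dim(dr)[1] * dim(dr)[2]),
    value = as.vector(dr))
  utils::write.csv(tidy, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(rhat = as.list(fit$diagnostics$rhat),
         ess_tail = as.list(fit$diagnostics$ess_tail),
         converged = fit$diagnostics$converged,
         accept_rate = fit$diagnostics$accept_rate %||% NULL,
         method = fit$method, data_fingerprint = fit$data_fingerprint),
    paste0(path, ".diag.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# fingerprint of the data a model was fit to, so downstream pointwise
# log-likelihood computations can refuse mismatched records
data_fingerprint <- function(records) {
  key <- paste(records$participant_id, records$trial_overall,
               records$item_position, records$correct,
               records$set_size, collapse = ";")
  format(fnv32(key), scientific = FALSE)
}
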