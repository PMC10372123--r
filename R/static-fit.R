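# Per-participant static Weibull maximum-likelihood fits and the
# capacity-based exclusion filter.

.STATIC_BOUNDS <- list(lth = log(c(0.05, 50)), lsh = log(c(0.5, 20)))

#' Static maximum-likelihood Weibull fit for one participant
#'
#' Maximizes the disaggregated Bernoulli log-likelihood over
#' (log threshold50, log shape) with a time-invariant threshold across all of
#' the participant's trials. Multi-start (5 starts) bounded quasi-Newton;
#' bounds keep the guesser's likelihood maximum at the lower threshold bound,
#' which makes the exclusion filter deterministic.
#'
#' @param records Trial records for a single participant.
#' @return One-row data frame: `threshold50`, `shape`, `capacity`, `excluded`
#'   (capacity < 1 item or no start converged), `status` (optimizer message).
#' @export
fit_static <- function(records) {
  stopifnot(nrow(records) >= 1, all(records$set_size >= 1))
  # static likelihood depends on the data only through per-set-size counts
  k <- tapply(records$correct, records$set_size, sum)
  n <- tapply(records$correct, records$set_size, length)
  ss <- as.numeric(names(k))
  nll <- function(par) {
    p <- clamp_prob(weibull_accuracy(ss, exp(par[1]), exp(par[2])))
    -sum(k * log(p) + (n - k) * log1p(-p))
  }
  lower <- c(.STATIC_BOUNDS$lth[1], .STATIC_BOUNDS$lsh[1])
  upper <- c(.STATIC_BOUNDS$lth[2], .STATIC_BOUNDS$lsh[2])
  starts <- rbind(c(log(3), log(3)), c(log(1), log(2)), c(log(6), log(1)),
                  c(log(0.3), log(3)), c(log(10), log(5)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], nll, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && fit$convergence == 0 &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    return(data.frame(participant_id = records$participant_id[1],
                      condition = records$condition[1],
                      threshold50 = NA_real_, shape = NA_real_,
                      capacity = NA_real_, excluded = TRUE,
                      status = "non-convergence from every start",
                      stringsAsFactors = FALSE))
  }
  th <- exp(best$par[1])
  data.frame(participant_id = records$participant_id[1],
             condition = records$condition[1],
             threshold50 = th, shape = exp(best$par[2]),
             capacity = capacity(th), excluded = capacity(th) < 1,
             status = "converged", stringsAsFactors = FALSE)
}

#' Static fits for every participant in a trial table
#' @param records Trial-record data frame (multiple participants).
#' @return Data frame with one [fit_static()] row per participant.
#' @export
fit_static_all <- function(records) {
  rows <- lapply(split(records, records$participant_id), fit_static)
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$participant_id), , drop = FALSE]
}

#' Apply the capacity exclusion filter
#'
#' Retains participants whose static-fit capacity is at least one item
#' (boundary inclusive). Non-converged fits count as excluded.
#'
#' @param static_fits Output of [fit_static_all()].
#' @param records Optional trial table; if given, the retained subset is
#'   returned too.
#' @return List: `retained_ids`, `excluded_ids`, `report` (per-condition
#'   retained/excluded counts), and `records` (filtered, if supplied).
#' @export
apply_exclusion <- function(static_fits, records = NULL) {
  keep <- !static_fits$excluded
  report <- as.data.frame(table(condition = static_fits$condition,
                                excluded = static_fits$excluded))
  out <- list(retained_ids = static_fits$participant_id[keep],
              excluded_ids = static_fits$participant_id[!keep],
              report = report)
  if (!is.null(records))
    out$records <- records[records$participant_id %in% out$retained_ids, ,
                           drop = FALSE]
  out
}
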