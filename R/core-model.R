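# Closed-form mathematical core: Weibull (Quick) psychometric accuracy,
# exponential threshold trajectory, monotone cross-block schedule, capacity,
# and the disaggregated Bernoulli log-likelihood.

#' Guessing rate of the six-alternative span task
#'
#' Probability of a correct item response by chance with six response buttons.
#' Fixed by the task design; not a fittable parameter.
#' @export
GUESS_RATE <- 1 / 6

# Base of the Weibull decay. (0.5 - 1/6) / (1 - 1/6) = 0.4 anchors
# accuracy at exactly 50% when set_size == threshold50.
.WEIBULL_BASE <- 0.4

# Probabilities inside log-likelihoods are clamped to this band so that
# gradients and log-densities stay finite for optimizers and samplers.
.P_CLAMP <- 1e-9

#' Psychometric parameters of the static Weibull accuracy function
#'
#' @param threshold50 Positive. Set size at which per-item accuracy is 50%.
#' @param shape Positive. Dimensionless steepness of the psychometric function.
#' @return An object of class `psychometric_params`.
#' @details The guessing rate is fixed at 1/6 (six response alternatives) and
#'   accuracy at set size 0 is fixed at 1; neither is fittable.
#' @examples
#' p <- psychometric_params(threshold50 = 4, shape = 3)
#' weibull_accuracy(4, p) # 0.5 by construction
#' @export
psychometric_params <- function(threshold50, shape) {
  stopifnot(is.numeric(threshold50), is.numeric(shape),
            length(threshold50) == 1L, length(shape) == 1L)
  if (!is.finite(threshold50) || threshold50 <= 0)
    stop("threshold50 must be a finite positive number")
  if (!is.finite(shape) || shape <= 0)
    stop("shape must be a finite positive number")
  structure(list(threshold50 = threshold50, shape = shape,
                 guess_rate = GUESS_RATE, ceiling = 1),
            class = "psychometric_params")
}

#' Weibull (Quick) psychometric accuracy function
#'
#' Probability of a correct item response at a given memory set size:
#' \deqn{p(s) = \gamma + (1 - \gamma)\, 0.4^{(s/\theta)^\beta}}
#' with guessing rate \eqn{\gamma = 1/6}, threshold \eqn{\theta} and shape
#' \eqn{\beta}. The base 0.4 equals \eqn{(0.5 - \gamma)/(1 - \gamma)}, which is
#' the unique choice anchoring \eqn{p(0) = 1}, \eqn{p(\infty) = 1/6} and
#' \eqn{p(\theta) = 0.5}.
#'
#' @param set_size Non-negative numeric vector of memory set sizes.
#' @param params A [psychometric_params()] object, or a positive numeric vector
#'   of 50%-thresholds (recycled against `set_size`).
#' @param shape Positive numeric vector of shapes; required (and only used)
#'   when `params` is given numerically.
#' @return Numeric vector of per-item accuracies in (1/6, 1].
#' @export
weibull_accuracy <- function(set_size, params, shape = NULL) {
  if (inherits(params, "psychometric_params")) {
    threshold50 <- params$threshold50
    shape <- params$shape
  } else {
    threshold50 <- params
    if (is.null(shape)) stop("shape must be supplied when params is numeric")
  }
  if (any(!is.finite(set_size)) || any(set_size < 0))
    stop("set_size must be finite and non-negative")
  if (any(!is.finite(threshold50)) || any(threshold50 <= 0))
    stop("threshold50 must be finite and positive")
  if (any(!is.finite(shape)) || any(shape <= 0))
    stop("shape must be finite and positive")
  GUESS_RATE + (1 - GUESS_RATE) * .WEIBULL_BASE^((set_size / threshold50)^shape)
}

#' Working-memory capacity implied by a 50% threshold
#'
#' Heuristic capacity: the 50%-accuracy threshold divided by two, read as the
#' number of items successfully recalled. Participants with capacity below one
#' item are excluded by [apply_exclusion()].
#' @param threshold50 Positive numeric vector of 50% thresholds (set sizes).
#' @return Capacity in items.
#' @export
capacity <- function(threshold50) {
  if (any(!is.finite(threshold50)) || any(threshold50 <= 0))
    stop("threshold50 must be finite and positive")
  threshold50 / 2
}

#' Exponential learning trajectory of the 50% threshold
#'
#' The threshold at trial \eqn{t} is
#' \deqn{\theta(t) = A + (S - A)\, 2^{-(t-1)/h}}
#' with start \eqn{S = e^{ls}}, asymptote \eqn{A = e^{la}} and half-time
#' \eqn{h = e^{lh}} (trials until 50% of the start-to-asymptote change).
#' Thresholds and the time constant live on log scales, matching how they are
#' estimated.
#'
#' @param log_start_threshold Log of the threshold at trial 1.
#' @param log_asym_threshold Log of the asymptotic threshold.
#' @param log_half_time Log of the number of trials to 50% of change.
#' @param shape Positive psychometric shape, constant over trials.
#' @return An object of class `learning_trajectory`.
#' @export
learning_trajectory <- function(log_start_threshold, log_asym_threshold,
                                log_half_time, shape) {
  vals <- c(log_start_threshold, log_asym_threshold, log_half_time)
  stopifnot(length(vals) == 3L)
  if (any(!is.finite(exp(vals))) || any(exp(vals) <= 0))
    stop("exp of each log-scale field must be finite and positive")
  if (!is.finite(shape) || shape <= 0) stop("shape must be finite and positive")
  structure(list(log_start_threshold = log_start_threshold,
                 log_asym_threshold = log_asym_threshold,
                 log_half_time = log_half_time,
                 shape = shape),
            class = "learning_trajectory")
}

#' Threshold at a given trial under an exponential learning trajectory
#'
#' @param trial Integer vector of trial numbers, `>= 1` (overall 1-120 or
#'   within-block 1-30 depending on the model's timescale).
#' @param traj A [learning_trajectory()].
#' @return Positive numeric vector of thresholds.
#' @export
threshold_at_trial <- function(trial, traj) {
  stopifnot(inherits(traj, "learning_trajectory"))
  if (any(!is.finite(trial)) || any(trial < 1))
    stop("trial must be >= 1")
  S <- exp(traj$log_start_threshold)
  A <- exp(traj$log_asym_threshold)
  h <- exp(traj$log_half_time)
  A + (S - A) * 2^(-(trial - 1) / h)
}

# Names and order of the three trajectory parameters that may change
# across blocks.
.SCHED_PARAMS <- c("start", "rate", "asym")

#' Monotone cross-block schedule of trajectory parameters
#'
#' Within-block learning parameters may change monotonically from block 1 to
#' block 4. Block 4 is the reference; block 1 equals reference + `total_delta`;
#' blocks 2 and 3 sit at ordered interior fractions of the way back toward the
#' reference, so each parameter's four block values are monotone by
#' construction (either non-increasing or non-decreasing, per the sign of its
#' delta).
#'
#' @param reference A [learning_trajectory()] holding the block-4 (reference)
#'   values.
#' @param total_delta Named or unnamed length-3 numeric: block-1 minus block-4
#'   offsets on the log scale, in the order (start, rate, asym).
#' @param interior_weights Length-2 numeric `c(w2, w3)` with
#'   `1 >= w2 >= w3 >= 0`: the weights of blocks 2 and 3 on the block-1 end.
#' @return An object of class `block_schedule`.
#' @export
block_schedule <- function(reference, total_delta,
                           interior_weights = c(2 / 3, 1 / 3)) {
  stopifnot(inherits(reference, "learning_trajectory"),
            length(total_delta) == 3L, length(interior_weights) == 2L)
  w2 <- interior_weights[[1]]; w3 <- interior_weights[[2]]
  if (!(1 >= w2 && w2 >= w3 && w3 >= 0))
    stop("interior_weights must satisfy 1 >= w2 >= w3 >= 0")
  td <- as.numeric(total_delta)
  names(td) <- .SCHED_PARAMS
  structure(list(reference = reference, total_delta = td,
                 interior_weights = c(w2 = w2, w3 = w3)),
            class = "block_schedule")
}

#' Block-specific value of a trajectory parameter under a schedule
#'
#' @param block Integer vector in 1-4.
#' @param schedule A [block_schedule()].
#' @param param One of `"start"`, `"rate"`, `"asym"` (or its index 1-3).
#' @return Numeric vector of log-scale parameter values, monotone in block.
#' @export
block_value <- function(block, schedule, param) {
  stopifnot(inherits(schedule, "block_schedule"))
  if (any(!(block %in% 1:4))) stop("block must be in 1..4")
  if (is.numeric(param)) param <- .SCHED_PARAMS[param]
  param <- match.arg(param, .SCHED_PARAMS)
  ref <- switch(param,
                start = schedule$reference$log_start_threshold,
                rate  = schedule$reference$log_half_time,
                asym  = schedule$reference$log_asym_threshold)
  w <- c(1, schedule$interior_weights[["w2"]],
         schedule$interior_weights[["w3"]], 0)
  ref + schedule$total_delta[[param]] * w[block]
}

#' Trajectory in effect for one block of a schedule
#'
#' @param schedule A [block_schedule()].
#' @param block Integer in 1-4.
#' @return A [learning_trajectory()] with the block's parameter values.
#' @export
block_trajectory <- function(schedule, block) {
  learning_trajectory(
    log_start_threshold = block_value(block, schedule, "start"),
    log_asym_threshold  = block_value(block, schedule, "asym"),
    log_half_time       = block_value(block, schedule, "rate"),
    shape               = schedule$reference$shape)
}

#' Resolve the per-record 50% threshold from a trajectory or schedule
#'
#' @param records Trial-record data frame (see [validate_trial_table()]).
#' @param trajectory A [learning_trajectory()] (overall-trial timescale) or a
#'   [block_schedule()] (within-block timescale with cross-block change).
#' @param timescale `"overall_1_120"` evaluates the trajectory at
#'   `trial_overall`; `"within_block_1_30"` at `trial_in_block` (using the
#'   record's block when `trajectory` is a schedule).
#' @return Numeric vector of thresholds, one per row of `records`.
#' @export
resolve_thresholds <- function(records, trajectory,
                               timescale = c("overall_1_120",
                                             "within_block_1_30")) {
  timescale <- match.arg(timescale)
  if (inherits(trajectory, "block_schedule")) {
    if (timescale != "within_block_1_30")
      stop("a block_schedule requires the within_block_1_30 timescale")
    th <- numeric(nrow(records))
    for (b in sort(unique(records$block))) {
      i <- records$block == b
      th[i] <- threshold_at_trial(records$trial_in_block[i],
                                  block_trajectory(trajectory, b))
    }
    th
  } else {
    stopifnot(inherits(trajectory, "learning_trajectory"))
    trial <- if (timescale == "overall_1_120") records$trial_overall
             else records$trial_in_block
    threshold_at_trial(trial, trajectory)
  }
}

# clamp probabilities away from 0/1 so log-likelihoods stay finite
clamp_prob <- function(p) pmin(pmax(p, .P_CLAMP), 1 - .P_CLAMP)

#' Disaggregated Bernoulli log-likelihood of item responses
#'
#' Each presented item contributes one Bernoulli term at its trial's set size:
#' `correct ~ Bernoulli(p)` with `p = weibull_accuracy(set_size, threshold50,
#' shape)` resolved at that trial. Probabilities are clamped to
#' `[1e-9, 1 - 1e-9]` so the result is always finite.
#'
#' @param records Data frame with at least `set_size` (>= 1) and `correct`
#'   (0/1) columns.
#' @param threshold50 Per-record 50% threshold (scalar or vector of
#'   `nrow(records)`), e.g. from [resolve_thresholds()].
#' @param shape Psychometric shape (scalar or per-record vector).
#' @return Scalar log-likelihood.
#' @export
span_loglik <- function(records, threshold50, shape) {
  if (nrow(records) == 0L) return(0)
  if (any(records$set_size < 1)) stop("all set sizes must be >= 1")
  if (!all(records$correct %in% c(0L, 1L)))
    stop("correct must be 0/1")
  p <- clamp_prob(weibull_accuracy(records$set_size, threshold50, shape))
  sum(ifelse(records$correct == 1L, log(p), log1p(-p)))
}
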