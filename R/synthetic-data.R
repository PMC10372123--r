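# Seeded synthetic span-task generator: 4 blocks x 30 trials, set sizes 2-6,
# six rotated stimuli per block mapped to six response buttons, five
# between-subject stimulus-response mapping conditions, per-item Bernoulli
# responses drawn from the psychometric learning model.

#' The five between-subject conditions
#' @export
CONDITIONS <- c("constant", "constant_search", "random",
                "blocked", "blocked_search")

.N_BLOCKS <- 4L
.TRIALS_PER_BLOCK <- 30L
.SET_SIZES <- 2:6
.N_STIMULI <- 6L
.ROT_STEP <- 28

.dual_task <- function(condition) condition %in% c("constant_search",
                                                   "blocked_search")

# The six candidate rotations for each block of one participant. Blocks come
# in same-shape pairs (oval on 1&3 or 2&4, pentagon on the others, coin-flip
# per participant); within a pair the two blocks use disjoint 28-degree-spaced
# angle sets displaced by 180 degrees, e.g. [20 48 76 104 132 160] vs
# [200 228 256 284 312 340].
.block_rotation_sets <- function() {
  oval_first <- runif(1) < 0.5
  shapes <- if (oval_first) c("oval_wedge", "pentagon", "oval_wedge", "pentagon")
            else c("pentagon", "oval_wedge", "pentagon", "oval_wedge")
  rots <- vector("list", .N_BLOCKS)
  for (shape in unique(shapes)) {
    pair <- which(shapes == shape)
    base <- runif(1, 0, .ROT_STEP)
    rots[[pair[1]]] <- round(base + .ROT_STEP * 0:(.N_STIMULI - 1), 1)
    rots[[pair[2]]] <- round((base + 180 + .ROT_STEP * 0:(.N_STIMULI - 1)) %% 360, 1)
  }
  list(shapes = shapes, rotations = rots)
}

#' Stimulus-to-button mapping for one trial
#'
#' Returns the bijection from a block's six stimulus rotations to response
#' buttons 1-6 under the condition's mapping regime: `constant` (and
#' `constant_search`) use one fixed canonical bijection everywhere (stimuli
#' sorted counterclockwise-to-clockwise map to buttons 1-6 in order, so the
#' most-counterclockwise stimulus is always on button 1); `blocked` (and
#' `blocked_search`) draw one uniform random bijection per participant-block;
#' `random` draws a fresh uniform bijection on every trial.
#'
#' @param condition One of [CONDITIONS].
#' @param rotations The block's six candidate rotations (degrees).
#' @param block Block number 1-4.
#' @param trial_in_block Trial number 1-30 within the block.
#' @param participant_seed Integer substream seed for this participant.
#' @return Named integer vector: `buttons[as.character(rotation)]` in 1-6.
#' @export
assign_mapping <- function(condition, rotations, block, trial_in_block,
                           participant_seed) {
  condition <- match.arg(condition, CONDITIONS)
  stopifnot(length(rotations) == .N_STIMULI)
  ord <- order(rotations)
  buttons <- switch(
    sub("_search$", "", condition),
    constant = { b <- integer(.N_STIMULI); b[ord] <- 1:.N_STIMULI; b },
    blocked = with_seed(stable_seed(participant_seed,
                                    paste0("map_b", block)),
                        sample.int(.N_STIMULI)),
    random = with_seed(stable_seed(participant_seed,
                                   paste0("map_b", block, "_t", trial_in_block)),
                       sample.int(.N_STIMULI)))
  names(buttons) <- as.character(rotations)
  buttons
}

#' Generate one participant's 120-trial span-task design
#'
#' Four blocks of 30 trials. The first five trials of every block present set
#' sizes 2,3,4,5,6 in that order; the remaining 25 trials are a random
#' permutation balancing every set size to exactly 6 occurrences per block.
#' Stimuli are six rotated shapes per block (see [assign_mapping()] for the
#' response-mapping regimes).
#'
#' @param condition One of [CONDITIONS].
#' @param participant_id Participant label (also keys the RNG substream).
#' @param seed Master integer seed.
#' @return Data frame with one row per trial: design columns plus list columns
#'   `stimulus_rotations` (the presented items' angles) and `item_buttons`
#'   (their mapped response buttons).
#' @export
generate_design <- function(condition, participant_id, seed) {
  condition <- match.arg(condition, CONDITIONS)
  pseed <- stable_seed(seed, participant_id)
  with_seed(pseed, {
    sets <- .block_rotation_sets()
    rows <- vector("list", .N_BLOCKS)
    for (b in seq_len(.N_BLOCKS)) {
      ss <- c(.SET_SIZES,
              sample(rep(.SET_SIZES, .TRIALS_PER_BLOCK / length(.SET_SIZES) - 1L)))
      rot <- sets$rotations[[b]]
      stim <- vector("list", .TRIALS_PER_BLOCK)
      butt <- vector("list", .TRIALS_PER_BLOCK)
      for (t in seq_len(.TRIALS_PER_BLOCK)) {
        map <- assign_mapping(condition, rot, b, t, pseed)
        items <- sample(rot, ss[t])
        stim[[t]] <- items
        butt[[t]] <- unname(map[as.character(items)])
      }
      rows[[b]] <- data.frame(
        participant_id = participant_id,
        condition = condition,
        block = b,
        trial_in_block = seq_len(.TRIALS_PER_BLOCK),
        trial_overall = (b - 1L) * .TRIALS_PER_BLOCK + seq_len(.TRIALS_PER_BLOCK),
        set_size = as.integer(ss),
        shape_family = sets$shapes[b],
        dual_task = .dual_task(condition),
        stringsAsFactors = FALSE)
      rows[[b]]$stimulus_rotations <- I(stim)
      rows[[b]]$item_buttons <- I(butt)
    }
    do.call(rbind, rows)
  })
}

# expand a design into one row per presented item
.design_items <- function(design) {
  n <- design$set_size
  idx <- rep.int(seq_len(nrow(design)), n)
  out <- design[idx, setdiff(names(design),
                             c("stimulus_rotations", "item_buttons"))]
  out$item_position <- unlist(lapply(n, seq_len), use.names = FALSE)
  out$rotation_deg <- unlist(design$stimulus_rotations, use.names = FALSE)
  out$button <- unlist(design$item_buttons, use.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate per-item responses from the psychometric learning model
#'
#' Each of a trial's `set_size` items is an independent Bernoulli draw with
#' success probability `weibull_accuracy(set_size, theta(trial))`, where the
#' threshold trajectory is evaluated on the requested timescale. This is the
#' generative mirror of the analysis likelihood (a descriptive generator, not
#' a mechanistic learner): condition differences enter only through the
#' supplied parameters.
#'
#' @param design Output of [generate_design()].
#' @param trajectory A [learning_trajectory()] or (within-block timescale) a
#'   [block_schedule()].
#' @param timescale See [resolve_thresholds()].
#' @param seed Integer seed for the response draws.
#' @return Trial-record data frame, one row per presented item, with `correct`
#'   in 0/1.
#' @export
simulate_responses <- function(design, trajectory,
                               timescale = c("overall_1_120",
                                             "within_block_1_30"),
                               seed = 1L) {
  timescale <- match.arg(timescale)
  items <- .design_items(design)
  th <- resolve_thresholds(items, trajectory, timescale)
  shape <- if (inherits(trajectory, "block_schedule"))
    trajectory$reference$shape else trajectory$shape
  p <- weibull_accuracy(items$set_size, th, shape)
  items$correct <- with_seed(seed, as.integer(runif(nrow(items)) < p))
  items
}

#' Simulate a pure guesser (exclusion-filter fixture)
#'
#' Every item is correct with probability exactly 1/6, independent of set size
#' and trial. Feeding the result to [fit_static()] should yield a capacity
#' below one item.
#'
#' @inheritParams simulate_responses
#' @export
chance_responder <- function(design, seed = 1L) {
  items <- .design_items(design)
  items$correct <- with_seed(seed, as.integer(runif(nrow(items)) < GUESS_RATE))
  items
}

#' Configuration of a synthetic cohort
#'
#' Defaults emulate the study design: five conditions with sample sizes
#' 31, 31, 30, 30, 29 (total 151); overall-trial exponential learning for the
#' `constant`, `constant_search` and `random` conditions; within-block
#' learning with a monotone cross-block schedule for `blocked` and
#' `blocked_search`. Default fixed effects are anchored to the published
#' effect sizes (constant-mapping learning magnitude ~0.58 on the log scale,
#' a large cross-block rate change ~2.3 for the blocked condition); random
#' effects are independent normals on the three log-scale parameters.
#'
#' @param n Named integer vector of per-condition sample sizes.
#' @param effects Named list: per condition either a [learning_trajectory()]
#'   or a [block_schedule()].
#' @param re_sd Named length-3 numeric: random-effect SDs for
#'   (start, rate, asym) on the log scale.
#' @param seed Master integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = c(constant = 31L, constant_search = 31L,
                                random = 30L, blocked = 30L,
                                blocked_search = 29L),
                          effects = default_effects(),
                          re_sd = c(start = 0.2, rate = 0.3, asym = 0.2),
                          seed = 1L) {
  stopifnot(all(names(n) %in% CONDITIONS), all(n >= 1),
            all(names(effects) %in% CONDITIONS),
            all(names(n) %in% names(effects)),
            length(re_sd) == 3L, all(re_sd >= 0))
  names(re_sd) <- .SCHED_PARAMS
  structure(list(n = n, effects = effects, re_sd = re_sd, seed = seed),
            class = "cohort_config")
}

#' Default generating fixed effects for the five conditions
#'
#' Trajectory parameters are on log scales. The constant-mapping condition
#' starts near threshold 3 and learns ~0.58 log units; the random-mapping
#' condition starts slightly lower and barely improves; blocked conditions use
#' a block-4 reference with a large positive block-1 rate offset (slow early
#' learning that speeds up across blocks: learning-to-learn). The block-4
#' reference half-time is short (3 trials): late-block learning is fast
#' relative to the 30-trial block, which is what makes the rate-only reduced
#' model clearly distinguishable from asymptote-only change, as reported.
#' @return Named list of [learning_trajectory()] / [block_schedule()] objects.
#' @export
default_effects <- function() {
  shp <- 3
  list(
    constant = learning_trajectory(log(3), log(3) + 0.583, log(20), shp),
    constant_search = learning_trajectory(1.00, 1.50, log(20), shp),
    random = learning_trajectory(log(3) - 0.122, 0.70, log(20), shp),
    blocked = block_schedule(
      learning_trajectory(1.0, 1.55, log(3), shp),
      total_delta = c(start = 0.091, rate = 2.312, asym = 0.012),
      interior_weights = c(2 / 3, 1 / 3)),
    blocked_search = block_schedule(
      learning_trajectory(0.9, 1.45, log(3), shp),
      total_delta = c(start = 0.10, rate = 2.0, asym = 0.05),
      interior_weights = c(2 / 3, 1 / 3)))
}

# shift a trajectory's (start, rate, asym) log-scale values by a length-3 re
.shift_trajectory <- function(traj, re) {
  learning_trajectory(traj$log_start_threshold + re[["start"]],
                      traj$log_asym_threshold + re[["asym"]],
                      traj$log_half_time + re[["rate"]],
                      traj$shape)
}

#' Generate a full synthetic cohort with ground truth
#'
#' Per participant, random effects are drawn as independent normals on the
#' three log-scale trajectory parameters around the condition's fixed effects
#' (for blocked conditions the random effects shift the block-4 reference;
#' cross-block deltas and weights are condition-level). Fully reproducible:
#' every participant has an RNG substream keyed by a stable hash of their id,
#' so the same master seed yields an identical cohort regardless of
#' generation order.
#'
#' @param config A [cohort_config()].
#' @return List with `records` (trial-record data frame over all participants)
#'   and `truth` (one row per participant: generating parameters).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  recs <- list(); truth <- list()
  for (cond in names(config$n)) {
    eff <- config$effects[[cond]]
    is_sched <- inherits(eff, "block_schedule")
    timescale <- if (is_sched) "within_block_1_30" else "overall_1_120"
    for (j in seq_len(config$n[[cond]])) {
      pid <- sprintf("%s_%02d", cond, j)
      pseed <- stable_seed(config$seed, pid)
      re <- with_seed(stable_seed(pseed, "re"),
                      stats::rnorm(3, 0, config$re_sd))
      names(re) <- .SCHED_PARAMS
      base <- if (is_sched) eff$reference else eff
      ptraj <- .shift_trajectory(base, re)
      gen <- if (is_sched)
        block_schedule(ptraj, eff$total_delta,
                       unname(eff$interior_weights)) else ptraj
      design <- generate_design(cond, pid, config$seed)
      recs[[pid]] <- simulate_responses(design, gen, timescale,
                                        seed = stable_seed(pseed, "resp"))
      truth[[pid]] <- data.frame(
        participant_id = pid, condition = cond,
        log_start = ptraj$log_start_threshold,
        log_asym = ptraj$log_asym_threshold,
        log_half_time = ptraj$log_half_time,
        shape = ptraj$shape,
        re_start = re[["start"]], re_rate = re[["rate"]],
        re_asym = re[["asym"]],
        stringsAsFactors = FALSE)
    }
  }
  list(records = do.call(rbind, c(recs, make.row.names = FALSE)),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}
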