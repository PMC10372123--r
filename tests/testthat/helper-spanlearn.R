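# Shared fixtures, all generated in code.

# a bare design table (no stimuli) with `ntrials` trials of one set size,
# for Monte-Carlo and static-fit tests
flat_design <- function(ntrials, set_size, participant_id = "px",
                        condition = "constant") {
  stopifnot(ntrials %% 120 == 0 || ntrials <= 120)
  blocks <- ((seq_len(ntrials) - 1) %/% 30) %% 4 + 1
  data.frame(participant_id = participant_id, condition = condition,
             block = blocks,
             trial_in_block = (seq_len(ntrials) - 1) %% 30 + 1,
             trial_overall = (blocks - 1) * 30 + (seq_len(ntrials) - 1) %% 30 + 1,
             set_size = set_size, shape_family = "oval_wedge",
             dual_task = FALSE, stringsAsFactors = FALSE)
}

# random item-level records for likelihood property tests
random_records <- function(n_items, seed) {
  spanlearn:::with_seed(seed, data.frame(
    set_size = sample(2:6, n_items, replace = TRUE),
    correct = sample(0:1, n_items, replace = TRUE)))
}

# small two-condition cohort used across fit tests (memoised per session)
.fixture_env <- new.env()
small_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    cfg <- cohort_config(n = c(constant = 4L, random = 4L), seed = 101)
    coh <- generate_cohort(cfg)
    .fixture_env$records <- coh$records
    .fixture_env$truth <- coh$truth
    .fixture_env$fit <- fit_learning_model(
      coh$records, model_spec("overall_1_120",
                              reference_condition = "constant"),
      sampler_control("laplace", chains = 4L, iter = 300L, seed = 7))
  }
  .fixture_env
}

# a hand-built posterior_draws object from named draw vectors, for contrast
# and diagnostics tests that need full control of the draws
fake_fit <- function(draws_list, chains = 2L) {
  stopifnot(length(unique(lengths(draws_list))) == 1)
  n <- lengths(draws_list)[1]
  stopifnot(n %% chains == 0)
  arr <- array(NA_real_, c(n / chains, chains, length(draws_list)),
               dimnames = list(NULL, NULL, names(draws_list)))
  for (j in seq_along(draws_list))
    arr[, , j] <- matrix(draws_list[[j]], n / chains, chains)
  fit <- structure(list(draws = arr, par_names = names(draws_list),
                        method = "fake", accept_rate = NA_real_,
                        divergences = 0L, data_fingerprint = "fake"),
                   class = "posterior_draws")
  fit$diagnostics <- list(rhat = setNames(rep(1, length(draws_list)),
                                          names(draws_list)),
                          ess_tail = setNames(rep(1e4, length(draws_list)),
                                              names(draws_list)),
                          max_rhat = 1, min_ess_tail = 1e4, converged = TRUE)
  fit
}
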