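# Hierarchical model: log-density identities, gradients, Laplace/static
# consistency, convergence diagnostics.

test_that("model log-density equals core loglik plus priors at random points", {
  # single participant, no condition offsets / REs: the model's linear
  # predictors ARE a learning trajectory, so the data term must equal
  # span_loglik evaluated through the core functions
  des <- generate_design("constant", "p1", 3)
  tr <- learning_trajectory(log(3), log(4.5), log(15), 3)
  rec <- simulate_responses(des, tr, "overall_1_120", seed = 4)
  spec <- model_spec("overall_1_120", reference_condition = "constant",
                     condition_effects = character(0),
                     random_effects = character(0))
  ctx <- build_model_context(rec, spec)
  expect_equal(ctx$par_names, c("mu_start", "mu_rate", "mu_asym", "mu_shape"))
  for (i in 1:20) {
    th <- spanlearn:::with_seed(i, rnorm(4, c(1, 2.5, 1.3, 1), 0.4))
    comp <- log_posterior(ctx, th, components = TRUE)
    tr_i <- learning_trajectory(th[1], th[3], th[2], exp(th[4]))
    ll_core <- span_loglik(rec, resolve_thresholds(rec, tr_i,
                                                   "overall_1_120"),
                           exp(th[4]))
    expect_equal(comp$loglik, ll_core, tolerance = 1e-10)
    expect_equal(log_posterior(ctx, th), comp$loglik + comp$logprior)
  }
})

test_that("log-density identity holds with random effects (manual resolve)", {
  cfg <- cohort_config(n = c(constant = 2L, random = 2L), seed = 23)
  coh <- generate_cohort(cfg)
  spec <- model_spec("overall_1_120", reference_condition = "constant")
  ctx <- build_model_context(coh$records, spec)
  nm <- ctx$par_names
  for (i in 1:5) {
    th <- spanlearn:::with_seed(100 + i, init_theta(ctx, jitter = 0.3))
    comp <- log_posterior(ctx, th, components = TRUE)
    # resolve each participant's trajectory by hand (non-centered REs)
    ll <- 0
    for (pid in ctx$pids) {
      rr <- coh$records[coh$records$participant_id == pid, ]
      cc <- rr$condition[1]
      d <- function(p) if (cc == "constant") 0
        else th[match(sprintf("d_%s[%s]", p, cc), nm)]
      b <- function(p) exp(th[match(paste0("log_sd_", p), nm)]) *
        th[match(sprintf("b_%s[%s]", p, pid), nm)]
      tr_i <- learning_trajectory(
        th[match("mu_start", nm)] + d("start") + b("start"),
        th[match("mu_asym", nm)] + d("asym") + b("asym"),
        th[match("mu_rate", nm)] + d("rate") + b("rate"),
        exp(th[match("mu_shape", nm)] + d("shape")))
      ll <- ll + span_loglik(rr, resolve_thresholds(rr, tr_i,
                                                    "overall_1_120"),
                             tr_i$shape)
    }
    expect_equal(comp$loglik, ll, tolerance = 1e-9)
  }
})

test_that("analytic gradient matches central differences (E1 and E2)", {
  cases <- list(
    list(cfg = cohort_config(n = c(constant = 2L, random = 2L), seed = 5),
         spec = model_spec("overall_1_120",
                           reference_condition = "constant")),
    list(cfg = cohort_config(n = c(blocked = 2L, blocked_search = 2L),
                             seed = 6),
         spec = model_spec("within_block_1_30", "full",
                           reference_condition = "blocked")),
    list(cfg = cohort_config(n = c(blocked = 3L), seed = 7),
         spec = model_spec("within_block_1_30", "rate_only",
                           reference_condition = "blocked")))
  for (case in cases) {
    coh <- generate_cohort(case$cfg)
    ctx <- build_model_context(coh$records, case$spec)
    for (rep in 1:3) {
      th <- spanlearn:::with_seed(rep * 11, init_theta(ctx, jitter = 0.3))
      g <- log_posterior_grad(ctx, th)
      gn <- vapply(seq_len(ctx$n_par), function(i) {
        e <- numeric(ctx$n_par); e[i] <- 1e-6
        (log_posterior(ctx, th + e) - log_posterior(ctx, th - e)) / 2e-6
      }, 0)
      expect_lt(max(abs(g - gn) / (abs(gn) + 1)), 1e-5)
    }
  }
})

test_that("MAP of a single-participant flat-learning model matches fit_static", {
  # flat trajectory (start == asym): the learning model collapses onto the
  # static Weibull fit; with 480 items the weak priors barely move the mode
  des <- generate_design("constant", "p1", 31)
  tr <- learning_trajectory(log(3.5), log(3.5), log(10), 3)
  rec <- simulate_responses(des, tr, "overall_1_120", seed = 41)
  static <- fit_static(rec)
  fit <- fit_learning_model(
    rec, model_spec("overall_1_120", reference_condition = "constant",
                    condition_effects = character(0),
                    random_effects = character(0)),
    sampler_control("laplace", chains = 2L, iter = 100L, seed = 2))
  m <- colMeans(draw_matrix(fit))
  th_hat <- exp((m["mu_start"] + m["mu_asym"]) / 2)  # flat: both ~ threshold
  expect_equal(unname(th_hat), static$threshold50, tolerance = 0.1)
  expect_equal(unname(exp(m["mu_shape"])), static$shape, tolerance = 0.35)
})

test_that("posterior SDs of fixed effects shrink with more data", {
  # without REs the fixed-effect information grows directly with item count
  # (with REs it saturates at the between-participant variance, so that
  # regime is not a clean test of the data -> precision monotonicity)
  cfg <- cohort_config(n = c(constant = 4L, random = 4L),
                       re_sd = c(0, 0, 0), seed = 55)
  coh <- generate_cohort(cfg)
  spec <- model_spec("overall_1_120", reference_condition = "constant",
                     random_effects = character(0))
  ctl <- sampler_control("laplace", chains = 2L, iter = 400L, seed = 3)
  half <- coh$records[coh$records$block <= 2, ]
  sd_of <- function(recs) {
    m <- draw_matrix(fit_learning_model(recs, spec, ctl))
    apply(m[, c("mu_asym", "d_asym[random]", "mu_start")], 2, sd)
  }
  expect_true(all(sd_of(coh$records) < sd_of(half)))
})

test_that("diagnostics: degenerate and trending chains, single-chain error", {
  set.seed(9)
  # well-mixed iid draws: rhat ~ 1, high ESS
  good <- array(rnorm(4000), c(1000, 4, 1), dimnames = list(NULL, NULL, "x"))
  dg <- diagnostics(good)
  expect_lt(dg$max_rhat, 1.01)
  expect_gt(dg$min_ess_tail, 1000)
  # identical copied chains: rhat ~ 1 exactly (B = 0)
  one <- rnorm(500)
  copied <- array(rep(one, 4), c(500, 4, 1),
                  dimnames = list(NULL, NULL, "x"))
  expect_equal(diagnostics(copied)$max_rhat, 1, tolerance = 0.01)
  # chains at different levels: rhat far above 1.02
  apart <- array(rnorm(2000) + rep(c(0, 5), each = 1000), c(1000, 2, 1),
                 dimnames = list(NULL, NULL, "x"))
  expect_gt(diagnostics(apart)$max_rhat, 1.5)
  # constant draws are flagged unconverged via undefined ESS
  const <- array(1, c(100, 2, 1), dimnames = list(NULL, NULL, "x"))
  expect_false(diagnostics(const)$converged)
  expect_error(diagnostics(array(rnorm(100), c(50, 1, 2))), "2 chains")
})

test_that("a deliberately tiny MCMC run is flagged non-converged", {
  cfg <- cohort_config(n = c(constant = 2L), seed = 71)
  coh <- generate_cohort(cfg)
  fit <- fit_learning_model(
    coh$records,
    model_spec("overall_1_120", reference_condition = "constant"),
    sampler_control("mcmc", chains = 2L, warmup = 30L, iter = 10L, seed = 1))
  expect_false(fit$diagnostics$converged)
  expect_error(standard_battery(fit), "non-converged")
})

test_that("sampler seed reproducibility and draw bookkeeping", {
  env <- small_fit()
  fit <- env$fit
  expect_equal(dim(fit$draws), c(300, 4, length(fit$par_names)))
  refit <- fit_learning_model(
    env$records, model_spec("overall_1_120",
                            reference_condition = "constant"),
    sampler_control("laplace", chains = 4L, iter = 300L, seed = 7))
  expect_identical(fit$draws, refit$draws)
})
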