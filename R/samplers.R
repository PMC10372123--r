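# Posterior computation: adaptive Hamiltonian Monte Carlo (production mode)
# and a MAP + Laplace-approximation fast mode for tests and smoke runs.

#' Sampler settings
#'
#' @param method `"mcmc"` (adaptive HMC; production default) or `"laplace"`
#'   (posterior mode plus Gaussian approximation; fast, for tests and smoke
#'   runs).
#' @param chains Number of chains (MCMC) or pseudo-chains the Laplace draws
#'   are arranged into.
#' @param warmup,iter Warmup and kept iterations per chain (MCMC). For
#'   Laplace, `iter * chains` independent draws are taken from the Gaussian
#'   approximation.
#' @param target_accept Dual-averaging target acceptance rate.
#' @param max_leapfrog Upper bound of the uniformly jittered leapfrog count.
#' @param seed Integer seed for the sampler's randomness.
#' @export
sampler_control <- function(method = c("mcmc", "laplace"), chains = 4L,
                            warmup = 1000L, iter = 2000L,
                            target_accept = 0.8, max_leapfrog = 24L,
                            seed = 1L) {
  method <- match.arg(method)
  stopifnot(chains >= 1, warmup >= 20 || method == "laplace", iter >= 1)
  structure(list(method = method, chains = as.integer(chains),
                 warmup = as.integer(warmup), iter = as.integer(iter),
                 target_accept = target_accept,
                 max_leapfrog = as.integer(max_leapfrog),
                 seed = as.integer(seed)),
            class = "sampler_control")
}

# one HMC chain with dual-averaging step size and diagonal mass adaptation
.hmc_chain <- function(lpfun, gradfun, init, control, chain_seed) {
  with_seed(chain_seed, {
    d <- length(init)
    q <- init
    lq <- lpfun(q); gq <- gradfun(q)
    inv_mass <- rep(1, d)
    W <- control$warmup; N <- control$iter
    # dual averaging (Hoffman & Gelman): adapt log step size toward
    # target acceptance
    eps <- 0.1; mu_da <- log(10 * eps); log_eps_bar <- 0; Hbar <- 0
    gamma <- 0.05; t0 <- 10; kappa <- 0.75; da_t <- 0
    da_reset <- function(e) { mu_da <<- log(10 * e); log_eps_bar <<- 0
                              Hbar <<- 0; da_t <<- 0 }
    mass_buf <- NULL
    draws <- matrix(NA_real_, N, d)
    n_div <- 0L; acc_sum <- 0
    upd1 <- floor(W * 0.5); upd2 <- floor(W * 0.9)
    Lmin <- max(1L, control$max_leapfrog %/% 2L)
    for (it in seq_len(W + N)) {
      warm <- it <= W
      # jitter trajectory length in the upper half of the budget: very short
      # trajectories explore the slow (hierarchy-scale) directions poorly
      L <- sample(Lmin:control$max_leapfrog, 1L)
      e <- eps * stats::runif(1, 0.9, 1.1)
      p <- stats::rnorm(d) / sqrt(inv_mass)
      H0 <- -lq + sum(p^2 * inv_mass) / 2
      qn <- q; gn <- gq
      p <- p + e / 2 * gn
      div <- FALSE
      for (l in seq_len(L)) {
        qn <- qn + e * inv_mass * p
        gn <- gradfun(qn)
        if (any(!is.finite(gn))) { div <- TRUE; break }
        p <- p + (if (l < L) e else e / 2) * gn
      }
      if (!div) {
        ln <- lpfun(qn)
        H1 <- -ln + sum(p^2 * inv_mass) / 2
        div <- !is.finite(H1) || (H1 - H0) > 1000
      }
      a <- if (div) 0 else min(1, exp(H0 - H1))
      if (!div && stats::runif(1) < a) { q <- qn; lq <- ln; gq <- gn }
      if (warm) {
        da_t <- da_t + 1
        Hbar <- (1 - 1 / (da_t + t0)) * Hbar +
          (control$target_accept - a) / (da_t + t0)
        log_eps <- mu_da - sqrt(da_t) / gamma * Hbar
        log_eps_bar <- da_t^(-kappa) * log_eps +
          (1 - da_t^(-kappa)) * log_eps_bar
        eps <- exp(log_eps)
        if (it > W * 0.15) mass_buf <- rbind(mass_buf, q)
        if (it %in% c(upd1, upd2) && !is.null(mass_buf) &&
            nrow(mass_buf) > 10) {
          v <- apply(mass_buf, 2, stats::var)
          nmb <- nrow(mass_buf)
          inv_mass <- v * nmb / (nmb + 5) + 1e-3 * 5 / (nmb + 5)
          mass_buf <- NULL
          da_reset(eps)
        }
        if (it == W) eps <- exp(log_eps_bar)
      } else {
        draws[it - W, ] <- q
        acc_sum <- acc_sum + a
        if (div) n_div <- n_div + 1L
      }
    }
    list(draws = draws, accept_rate = acc_sum / N, divergences = n_div,
         step_size = eps)
  })
}

.fit_mcmc <- function(ctx, control) {
  lpfun <- function(th) log_posterior(ctx, th)
  gradfun <- function(th) log_posterior_grad(ctx, th)
  chains <- vector("list", control$chains)
  for (ch in seq_len(control$chains)) {
    init <- with_seed(stable_seed(control$seed, paste0("init", ch)),
                      init_theta(ctx, jitter = 0.05))
    chains[[ch]] <- .hmc_chain(lpfun, gradfun, init, control,
                               stable_seed(control$seed, paste0("chain", ch)))
  }
  draws <- array(NA_real_, c(control$iter, control$chains, ctx$n_par),
                 dimnames = list(NULL, NULL, ctx$par_names))
  for (ch in seq_along(chains)) draws[, ch, ] <- chains[[ch]]$draws
  list(draws = draws,
       accept_rate = mean(vapply(chains, `[[`, 0, "accept_rate")),
       divergences = sum(vapply(chains, `[[`, 0L, "divergences")))
}

# MAP via gradient-based quasi-Newton, then draws from the Gaussian
# (Laplace) approximation at the mode
.fit_laplace <- function(ctx, control) {
  nll <- function(th) -log_posterior(ctx, th)
  ngr <- function(th) -log_posterior_grad(ctx, th)
  init <- with_seed(stable_seed(control$seed, "map_init"),
                    init_theta(ctx, jitter = 0.01))
  mode <- init; conv <- 1L
  for (round in 1:10) {  # restart BFGS until the gradient is flat
    opt <- stats::optim(mode, nll, ngr, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-13))
    mode <- opt$par; conv <- opt$convergence
    if (max(abs(ngr(mode))) < 1e-2) break
  }
  H <- .grad_jacobian(ngr, mode)      # Hessian of the negative log-posterior
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-8 * max(ev$values))
  # draw z ~ N(0, I); theta = mode + V diag(1/sqrt(lam)) z
  ndraw <- control$iter * control$chains
  z <- with_seed(stable_seed(control$seed, "laplace_draws"),
                 matrix(stats::rnorm(ndraw * length(mode)), ndraw))
  th <- sweep(z %*% diag(1 / sqrt(lam), length(lam)) %*% t(ev$vectors), 2,
              mode, `+`)
  draws <- array(NA_real_, c(control$iter, control$chains, ctx$n_par),
                 dimnames = list(NULL, NULL, ctx$par_names))
  for (ch in seq_len(control$chains))
    draws[, ch, ] <- th[(ch - 1) * control$iter + seq_len(control$iter), ]
  list(draws = draws, mode = mode, opt_convergence = conv,
       accept_rate = NA_real_, divergences = 0L)
}

# central-difference Jacobian of a gradient function (Hessian)
.grad_jacobian <- function(gr, x, h = 1e-4) {
  d <- length(x)
  J <- matrix(0, d, d)
  for (i in seq_len(d)) {
    e <- numeric(d); e[i] <- h
    J[, i] <- (gr(x + e) - gr(x - e)) / (2 * h)
  }
  J
}

#' Fit the hierarchical time-evolving learning model
#'
#' Fits the per-item Bernoulli likelihood with Weibull accuracy and an
#' exponentially evolving 50% threshold (see [build_model_context()] for the
#' full linear-predictor and prior structure) by adaptive HMC, or by a
#' MAP+Laplace approximation in fast mode.
#'
#' @param records Validated trial-record data frame.
#' @param spec A [model_spec()].
#' @param control A [sampler_control()].
#' @param complete_trials Passed to [validate_trial_table()]; relax for
#'   cross-validation refits holding out single items.
#' @return A `posterior_draws` object: `$draws` (iterations x chains x
#'   parameters array), `$diagnostics` (per-parameter split R-hat and tail
#'   ESS, `converged` flag), `$spec`, `$method`, `$data_fingerprint`.
#'   Non-converged fits are returned but flagged; downstream contrast and LOO
#'   functions refuse them unless forced.
#' @export
fit_learning_model <- function(records, spec, control = sampler_control(),
                               complete_trials = TRUE) {
  ctx <- build_model_context(records, spec, complete_trials)
  res <- if (control$method == "mcmc") .fit_mcmc(ctx, control)
         else .fit_laplace(ctx, control)
  fit <- structure(list(
    draws = res$draws, par_names = ctx$par_names, spec = spec,
    method = control$method, control = control, ctx = ctx,
    accept_rate = res$accept_rate, divergences = res$divergences,
    data_fingerprint = ctx$fingerprint), class = "posterior_draws")
  fit$diagnostics <- diagnostics(fit)
  fit
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d parameters, %d chains x %d draws (%s)\n",
              length(x$par_names), dim(x$draws)[2], dim(x$draws)[1],
              x$method))
  cat(sprintf("  max R-hat %.4f, min tail ESS %.0f, converged: %s\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess_tail),
              x$diagnostics$converged))
  invisible(x)
}

# flatten the draws array to a (draws*chains) x parameter matrix
draw_matrix <- function(fit) {
  dr <- fit$draws
  m <- matrix(dr, prod(dim(dr)[1:2]), dim(dr)[3])
  colnames(m) <- dimnames(dr)[[3]]
  m
}
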