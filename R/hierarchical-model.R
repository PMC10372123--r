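# Model context, log-posterior and analytic gradient of the hierarchical
# time-evolving psychometric model.
#
# Likelihood (per presented item, aggregated here to per-trial binomial
# counts since p is constant within a trial):
#   correct ~ Bernoulli(p),  p = 1/6 + 5/6 * 0.4^((s / theta(t))^beta)
#   theta(t) = A + (S - A) * 2^(-(t - 1) / h)
# with, on log scales and per trial,
#   log S = mu_start + d_start[cond] + b_start[pid] + delta_start[cond] * w[block]
#   log h = mu_rate  + d_rate[cond]  + b_rate[pid]  + delta_rate[cond]  * w[block]
#   log A = mu_asym  + d_asym[cond]  + b_asym[pid]  + delta_asym[cond]  * w[block]
#   log beta = mu_shape + d_shape[cond]
# d terms are zero for the reference condition; delta terms exist only for
# block-flexible parameters (within-block timescale); w = (1, w2, w3, 0) with
# 1 >= w2 >= w3 >= 0 per condition (monotone by construction), parameterized
# as w2 = plogis(a), w3 = w2 * plogis(b).
#
# Random effects are non-centered: b_p[pid] = exp(log_sd_p) * z_p[pid] with
# z ~ N(0, 1). The parameter vector holds the standardized z (still named
# b_p[pid]); the centered effect is sd * z. This keeps the posterior mode
# well-defined (the centered parameterization has an unbounded density spike
# at sd -> 0) and tames the funnel for HMC.
#
# Priors: mu_start, mu_asym ~ N(log 3, 1); mu_rate ~ N(log 10, 1);
# mu_shape ~ N(log 3, 0.5); condition offsets and block deltas ~ N(0, 1);
# random effects b ~ N(0, sd_p) with sd_p ~ half-N(0.5) (log-parameterized
# with Jacobian); a, b ~ standard logistic (=> uniform ordered weights).

.LN04 <- log(0.4)
.LN2 <- log(2)

#' Build the internal model context for a records/spec pair
#'
#' Aggregates items to per-trial binomial counts, indexes participants,
#' conditions and blocks, and lays out the unconstrained parameter vector.
#' Exposed mainly for testing the log-density identity against
#' [span_loglik()].
#'
#' @param records Validated trial-record data frame.
#' @param spec A [model_spec()].
#' @param complete_trials Passed to [validate_trial_table()]; set `FALSE`
#'   for cross-validation refits that hold out single items.
#' @return A `model_ctx` list with the parameter layout (`$par_names`), data
#'   index vectors and prior definitions.
#' @export
build_model_context <- function(records, spec, complete_trials = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  validate_trial_table(records, complete_trials = complete_trials)
  conds <- unique(records$condition)
  if (!spec$reference_condition %in% conds)
    stop("reference_condition '", spec$reference_condition,
         "' not present in data")
  conds <- c(spec$reference_condition,
             sort(setdiff(conds, spec$reference_condition)))
  pids <- sort(unique(records$participant_id))

  key <- paste(records$participant_id, records$trial_overall)
  first <- !duplicated(key)
  tr <- records[first, c("participant_id", "condition", "block",
                         "trial_in_block", "trial_overall", "set_size")]
  ord <- match(key[first], sort(unique(key)))
  tr$k <- as.vector(rowsum(as.numeric(records$correct), key)[ord, 1])
  # actual item count per trial (== set_size for complete data, fewer for
  # cross-validation refits that hold out single items)
  tr$n <- as.vector(rowsum(rep(1, nrow(records)), key)[ord, 1])
  ntr <- nrow(tr)
  cond_idx <- match(tr$condition, conds)
  pid_idx <- match(tr$participant_id, pids)
  tt <- if (spec$timescale == "overall_1_120") tr$trial_overall
        else tr$trial_in_block

  fx <- flex_params(spec)
  nm <- c("mu_start", "mu_rate", "mu_asym", "mu_shape")
  for (p in setdiff(spec$condition_effects, NULL))
    for (cc in conds[-1]) nm <- c(nm, sprintf("d_%s[%s]", p, cc))
  for (p in spec$random_effects) nm <- c(nm, sprintf("log_sd_%s", p))
  for (p in spec$random_effects)
    for (id in pids) nm <- c(nm, sprintf("b_%s[%s]", p, id))
  if (length(fx)) {
    for (p in fx) for (cc in conds) nm <- c(nm, sprintf("delta_%s[%s]", p, cc))
    for (cc in conds) nm <- c(nm, sprintf("w2_raw[%s]", cc),
                              sprintf("w3_raw[%s]", cc))
  }
  np <- length(nm)
  zero <- np + 1L  # index of an appended structural zero
  pos <- function(x) { i <- match(x, nm); i[is.na(i)] <- zero; i }

  ix <- list()
  for (p in c("start", "rate", "asym", "shape")) {
    mu <- pos(paste0("mu_", p))
    d <- if (p %in% spec$condition_effects)
      pos(sprintf("d_%s[%s]", p, tr$condition)) else rep(zero, ntr)
    d[tr$condition == conds[1]] <- zero
    b <- if (p %in% spec$random_effects)
      pos(sprintf("b_%s[%s]", p, tr$participant_id)) else rep(zero, ntr)
    dl <- if (p %in% fx) pos(sprintf("delta_%s[%s]", p, tr$condition))
          else rep(zero, ntr)
    ix[[p]] <- list(mu = mu, d = d, b = b, delta = dl)
  }
  w_pos <- if (length(fx))
    list(a = pos(sprintf("w2_raw[%s]", conds)),
         b = pos(sprintf("w3_raw[%s]", conds)))
  else NULL

  # precomputed scatter-add plans (sorted-group cumsum) for the gradient
  acc_plan <- function(idx) {
    ord <- order(idx); s <- idx[ord]
    ends <- which(c(s[-1] != s[-length(s)], TRUE))
    list(ord = ord, ends = ends, pos = s[ends])
  }
  plans <- list()
  for (p in c("start", "rate", "asym", "shape")) {
    plans[[p]] <- list(
      mu = acc_plan(rep.int(ix[[p]]$mu, ntr)),
      d = acc_plan(ix[[p]]$d), b = acc_plan(ix[[p]]$b),
      delta = if (p %in% fx) acc_plan(ix[[p]]$delta) else NULL)
  }
  cb_plan <- if (length(fx))  # column-major (condition, block) cell index
    acc_plan((tr$block - 1L) * length(conds) + cond_idx) else NULL

  # prior bookkeeping: positions of each prior family
  pr <- list(
    mu_i = match(names(.prior_spec), nm),
    mu_mean = vapply(.prior_spec, `[`, 0, 1),
    mu_sd = vapply(.prior_spec, `[`, 0, 2),
    d_i = grep("^(d|delta)_", nm),
    w_i = grep("^w[23]_raw", nm),
    re = lapply(spec$random_effects, function(p)
      list(sd_i = match(paste0("log_sd_", p), nm),
           b_i = grep(sprintf("^b_%s\\[", p), nm))),
    re_sd_i = vapply(c("start", "rate", "asym", "shape"), function(p)
      match(paste0("log_sd_", p), nm), 0L))
  keep <- !is.na(pr$mu_i)
  pr$mu_i <- pr$mu_i[keep]; pr$mu_mean <- pr$mu_mean[keep]
  pr$mu_sd <- pr$mu_sd[keep]

  structure(list(
    spec = spec, par_names = nm, n_par = np, zero = zero,
    conds = conds, pids = pids, flex = fx,
    trials = tr, cond_idx = cond_idx, pid_idx = pid_idx,
    block = tr$block, t = tt, s = tr$set_size, k = tr$k, n = tr$n,
    ix = ix, w_pos = w_pos, plans = plans, cb_plan = cb_plan, prior = pr,
    fingerprint = data_fingerprint(records)),
    class = "model_ctx")
}

# per-trial linear predictors; returns list of ls, lr, la, lb and intermediates
.resolve_linpred <- function(ctx, theta) {
  tv <- c(theta, 0)
  wt <- NULL; w2 <- NULL; w3 <- NULL
  if (length(ctx$flex)) {
    w2 <- stats::plogis(tv[ctx$w_pos$a])
    w3 <- w2 * stats::plogis(tv[ctx$w_pos$b])
    W <- cbind(1, w2, w3, 0)
    wt <- W[cbind(ctx$cond_idx, ctx$block)]
  }
  re_sd <- vapply(ctx$prior$re_sd_i, function(i)
    if (is.na(i)) 0 else exp(theta[i]), 0)
  lin <- function(p) {
    v <- tv[ctx$ix[[p]]$mu] + tv[ctx$ix[[p]]$d] +
      re_sd[[p]] * tv[ctx$ix[[p]]$b]
    if (length(ctx$flex) && p %in% ctx$flex)
      v <- v + tv[ctx$ix[[p]]$delta] * wt
    v
  }
  list(ls = lin("start"), lr = lin("rate"), la = lin("asym"),
       lb = tv[ctx$ix$shape$mu] + tv[ctx$ix$shape$d],
       wt = wt, w2 = w2, w3 = w3, re_sd = re_sd)
}

# per-trial likelihood pieces shared by value and gradient
.lik_pieces <- function(ctx, lp) {
  S <- exp(lp$ls); A <- exp(lp$la); h <- exp(lp$lr); beta <- exp(lp$lb)
  r <- 2^(-(ctx$t - 1) / h)
  theta <- A + (S - A) * r
  u <- (ctx$s / theta)^beta
  q <- .WEIBULL_BASE^u
  p <- GUESS_RATE + (1 - GUESS_RATE) * q
  pc <- clamp_prob(p)
  list(S = S, A = A, h = h, beta = beta, r = r, theta = theta,
       u = u, q = q, p = p, pc = pc)
}

#' Log-posterior of the hierarchical model (and its pieces)
#'
#' @param ctx A [build_model_context()] result.
#' @param theta Unconstrained parameter vector in `ctx$par_names` order.
#' @param components If `TRUE`, return `list(loglik, logprior)` instead of
#'   their sum, so the data term can be checked against [span_loglik()].
#' @return Scalar log-posterior, or the two components.
#' @export
log_posterior <- function(ctx, theta, components = FALSE) {
  lp <- .resolve_linpred(ctx, theta)
  pcs <- .lik_pieces(ctx, lp)
  ll <- sum(ctx$k * log(pcs$pc) + (ctx$n - ctx$k) * log1p(-pcs$pc))
  pr <- .log_prior(ctx, theta)
  if (components) list(loglik = ll, logprior = pr) else ll + pr
}

.prior_spec <- list(mu_start = c(log(3), 1), mu_rate = c(log(10), 1),
                    mu_asym = c(log(3), 1), mu_shape = c(log(3), 0.5))
.SD_PRIOR_SCALE <- 0.5

.log_prior <- function(ctx, theta) {
  pr <- ctx$prior
  lp <- sum(stats::dnorm(theta[pr$mu_i], pr$mu_mean, pr$mu_sd, log = TRUE))
  if (length(pr$d_i))
    lp <- lp + sum(stats::dnorm(theta[pr$d_i], 0, 1, log = TRUE))
  for (re in pr$re) {
    lsd <- theta[re$sd_i]
    sd <- exp(lsd)
    z <- theta[re$b_i]  # non-centered: standardized effects ~ N(0, 1)
    lp <- lp + stats::dnorm(sd, 0, .SD_PRIOR_SCALE, log = TRUE) + log(2) +
      lsd +  # Jacobian of sd = exp(lsd)
      sum(stats::dnorm(z, log = TRUE))
  }
  if (length(pr$w_i))
    lp <- lp + sum(stats::dlogis(theta[pr$w_i], log = TRUE))
  lp
}

#' Gradient of the log-posterior
#'
#' Analytic chain-rule gradient matching [log_posterior()] exactly (verified
#' against central finite differences in the test suite).
#' @inheritParams log_posterior
#' @return Numeric vector `length(theta)`.
#' @export
log_posterior_grad <- function(ctx, theta) {
  lp <- .resolve_linpred(ctx, theta)
  z <- .lik_pieces(ctx, lp)
  # d loglik / d p, zero where the clamp binds
  dldp <- ctx$k / z$pc - (ctx$n - ctx$k) / (1 - z$pc)
  dldp[z$p <= .P_CLAMP | z$p >= 1 - .P_CLAMP] <- 0
  dldu <- dldp * (1 - GUESS_RATE) * z$q * .LN04
  dldtheta <- dldu * (-z$beta * z$u / z$theta)
  gtr <- list(
    start = dldtheta * z$S * z$r,
    rate = dldtheta * (z$S - z$A) * z$r * .LN2 * (ctx$t - 1) / z$h,
    asym = dldtheta * z$A * (1 - z$r),
    shape = dldu * z$u * log(ctx$s / z$theta) * z$beta)

  g <- numeric(ctx$n_par + 1L)  # final slot absorbs the structural zero
  acc <- function(plan, val) {
    cs <- cumsum(val[plan$ord])[plan$ends]
    g[plan$pos] <<- g[plan$pos] + cs - c(0, cs[-length(cs)])
  }
  tvz <- c(theta, 0)
  for (p in c("start", "rate", "asym", "shape")) {
    pl <- ctx$plans[[p]]
    acc(pl$mu, gtr[[p]]); acc(pl$d, gtr[[p]])
    sd_i <- ctx$prior$re_sd_i[[p]]
    if (!is.na(sd_i)) {
      sd <- exp(theta[sd_i])
      acc(pl$b, gtr[[p]] * sd)  # d/dz through b = sd * z
      g[sd_i] <- g[sd_i] + sd * sum(gtr[[p]] * tvz[ctx$ix[[p]]$b])
    }
  }
  if (length(ctx$flex)) {
    # delta gradients carry the block weight; weight gradients collect the
    # sum over flexible params of g * delta, per condition-block cell
    tv <- c(theta, 0)
    gw_cb <- numeric(length(ctx$conds) * 4L)
    for (p in ctx$flex) {
      acc(ctx$plans[[p]]$delta, gtr[[p]] * lp$wt)
      gd <- gtr[[p]] * tv[ctx$ix[[p]]$delta]
      pl <- ctx$cb_plan
      cs <- cumsum(gd[pl$ord])[pl$ends]
      gw_cb[pl$pos] <- gw_cb[pl$pos] + cs - c(0, cs[-length(cs)])
    }
    dim(gw_cb) <- c(length(ctx$conds), 4L)
    sa <- stats::plogis(tv[ctx$w_pos$a]); sb <- stats::plogis(tv[ctx$w_pos$b])
    # w2 = sa, w3 = sa*sb; blocks 2 and 3 carry w2 and w3 respectively
    g[ctx$w_pos$a] <- g[ctx$w_pos$a] +
      gw_cb[, 2] * sa * (1 - sa) + gw_cb[, 3] * sb * sa * (1 - sa)
    g[ctx$w_pos$b] <- g[ctx$w_pos$b] + gw_cb[, 3] * sa * sb * (1 - sb)
  }
  g <- g[seq_len(ctx$n_par)]

  # prior gradients
  pr <- ctx$prior
  g[pr$mu_i] <- g[pr$mu_i] - (theta[pr$mu_i] - pr$mu_mean) / pr$mu_sd^2
  if (length(pr$d_i)) g[pr$d_i] <- g[pr$d_i] - theta[pr$d_i]
  for (re in pr$re) {
    sd <- exp(theta[re$sd_i])
    g[re$b_i] <- g[re$b_i] - theta[re$b_i]       # z ~ N(0, 1)
    g[re$sd_i] <- g[re$sd_i] - sd^2 / .SD_PRIOR_SCALE^2 + 1
  }
  if (length(pr$w_i))
    g[pr$w_i] <- g[pr$w_i] + 1 - 2 * stats::plogis(theta[pr$w_i])
  g
}

# default initial values: prior centres with optional jitter
init_theta <- function(ctx, jitter = 0) {
  nm <- ctx$par_names
  th <- numeric(ctx$n_par)
  for (m in names(.prior_spec)) {
    i <- match(m, nm); if (!is.na(i)) th[i] <- .prior_spec[[m]][1]
  }
  th[grep("^log_sd_", nm)] <- log(0.2)
  if (jitter > 0) th <- th + stats::rnorm(ctx$n_par, 0, jitter)
  th
}
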