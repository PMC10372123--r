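# Reduced-model comparison via Pareto-smoothed importance-sampling
# approximate leave-one-out cross-validation (PSIS-LOO). The unit of
# cross-validation is the single presented item -- the same disaggregated
# Bernoulli observation the likelihood is built on.

#' Pointwise log-likelihood matrix
#'
#' Entry (i, d) is the log Bernoulli likelihood of item i under posterior
#' draw d's parameters. Column sums equal the model log-likelihood at each
#' draw's parameters.
#'
#' @param fit A converged `posterior_draws` object.
#' @param records The trial records the model was fitted to (checked against
#'   the fit's data fingerprint).
#' @param max_draws Thin to at most this many draws (evenly across the
#'   flattened chains) to bound memory; `Inf` keeps all.
#' @param force Use a non-converged fit anyway.
#' @return Items x draws numeric matrix, finite everywhere.
#' @export
pointwise_loglik <- function(fit, records, max_draws = 1000L, force = FALSE) {
  .check_usable(fit, force)
  if (!identical(data_fingerprint(records), fit$data_fingerprint))
    stop("records do not match the data this model was fitted to ",
         "(fingerprint mismatch)")
  ctx <- fit$ctx
  m <- draw_matrix(fit)
  if (nrow(m) > max_draws)
    m <- m[round(seq(1, nrow(m), length.out = max_draws)), , drop = FALSE]
  # map each item row to its trial row in the context
  tkey <- paste(ctx$trials$participant_id, ctx$trials$trial_overall)
  item_tr <- match(paste(records$participant_id, records$trial_overall), tkey)
  corr <- records$correct == 1L
  out <- matrix(NA_real_, nrow(records), nrow(m))
  for (d in seq_len(nrow(m))) {
    lp <- .resolve_linpred(ctx, m[d, ])
    pc <- .lik_pieces(ctx, lp)$pc[item_tr]
    out[, d] <- ifelse(corr, log(pc), log1p(-pc))
  }
  out
}

# Generalized Pareto fit to tail exceedances (profile-likelihood method with
# the standard weakly-informative shape regularization).
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30 + floor(sqrt(n))
  prior_scale <- x[max(1, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (3 * prior_scale)
  k_of_b <- vapply(b, function(bj) mean(log1p(-bj * x)), 0)
  l <- n * (log(-b / k_of_b) - k_of_b - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(l - l[j])), 0)
  b_hat <- sum(b * w)
  k_hat <- mean(log1p(-b_hat * x))
  sigma <- -k_hat / b_hat
  # regularize k toward 0.5 as in the published implementation
  k_hat <- (n * k_hat + 10 * 0.5) / (n + 10)
  list(k = k_hat, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p)
  else sigma * expm1(-k * log1p(-p)) / k
}

#' Pareto-smoothed importance-sampling weights
#'
#' Smooths the largest importance ratios by replacing them with expected
#' order statistics of a generalized Pareto distribution fitted to the tail,
#' then truncates at the raw maximum.
#'
#' @param lw Vector of log importance ratios (one per draw).
#' @return List: `log_weights` (normalized to `logsumexp = 0`) and `k` (the
#'   Pareto shape diagnostic; values above 0.7 indicate unreliability).
#' @export
psis_weights <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exc <- exp(lw[tail_ids]) - exp(cutoff)
  k <- Inf
  if (length(unique(exc)) >= 5 && max(exc) > 0) {
    gf <- gpd_fit(exc[exc > 0])
    k <- gf$k
    if (is.finite(k)) {
      pr <- (seq_len(M) - 0.5) / M
      sm <- log(exp(cutoff) +
                  vapply(pr, gpd_quantile, 0, k = gf$k, sigma = gf$sigma))
      lw[tail_ids[order(lw[tail_ids])]] <- pmin(sm, 0)
    }
  }
  lw <- lw - logsumexp(lw)
  list(log_weights = lw, k = k)
}

#' Approximate leave-one-out cross-validation (PSIS-LOO)
#'
#' @param ll Items x draws pointwise log-likelihood matrix from
#'   [pointwise_loglik()].
#' @param model_id Label for comparison tables.
#' @return A `loo_result`: `elpd` and its SE, `looic = -2 * elpd`, `p_loo`,
#'   `pointwise` contributions, per-item Pareto `k`, and `bad_k_share` (the
#'   share of items with k > 0.7).
#' @export
loo_psis <- function(ll, model_id = "model") {
  n <- nrow(ll)
  pw <- numeric(n); ks <- numeric(n)
  lpd <- numeric(n)
  for (i in seq_len(n)) {
    w <- psis_weights(-ll[i, ])
    pw[i] <- logsumexp(w$log_weights + ll[i, ])
    ks[i] <- w$k
    lpd[i] <- logsumexp(ll[i, ]) - log(ncol(ll))
  }
  elpd <- sum(pw)
  structure(list(model_id = model_id, elpd = elpd,
                 se = sqrt(n * stats::var(pw)),
                 looic = -2 * elpd, p_loo = sum(lpd - pw),
                 pointwise = pw, pareto_k = ks,
                 bad_k_share = mean(ks > 0.7), n_items = n),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("loo_result [%s]: elpd %.1f (SE %.1f), LOOIC %.1f, p_loo %.1f",
              x$model_id, x$elpd, x$se, x$looic, x$p_loo),
      sprintf("| %.1f%% of Pareto k > 0.7\n", 100 * x$bad_k_share))
  invisible(x)
}

#' Compare models by approximate leave-one-out cross-validation
#'
#' Ranks models by expected log predictive density and reports each model's
#' LOOIC difference from the best model with the paired pointwise SE of that
#' difference.
#'
#' @param results Named list of `loo_result` objects on identical data.
#' @return Data frame ranked by elpd: `model_id`, `elpd`, `se`, `looic`,
#'   `delta_looic`, `se_delta`, `bad_k_share`.
#' @export
loo_compare <- function(results) {
  stopifnot(length(results) >= 2,
            all(vapply(results, inherits, TRUE, "loo_result")))
  n <- vapply(results, `[[`, 0, "n_items")
  if (length(unique(n)) != 1)
    stop("models were evaluated on different item counts; not comparable")
  elpd <- vapply(results, `[[`, 0, "elpd")
  ord <- order(elpd, decreasing = TRUE)
  best <- results[[ord[1]]]
  rows <- lapply(results[ord], function(r) {
    dpw <- best$pointwise - r$pointwise
    data.frame(model_id = r$model_id, elpd = r$elpd, se = r$se,
               looic = r$looic,
               delta_looic = r$looic - best$looic,
               se_delta = 2 * sqrt(r$n_items * stats::var(dpw)),
               bad_k_share = r$bad_k_share, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out
}
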