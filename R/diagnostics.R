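# Convergence diagnostics: rank-normalized split R-hat and tail effective
# sample size, computed per parameter across chains. Implemented from the
# published formulas (split chains, rank-normalization via the inverse normal
# CDF of fractional ranks, Geyer initial-monotone-sequence autocorrelation
# truncation with FFT autocovariances).

# split an iterations x chains matrix into 2*chains half-chains
.split_chains <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

# classic (potential scale reduction) R-hat on an iters x chains matrix
.rhat_basic <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(mu)
  if (W <= 0 || !is.finite(W)) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  array(z, dim = dim(x))
}

#' Rank-normalized split R-hat for one parameter
#' @param x Iterations x chains matrix of draws.
#' @return Scalar R-hat (max of the bulk and folded versions).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("R-hat requires at least 2 chains")
  xs <- .split_chains(x)
  if (all(abs(xs - xs[1]) < 1e-12)) return(1)  # constant draws
  bulk <- .rhat_basic(.rank_normalize(xs))
  folded <- .rhat_basic(.rank_normalize(abs(xs - stats::median(xs))))
  max(bulk, folded, na.rm = TRUE)
}

# FFT autocovariance of a single chain (biased, as the ESS formula expects)
.autocov <- function(y) {
  n <- length(y)
  y <- y - mean(y)
  m <- stats::nextn(2 * n)
  f <- stats::fft(c(y, numeric(m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (m * n)
  ac * n / (n - 1)
}

# effective sample size of the mean of an iters x chains matrix
.ess_mean <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  if (all(abs(x - x[1]) < 1e-12)) return(NA_real_)
  ac <- apply(x, 2, .autocov)
  mean_var <- mean(ac[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1) var_plus <- var_plus + stats::var(colMeans(x))
  rho <- 1 - (mean_var - rowMeans(ac)) / var_plus
  # Geyer: sum consecutive pairs, truncate at first negative pair, enforce
  # monotone non-increasing
  maxpair <- floor((n - 1) / 2)
  tau <- 0; prev <- Inf
  for (kk in seq_len(maxpair)) {
    pr <- rho[2 * kk - 1] + rho[2 * kk]
    if (!is.finite(pr) || pr < 0) break
    pr <- min(pr, prev)
    tau <- tau + pr
    prev <- pr
  }
  tau <- -1 + 2 * tau
  ess <- n * m / max(tau, 1 / (n * m))
  min(ess, n * m * log10(n * m))  # cap per the published recommendation
}

#' Tail effective sample size for one parameter
#'
#' Minimum of the effective sample sizes of the 5% and 95% quantile
#' indicator functions, computed on split chains.
#' @param x Iterations x chains matrix of draws.
#' @export
ess_tail <- function(x) {
  x <- as.matrix(x)
  xs <- .split_chains(x)
  q <- stats::quantile(xs, c(0.05, 0.95), names = FALSE)
  e <- vapply(q, function(qq) .ess_mean((xs <= qq) * 1), 0)
  min(e)
}

#' Convergence summary of a fitted model
#'
#' Per-parameter rank-normalized split R-hat and tail ESS, plus the overall
#' convergence flag used throughout: `max R-hat < 1.02` and
#' `min tail ESS > 500`.
#'
#' @param fit A `posterior_draws` object (or iterations x chains x parameters
#'   array).
#' @return List: `rhat` and `ess_tail` (named per parameter), `max_rhat`,
#'   `min_ess_tail`, `converged`, `accept_rate`, `divergences`.
#' @export
diagnostics <- function(fit) {
  dr <- if (inherits(fit, "posterior_draws")) fit$draws else fit
  stopifnot(length(dim(dr)) == 3)
  if (dim(dr)[2] < 2) stop("diagnostics require at least 2 chains")
  pn <- dimnames(dr)[[3]] %||% paste0("par", seq_len(dim(dr)[3]))
  rhat <- vapply(seq_len(dim(dr)[3]), function(j) split_rhat(dr[, , j]), 0)
  esst <- vapply(seq_len(dim(dr)[3]), function(j) ess_tail(dr[, , j]), 0)
  names(rhat) <- names(esst) <- pn
  max_rhat <- suppressWarnings(max(rhat, na.rm = TRUE))
  min_ess <- suppressWarnings(min(esst, na.rm = TRUE))
  list(rhat = rhat, ess_tail = esst,
       max_rhat = max_rhat,
       min_ess_tail = min_ess,
       converged = isTRUE(is.finite(max_rhat) && is.finite(min_ess) &&
                            max_rhat < 1.02 && min_ess > 500),
       accept_rate = if (inherits(fit, "posterior_draws"))
         fit$accept_rate else NA_real_,
       divergences = if (inherits(fit, "posterior_draws"))
         fit$divergences else NA_integer_)
}
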