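# Posterior contrasts with the 95%-credible-interval reliability rule.

.check_usable <- function(fit, force) {
  stopifnot(inherits(fit, "posterior_draws"))
  if (!fit$diagnostics$converged && !force)
    stop("fit is flagged non-converged (max R-hat ",
         round(fit$diagnostics$max_rhat, 3), ", min tail ESS ",
         round(fit$diagnostics$min_ess_tail), "); pass force = TRUE to use it")
}

#' Posterior contrast of a parameter expression
#'
#' Evaluates an R expression over parameter names draw-wise and summarizes it
#' with the posterior median `b`, the equal-tailed 95% credible interval, and
#' the reliability rule: a contrast is *reliable* when its 95% CI falls
#' entirely above or below zero. Parameter names containing brackets must be
#' backquoted in the expression, e.g. `` contrast(fit, "`d_asym[random]`") ``.
#'
#' @param fit A converged `posterior_draws` object (or `force = TRUE`).
#' @param expr Character scalar: expression over parameter names.
#' @param name Label for the contrast (defaults to the expression).
#' @param point `"median"` (default) or `"mean"` for the point estimate `b`.
#' @param force Use a non-converged fit anyway.
#' @return A one-row `contrast` data frame: `name`, `b`, `mean`, `ci_lower`,
#'   `ci_upper`, `reliable`, `n_draws`.
#' @export
contrast <- function(fit, expr, name = expr, point = c("median", "mean"),
                     force = FALSE) {
  point <- match.arg(point)
  .check_usable(fit, force)
  m <- draw_matrix(fit)
  parsed <- parse(text = expr)
  unknown <- setdiff(all.vars(parsed), colnames(m))
  if (length(unknown))
    stop("unknown parameter(s) in contrast '", expr, "': ",
         paste(unknown, collapse = ", "),
         "\navailable parameters: ",
         paste(utils::head(colnames(m), 30), collapse = ", "),
         if (ncol(m) > 30) " ...")
  env <- list2env(stats::setNames(lapply(seq_len(ncol(m)), function(j) m[, j]),
                                  colnames(m)), parent = baseenv())
  val <- eval(parsed, env)
  if (length(val) == 1L) val <- rep(val, nrow(m))
  stopifnot(is.numeric(val), length(val) == nrow(m))
  ci <- unname(stats::quantile(val, c(0.025, 0.975)))
  out <- data.frame(name = name,
                    b = if (point == "median") stats::median(val)
                        else mean(val),
                    mean = mean(val),
                    ci_lower = ci[1], ci_upper = ci[2],
                    reliable = ci[1] > 0 || ci[2] < 0,
                    n_draws = length(val), stringsAsFactors = FALSE)
  class(out) <- c("contrast", "data.frame")
  out
}

.q <- function(x) paste0("`", x, "`")

#' The standard contrast battery
#'
#' Emits, as applicable to the fitted specification:
#' per-condition learning magnitude (log asymptote minus log start);
#' between-condition offsets at start, asymptote and rate; and, for
#' cross-block models, the block-1-minus-block-4 contrast per flexible
#' parameter and condition (block 4 is the reference, so that contrast is the
#' total delta itself).
#'
#' @inheritParams contrast
#' @return A `contrast` data frame, one row per contrast.
#' @export
standard_battery <- function(fit, point = "median", force = FALSE) {
  .check_usable(fit, force)
  ctx <- fit$ctx
  spec <- fit$spec
  rows <- list()
  for (cc in ctx$conds) {
    off <- function(p) if (cc == ctx$conds[1] ||
                           !p %in% spec$condition_effects) ""
                       else paste0(" + ", .q(sprintf("d_%s[%s]", p, cc)))
    rows[[length(rows) + 1]] <- contrast(
      fit, sprintf("(mu_asym%s) - (mu_start%s)", off("asym"), off("start")),
      name = sprintf("learning[%s]", cc), point = point, force = force)
  }
  for (cc in ctx$conds[-1]) {
    for (p in intersect(c("start", "asym", "rate"), spec$condition_effects)) {
      rows[[length(rows) + 1]] <- contrast(
        fit, .q(sprintf("d_%s[%s]", p, cc)),
        name = sprintf("cond_%s[%s - %s]", p, cc, ctx$conds[1]),
        point = point, force = force)
    }
  }
  if (spec$cross_block != "none")
    rows <- c(rows, list(block_contrasts(fit, point = point, force = force)))
  out <- do.call(rbind, rows)
  class(out) <- c("contrast", "data.frame")
  out
}

#' Block-1-versus-block-4 contrasts of a cross-block fit
#'
#' @inheritParams contrast
#' @export
block_contrasts <- function(fit, point = "median", force = FALSE) {
  if (fit$spec$cross_block == "none")
    stop("block contrasts require a cross-block (within-block timescale) fit")
  .check_usable(fit, force)
  ctx <- fit$ctx
  rows <- list()
  for (p in ctx$flex) for (cc in ctx$conds) {
    rows[[length(rows) + 1]] <- contrast(
      fit, .q(sprintf("delta_%s[%s]", p, cc)),
      name = sprintf("block1_minus_block4_%s[%s]", p, cc),
      point = point, force = force)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("contrast", "data.frame")
  out
}

#' Render a contrast table as a Markdown report
#' @param contrasts A `contrast` data frame.
#' @return Character vector of Markdown lines.
#' @export
contrast_report <- function(contrasts) {
  c("| contrast | b | 95% CI | reliable |",
    "|---|---|---|---|",
    sprintf("| %s | %.3f | [%.3f, %.3f] | %s |",
            contrasts$name, contrasts$b, contrasts$ci_lower,
            contrasts$ci_upper, ifelse(contrasts$reliable, "yes", "no")))
}
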