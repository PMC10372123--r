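# Specification of the hierarchical time-evolving model.

#' Specify a hierarchical learning model
#'
#' The two published parameterizations are `model_spec("overall_1_120")`
#' (threshold an exponential function of overall trial 1-120; no cross-block
#' structure) and `model_spec("within_block_1_30", cross_block = "full")`
#' (within-block trial 1-30 with all three trajectory parameters changing
#' monotonically across blocks). Reduced models let exactly one parameter
#' change across blocks (`"start_only"`, `"rate_only"`, `"asym_only"`).
#'
#' @param timescale `"overall_1_120"` or `"within_block_1_30"`.
#' @param cross_block `"none"`, `"full"`, `"start_only"`, `"rate_only"` or
#'   `"asym_only"`. Non-`none` requires the within-block timescale.
#' @param reference_condition Condition whose fixed effects anchor the model;
#'   other conditions are parameterized as zero-centered offsets from it.
#' @param condition_effects Which parameters get per-condition fixed effects.
#' @param random_effects Which trajectory parameters get by-participant
#'   random intercepts (shape never does in the learning model).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(timescale = c("overall_1_120", "within_block_1_30"),
                       cross_block = c("none", "full", "start_only",
                                       "rate_only", "asym_only"),
                       reference_condition = "constant",
                       condition_effects = c("start", "rate", "asym", "shape"),
                       random_effects = c("start", "rate", "asym")) {
  timescale <- match.arg(timescale)
  cross_block <- match.arg(cross_block)
  condition_effects <- if (length(condition_effects))
    match.arg(condition_effects, c("start", "rate", "asym", "shape"),
              several.ok = TRUE) else character(0)
  random_effects <- if (length(random_effects))
    match.arg(random_effects, c("start", "rate", "asym"),
              several.ok = TRUE) else character(0)
  if (cross_block != "none" && timescale != "within_block_1_30")
    stop("cross_block structure requires the within_block_1_30 timescale")
  structure(list(timescale = timescale, cross_block = cross_block,
                 reference_condition = reference_condition,
                 condition_effects = condition_effects,
                 random_effects = random_effects),
            class = "model_spec")
}

# which trajectory parameters are block-flexible under a spec
flex_params <- function(spec) {
  switch(spec$cross_block,
         none = character(0),
         full = c("start", "rate", "asym"),
         start_only = "start", rate_only = "rate", asym_only = "asym")
}
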