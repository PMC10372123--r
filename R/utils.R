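# small shared helpers

# FNV-1a 32-bit hash of a string (multiplication done in 16-bit halves so
# all intermediates stay exactly representable as doubles)
fnv32 <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(as.character(s))) {
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- bitwXor(as.integer(lo), b) + hi * 65536
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  h
}

# stable hash of a key folded with a master seed into a strictly positive
# seed below 2^31; gives every participant (or other keyed unit) an RNG
# substream independent of generation order
stable_seed <- function(master_seed, key) {
  stopifnot(length(key) == 1L)
  h <- fnv32(paste0(key, ":", format(master_seed %% 2147483647,
                                     scientific = FALSE)))
  as.integer(h %% 2147483629) + 1L
}

# run expr under a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
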