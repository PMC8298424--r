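# Shared internal helpers: seed stream derivation and guarded RNG scope.

# Deterministically derive a substream seed (< 2^31) from a master seed and
# a stage key, so replicates/conditions get independent but reproducible noise.
deriveSeed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, character(1))),
               collapse = "/")
  h <- 17
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate expr under set.seed(seed), restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  expr
}

# midpoint of ranges (1-based bp)
rangeMid <- function(gr) {
  floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
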