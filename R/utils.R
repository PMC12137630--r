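# Internal helpers shared across modules.

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All package randomness flows through this.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

# Derive a substream seed from a master seed and a stream label, so that
# e.g. adding cells (placement stream) cannot perturb event timing (events
# stream). Kept below 2^31 - 1.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 104729L)
}

# Half-open frame window [start, end) as 1-based R column indices.
frames_in <- function(start_frame, end_frame) {
  if (end_frame <= start_frame)
    stop("empty frame window [", start_frame, ", ", end_frame, ")")
  seq.int(start_frame + 1L, end_frame)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
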