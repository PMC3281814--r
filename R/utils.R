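# Seed scoping: analyses that consume randomness set their own stream from
# an integer seed and restore the caller's RNG state afterwards, so a
# pipeline stage cannot shift another stage's stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}

# Counter-based per-stage seed derivation from one global seed.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, seqio = 211L, diversity = 307L,
               structure = 401L, network = 503L, spatial = 601L,
               mismatch = 701L, im = 809L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1000 + off) %% 2147483647)
}
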