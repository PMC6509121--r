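# Seed the RNG locally, preserving the caller's RNG state. Returns a handle
# whose $restore() puts the previous state back.
.seeded_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  })
}
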