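# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library code never perturbs the user's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a distinct child seed from a base seed and a stream index, staying
# within the 32-bit integer range R requires.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(stream)) %% 2147483647)
}

# Stage logger: timestamped record to stderr, and appended to a collector
# environment when one is supplied. Results never interleave with logs.
log_stage <- function(stage, ..., collector = NULL, verbose = TRUE) {
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  if (verbose) message(msg)
  if (!is.null(collector))
    collector$records <- c(collector$records,
                           list(list(stage = stage, message = paste0(...),
                                     time = Sys.time())))
  invisible(msg)
}
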