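# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic uniform deviates in [0, 1) that do not touch R's RNG stream.
# Small multiplier LCG mod 2^32 (exact in doubles), iterated a few times.
det_uniform <- function(n, stream = 1L) {
  s <- (seq_len(n) + 2654435.0 * as.double(stream)) %% 4294967296
  for (k in 1:4) s <- (s * 69069 + 1) %% 4294967296
  s / 4294967296
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sp_log <- function(..., verbose = getOption("surfpatch.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[surfpatch] ", ...)
  invisible(NULL)
}

stop2 <- function(..., class) {
  stop(structure(class = c(class, "surfpatch_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
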