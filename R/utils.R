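# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream; a NULL/NA seed leaves the stream untouched.
.withSeed <- function(seed, code) {
  if (!is.null(seed) && !is.na(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

.assertScalarPositive <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

.assertPositive <- function(x, name) {
  if (!length(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be positive and finite", name), call. = FALSE)
  invisible(x)
}

# Deterministic per-stage seed fanout from a single run seed: the stage name
# is folded into a 31-bit integer so stages draw from unrelated substreams.
.stageSeed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- as.double(seed)
  for (i in seq_along(codes))
    h <- (h * 31 + codes[i]) %% 2147483647
  as.integer(h)
}
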