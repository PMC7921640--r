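# Internal helpers: seeding, rounding, validation.

#' Derive a child seed from a master seed
#'
#' Expands one master seed into reproducible per-purpose seeds (splitting,
#' subsampling, augmentation, weight initialisation, ...) via a fixed
#' counter scheme, so that independent stages of a pipeline draw from
#' independent, documented streams.
#'
#' @param master integer master seed.
#' @param purpose character tag naming the consumer (e.g. `"split"`).
#' @param index non-negative integer counter (e.g. replicate number).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' child_seed(1, "split", 1)
#' @export
child_seed <- function(master, purpose, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- sum(utf8ToInt(as.character(purpose)) * seq_along(utf8ToInt(as.character(purpose))))
  m <- 2147483647  # 2^31 - 1, keeps results in integer range
  s <- (abs(master) %% m)
  s <- (s * 69621 + h * 1013 + index * 7919 + 12345) %% m
  as.integer(s)
}

# Round half away from zero (R's round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

# Evaluate expr with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# stop() with a consistent error class so callers/tests can match on it.
hs_stop <- function(msg, class) {
  stop(structure(class = c(class, "hs_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
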