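# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards so seeded components never disturb user simulations.
#' A `NULL` seed evaluates `code` against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Derive a named substream seed from a root seed
#'
#' Mixes a root seed with arbitrary labels (session indices, participant ids,
#' component names) into a new 31-bit seed. Deterministic, so every component
#' of a run is reproducible from the single root seed.
#'
#' @param seed integer root seed.
#' @param ... labels (numbers or strings) identifying the substream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "session", 13)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  parts <- vapply(list(...), function(x) {
    if (is.numeric(x)) sum(as.numeric(x)) else
      sum(utf8ToInt(paste(as.character(x), collapse = "")))
  }, numeric(1))
  h <- abs(as.numeric(seed)) %% 2147483647
  for (p in parts) h <- (h * 48271 + abs(p) + 1) %% 2147483647
  as.integer(h)
}

# difftime in hours regardless of the inputs' native units
hours_between <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "hours"))
}

# minutes, same contract
minutes_between <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "mins"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
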