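#' Derive a reproducible child seed from a root seed and a stream label
#'
#' Every stochastic stage of the package draws from its own named stream so
#' that adding draws to one stage never perturbs another. The child seed is a
#' deterministic hash of the root seed and the label, kept strictly below
#' 2^31 so it is always a valid R integer seed.
#'
#' @param root_seed Integer root seed.
#' @param stream Character label of the consuming stage (e.g. "positions").
#' @return A single integer seed.
#' @export
derive_seed <- function(root_seed, stream) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L,
            is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream))) %% 104729
  as.integer((abs(as.numeric(root_seed)) * 48271 + h * 16807 + 12345) %%
               2147483647)
}

#' Evaluate an expression under a local RNG stream
#'
#' Saves and restores the global RNG state so simulation internals do not
#' disturb the caller's random sequence.
#'
#' @param seed Integer seed for the stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
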