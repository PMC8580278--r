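#' @keywords internal
#' @import stats
#' @importFrom utils write.csv read.csv write.table read.delim
"_PACKAGE"

# Derive a stage-specific sub-seed from a global seed so pipeline stages can
# be rerun in isolation reproducibly.  The multiplicative mixing keeps
# nested derivations (sub_seed of a sub_seed) from colliding with sibling
# streams, which a plain additive offset would not.  Kept below 2^31 - 1.
sub_seed <- function(seed, k) {
  x <- (as.numeric(seed) * 48271 + as.numeric(k) * 69621 + 1013904223) %%
    2147483647
  as.integer(x)
}

# Run an expression under a local RNG state; the caller's state is restored.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    stop(sprintf("`%s` must lie strictly in (0, 1)", name), call. = FALSE)
  }
  invisible(x)
}
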