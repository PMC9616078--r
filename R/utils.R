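# Internal helpers shared across modules.

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed, kept inside 32-bit integer range.
child_seed <- function(seed, index, salt = 0L) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729 +
                as.numeric(salt) * 131071) %% 2147483629)
}

stopifnot_prob <- function(x, name = deparse(substitute(x))) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must contain probabilities in [0, 1]", name))
  invisible(x)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 0 && x == floor(x)
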