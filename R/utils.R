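#' Derive a child seed from a master seed
#'
#' Each simulator draws from its own RNG stream so that adding or removing a
#' generator never perturbs the others. Streams are indexed by a small
#' counter; the child seed is a deterministic 31-bit hash of (seed, index).
#'
#' @param seed Integer master seed.
#' @param index Nonnegative integer stream index.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index))
  # 64-bit-safe multiplicative mix kept below 2^31 (R integers are 32-bit)
  x <- (abs(seed) %% 2147483647) + 1
  for (k in seq_len(index + 1)) {
    x <- (x * 48271) %% 2147483647
  }
  as.integer(x %% 2147483646L)
}

stop_config <- function(...) {
  stop(structure(class = c("citemp_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_config(name, " must be a single value in [0, 1]")
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0)
    stop_config(name, " must be a single nonnegative value")
  invisible(x)
}

# Evaluate expr with a locally-set RNG seed, restoring the caller's RNG state.
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
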