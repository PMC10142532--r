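# Internal helpers shared across modules.

# Deterministic child seed from a parent seed and a stream index.
# Kept below 2^31 so it is always a valid R integer.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629L)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Population standard deviation (divisor n, not n - 1).
pop_sd <- function(x) {
  n <- length(x)
  if (n < 1L) return(NA_real_)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count_kind <- function(kind) kind %in% c("substructure_counts", "circular_counts")
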