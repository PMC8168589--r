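# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards. All stochastic operations in the package go through
# this so that results are a pure function of the supplied seed.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage sub-seed from a run seed by a fixed offset, kept inside
# the 32-bit integer range.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}

# z-score over the non-NA entries; a constant (sd == 0) vector maps to all
# zeros rather than 0/0.
zscore <- function(x) {
  ok <- is.finite(x)
  if (!any(ok)) return(x)
  m <- mean(x[ok])
  s <- stats::sd(x[ok])
  out <- rep(NA_real_, length(x))
  out[ok] <- if (is.na(s) || s == 0) 0 else (x[ok] - m) / s
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
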