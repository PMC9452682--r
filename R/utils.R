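# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic seed derivation; keeps results inside the 32-bit integer range
# R's RNG accepts. i/j index sub-streams (e.g. one per dose-grid cell).
derive_seed <- function(seed, i = 0L, j = 0L) {
  as.integer((as.double(seed) + 10007 * as.double(i) + 1299709 * as.double(j)) %%
               2147483647)
}

stop_schema <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("therawin_schema_error", "therawin_error")))
}

stop_twin <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "therawin_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# First dose at which a normalized curve reaches `level`, by linear
# interpolation between grid points; NA_real_ when never reached.
first_crossing <- function(doses, values, level) {
  hit <- which(values >= level)
  if (length(hit) == 0L) return(NA_real_)
  j <- hit[1L]
  if (j == 1L) return(doses[1L])
  x1 <- doses[j - 1L]; x2 <- doses[j]
  f1 <- values[j - 1L]; f2 <- values[j]
  x1 + (level - f1) / (f2 - f1) * (x2 - x1)
}

set_equal <- function(a, b) length(a) == length(b) && setequal(a, b)
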