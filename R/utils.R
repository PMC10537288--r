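# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All package randomness funnels through this so a
# single integer seed gives bit-identical results without touching global state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a distinct child seed from a parent seed; keeps within 32-bit range.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + 97L * as.integer(k) %% 2147480000L
}

icpr_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "icpr_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Half-up rounding at `digits` decimals, matching how report tables are printed
# (base round() is half-to-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Strict local maxima of a numeric vector; a plateau contributes its left-most
# sample. Endpoints never qualify.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  # carry the last nonzero slope through flat runs so plateaus are classified
  # by the slopes on either side
  idx <- which(s != 0)
  if (length(idx) == 0L) return(integer(0))
  out <- integer(0)
  prev_up_end <- NA_integer_  # index where the signal last stopped rising
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (s[i] > 0) {
      prev_up_end <- i + 1L  # position after this rise
    } else {
      # falling at i: a maximum if we were rising before (plateau start kept)
      if (!is.na(prev_up_end)) {
        out <- c(out, prev_up_end)
        prev_up_end <- NA_integer_
      }
    }
  }
  out[out > 1L & out < n]
}
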