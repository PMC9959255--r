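# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so simulators never clobber a user's random stream.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == as.integer(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

# Unordered pair indices (i < j) in row-major order: (1,2), (1,3), ...,
# (1,k), (2,3), ...  This matches lower-triangle column-major extraction.
pair_index <- function(k) {
  i <- rep.int(seq_len(k - 1L), times = (k - 1L):1L)
  j <- sequence((k - 1L):1L) + i
  cbind(i = i, j = j)
}
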