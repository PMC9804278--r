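# internal helpers shared across modules

#' Derive a deterministic sub-seed from a master seed and a label
#'
#' All stochastic operations in the package draw their seed from a single
#' master seed plus a stage label, so that a pipeline run is reproducible
#' end to end while stages remain independently re-runnable.
#'
#' @param seed master integer seed.
#' @param label character tag naming the consumer of the sub-seed.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
sub_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147480009
  as.integer((abs(as.numeric(seed)) * 69069 + h) %% 2147480009)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_fraction <- function(x, lo = 0, hi = 1, open_lo = TRUE, open_hi = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) return(FALSE)
  lo_ok <- if (open_lo) x > lo else x >= lo
  hi_ok <- if (open_hi) x < hi else x <= hi
  lo_ok && hi_ok
}

# upper-triangle (i < j) index pairs of an n x n matrix, as a two-column matrix
pair_index <- function(n) {
  if (n < 2) return(cbind(i = integer(0), j = integer(0)))
  j <- rep.int(seq_len(n), seq_len(n) - 1L)
  idx <- which(upper.tri(diag(n)))
  i <- idx - (j - 1L) * n
  cbind(i = i, j = j)
}
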