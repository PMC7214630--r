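# Internal IIR machinery shared by the batch estimator and the streaming
# closed-loop simulator. Both paths run the same direct-form-II-transposed
# recursion so that batch and per-bin filtering are bit-identical.

FS <- 2000          # sampling rate, Hz
BIN_LEN <- 120L     # samples per inter-stimulus bin (60 ms at 2 kHz)
BIN_DT <- 0.06      # bin duration, s
EMG_BAND <- c(20, 450)  # synthetic surface-EMG band, Hz

#' @noRd
design_bandpass <- function(low, high, order = 1L, fs = FS) {
  signal::butter(order, c(low, high) / (fs / 2), type = "pass")
}

# Direct-form II transposed filter with explicit state carry-over.
# b, a: coefficient vectors (a[1] == 1). state: length(a) - 1 delay registers.
#' @noRd
iir_filter <- function(b, a, x, state = NULL) {
  n <- length(a) - 1L
  if (is.null(state)) state <- numeric(n)
  stopifnot(length(b) == n + 1L, length(state) == n)
  y <- numeric(length(x))
  z <- state
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    if (n > 1L) {
      z[seq_len(n - 1L)] <- b[2L:n] * xi + z[2L:n] - a[2L:n] * yi
    }
    z[n] <- b[n + 1L] * xi - a[n + 1L] * yi
    y[i] <- yi
  }
  list(y = y, state = z)
}

# RMS gain of a filter for white-noise input, from the impulse response.
#' @noRd
impulse_rms_gain <- function(filt, n = 4096L) {
  h <- iir_filter(filt$b, filt$a, c(1, numeric(n - 1L)))$y
  sqrt(sum(h^2))
}

# Evaluate and restore the global RNG around a seeded computation.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
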