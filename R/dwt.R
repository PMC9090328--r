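# Periodised Daubechies-2 (4-tap) discrete wavelet transform.
# Implemented in-package: used only by the motion-artifact wavelet
# correction, which zeroes outlying detail coefficients level by level.

.db2_lo <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
.db2_hi <- rev(.db2_lo) * c(1, -1, 1, -1)

# one level of periodised analysis: x (even length) -> list(approx, detail)
.dwt_step <- function(x) {
  n <- length(x)
  xp <- c(x, x[1:3])                       # periodic extension for the 4 taps
  idx <- seq(1, n, by = 2)
  a <- .db2_lo[1] * xp[idx] + .db2_lo[2] * xp[idx + 1] +
       .db2_lo[3] * xp[idx + 2] + .db2_lo[4] * xp[idx + 3]
  d <- .db2_hi[1] * xp[idx] + .db2_hi[2] * xp[idx + 1] +
       .db2_hi[3] * xp[idx + 2] + .db2_hi[4] * xp[idx + 3]
  list(a = a, d = d)
}

# inverse of .dwt_step
.idwt_step <- function(a, d) {
  n <- 2 * length(a)
  x <- numeric(n)
  ap <- c(a[length(a)], a)                 # periodic wrap on the left
  dp <- c(d[length(d)], d)
  even <- seq(2, n, by = 2); odd <- seq(1, n, by = 2)
  # reconstruction from the two polyphase components of the synthesis filters
  x[odd]  <- .db2_lo[3] * ap[-length(ap)] + .db2_lo[1] * ap[-1] +
             .db2_hi[3] * dp[-length(dp)] + .db2_hi[1] * dp[-1]
  x[even] <- .db2_lo[4] * ap[-length(ap)] + .db2_lo[2] * ap[-1] +
             .db2_hi[4] * dp[-length(dp)] + .db2_hi[2] * dp[-1]
  x
}

# full decomposition to maximum dyadic depth (approx length >= 4).
# x is reflection-padded to the next power of two; the original length is
# kept so the reconstruction can be truncated.
.dwt <- function(x) {
  n <- length(x)
  n2 <- 2^ceiling(log2(n))
  pad <- n2 - n
  xp <- if (pad > 0) c(x, x[n - seq_len(pad) + 1]) else x
  details <- list()
  a <- xp
  while (length(a) >= 8) {
    s <- .dwt_step(a)
    details[[length(details) + 1]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details, n = n)
}

.idwt <- function(w) {
  a <- w$approx
  for (j in rev(seq_along(w$details))) a <- .idwt_step(a, w$details[[j]])
  a[seq_len(w$n)]
}
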