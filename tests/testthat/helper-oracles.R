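# Independent brute-force MFCC oracle: explicit per-filter triangles and
# explicit DCT sums, sharing no code with compute_mfcc.
oracle_mfcc <- function(frame, sr, n_fft = 512L, n_mel = 26L, n_coeff = 12L) {
  padded <- c(frame, numeric(n_fft - length(frame)))
  P <- abs(fft(padded))^2 / n_fft
  P <- P[1:(n_fft / 2 + 1)]
  freqs <- (0:(n_fft / 2)) * sr / n_fft
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- imel(seq(mel(0), mel(sr / 2), length.out = n_mel + 2))
  energies <- numeric(n_mel)
  for (m in 1:n_mel) {
    w <- numeric(length(freqs))
    for (b in seq_along(freqs)) {
      f <- freqs[b]
      if (f >= pts[m] && f <= pts[m + 1]) {
        w[b] <- (f - pts[m]) / (pts[m + 1] - pts[m])
      } else if (f > pts[m + 1] && f <= pts[m + 2]) {
        w[b] <- (pts[m + 2] - f) / (pts[m + 2] - pts[m + 1])
      }
    }
    energies[m] <- sum(w * P)
  }
  le <- log(pmax(energies, 1e-10))
  out <- numeric(n_coeff)
  for (k in 1:n_coeff) {
    s <- 0
    for (n in 1:n_mel) s <- s + le[n] * cos(pi * k * (n - 0.5) / n_mel)
    out[k] <- sqrt(2 / n_mel) * s
  }
  out
}
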