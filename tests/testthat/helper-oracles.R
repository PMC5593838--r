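# Independent brute-force oracles used to cross-check the transform and
# area computations. These deliberately avoid the package's vectorised
# implementations (direct sums and loops only).

# trapezoidal area from a 10x oversampled linear interpolation of the
# samples (dense Riemann midpoint sum)
oracle_area_oversampled <- function(samples, fs, over = 10) {
  n <- length(samples)
  grid <- seq(1, n, length.out = (n - 1) * over + 1)
  dense <- stats::approx(seq_len(n), samples, xout = grid)$y
  dt <- 1 / fs / over
  sum((dense[-1] + dense[-length(dense)]) / 2) * dt
}

# direct DFT magnitude spectrogram with the package's framing contract
oracle_stft <- function(segment, window_n = 32, hop = 8, nfft = 128) {
  n <- length(segment)
  if (n < window_n) {
    frames <- matrix(c(segment, numeric(window_n - n)), ncol = 1)
  } else {
    starts <- seq(1, n - window_n + 1, by = hop)
    frames <- sapply(starts, function(s) segment[s:(s + window_n - 1)])
    if (is.null(dim(frames))) frames <- matrix(frames, ncol = 1)
  }
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(window_n - 1)) / (window_n - 1))
  S <- matrix(0, nfft %/% 2, ncol(frames))
  for (j in seq_len(ncol(frames))) {
    f <- frames[, j] * w
    for (k in 1:(nfft %/% 2)) {         # rows 1..nfft/2 exclude DC
      S[k, j] <- Mod(sum(f * exp(-2i * pi * k * (0:(window_n - 1)) / nfft)))
    }
  }
  S
}

# exhaustive (scale, placement) correlation grid by explicit loops
oracle_corr_grid <- function(segment, scales) {
  n <- length(segment)
  grid <- matrix(0, length(scales), n)
  for (si in seq_along(scales)) {
    w <- ecgbeats:::sym2_at_scale(scales[si])
    m <- length(w)
    nw <- sqrt(sum(w^2))
    for (c0 in 1:n) {
      b <- c0 - floor((m - 1) / 2)
      idx <- b:(b + m - 1)
      xs <- numeric(m)
      ok <- idx >= 1 & idx <= n
      xs[ok] <- segment[idx[ok]]
      nx <- sqrt(sum(xs^2))
      grid[si, c0] <- if (nx > 0) sum(xs * w) / (nx * nw) else 0
    }
  }
  grid
}

# direct double-sum pseudo-Wigner-Ville over the band
oracle_wvd <- function(segment, fs, band = c(0, 500), nfft = 256) {
  z <- ecgbeats:::analytic_signal(segment)
  N <- length(z)
  f <- (0:(nfft - 1)) * fs / (2 * nfft)
  sel <- which(f >= band[1] & f <= band[2])
  A <- matrix(0, length(sel), N)
  for (t in 1:N) {
    M <- min(t - 1, N - t, nfft %/% 2 - 1)
    for (ki in seq_along(sel)) {
      k <- sel[ki] - 1
      s <- z[t] * Conj(z[t])
      if (M > 0) for (m in 1:M) {
        s <- s + z[t + m] * Conj(z[t - m]) * exp(-2i * pi * k * m / nfft) +
          Conj(z[t + m] * Conj(z[t - m])) * exp(-2i * pi * k * (nfft - m) / nfft)
      }
      A[ki, t] <- abs(Re(s))
    }
  }
  A
}

# noiseless configuration without heart effects or amplitude/ST jitter
# (durations still drawn per beat); useful for closed-form checks
config_clean <- function(...) {
  default_config(noise_sd = 0, baseline_amp = 0, heart_amp_sd = 0,
                 heart_dur_rho = 0, heart_st_sd = 0, heart_isch_sd = 0,
                 amp_jitter = 0, lead_jitter = 0, st_jitter = 0, ...)
}
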