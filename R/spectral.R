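# Orthogonal wavelet sym2 (identical to db2): analysis filter pair,
# standard closed-form coefficients ((1 +/- sqrt(3)) / (4 sqrt(2)) family).
SYM2_DEC_LO <- c((1 - sqrt(3)), (3 - sqrt(3)), (3 + sqrt(3)), (1 + sqrt(3))) /
  (4 * sqrt(2))
SYM2_REC_LO <- rev(SYM2_DEC_LO)
SYM2_REC_HI <- SYM2_DEC_LO * c(1, -1, 1, -1)

# mother-wavelet samples psi on a dyadic grid over its support [0, 3],
# by the cascade algorithm (iterated upsample + low-pass refinement)
sym2_psi <- function(levels = 10) {
  up2 <- function(v) { r <- numeric(2 * length(v) - 1); r[seq(1, length(r), 2)] <- v; r }
  p <- SYM2_REC_HI
  for (j in seq_len(levels))
    p <- sqrt(2) * stats::convolve(up2(p), rev(SYM2_REC_LO), type = "open")
  p
}

.sym2_cache <- new.env(parent = emptyenv())

# wavelet sampled at integer-scale a: w[k] = psi(k / a), k = 0..3a
sym2_at_scale <- function(a, levels = 10) {
  key <- paste0("s", a, "_", levels)
  if (!is.null(.sym2_cache[[key]])) return(.sym2_cache[[key]])
  psi <- sym2_psi(levels)
  grid_n <- length(psi)                  # spans [0, 3]
  k <- 0:(3 * a)
  idx <- pmin(grid_n, pmax(1, round(k / a / 3 * (grid_n - 1)) + 1))
  w <- psi[idx]
  .sym2_cache[[key]] <- w
  w
}

# analytic signal via the frequency-domain Hilbert construction
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' FFT band power sums
#'
#' Power spectrum (squared FFT magnitude) of the unwindowed segment,
#' zero-padded to a fixed length; each feature is the one-sided sum of
#' power over a frequency band `[low, high)`.
#'
#' @param segment numeric vector, mV.
#' @param fs sampling rate, Hz.
#' @param bands list of `c(low, high)` band edges in Hz
#'   (default the three QRS analysis bands 0-35, 35-90, 125-250 Hz).
#' @param nfft zero-padded transform length (default 1024).
#' @return numeric vector of band power sums (mV^2), one per band.
#' @export
fft_band_sums <- function(segment, fs,
                          bands = list(c(0, 35), c(35, 90), c(125, 250)),
                          nfft = 1024) {
  stopifnot(length(segment) >= 4, nfft >= length(segment))
  X <- stats::fft(c(segment, numeric(nfft - length(segment))))
  k <- 0:(nfft %/% 2)
  P <- Mod(X[k + 1])^2
  f <- k * fs / nfft
  vapply(bands, function(b) sum(P[f >= b[1] & f < b[2]]), 0)
}

# frame the segment for the STFT: fixed 32-sample Hamming window, 75%
# overlap; a segment shorter than one window becomes a single
# zero-padded frame
stft_frames <- function(segment, window_n = 32, hop = 8) {
  n <- length(segment)
  if (n < window_n) {
    matrix(c(segment, numeric(window_n - n)), ncol = 1)
  } else {
    starts <- seq(1, n - window_n + 1, by = hop)
    vapply(starts, function(s) segment[s:(s + window_n - 1)],
           numeric(window_n))
  }
}

#' Short-time Fourier transform statistics
#'
#' Magnitude spectrogram with a 32-sample Hamming window, 75% overlap and
#' zero-padding to 128 frequency bins; the DC row is excluded and the
#' statistics are taken over all remaining time-frequency cells.
#'
#' @param segment numeric vector, mV.
#' @param fs sampling rate, Hz (kept for interface symmetry).
#' @param window_n,hop,nfft window length, hop and padded FFT length.
#' @return numeric `c(mean, median, max)` of the magnitude spectrogram.
#' @export
stft_stats <- function(segment, fs, window_n = 32, hop = 8, nfft = 128) {
  fr <- stft_frames(segment, window_n, hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(window_n - 1)) / (window_n - 1))
  fr <- fr * w
  fr <- rbind(fr, matrix(0, nfft - window_n, ncol(fr)))
  S <- Mod(stats::mvfft(fr))[2:(nfft %/% 2 + 1), , drop = FALSE]  # drop DC
  c(mean = mean(S), median = stats::median(S), max = max(S))
}

# correlation grid: rows = scales, cols = centre positions 1..n of the
# segment; entries are normalised correlations between the segment and
# the scaled wavelet centred there (segment zero-padded beyond its ends)
cwt_corr_grid <- function(segment, scales) {
  n <- length(segment)
  grid <- matrix(0, nrow = length(scales), ncol = n)
  for (si in seq_along(scales)) {
    w <- sym2_at_scale(scales[si])
    m <- length(w)
    nw <- sqrt(sum(w^2))
    if (nw == 0) next
    pad <- m
    xp <- c(numeric(pad), segment, numeric(pad))
    # cross-correlation and sliding segment norm over windows of length m
    num <- stats::convolve(xp, w, type = "open")   # cc at start b = idx-m+1
    cs2 <- cumsum(c(0, xp^2))
    nb <- length(xp) - m + 1
    sl <- sqrt(cs2[(m + 1):(m + nb)] - cs2[1:nb])
    rho <- numeric(nb)
    ok <- sl > 0
    rho[ok] <- num[(m:(m + nb - 1))][ok] / (sl[ok] * nw)
    # map start position b (in padded coords) to centre c (segment coords)
    centers_b <- (1:n) + pad - floor((m - 1) / 2)
    centers_b <- pmin(pmax(centers_b, 1), nb)
    grid[si, ] <- rho[centers_b]
  }
  grid
}

#' Continuous-wavelet-transform features
#'
#' CWT with the sym2 wavelet over integer scales (default 1..32):
#' mean and maximum of the absolute coefficient matrix, plus two
#' correlation features on a (scale, placement) grid of normalised
#' correlations between the segment and the placed, scaled wavelet:
#' `corr_bestpos` is the mean over scales of the best-placement
#' correlation, `corr_bestscale` the mean over placements of the
#' best-scale correlation.
#'
#' @param segment numeric vector, mV.
#' @param fs sampling rate, Hz (interface symmetry).
#' @param scales integer scales (default 1:32).
#' @return numeric `c(mean, max, corr_bestpos, corr_bestscale)`.
#' @export
cwt_features <- function(segment, fs, scales = 1:32) {
  n <- length(segment)
  if (all(segment == 0))
    return(c(mean = 0, max = 0, corr_bestpos = 0, corr_bestscale = 0))
  coefs <- matrix(0, nrow = length(scales), ncol = n)
  for (si in seq_along(scales)) {
    a <- scales[si]
    w <- sym2_at_scale(a) / sqrt(a)
    m <- length(w)
    pad <- m
    xp <- c(numeric(pad), segment, numeric(pad))
    cc <- stats::convolve(xp, w, type = "open")
    centers_b <- (1:n) + pad - floor((m - 1) / 2)
    coefs[si, ] <- cc[centers_b + m - 1]
  }
  grid <- cwt_corr_grid(segment, scales)
  c(mean = mean(abs(coefs)), max = max(abs(coefs)),
    corr_bestpos = mean(apply(grid, 1, max)),
    corr_bestscale = mean(apply(grid, 2, max)))
}

#' Wigner-Ville distribution features
#'
#' Discrete (pseudo-)Wigner-Ville distribution of the analytic segment;
#' features are the maximum and mean of the distribution magnitude over
#' cells with frequency inside the band (default 0-500 Hz).
#'
#' @param segment numeric vector, mV.
#' @param fs sampling rate, Hz.
#' @param band `c(low, high)` frequency band in Hz.
#' @param nfft lag-transform length (default 256); the frequency axis is
#'   `k * fs / (2 * nfft)`.
#' @return numeric `c(max, mean)` (mV^2-scaled distribution values).
#' @export
wvd_features <- function(segment, fs, band = c(0, 500), nfft = 256) {
  stopifnot(length(segment) >= 8)
  z <- analytic_signal(segment)
  N <- length(z)
  Mh <- nfft %/% 2 - 1
  R <- matrix(0 + 0i, nrow = nfft, ncol = N)
  for (t in 1:N) {
    M <- min(t - 1, N - t, Mh)
    R[1, t] <- z[t] * Conj(z[t])
    if (M > 0) {
      m <- 1:M
      v <- z[t + m] * Conj(z[t - m])
      R[m + 1, t] <- v
      R[nfft - m + 1, t] <- Conj(v)
    }
  }
  W <- Re(stats::mvfft(R))
  f <- (0:(nfft - 1)) * fs / (2 * nfft)
  sel <- f >= band[1] & f <= band[2]
  A <- abs(W[sel, , drop = FALSE])
  c(max = max(A), mean = mean(A))
}

spectral_battery <- function(segment, fs, prefix, sfx) {
  v <- c(fft_band_sums(segment, fs),
         stft_stats(segment, fs),
         cwt_features(segment, fs),
         wvd_features(segment, fs))
  names(v) <- paste0(prefix,
                     c("FFT_0_35", "FFT_35_90", "FFT_125_250",
                       "STFT_mean", "STFT_med", "STFT_max",
                       "CWT_mean", "CWT_max", "CWT_corr_pos",
                       "CWT_corr_scale", "WVD_max", "WVD_mean"), sfx)
  v
}

#' Delineation-based spectral features (SpectralD, 24)
#'
#' The 12-per-lead FFT/STFT/CWT/WVD battery applied to the delineated QRS
#' interval `[qrs_onset, j_point)` of each lead, isoline-corrected
#' (median of the first 10 ms of the window).
#'
#' @param beat an `ecg_beat` or a 2 x L waveform matrix.
#' @param fiducials 0-based fiducials (defaults to the beat's own).
#' @param fs sampling rate (defaults to the beat's own).
#' @return named numeric vector of length 24, in registry order.
#' @export
extract_spectralD <- function(beat, fiducials = NULL, fs = NULL) {
  if (inherits(beat, "ecg_beat")) {
    wav <- beat$waveform
    if (is.null(fiducials)) fiducials <- beat$fiducials
    if (is.null(fs)) fs <- beat$fs
  } else wav <- beat
  stopifnot(is.matrix(wav), nrow(wav) == 2, !is.null(fiducials), !is.null(fs))
  fid_check(fiducials, ncol(wav))
  if (fiducials$j_point - fiducials$qrs_onset < 4)
    stop("QRS interval empty or too short for spectral analysis")
  iso_n <- max(2, round(0.010 * fs))
  iso <- apply(wav[, 1:iso_n, drop = FALSE], 1, stats::median)
  idx <- (fiducials$qrs_onset + 1):fiducials$j_point
  out <- c()
  for (ld in 1:2) {
    sfx <- paste0("_", c("I", "II")[ld])
    out <- c(out, spectral_battery(wav[ld, idx] - iso[ld], fs, "", sfx))
  }
  reg <- feature_registry("SpectralD")$name
  stopifnot(identical(names(out), reg))
  out
}

#' R-peak-based spectral features (SpectralR, 24 per half-width)
#'
#' The same 12-per-lead battery applied to `<R-t, R+t>` segments for each
#' half-width t (default 20, 30, 50 ms), tagged S20/S30/S50. Segments
#' clipped at the window edge are analysed over the available part
#' (flagged in the `clipped` attribute).
#'
#' @param beat an `ecg_beat` or a 2 x L waveform matrix.
#' @param r_index 0-based R index (defaults to the beat's own fiducial).
#' @param fs sampling rate (defaults to the beat's own).
#' @param t_ms half-widths in ms (default `c(20, 30, 50)`).
#' @return named numeric vector (24 per t; 72 for the default t set), in
#'   registry order.
#' @export
extract_spectralR <- function(beat, r_index = NULL, fs = NULL,
                              t_ms = c(20, 30, 50)) {
  if (inherits(beat, "ecg_beat")) {
    wav <- beat$waveform
    if (is.null(r_index)) r_index <- beat$fiducials$r_peak
    if (is.null(fs)) fs <- beat$fs
  } else wav <- beat
  stopifnot(is.matrix(wav), nrow(wav) == 2, !is.null(r_index), !is.null(fs))
  L <- ncol(wav)
  clipped <- character(0)
  out <- c()
  for (t in t_ms) {
    h <- round(t / 1000 * fs)
    lo <- r_index - h; hi <- r_index + h
    if (lo < 0 || hi > L - 1) {
      clipped <- c(clipped, paste0("t", t))
      lo <- max(lo, 0); hi <- min(hi, L - 1)
    }
    for (ld in 1:2) {
      sfx <- paste0("_", c("I", "II")[ld])
      out <- c(out, spectral_battery(wav[ld, (lo + 1):(hi + 1)], fs,
                                     paste0("S", t, "_"), sfx))
    }
  }
  if (identical(t_ms, c(20, 30, 50))) {
    reg <- feature_registry("SpectralR")$name
    stopifnot(identical(names(out), reg))
  }
  attr(out, "clipped") <- clipped
  out
}
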