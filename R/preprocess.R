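# Analysis filter pair of the biorthogonal spline wavelet bior1.5
# (standard published coefficients; the high-pass side is the Haar pair).
BIOR15_DEC_LO <- c(0.016572815184059706, -0.016572815184059706,
                   -0.12153397801643785, 0.12153397801643785,
                   0.7071067811865476, 0.7071067811865476,
                   0.12153397801643785, -0.12153397801643785,
                   -0.016572815184059706, 0.016572815184059706)
BIOR15_DEC_HI <- c(-0.7071067811865476, 0.7071067811865476)

# centered moving average with reflected edges; odd width, zero phase
centered_ma <- function(x, n) {
  stopifnot(n %% 2 == 1)
  h <- (n - 1) / 2
  xp <- c(rev(x[2:(h + 1)]), x, rev(x[(length(x) - h):(length(x) - 1)]))
  cs <- cumsum(c(0, xp))
  (cs[(n + 1):(length(xp) + 1)] - cs[1:(length(xp) - n + 1)]) / n
}

#' Remove baseline wander (zero-phase comb/moving-average filter)
#'
#' Estimates the baseline with a centered (hence exactly zero-phase)
#' moving-average comb low-pass whose width is set so its -3 dB point sits
#' at `cutoff`, and subtracts it from the signal. Edges are handled by
#' reflection; output length equals input length.
#'
#' @param signal numeric vector, or leads-by-samples matrix (each row
#'   filtered independently).
#' @param fs sampling rate, Hz.
#' @param cutoff baseline cut-off frequency, Hz (default 0.5).
#' @return filtered signal, same shape as the input.
#' @export
remove_baseline <- function(signal, fs, cutoff = 0.5) {
  stopifnot(fs > 2 * cutoff)
  if (is.matrix(signal)) {
    out <- signal
    for (i in seq_len(nrow(signal)))
      out[i, ] <- remove_baseline(signal[i, ], fs, cutoff)
    return(out)
  }
  if (!all(is.finite(signal))) stop("non-finite samples in signal")
  n <- round(0.443 * fs / cutoff)       # MA -3 dB point ~ 0.443 fs / n
  if (n %% 2 == 0) n <- n + 1
  if (n <= 1 || n >= length(signal)) {
    baseline <- mean(signal)
    return(signal - baseline)
  }
  signal - centered_ma(signal, n)
}

# a trous stationary-wavelet detail at `level` using the bior1.5 pair:
# cascade of zero-stuffed low-pass stages followed by the dilated high-pass
swt_detail <- function(x, level) {
  conv_same <- function(x, h) {
    # linear convolution via padded FFT (nextn keeps lengths composite),
    # center-aligned with x
    n <- length(x); nf <- length(h)
    np <- stats::nextn(n + nf - 1)
    full <- Re(stats::fft(stats::fft(c(x, numeric(np - n))) *
                          stats::fft(c(h, numeric(np - nf))),
                          inverse = TRUE)) / np
    off <- floor((nf - 1) / 2)
    full[(1 + off):(n + off)]
  }
  dilate <- function(h, d) {
    if (d == 1) return(h)
    hd <- numeric((length(h) - 1) * d + 1)
    hd[seq(1, length(hd), by = d)] <- h
    hd
  }
  a <- x
  if (level > 1)
    for (j in seq_len(level - 1))
      a <- conv_same(a, dilate(BIOR15_DEC_LO, 2^(j - 1)))
  conv_same(a, dilate(BIOR15_DEC_HI, 2^(level - 1)))
}

#' Detect QRS complexes (wavelet detector, bior1.5)
#'
#' Band-passes each lead with a single-scale stationary bior1.5 wavelet
#' detail, sums absolute wavelet responses across leads, applies an
#' adaptive threshold (a fraction of a running 2 s upper percentile, with
#' a floor relative to the global envelope maximum, so detections are
#' invariant to amplitude scaling), enforces a 150 ms refractory period
#' and refines each candidate to the extremum of the summed absolute
#' baseline-corrected signal within +/-25 ms.
#'
#' @param signal 2 x N matrix (leads I, II), baseline-corrected, mV.
#' @param fs sampling rate, Hz.
#' @param level wavelet scale (dyadic level) of the detail used for
#'   detection; default 5 (passband centred near 30 Hz at 2 kHz).
#' @param threshold_frac fraction of the running 98th percentile used as
#'   the adaptive threshold (default 0.35).
#' @param refractory_ms minimum distance between detections, ms
#'   (default 150, about half the sinus RR of the study system).
#' @return object of class `qrs_detections`: list with `positions`
#'   (0-based, strictly increasing sample indices) and `fs`.
#' @export
detect_qrs <- function(signal, fs, level = 5, threshold_frac = 0.35,
                       refractory_ms = 150) {
  stopifnot(is.matrix(signal), nrow(signal) == 2, ncol(signal) >= fs)
  env <- abs(swt_detail(signal[1, ], level)) +
         abs(swt_detail(signal[2, ], level))
  N <- length(env)
  gmax <- max(env)
  out <- list(positions = integer(0), fs = fs)
  class(out) <- "qrs_detections"
  if (gmax <= 0) return(out)

  # blockwise 2 s running percentile -> stepwise adaptive threshold
  block <- max(1L, round(2 * fs))
  starts <- seq(1L, N, by = block)
  thr <- numeric(N)
  for (s in starts) {
    e <- min(N, s + block - 1L)
    thr[s:e] <- stats::quantile(env[s:e], 0.98, names = FALSE)
  }
  thr <- pmax(threshold_frac * thr, 0.10 * gmax)

  refr <- round(refractory_ms / 1000 * fs)
  above <- which(env > thr)
  cand <- integer(0)
  if (length(above)) {
    runs <- split(above, cumsum(c(1, diff(above) > 1)))
    cand <- vapply(runs, function(r) r[which.max(env[r])], 0L)
  }
  # refractory: greedy by envelope amplitude
  keep <- logical(length(cand))
  for (i in order(env[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[i]) < refr)) keep[i] <- TRUE
  }
  cand <- sort(cand[keep])

  # refine to the raw-signal extremum within +/-25 ms
  w <- as.integer(round(0.025 * fs))
  raw <- abs(signal[1, ]) + abs(signal[2, ])
  pos <- vapply(cand, function(c0) {
    lo <- max(1L, as.integer(c0) - w); hi <- min(N, as.integer(c0) + w)
    lo + which.max(raw[lo:hi]) - 1L
  }, 0L)
  pos <- sort(unique(pos))
  if (length(pos) > 1) pos <- pos[c(TRUE, diff(pos) >= refr)]
  out$positions <- as.integer(pos - 1L)   # 0-based
  out
}

#' Segment fixed windows around detected R peaks
#'
#' @param signal 2 x N matrix.
#' @param detections `qrs_detections` object or 0-based integer positions.
#' @param fs sampling rate, Hz.
#' @param pre_ms,post_ms window extent before/after R (defaults 30/250 ms;
#'   the window is half-open, `[R - pre, R + post)`).
#' @return list of 2 x L matrices (L = `round((pre_ms + post_ms)/1000 * fs)`)
#'   with attributes `r_index` (0-based R index within the window) and
#'   `r_position` (0-based record coordinate). Windows overrunning the
#'   record edges are dropped; the number dropped is attached to the
#'   result as attribute `n_dropped`.
#' @export
segment_beats <- function(signal, detections, fs, pre_ms = 30, post_ms = 250) {
  pos <- if (inherits(detections, "qrs_detections")) detections$positions
         else as.integer(detections)
  pre <- round(pre_ms / 1000 * fs)
  L <- round((pre_ms + post_ms) / 1000 * fs)
  N <- ncol(signal)
  out <- list()
  dropped <- 0L
  for (p in pos) {
    a <- p - pre                      # 0-based window start
    if (a < 0 || a + L > N) { dropped <- dropped + 1L; next }
    w <- signal[, (a + 1):(a + L), drop = FALSE]
    attr(w, "r_index") <- pre
    attr(w, "r_position") <- p
    out[[length(out) + 1L]] <- w
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Match detections against reference positions
#'
#' Tolerance-window bipartite matching (greedy, nearest-first) used to
#' score a detector against ground-truth annotations.
#'
#' @param detected,reference 0-based sample positions.
#' @param fs sampling rate, Hz.
#' @param tol_ms matching tolerance, ms (default 50).
#' @return list with `tp`, `fp`, `fn`, `sensitivity`, `ppv`, `f1`.
#' @export
match_detections <- function(detected, reference, fs, tol_ms = 50) {
  tol <- tol_ms / 1000 * fs
  used <- logical(length(detected))
  tp <- 0L
  for (r in reference) {
    d <- abs(detected - r)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      used[which.min(d)] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- sum(!used)
  fn <- length(reference) - tp
  se <- if (length(reference)) tp / (tp + fn) else NA_real_
  ppv <- if (length(detected)) tp / (tp + fp) else NA_real_
  f1 <- if (is.na(se) || is.na(ppv) || (se + ppv) == 0) NA_real_
        else 2 * se * ppv / (se + ppv)
  list(tp = tp, fp = fp, fn = fn, sensitivity = se, ppv = ppv, f1 = f1)
}
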