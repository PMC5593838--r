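#' Trapezoidal area under part of a waveform
#'
#' @param samples numeric vector, mV.
#' @param fs sampling rate, Hz.
#' @param part which part to integrate: `"signed"` (the waveform itself),
#'   `"positive"` (its positive part), `"negative"` (its negative part, a
#'   non-positive value) or `"absolute"` (its absolute value). By
#'   construction `signed = positive + negative` and
#'   `absolute = positive - negative`.
#' @return area in mV.s.
#' @export
area_under <- function(samples, fs,
                       part = c("signed", "positive", "negative", "absolute")) {
  part <- match.arg(part)
  stopifnot(all(is.finite(samples)))
  v <- switch(part,
              signed = samples,
              positive = pmax(samples, 0),
              negative = pmin(samples, 0),
              absolute = abs(samples))
  if (length(v) < 2) return(0)
  sum((v[-1] + v[-length(v)]) / 2) / fs
}

#' Length and angle of the maximal 2D-loop vector
#'
#' Treats the two leads as orthogonal horizontal-plane coordinates and
#' returns the maximal vector magnitude over the interval and its angle.
#'
#' @param x,y same-length numeric vectors (lead I, lead II) over the loop
#'   interval, mV.
#' @return numeric `c(length, angle)`; angle in degrees from `atan2(y, x)`
#'   at the maximal-magnitude sample (0 for an all-zero loop). Ties go to
#'   the earliest sample.
#' @export
loop_features <- function(x, y) {
  stopifnot(length(x) == length(y))
  r <- sqrt(x^2 + y^2)
  i <- which.max(r)
  if (!length(i) || r[i] == 0) return(c(length = 0, angle = 0))
  c(length = r[i], angle = atan2(y[i], x[i]) * 180 / pi)
}

# sign-preserving capped ratio; zero/zero -> 0, x/0 -> +/- cap
safe_ratio <- function(num, den, cap = 1e6) {
  if (abs(den) < 1e-300) {
    if (num == 0) return(0)
    return(sign(num) * cap)
  }
  max(min(num / den, cap), -cap)
}

fid_check <- function(fid, L) {
  with(fid, {
    if (!(qrs_onset < r_peak && r_peak < j_point && j_point < t_end))
      stop("fiducials out of order")
    if (qrs_onset < 0 || t_end > L - 1)
      stop("fiducials out of window")
  })
  invisible(fid)
}

# 1-based index range from 0-based half-open fiducial pair [a, b)
rng0 <- function(a, b) (a + 1):b

#' Delineation-based morphological features (MorphD, 71)
#'
#' Interval, voltage, area and 2D-loop characteristics of a 280 ms QRS-T
#' window, computed from the QRS onset, J point and T end. Voltage
#' deviations and areas are measured against the isoline, estimated as
#' the median of the first 10 ms of the window (pre-QRS). Ratio features
#' with a vanishing denominator are mapped to a sign-preserving capped
#' sentinel (+/- 1e6) so vectors stay finite.
#'
#' @param beat an `ecg_beat`, or a 2 x L waveform matrix (then `fiducials`
#'   must be given).
#' @param fiducials list with 0-based `qrs_onset`, `r_peak`, `j_point`,
#'   `t_end` (defaults to the beat's own).
#' @param fs sampling rate (defaults to the beat's own).
#' @return named numeric vector of length 71, in registry order.
#' @export
extract_morphD <- function(beat, fiducials = NULL, fs = NULL) {
  if (inherits(beat, "ecg_beat")) {
    wav <- beat$waveform
    if (is.null(fiducials)) fiducials <- beat$fiducials
    if (is.null(fs)) fs <- beat$fs
  } else wav <- beat
  stopifnot(is.matrix(wav), nrow(wav) == 2, !is.null(fiducials), !is.null(fs))
  L <- ncol(wav)
  fid_check(fiducials, L)
  on0 <- fiducials$qrs_onset; j0 <- fiducials$j_point
  tend0 <- fiducials$t_end
  iso_n <- max(2, round(0.010 * fs))
  iso <- apply(wav[, 1:iso_n, drop = FALSE], 1, stats::median)

  qrs_idx  <- rng0(on0, j0)
  stt_idx  <- rng0(j0, tend0 + 1)
  qrst_idx <- rng0(on0, tend0 + 1)
  st20_i <- j0 + round(0.020 * fs) + 1
  if (st20_i > L) stop("ST20 sample outside window")

  dev <- wav - iso          # per-lead deviation from isoline
  # JTmax: J point to the sample of maximal two-lead ST-T deviation
  mag <- sqrt(dev[1, stt_idx]^2 + dev[2, stt_idx]^2)
  jtmax_ms <- (which.max(mag) - 1) / fs * 1000

  out <- c(
    QRS_D = (j0 - on0) / fs * 1000,
    QT = (tend0 - on0) / fs * 1000,
    JTmax = jtmax_ms,
    stats::setNames(loop_features(dev[1, qrs_idx], dev[2, qrs_idx]),
                    c("QRSloop_len", "QRSloop_ang")),
    stats::setNames(loop_features(dev[1, stt_idx], dev[2, stt_idx]),
                    c("STTloop_len", "STTloop_ang"))
  )

  for (ld in 1:2) {
    sfx <- paste0("_", c("I", "II")[ld])
    v_qrs <- dev[ld, qrs_idx]; v_stt <- dev[ld, stt_idx]
    v_qrst <- dev[ld, qrst_idx]
    volt <- c(max(v_qrs), min(v_qrs), max(abs(v_qrs)),
              v_stt[which.max(abs(v_stt))], max(abs(v_stt)),
              dev[ld, st20_i])
    names(volt) <- paste0(c("QRSp_A", "QRSn_A", "QRSmax", "T_A",
                            "STTmax", "ST20"), sfx)
    auc <- c()
    for (iv in c("qrs", "stt", "qrst")) {
      v <- switch(iv, qrs = v_qrs, stt = v_stt, qrst = v_qrst)
      a <- c(area_under(v, fs, "signed"), area_under(v, fs, "positive"),
             area_under(v, fs, "negative"), area_under(v, fs, "absolute"))
      names(a) <- paste0("AUC_", iv, c("", "_pos", "_neg", "_abs"), sfx)
      auc <- c(auc, a)
    }
    den <- auc[[paste0("AUC_qrst", sfx)]]
    rel_src <- setdiff(names(auc), paste0("AUC_qrst", sfx))
    rel <- vapply(rel_src, function(nm) safe_ratio(auc[[nm]], den), 0)
    names(rel) <- sub("^AUC_", "relAUC_", rel_src)
    rat <- vapply(c("qrs", "stt", "qrst"), function(iv)
      safe_ratio(auc[[paste0("AUC_", iv, "_pos", sfx)]],
                 -auc[[paste0("AUC_", iv, "_neg", sfx)]]), 0)
    names(rat) <- paste0("ratioAUC_", c("qrs", "stt", "qrst"), sfx)
    out <- c(out, volt, auc, rel, rat)
  }
  reg <- feature_registry("MorphD")$name
  stopifnot(identical(sort(names(out)), sort(reg)))
  out[reg]
}

#' R-peak-based morphological features (MorphR, 44)
#'
#' Delineation-free characteristics of the 280 ms window: extremum values
#' and positions, and trapezoidal areas over `<R-t, R+t>` windows for
#' t = 40, 60 and 100 ms and over the full window. Windows clipped at the
#' segment edge are integrated over the available part (the window holds
#' only 30 ms before R); clipping is flagged in the `clipped` attribute.
#' Extremum positions are in ms relative to R (so the features are
#' invariant to translating the waveform and `r_index` together); ties go
#' to the earliest sample.
#'
#' @param beat an `ecg_beat` or a 2 x L waveform matrix.
#' @param r_index 0-based R index within the window (defaults to the
#'   beat's own fiducial).
#' @param fs sampling rate (defaults to the beat's own).
#' @param t_ms half-widths of the R-centred windows, ms.
#' @return named numeric vector of length 44, in registry order.
#' @export
extract_morphR <- function(beat, r_index = NULL, fs = NULL,
                           t_ms = c(40, 60, 100)) {
  if (inherits(beat, "ecg_beat")) {
    wav <- beat$waveform
    if (is.null(r_index)) r_index <- beat$fiducials$r_peak
    if (is.null(fs)) fs <- beat$fs
  } else wav <- beat
  stopifnot(is.matrix(wav), nrow(wav) == 2, !is.null(r_index), !is.null(fs))
  L <- ncol(wav)
  stopifnot(r_index >= 0, r_index <= L - 1)

  clipped <- character(0)
  out <- c()
  for (ld in 1:2) {
    sfx <- paste0("_", c("I", "II")[ld])
    x <- wav[ld, ]
    imax <- which.max(x); imin <- which.min(x)
    common <- c(x[imax], (imax - 1 - r_index) / fs * 1000, x[imin],
                (imin - 1 - r_index) / fs * 1000, x[imax] - x[imin],
                abs(imax - imin) / fs * 1000)
    names(common) <- paste0(c("Rmax", "Rmax_pos", "Rmin", "Rmin_pos",
                              "Rrange", "Rmaxmin_dt"), sfx)
    a_sgn <- a_abs <- c()
    for (t in t_ms) {
      h <- round(t / 1000 * fs)
      lo <- r_index - h; hi <- r_index + h
      if (lo < 0 || hi > L - 1) {
        clipped <- c(clipped, paste0("t", t, sfx))
        lo <- max(lo, 0); hi <- min(hi, L - 1)
      }
      seg <- x[(lo + 1):(hi + 1)]
      a_sgn[paste0("AUC_t", t, sfx)] <- area_under(seg, fs, "signed")
      a_abs[paste0("AUC_t", t, "_abs", sfx)] <- area_under(seg, fs, "absolute")
    }
    full <- c(area_under(x, fs, "signed"), area_under(x, fs, "positive"),
              area_under(x, fs, "negative"))
    names(full) <- paste0(c("AUC_full", "AUC_full_pos", "AUC_full_neg"), sfx)
    full_abs <- full[[2]] - full[[3]]
    rel_sgn <- vapply(a_sgn, function(a) safe_ratio(a, full[[1]]), 0)
    names(rel_sgn) <- sub("^AUC_", "relAUC_", names(a_sgn))
    rel_abs <- vapply(a_abs, function(a) safe_ratio(a, full_abs), 0)
    names(rel_abs) <- sub("^AUC_", "relAUC_", names(a_abs))
    rat <- c(safe_ratio(full[[2]], -full[[3]]))
    names(rat) <- paste0("ratioAUC_full", sfx)
    out <- c(out, common, a_sgn, a_abs, full, rel_sgn, rel_abs, rat)
  }
  reg <- feature_registry("MorphR")$name
  stopifnot(identical(sort(names(out)), sort(reg)))
  out <- out[reg]
  attr(out, "clipped") <- clipped
  out
}
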