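#' Default generator configuration
#'
#' Parameters of the synthetic two-lead beat generator. The non-ischemic
#' class is calibrated to the stabilization-period statistics of the study
#' system (isolated rabbit heart): RR 344 +/- 46 ms, QRS 24 +/- 4 ms,
#' QT 175 +/- 22 ms. The pathological classes express the qualitative
#' ischemic signature -- QRS widening, ST deviation (elevation, the
#' transmural pattern of the globally ischemic isolated heart) and T-wave
#' inversion -- graded from moderate (ISM) to severe (ISE), and a wide
#' bizarre biphasic complex with discordant T for VPB. Intra-class
#' variability is carried by a log-normal per-beat amplitude scale and
#' per-lead jitter.
#'
#' @param fs sampling rate in Hz (default 2000).
#' @param noise_sd additive Gaussian noise SD in mV (default 0.02).
#' @param baseline_amp baseline-wander sinusoid amplitude in mV
#'   (records only; default 0.1).
#' @param baseline_freq baseline-wander frequency in Hz, must be < 0.5
#'   (default 0.3).
#' @param n_hearts number of simulated experiments (isolated hearts) the
#'   beat population is drawn from (default 21). Each heart carries its
#'   own amplitude, duration and ST-magnitude factors, so every class is
#'   a mixture of per-heart clusters, mirroring the high inter-experiment
#'   variability of isolated-heart recordings.
#' @param heart_amp_sd log-scale SD of the per-heart, per-lead amplitude
#'   factor (default 0.25).
#' @param heart_dur_rho fraction of each duration's SD carried by the
#'   between-heart effect (default 0.9: class representatives are sampled
#'   within a single recording minute, so same-heart beats are
#'   near-replicates and the between-experiment spread dominates); the
#'   within-beat remainder keeps the total SD at the configured value.
#' @param heart_st_sd log-scale SD of the per-heart ST-magnitude factor
#'   (default 0.3).
#' @param heart_isch_sd log-scale SD of the per-heart ischemia-expression
#'   factors (default 0.5). Each heart expresses the pathological
#'   deviation from the non-ischemic template with its own mixture of ST
#'   shift, interval change (QRS widening / QT shortening) and T-wave
#'   inversion, so no single feature direction separates the classes in
#'   every heart -- the hallmark of real ischemic ECG populations.
#' @param amp_jitter SD of the per-beat log-normal amplitude scale on top
#'   of the heart factor (default 0.05).
#' @param lead_jitter SD of the per-lead relative amplitude jitter
#'   (default 0.05).
#' @param st_jitter relative SD of the per-beat ST-level magnitude
#'   (default 0.15).
#' @param quantize logical; apply 16-bit amplitude quantization
#'   (default FALSE).
#' @param quant_step quantization step in mV (default 20/2^16, i.e. a
#'   16-bit converter spanning +/-10 mV).
#' @return an object of class `ecg_gen_config`: a list with the above
#'   fields plus `classes`, a per-class list of morphology parameters
#'   (`rr_mean_ms`, `rr_sd_ms`, `qrs_ms_mean`, `qrs_ms_sd`, `qt_ms_mean`,
#'   `qt_ms_sd`, per-lead amplitudes `q_amp`, `r_amp`, `s_amp`, `t_amp`
#'   in mV, per-lead `st_level` in mV, `t_polarity`, `st_sign_random`,
#'   `prematurity_frac`).
#' @export
default_config <- function(fs = 2000, noise_sd = 0.02,
                           baseline_amp = 0.1, baseline_freq = 0.3,
                           n_hearts = 21, heart_amp_sd = 0.25,
                           heart_dur_rho = 0.9, heart_st_sd = 0.3,
                           heart_isch_sd = 0.5,
                           amp_jitter = 0.04, lead_jitter = 0.03,
                           st_jitter = 0.08,
                           quantize = FALSE, quant_step = 20 / 65536) {
  morph <- function(rr, rr_sd, qrs, qrs_sd, qt, qt_sd,
                    q_amp, r_amp, s_amp, t_amp, st_level, t_polarity,
                    st_sign_random = FALSE, prematurity_frac = NA_real_,
                    qrs_min_ms = 8) {
    list(rr_mean_ms = rr, rr_sd_ms = rr_sd,
         qrs_ms_mean = qrs, qrs_ms_sd = qrs_sd,
         qt_ms_mean = qt, qt_ms_sd = qt_sd,
         q_amp = q_amp, r_amp = r_amp, s_amp = s_amp, t_amp = t_amp,
         st_level = st_level, t_polarity = t_polarity,
         st_sign_random = st_sign_random,
         prematurity_frac = prematurity_frac, qrs_min_ms = qrs_min_ms)
  }
  cfg <- list(
    fs = fs, noise_sd = noise_sd,
    baseline_amp = baseline_amp, baseline_freq = baseline_freq,
    n_hearts = n_hearts, heart_amp_sd = heart_amp_sd,
    heart_dur_rho = heart_dur_rho, heart_st_sd = heart_st_sd,
    heart_isch_sd = heart_isch_sd,
    amp_jitter = amp_jitter, lead_jitter = lead_jitter,
    st_jitter = st_jitter,
    quantize = quantize, quant_step = quant_step,
    classes = list(
      # lead II amplitudes 1.2x lead I so the 2D loops are non-degenerate
      NOR = morph(344, 46, 24, 4, 175, 22,
                  q_amp = c(-0.08, -0.10), r_amp = c(1.00, 1.20),
                  s_amp = c(-0.25, -0.30), t_amp = c(0.25, 0.30),
                  st_level = c(0.00, 0.00), t_polarity = c(1, 1)),
      ISM = morph(352, 48, 30, 5, 170, 22,
                  q_amp = c(-0.08, -0.10), r_amp = c(0.95, 1.15),
                  s_amp = c(-0.25, -0.30), t_amp = c(0.10, 0.12),
                  st_level = c(0.08, 0.10), t_polarity = c(1, 1)),
      ISE = morph(372, 55, 46, 6, 168, 20,
                  q_amp = c(-0.06, -0.08), r_amp = c(0.80, 0.95),
                  s_amp = c(-0.30, -0.35), t_amp = c(0.30, 0.35),
                  st_level = c(0.25, 0.30), t_polarity = c(-1, -1)),
      VPB = morph(344, 46, 64, 6, 200, 18,
                  q_amp = c(-0.05, -0.05), r_amp = c(1.10, 0.90),
                  s_amp = c(-0.90, -1.20), t_amp = c(0.40, 0.45),
                  st_level = c(0.10, 0.12), t_polarity = c(-1, -1),
                  prematurity_frac = 0.7, qrs_min_ms = 60)
    )
  )
  class(cfg) <- "ecg_gen_config"
  validate_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' @param config an `ecg_gen_config` object.
#' @return `config`, invisibly; errors on a degenerate configuration.
#' @export
validate_config <- function(config) {
  stopifnot(config$fs >= 1000, config$baseline_freq < 0.5,
            config$noise_sd >= 0)
  for (cls in beat_classes()) {
    m <- config$classes[[cls]]
    if (is.null(m)) stop("missing class morphology for ", cls)
    if (m$qrs_ms_mean <= 0 || m$qt_ms_mean <= 0 || m$rr_mean_ms <= 0)
      stop("durations must be positive for class ", cls)
    if (m$qrs_ms_mean >= m$qt_ms_mean)
      stop("degenerate morphology for ", cls, ": QRS duration >= QT")
    if (m$rr_mean_ms <= m$qt_ms_mean)
      stop("degenerate morphology for ", cls, ": RR <= QT")
  }
  invisible(config)
}

# Fixed population of simulated hearts: one row per heart with a shared
# duration effect (z_dur), per-lead amplitude effects and an ST effect.
# Columns are standardized across hearts (exact mean 0, SD 1), so the
# between/within variance split of the durations is exact and the
# configured class means/SDs are preserved in the mixture.
.heart_cache <- new.env(parent = emptyenv())

heart_population <- function(n_hearts) {
  key <- paste0("h", n_hearts)
  if (!is.null(.heart_cache[[key]])) return(.heart_cache[[key]])
  set.seed(derive_seed(97531, n_hearts))
  P <- matrix(stats::rnorm(n_hearts * 7), n_hearts, 7,
              dimnames = list(NULL, c("z_dur", "w_ampI", "w_ampII", "u_st",
                                      "v_st", "v_int", "v_t")))
  if (n_hearts > 1) {
    P <- scale(P)                    # exact mean 0, sd 1 per column
    attr(P, "scaled:center") <- NULL
    attr(P, "scaled:scale") <- NULL
  } else P[] <- 0
  .heart_cache[[key]] <- P
  P
}

# raised-cosine bump, compact support |t - center| < halfwidth (samples)
rc_bump <- function(idx, center, halfwidth) {
  u <- (idx - center) / halfwidth
  ifelse(abs(u) < 1, cos(pi * u / 2)^2, 0)
}

# truncated normal draw (vector length 1), +/- 3 SD, optional bounds
draw_trunc <- function(mean, sd, lo = -Inf, hi = Inf) {
  lo <- max(lo, mean - 3 * sd)
  hi <- min(hi, mean + 3 * sd)
  if (lo >= hi) return((lo + hi) / 2)
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Generate one synthetic two-lead beat
#'
#' Builds a 280 ms two-lead QRS-T window (R-30 ms to R+250 ms) as a sum of
#' smooth compact bumps (Q, R, S within the QRS support, a T bump after an
#' ST plateau) plus an ST-level offset that ramps up under the QRS, holds
#' between the J point and T onset, and decays over the T wave. Fiducials
#' are the exact analytic support boundaries of the construction; noise is
#' added after they are fixed, so ground truth is unaffected by noise.
#'
#' @param label one of `"NOR"`, `"ISM"`, `"ISE"`, `"VPB"`.
#' @param config an `ecg_gen_config` (see [default_config()]).
#' @param seed integer seed for this beat's substream.
#' @return object of class `ecg_beat`: list with `waveform` (2 x L matrix,
#'   mV; rows = leads I, II; L = round(0.280 fs)), `fs`, `fiducials`
#'   (list `qrs_onset`, `r_peak`, `j_point`, `t_end`; 0-based sample
#'   indices within the window), `label`, `rr_prev_ms` (preceding RR
#'   interval; premature for VPB) and `params` (the per-beat drawn
#'   parameters, including the effective per-lead ST level).
#' @export
generate_beat <- function(label, config = default_config(), seed = 1L) {
  label <- as.character(label)
  stopifnot(label %in% beat_classes())
  validate_config(config)
  m <- config$classes[[label]]
  fs <- config$fs
  L <- round(0.280 * fs)
  r0 <- round(0.030 * fs)           # 0-based R index in the window

  pop <- heart_population(config$n_hearts)
  set.seed(seed)
  heart <- sample.int(config$n_hearts, 1)
  hp <- pop[heart, ]
  rho <- config$heart_dur_rho
  wsd <- sqrt(1 - rho^2)                # within-beat share of duration SD

  # per-heart ischemia-expression factors (mean 1, floored at 0.5): how
  # much of the class's ST / interval / T-wave deviation this heart
  # expresses. Global ischemia changes every heart's ECG clearly; what
  # varies between hearts is the mix of ST shift, interval change and
  # T inversion, not its presence.
  isd <- config$heart_isch_sd
  expr <- function(v) 0.5 + 0.5 * exp(isd * v - isd^2 / 2)
  s_st  <- expr(hp[["v_st"]])
  s_int <- expr(hp[["v_int"]])
  s_t   <- expr(hp[["v_t"]])

  nor <- config$classes$NOR
  qrs_mu <- m$qrs_ms_mean; qt_mu <- m$qt_ms_mean
  if (label %in% c("ISM", "ISE")) {
    qrs_mu <- nor$qrs_ms_mean + s_int * (m$qrs_ms_mean - nor$qrs_ms_mean)
    qt_mu  <- nor$qt_ms_mean + s_int * (m$qt_ms_mean - nor$qt_ms_mean)
  }
  dur <- function(mean, sd, lo, hi = Inf)
    draw_trunc(min(mean * (1 + rho * (sd / mean) * hp[["z_dur"]]), hi),
               wsd * sd, lo = lo, hi = hi)
  # window geometry caps: QRS onset (R - 0.35 QRS) must stay inside the
  # 30 ms pre-R budget, T end inside the 250 ms post-R budget
  fsm <- config$fs / 1000
  qrs_cap <- floor((0.030 * config$fs) / 0.35) / fsm - 1
  qrs_ms <- dur(min(qrs_mu, qrs_cap - 5), m$qrs_ms_sd,
                lo = m$qrs_min_ms, hi = qrs_cap)
  qt_cap <- (round(0.280 * config$fs) - 2 -
             (round(0.030 * config$fs) - round(0.35 * qrs_ms * fsm))) / fsm
  qt_ms  <- dur(min(qt_mu, qt_cap - 5), m$qt_ms_sd,
                lo = qrs_ms + 50, hi = qt_cap)
  rr_ms  <- dur(m$rr_mean_ms, m$rr_sd_ms, lo = 150)
  rr_prev_ms <- if (is.finite(m$prematurity_frac) && !is.na(m$prematurity_frac))
    m$prematurity_frac * rr_ms else rr_ms

  # amplitude: per-heart lead factors, shared per-beat log-normal scale,
  # small per-lead relative jitter
  heart_amp <- exp(config$heart_amp_sd * c(hp[["w_ampI"]], hp[["w_ampII"]]))
  g <- exp(stats::rnorm(1, 0, config$amp_jitter))
  lead_g <- heart_amp * g * (1 + stats::rnorm(2, 0, config$lead_jitter))
  st_sign <- if (isTRUE(m$st_sign_random)) sample(c(-1, 1), 1) else 1
  st_expr <- if (label == "NOR") 1 else s_st
  st_eff <- lead_g * st_sign * m$st_level * st_expr *
    exp(config$heart_st_sd * hp[["u_st"]]) *
    (1 + stats::rnorm(1, 0, config$st_jitter))
  t_signed <- m$t_amp * m$t_polarity
  if (label != "NOR") {
    t_nor <- nor$t_amp * nor$t_polarity
    t_signed <- t_nor + s_t * (t_signed - t_nor)
  }

  qrs_n <- round(qrs_ms * fs / 1000)
  qt_n  <- round(qt_ms * fs / 1000)
  on0   <- r0 - round(0.35 * qrs_n)
  if (on0 < 0) stop("QRS onset precedes window start; QRS too wide for window")
  j0    <- on0 + qrs_n
  tend0 <- min(on0 + qt_n, L - 2)
  ton0  <- j0 + max(round(0.025 * fs), round(0.25 * (tend0 - j0)))

  idx <- 0:(L - 1)
  wav <- matrix(0, nrow = 2, ncol = L,
                dimnames = list(c("I", "II"), NULL))
  for (ld in 1:2) {
    q_c <- on0 + 0.12 * qrs_n
    s_c <- j0 - 0.20 * qrs_n
    x <- lead_g[ld] * (
      m$q_amp[ld] * rc_bump(idx, q_c, 0.12 * qrs_n) +
      m$r_amp[ld] * rc_bump(idx, r0, 0.30 * qrs_n) +
      m$s_amp[ld] * rc_bump(idx, s_c, 0.20 * qrs_n) +
      t_signed[ld] *
        rc_bump(idx, (ton0 + tend0) / 2, (tend0 - ton0) / 2))
    # ST offset: half-cosine ramp R -> J, plateau J -> T onset, decay to T end
    st <- numeric(L)
    up <- idx >= r0 & idx < j0
    st[up] <- st_eff[ld] * (1 - cos(pi * (idx[up] - r0) / (j0 - r0))) / 2
    st[idx >= j0 & idx < ton0] <- st_eff[ld]
    dn <- idx >= ton0 & idx <= tend0
    st[dn] <- st_eff[ld] * (1 + cos(pi * (idx[dn] - ton0) / (tend0 - ton0))) / 2
    wav[ld, ] <- x + st
  }
  if (config$noise_sd > 0)
    wav <- wav + matrix(stats::rnorm(2 * L, 0, config$noise_sd), nrow = 2)
  if (isTRUE(config$quantize))
    wav <- round(wav / config$quant_step) * config$quant_step

  structure(list(
    waveform = wav, fs = fs,
    fiducials = list(qrs_onset = on0, r_peak = r0, j_point = j0,
                     t_end = tend0),
    label = label, rr_prev_ms = rr_prev_ms,
    params = list(qrs_ms = qrs_ms, qt_ms = qt_ms, rr_ms = rr_ms,
                  heart = heart, amp_scale = lead_g, st_level = st_eff,
                  st_sign = st_sign)
  ), class = "ecg_beat")
}

#' Generate a labelled beat dataset
#'
#' Draws `counts[class]` beats per class with per-beat substream seeds
#' derived from the root seed by a (class, index) counter, so each beat's
#' waveform is independent of the other classes' counts, then shuffles the
#' order deterministically.
#'
#' @param counts named integer vector over (a subset of) the four classes,
#'   e.g. `c(NOR = 220, ISM = 220, ISE = 220, VPB = 172)`.
#' @param config generator configuration.
#' @param seed integer root seed.
#' @return list of `ecg_beat` objects.
#' @export
generate_dataset <- function(counts, config = default_config(), seed = 1L) {
  stopifnot(all(names(counts) %in% beat_classes()), all(counts >= 0))
  beats <- list()
  for (ci in seq_along(beat_classes())) {
    cls <- beat_classes()[ci]
    n <- if (cls %in% names(counts)) as.integer(counts[[cls]]) else 0L
    if (n == 0L) next
    for (i in seq_len(n)) {
      beats[[length(beats) + 1L]] <-
        generate_beat(cls, config, seed = derive_seed(seed, ci * 1e6 + i))
    }
  }
  if (length(beats) > 1L) {
    set.seed(derive_seed(seed, 999))
    beats <- beats[sample.int(length(beats))]
  }
  beats
}

#' Generate a continuous annotated two-lead record
#'
#' Concatenates beats at their drawn RR intervals (VPBs premature by the
#' configured fraction of the drawn sinus RR), then adds a baseline-wander
#' sinusoid and measurement noise. Annotations carry ground-truth R
#' positions, labels and fiducials in record coordinates.
#'
#' @param beat_sequence character vector of class labels in temporal order.
#' @param config generator configuration; `baseline_amp`/`baseline_freq`
#'   control the wander, `noise_sd` the noise.
#' @param seed integer root seed.
#' @return object of class `ecg_record`: list with `signal` (2 x N matrix,
#'   mV), `fs`, and `annotations` (data.frame with 0-based `r_peak`,
#'   `label`, `qrs_onset`, `j_point`, `t_end` in record coordinates, and
#'   `rr_prev_ms`).
#' @export
generate_record <- function(beat_sequence, config = default_config(),
                            seed = 1L) {
  stopifnot(length(beat_sequence) >= 1)
  validate_config(config)
  fs <- config$fs
  clean_cfg <- config
  clean_cfg$noise_sd <- 0
  clean_cfg$quantize <- FALSE

  nb <- length(beat_sequence)
  beats <- vector("list", nb)
  for (i in seq_len(nb))
    beats[[i]] <- generate_beat(beat_sequence[i], clean_cfg,
                                seed = derive_seed(seed, 5e7 + i))
  gaps <- round(vapply(beats, function(b) b$rr_prev_ms, 0) * fs / 1000)
  gaps <- pmax(gaps, round(0.150 * fs))
  r_pos <- round(0.100 * fs) + cumsum(c(0, gaps[-1]))   # 0-based R indices
  L <- ncol(beats[[1]]$waveform)
  r0 <- beats[[1]]$fiducials$r_peak
  N <- r_pos[nb] + (L - r0) + round(0.100 * fs)

  sig <- matrix(0, nrow = 2, ncol = N, dimnames = list(c("I", "II"), NULL))
  for (i in seq_len(nb)) {
    a <- r_pos[i] - r0              # 0-based start of window
    cols <- (a + 1):(a + L)
    sig[, cols] <- sig[, cols] + beats[[i]]$waveform
  }
  set.seed(derive_seed(seed, 4e7))
  if (config$baseline_amp > 0) {
    ph <- stats::runif(2, 0, 2 * pi)
    t <- (0:(N - 1)) / fs
    for (ld in 1:2)
      sig[ld, ] <- sig[ld, ] +
        config$baseline_amp * sin(2 * pi * config$baseline_freq * t + ph[ld])
  }
  if (config$noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(2 * N, 0, config$noise_sd), nrow = 2)
  if (isTRUE(config$quantize))
    sig <- round(sig / config$quant_step) * config$quant_step

  ann <- data.frame(
    r_peak = r_pos,
    label = vapply(beats, function(b) b$label, ""),
    qrs_onset = r_pos - r0 + vapply(beats, function(b) b$fiducials$qrs_onset, 0),
    j_point = r_pos - r0 + vapply(beats, function(b) b$fiducials$j_point, 0),
    t_end = r_pos - r0 + vapply(beats, function(b) b$fiducials$t_end, 0),
    rr_prev_ms = vapply(beats, function(b) b$rr_prev_ms, 0),
    stringsAsFactors = FALSE)

  structure(list(signal = sig, fs = fs, annotations = ann),
            class = "ecg_record")
}
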