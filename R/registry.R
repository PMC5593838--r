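#' Feature registry
#'
#' The single source of truth for the feature inventory: name, family,
#' subgroup, lead and units of every feature the four extractors emit, in
#' their fixed output order. Family sizes: MorphD 71 (7 both-lead interval
#' and 2D-loop features + 32 per lead), MorphR 44 (22 per lead),
#' SpectralD 24 (12 per lead), SpectralR 72 (the 12-per-lead battery for
#' each half-width t in 20, 30, 50 ms).
#'
#' Subgroups follow the study's split: CommonD/CommonR (interval and
#' voltage characteristics), LoopD (2D-loop features), AreaD/AreaR
#' (signed-area features), AreaDa/AreaRa (areas of absolute values),
#' AreaDr (relative areas and ratios), S20/S30/S50 (spectral R-segment
#' half-widths).
#'
#' @param family optional filter: one or more of `"MorphD"`, `"MorphR"`,
#'   `"SpectralD"`, `"SpectralR"`.
#' @return data.frame with columns `name`, `family`, `subgroup`, `lead`
#'   (`"I"`, `"II"` or `"both"`) and `units`.
#' @export
feature_registry <- function(family = NULL) {
  if (!is.null(.registry_cache$full)) {
    reg <- .registry_cache$full
    if (!is.null(family)) reg <- reg[reg$family %in% family, , drop = FALSE]
    rownames(reg) <- NULL
    return(reg)
  }
  rows <- list()
  add <- function(name, fam, sub, lead, units)
    rows[[length(rows) + 1L]] <<-
      data.frame(name = name, family = fam, subgroup = sub, lead = lead,
                 units = units, stringsAsFactors = FALSE)

  ## ---- MorphD: 7 both-lead + 32 per lead --------------------------------
  add("QRS_D",  "MorphD", "CommonD", "both", "ms")
  add("QT",     "MorphD", "CommonD", "both", "ms")
  add("JTmax",  "MorphD", "CommonD", "both", "ms")
  add("QRSloop_len", "MorphD", "LoopD", "both", "mV")
  add("QRSloop_ang", "MorphD", "LoopD", "both", "deg")
  add("STTloop_len", "MorphD", "LoopD", "both", "mV")
  add("STTloop_ang", "MorphD", "LoopD", "both", "deg")
  for (ld in c("I", "II")) {
    sfx <- paste0("_", ld)
    add(paste0("QRSp_A", sfx), "MorphD", "CommonD", ld, "mV")
    add(paste0("QRSn_A", sfx), "MorphD", "CommonD", ld, "mV")
    add(paste0("QRSmax", sfx), "MorphD", "CommonD", ld, "mV")
    add(paste0("T_A", sfx),    "MorphD", "CommonD", ld, "mV")
    add(paste0("STTmax", sfx), "MorphD", "CommonD", ld, "mV")
    add(paste0("ST20", sfx),   "MorphD", "CommonD", ld, "mV")
    for (iv in c("qrs", "stt", "qrst")) {
      add(paste0("AUC_", iv, sfx),        "MorphD", "AreaD",  ld, "mV.s")
      add(paste0("AUC_", iv, "_pos", sfx), "MorphD", "AreaD",  ld, "mV.s")
      add(paste0("AUC_", iv, "_neg", sfx), "MorphD", "AreaD",  ld, "mV.s")
      add(paste0("AUC_", iv, "_abs", sfx), "MorphD", "AreaDa", ld, "mV.s")
    }
    # relative to signed AUC_qrst (the whole-segment area); the trivial
    # qrst/qrst entry is excluded
    for (iv in c("qrs", "stt")) {
      add(paste0("relAUC_", iv, sfx),        "MorphD", "AreaDr", ld, "ratio")
      add(paste0("relAUC_", iv, "_pos", sfx), "MorphD", "AreaDr", ld, "ratio")
      add(paste0("relAUC_", iv, "_neg", sfx), "MorphD", "AreaDr", ld, "ratio")
      add(paste0("relAUC_", iv, "_abs", sfx), "MorphD", "AreaDr", ld, "ratio")
    }
    add(paste0("relAUC_qrst_pos", sfx), "MorphD", "AreaDr", ld, "ratio")
    add(paste0("relAUC_qrst_neg", sfx), "MorphD", "AreaDr", ld, "ratio")
    add(paste0("relAUC_qrst_abs", sfx), "MorphD", "AreaDr", ld, "ratio")
    for (iv in c("qrs", "stt", "qrst"))
      add(paste0("ratioAUC_", iv, sfx), "MorphD", "AreaDr", ld, "ratio")
  }

  ## ---- MorphR: 22 per lead ----------------------------------------------
  for (ld in c("I", "II")) {
    sfx <- paste0("_", ld)
    add(paste0("Rmax", sfx),       "MorphR", "CommonR", ld, "mV")
    add(paste0("Rmax_pos", sfx),   "MorphR", "CommonR", ld, "ms")
    add(paste0("Rmin", sfx),       "MorphR", "CommonR", ld, "mV")
    add(paste0("Rmin_pos", sfx),   "MorphR", "CommonR", ld, "ms")
    add(paste0("Rrange", sfx),     "MorphR", "CommonR", ld, "mV")
    add(paste0("Rmaxmin_dt", sfx), "MorphR", "CommonR", ld, "ms")
    for (t in c(40, 60, 100))
      add(paste0("AUC_t", t, sfx), "MorphR", "AreaR", ld, "mV.s")
    for (t in c(40, 60, 100))
      add(paste0("AUC_t", t, "_abs", sfx), "MorphR", "AreaRa", ld, "mV.s")
    add(paste0("AUC_full", sfx),     "MorphR", "AreaR", ld, "mV.s")
    add(paste0("AUC_full_pos", sfx), "MorphR", "AreaR", ld, "mV.s")
    add(paste0("AUC_full_neg", sfx), "MorphR", "AreaR", ld, "mV.s")
    for (t in c(40, 60, 100))
      add(paste0("relAUC_t", t, sfx), "MorphR", "AreaR", ld, "ratio")
    for (t in c(40, 60, 100))
      add(paste0("relAUC_t", t, "_abs", sfx), "MorphR", "AreaRa", ld, "ratio")
    add(paste0("ratioAUC_full", sfx), "MorphR", "AreaR", ld, "ratio")
  }

  ## ---- SpectralD / SpectralR: 12-per-lead battery -----------------------
  battery <- function(fam, sub, prefix = "") {
    for (ld in c("I", "II")) {
      sfx <- paste0("_", ld)
      add(paste0(prefix, "FFT_0_35", sfx),    fam, sub, ld, "mV2")
      add(paste0(prefix, "FFT_35_90", sfx),   fam, sub, ld, "mV2")
      add(paste0(prefix, "FFT_125_250", sfx), fam, sub, ld, "mV2")
      add(paste0(prefix, "STFT_mean", sfx),   fam, sub, ld, "mV")
      add(paste0(prefix, "STFT_med", sfx),    fam, sub, ld, "mV")
      add(paste0(prefix, "STFT_max", sfx),    fam, sub, ld, "mV")
      add(paste0(prefix, "CWT_mean", sfx),    fam, sub, ld, "mV")
      add(paste0(prefix, "CWT_max", sfx),     fam, sub, ld, "mV")
      add(paste0(prefix, "CWT_corr_pos", sfx),   fam, sub, ld, "ratio")
      add(paste0(prefix, "CWT_corr_scale", sfx), fam, sub, ld, "ratio")
      add(paste0(prefix, "WVD_max", sfx),  fam, sub, ld, "mV2")
      add(paste0(prefix, "WVD_mean", sfx), fam, sub, ld, "mV2")
    }
  }
  battery("SpectralD", "SpectralD")
  for (t in c(20, 30, 50))
    battery("SpectralR", paste0("S", t), prefix = paste0("S", t, "_"))

  reg <- do.call(rbind, rows)
  .registry_cache$full <- reg
  if (!is.null(family)) reg <- reg[reg$family %in% family, , drop = FALSE]
  rownames(reg) <- NULL
  reg
}

.registry_cache <- new.env(parent = emptyenv())

#' Export the feature registry as JSON
#'
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(path) {
  jsonlite::write_json(feature_registry(), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
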