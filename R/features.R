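#' Extract a feature matrix from a list of beats
#'
#' Runs the requested extractor families on every beat and assembles the
#' feature matrix in registry order.
#'
#' @param beats list of `ecg_beat` objects (ground-truth fiducials are
#'   used for the delineation-based families).
#' @param families subset of `c("MorphD", "MorphR", "SpectralD",
#'   "SpectralR")`.
#' @return object of class `feature_table`: list with `matrix` (beats x
#'   features, registry-ordered column names), `labels` (beat-class
#'   factor) and `registry` (the matching registry rows).
#' @export
extract_features <- function(beats,
                             families = c("MorphD", "MorphR",
                                          "SpectralD", "SpectralR")) {
  families <- match.arg(families, several.ok = TRUE)
  stopifnot(length(beats) >= 1)
  reg <- feature_registry(families)
  one <- function(b) {
    v <- c()
    if ("MorphD" %in% families) v <- c(v, extract_morphD(b))
    if ("MorphR" %in% families) v <- c(v, as.vector(extract_morphR(b)) |>
                                         stats::setNames(feature_registry("MorphR")$name))
    if ("SpectralD" %in% families) v <- c(v, extract_spectralD(b))
    if ("SpectralR" %in% families) v <- c(v, as.vector(extract_spectralR(b)) |>
                                            stats::setNames(feature_registry("SpectralR")$name))
    v[reg$name]
  }
  mat <- t(vapply(beats, one, numeric(nrow(reg))))
  colnames(mat) <- reg$name
  labels <- as_beat_class(vapply(beats, function(b) b$label, ""))
  structure(list(matrix = mat, labels = labels, registry = reg),
            class = "feature_table")
}
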