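#' Heartbeat class labels
#'
#' The four beat classes of the study, with a stable integer coding used
#' throughout (confusion matrices, generated labels): non-ischemic sinus
#' beats (`NOR`), moderate ischemic beats (`ISM`, 5th minute of global
#' ischemia, slight ST/QRS changes), severe ischemic beats (`ISE`, 10th
#' minute, prominent QRS widening, large ST deviation, inverted T) and
#' ventricular premature beats (`VPB`, wide bizarre complexes occurring
#' early).
#'
#' @format Character vector of length 4; `match(label, beat_classes())`
#'   gives the integer coding 1..4.
#' @export
beat_classes <- function() c("NOR", "ISM", "ISE", "VPB")

#' Coerce labels to the beat-class factor
#'
#' @param x character or factor of class labels.
#' @return factor with levels `NOR, ISM, ISE, VPB`.
#' @export
as_beat_class <- function(x) {
  f <- factor(as.character(x), levels = beat_classes())
  if (anyNA(f)) stop("unknown beat class label(s): ",
                     paste(unique(setdiff(as.character(x), beat_classes())), collapse = ", "))
  f
}

# deterministic substream seed for beat `counter` under root `seed`
# (Lehmer step; exact in double arithmetic since 48271 * 2^31 < 2^53)
derive_seed <- function(seed, counter) {
  s <- (abs(as.numeric(seed)) + as.numeric(counter)) %% 2147483647
  as.integer((s * 48271 + 1) %% 2147483647)
}
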