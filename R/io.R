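#' Write / read a two-lead record as delimited text + JSON annotations
#'
#' The record file is tab-separated with columns `time_s`, `leadI_mV`,
#' `leadII_mV`; annotations (0-based sample indices) go to a JSON sidecar
#' `<path>.ann.json`.
#'
#' @param record an `ecg_record`.
#' @param path output file path for the signal table.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  N <- ncol(record$signal)
  df <- data.frame(time_s = (0:(N - 1)) / record$fs,
                   leadI_mV = record$signal[1, ],
                   leadII_mV = record$signal[2, ])
  utils::write.table(format(df, digits = 15, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = record$fs, annotations = record$annotations),
                       paste0(path, ".ann.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_record
#' @return for `read_record`: the reconstructed `ecg_record`.
#' @export
read_record <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("time_s", "leadI_mV", "leadII_mV")
  if (!identical(names(df), need))
    stop("malformed record header: expected ", paste(need, collapse = ", "),
         " got ", paste(names(df), collapse = ", "))
  side <- paste0(path, ".ann.json")
  ann <- NULL; fs <- NULL
  if (file.exists(side)) {
    j <- jsonlite::read_json(side, simplifyVector = TRUE)
    fs <- j$fs
    ann <- as.data.frame(j$annotations)
  }
  if (is.null(fs)) fs <- round(1 / stats::median(diff(df$time_s)))
  structure(list(signal = rbind(I = df$leadI_mV, II = df$leadII_mV),
                 fs = fs, annotations = ann),
            class = "ecg_record")
}

#' Write / read a feature table as CSV
#'
#' One row per beat; `beat_id` and `label` columns followed by the
#' feature columns in registry order. `read_features` validates the
#' header against the registry and reports the offending column.
#'
#' @param ft a `feature_table` (see [extract_features()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(beat_id = seq_len(nrow(ft$matrix)),
                   label = as.character(ft$labels))
  df <- cbind(df, as.data.frame(ft$matrix))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @return for `read_features`: the reconstructed `feature_table`.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("beat_id", "label") %in% names(df)[1:2]))
    stop("malformed feature table: first columns must be beat_id, label")
  feat <- setdiff(names(df), c("beat_id", "label"))
  reg <- feature_registry()
  unknown <- setdiff(feat, reg$name)
  if (length(unknown))
    stop("unknown feature column(s): ", paste(unknown, collapse = ", "),
         " (column ", which(names(df) %in% unknown)[1], ")")
  mat <- as.matrix(df[, feat, drop = FALSE])
  structure(list(matrix = mat, labels = as_beat_class(df$label),
                 registry = reg[match(feat, reg$name), , drop = FALSE]),
            class = "feature_table")
}
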