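#' Per-class Shapiro-Wilk normality scan
#'
#' Reports the Shapiro-Wilk p-value of every feature within every class.
#' The scan motivates the non-parametric selection path; it does not gate
#' the pipeline. Constant-within-class features are flagged and reported
#' with p = 0.
#'
#' @param matrix beats x features numeric matrix.
#' @param labels beat-class factor/character, one per row.
#' @return list with `p` (features x classes matrix of p-values) and
#'   `degenerate` (logical matrix flagging constant feature/class cells).
#' @export
normality_scan <- function(matrix, labels) {
  labels <- as_beat_class(labels)
  cls <- levels(labels)
  p <- deg <- base::matrix(NA_real_, ncol(matrix), length(cls),
                           dimnames = list(colnames(matrix), cls))
  for (ci in seq_along(cls)) {
    idx <- labels == cls[ci]
    if (sum(idx) < 3) next
    for (j in seq_len(ncol(matrix))) {
      x <- matrix[idx, j]
      if (diff(range(x)) == 0) { p[j, ci] <- 0; deg[j, ci] <- TRUE }
      else { p[j, ci] <- stats::shapiro.test(x)$p.value; deg[j, ci] <- FALSE }
    }
  }
  list(p = p, degenerate = deg == TRUE)
}

#' Kruskal-Wallis test for one feature
#'
#' Thin wrapper around [stats::kruskal.test()] (mid-rank ties with tie
#' correction, chi-square reference with groups-1 degrees of freedom),
#' with the degenerate all-equal case mapped to H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param labels group labels, one per value.
#' @return list with `H` and `p`.
#' @export
kruskal_wallis <- function(values, labels) {
  if (diff(range(values)) == 0) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(values, factor(labels))
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Tukey-Kramer all-pairs post-hoc on mean ranks
#'
#' Multiple comparison of group mean ranks after a Kruskal-Wallis test:
#' for each pair the statistic is the mean-rank difference divided by its
#' tie-corrected standard error (unequal group sizes allowed), referred
#' to the studentized-range distribution (infinite degrees of freedom),
#' the standard rank-based Tukey-Kramer procedure.
#'
#' @param values numeric vector.
#' @param labels group labels, one per value.
#' @return data.frame with columns `group1`, `group2`, `p`; one row per
#'   unordered pair, ordered by class coding. Pairs involving a group
#'   with fewer than 2 observations get p = 1 and `flagged = TRUE`.
#' @export
posthoc_all_pairs <- function(values, labels) {
  labels <- factor(labels)
  cls <- levels(labels)
  k <- length(cls)
  N <- length(values)
  r <- rank(values)                       # mid-ranks
  n <- tabulate(labels, nbins = k)
  rbar <- tapply(r, labels, mean)
  # tie-corrected rank variance
  ties <- table(values)
  tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tiecor
  pairs <- utils::combn(k, 2)
  out <- data.frame(group1 = cls[pairs[1, ]], group2 = cls[pairs[2, ]],
                    p = NA_real_, flagged = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    if (n[a] < 2 || n[b] < 2 || v <= 0) {
      out$p[i] <- 1; out$flagged[i] <- TRUE; next
    }
    se <- sqrt(v * (1 / n[a] + 1 / n[b]))
    q <- sqrt(2) * abs(rbar[[a]] - rbar[[b]]) / se
    out$p[i] <- stats::ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
  }
  out
}

#' Filter-method feature selection
#'
#' Keeps only features that differ significantly between every pair of
#' the four classes: Kruskal-Wallis followed by the Tukey-Kramer
#' all-pairs post-hoc; a feature is retained iff all six pairwise p-values
#' fall below `alpha`. The Shapiro-Wilk scan is reported alongside. No
#' correction across features is applied.
#'
#' @param matrix beats x features numeric matrix (finite).
#' @param labels beat-class labels, one per row.
#' @param alpha significance level (default 0.05).
#' @return object of class `selection_result`: list with `retained`
#'   (feature names, registry order preserved), `pairwise_p` (features x
#'   pairs matrix), `kw` (data.frame of H and p per feature), `shapiro`
#'   (the [normality_scan()] output) and `alpha`.
#' @export
filter_features <- function(matrix, labels, alpha = 0.05) {
  stopifnot(all(is.finite(matrix)))
  labels <- as_beat_class(labels)
  nf <- ncol(matrix)
  kw <- data.frame(feature = colnames(matrix), H = NA_real_, p = NA_real_)
  pair_names <- NULL
  pw <- NULL
  for (j in seq_len(nf)) {
    k <- kruskal_wallis(matrix[, j], labels)
    kw$H[j] <- k$H; kw$p[j] <- k$p
    ph <- posthoc_all_pairs(matrix[, j], labels)
    if (is.null(pw)) {
      pair_names <- paste(ph$group1, ph$group2, sep = "-")
      pw <- base::matrix(NA_real_, nf, length(pair_names),
                         dimnames = list(colnames(matrix), pair_names))
    }
    pw[j, ] <- ph$p
  }
  retained <- colnames(matrix)[apply(pw < alpha, 1, all)]
  structure(list(retained = retained, pairwise_p = pw, kw = kw,
                 shapiro = normality_scan(matrix, labels), alpha = alpha),
            class = "selection_result")
}

#' Map retained features to study subgroups
#'
#' @param selection a `selection_result`.
#' @param registry the feature registry (default [feature_registry()]).
#' @return named list of character vectors: retained feature names per
#'   (family, subgroup), plus one entry per whole family.
#' @export
selection_subgroups <- function(selection, registry = feature_registry()) {
  reg <- registry[registry$name %in% selection$retained, , drop = FALSE]
  out <- list()
  for (fam in unique(reg$family))
    out[[fam]] <- reg$name[reg$family == fam]
  for (sg in unique(reg$subgroup))
    out[[sg]] <- reg$name[reg$subgroup == sg]
  out
}
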