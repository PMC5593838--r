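#' The nine benchmark classifier configurations
#'
#' Discriminant function analysis (linear, quadratic), naive Bayes
#' (Gaussian, kernel-density), one-vs-all support vector machines
#' (linear, RBF) and k-nearest neighbours (k = 1, 5, 10).
#'
#' @return list of model specs; each a list with `family`, `variant`,
#'   `label` and `hyper`.
#' @export
model_specs <- function() {
  spec <- function(family, variant, hyper = list())
    list(family = family, variant = variant,
         label = paste(family, variant, sep = "_"), hyper = hyper)
  list(
    spec("kNN", "k1", list(k = 1)),
    spec("kNN", "k5", list(k = 5)),
    spec("kNN", "k10", list(k = 10)),
    spec("DFA", "linear"),
    spec("DFA", "quadratic"),
    spec("NB", "gaussian"),
    spec("NB", "kernel"),
    spec("SVM", "rbf", list(cost = 1)),
    spec("SVM", "linear", list(cost = 1))
  )
}

#' Per-fold feature standardization
#'
#' Z-scores both matrices with the training mean and SD. Features with
#' zero training SD are mapped to 0 and flagged.
#'
#' @param train,test numeric matrices with identical columns.
#' @return list with `train`, `test`, `mean`, `sd`, `constant` (logical).
#' @export
standardize_fold <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  const <- !is.finite(sd) | sd == 0
  sd[const] <- 1
  ztr <- sweep(sweep(train, 2, mu), 2, sd, "/")
  zte <- sweep(sweep(test, 2, mu), 2, sd, "/")
  ztr[, const] <- 0
  zte[, const] <- 0
  list(train = ztr, test = zte, mean = mu, sd = sd, constant = const)
}

## ---- model fitting (standardized inputs) --------------------------------

# Gaussian discriminant analysis with a small ridge on the covariance
# diagonal: pooled covariance for the linear variant, per-class for the
# quadratic one. Priors = class proportions.
dfa_fit <- function(X, y, variant, ridge = 1e-6) {
  cls <- levels(y)
  p <- ncol(X)
  means <- lapply(cls, function(c) colMeans(X[y == c, , drop = FALSE]))
  priors <- as.vector(table(y)) / length(y)
  if (variant == "linear") {
    S <- matrix(0, p, p)
    for (c in cls) {
      Xc <- X[y == c, , drop = FALSE]
      S <- S + crossprod(sweep(Xc, 2, colMeans(Xc)))
    }
    S <- S / (nrow(X) - length(cls)) + ridge * diag(p)
    covs <- rep(list(S), length(cls))
  } else {
    covs <- lapply(cls, function(c) {
      Xc <- X[y == c, , drop = FALSE]
      stats::cov(Xc) + ridge * diag(p)
    })
  }
  list(means = means, covs = covs, priors = priors, cls = cls,
       variant = variant)
}

dfa_predict <- function(fit, X) {
  k <- length(fit$cls)
  sc <- matrix(NA_real_, nrow(X), k)
  for (ci in seq_len(k)) {
    ch <- chol(fit$covs[[ci]])
    d <- forwardsolve(t(ch), t(sweep(X, 2, fit$means[[ci]])))
    m2 <- colSums(d^2)
    logdet <- 2 * sum(log(diag(ch)))
    sc[, ci] <- -0.5 * (m2 + logdet) + log(fit$priors[ci])
  }
  factor(fit$cls[max.col(sc, ties.method = "first")], levels = fit$cls)
}

# kernel-density naive Bayes: per feature per class Gaussian KDE with
# Silverman's rule-of-thumb bandwidth
nbk_fit <- function(X, y) {
  cls <- levels(y)
  list(cls = cls, priors = as.vector(table(y)) / length(y),
       data = lapply(cls, function(c) X[y == c, , drop = FALSE]))
}

nbk_predict <- function(fit, X) {
  k <- length(fit$cls)
  ll <- matrix(log(fit$priors), nrow(X), k, byrow = TRUE)
  for (ci in seq_len(k)) {
    Xc <- fit$data[[ci]]
    n <- nrow(Xc)
    for (j in seq_len(ncol(X))) {
      xj <- Xc[, j]
      sdj <- stats::sd(xj)
      h <- if (is.finite(sdj) && sdj > 0) 0.9 * min(sdj, stats::IQR(xj) / 1.34) *
             n^(-1 / 5) else 0
      if (h <= 0) h <- max(1e-3, abs(mean(xj)) * 1e-3 + 1e-3)
      dens <- vapply(X[, j], function(x0)
        mean(stats::dnorm(x0, mean = xj, sd = h)), 0)
      ll[, ci] <- ll[, ci] + log(pmax(dens, 1e-300))
    }
  }
  factor(fit$cls[max.col(ll, ties.method = "first")], levels = fit$cls)
}

# deterministic k-NN on standardized features (Euclidean); vote ties are
# broken by the class of the single nearest neighbour
knn_predict <- function(Xtr, ytr, Xte, k) {
  cls <- levels(ytr)
  d2 <- outer(rowSums(Xte^2), rep(1, nrow(Xtr))) +
        outer(rep(1, nrow(Xte)), rowSums(Xtr^2)) -
        2 * Xte %*% t(Xtr)
  pred <- character(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    o <- order(d2[i, ], decreasing = FALSE)
    nn <- o[seq_len(min(k, length(o)))]
    votes <- table(factor(ytr[nn], levels = cls))
    top <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(top) == 1) top else as.character(ytr[o[1]])
  }
  factor(pred, levels = cls)
}

# one-vs-all SVM (linear or RBF kernel, C = 1); class by maximal binary
# decision value, ties to the lowest class index
svm_ova_fit <- function(X, y, variant, cost = 1) {
  cls <- levels(y)
  gamma <- 1 / (ncol(X) * max(mean(apply(X, 2, stats::var)), 1e-12))
  fits <- lapply(cls, function(c) {
    yc <- factor(ifelse(y == c, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(X, yc, kernel = if (variant == "rbf") "radial" else "linear",
               cost = cost, gamma = gamma, scale = FALSE)
  })
  list(cls = cls, fits = fits)
}

svm_ova_predict <- function(fit, X) {
  dec <- vapply(seq_along(fit$cls), function(ci) {
    pr <- stats::predict(fit$fits[[ci]], X, decision.values = TRUE)
    dv <- attr(pr, "decision.values")[, 1]
    # orient toward the "pos" class whatever level ordering svm used
    if (grepl("^pos", colnames(attr(pr, "decision.values"))[1])) dv else -dv
  }, numeric(nrow(X)))
  factor(fit$cls[max.col(dec, ties.method = "first")], levels = fit$cls)
}

# fit + predict for one spec on standardized train/test
fit_predict <- function(spec, Xtr, ytr, Xte) {
  switch(spec$family,
    kNN = knn_predict(Xtr, ytr, Xte, spec$hyper$k),
    DFA = dfa_predict(dfa_fit(Xtr, ytr, spec$variant), Xte),
    NB = if (spec$variant == "gaussian") {
      fit <- e1071::naiveBayes(data.frame(Xtr), ytr)
      stats::predict(fit, data.frame(Xte))
    } else nbk_predict(nbk_fit(Xtr, ytr), Xte),
    SVM = svm_ova_predict(svm_ova_fit(Xtr, ytr, spec$variant,
                                      spec$hyper$cost), Xte),
    stop("unknown model family ", spec$family))
}

#' Confusion matrix (rows = true class, columns = prediction)
#'
#' @param true,pred equal-length label vectors over the four classes.
#' @return 4 x 4 integer matrix.
#' @export
confusion_matrix <- function(true, pred) {
  true <- as_beat_class(true); pred <- as_beat_class(pred)
  stopifnot(length(true) == length(pred))
  table(true = true, pred = pred)
}

# stratified fold assignment: within each class, shuffled indices are
# dealt round-robin over folds
stratified_folds <- function(labels, folds, seed) {
  set.seed(derive_seed(seed, 7e7))
  assign <- integer(length(labels))
  for (c in levels(labels)) {
    idx <- which(labels == c)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Cross-validated evaluation of one classifier configuration
#'
#' Stratified k-fold cross-validation with per-fold standardization
#' (training mean/SD applied to both partitions). Reports per-fold and
#' mean overall accuracy, per-class sensitivity and specificity
#' (one-vs-rest) and the confusion matrix cumulated across folds.
#'
#' @param spec a model spec from [model_specs()].
#' @param matrix beats x features numeric matrix.
#' @param labels beat-class labels, one per row.
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return object of class `cv_report`: list with `model`, `fold_acc`,
#'   `mean_acc`, `sensitivity`, `specificity` (per class), `confusion`,
#'   `predictions`, `fold_assignment`, `seed`.
#' @export
cross_validate <- function(spec, matrix, labels, folds = 10, seed = 1L) {
  labels <- as_beat_class(labels)
  present <- levels(labels)[table(labels) > 0]
  if (any(table(labels)[present] < folds))
    warning("some class has fewer members than folds; ",
            "folds will not all contain every class")
  fa <- stratified_folds(labels, folds, seed)
  pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    te <- fa == f
    z <- standardize_fold(matrix[!te, , drop = FALSE],
                          matrix[te, , drop = FALSE])
    ytr <- droplevels(labels[!te])
    p <- fit_predict(spec, z$train, ytr, z$test)
    pred[te] <- factor(as.character(p), levels = levels(labels))
    fold_acc[f] <- mean(p == labels[te])
  }
  cm <- confusion_matrix(labels, pred)
  tp <- diag(cm)
  se <- tp / rowSums(cm)
  sp <- vapply(seq_len(nrow(cm)), function(c) {
    tn <- sum(cm[-c, -c]); fp <- sum(cm[-c, c])
    tn / (tn + fp)
  }, 0)
  names(sp) <- rownames(cm)
  structure(list(model = spec$label, fold_acc = fold_acc,
                 mean_acc = mean(fold_acc), sensitivity = se,
                 specificity = sp, confusion = cm, predictions = pred,
                 fold_assignment = fa, seed = seed),
            class = "cv_report")
}

#' Benchmark feature groups against classifier configurations
#'
#' Runs [cross_validate()] for every (feature group, model) pair and
#' collects mean accuracies in a groups x models grid.
#'
#' @param feature_groups named list of character vectors of column names.
#' @param models list of model specs (default all nine).
#' @param matrix beats x features matrix with named columns.
#' @param labels beat-class labels.
#' @param folds number of folds (default 10).
#' @param seed integer seed.
#' @return list with `grid` (mean accuracy matrix, groups as rows) and
#'   `reports` (nested list of full `cv_report`s).
#' @export
run_benchmark <- function(feature_groups, models = model_specs(), matrix,
                          labels, folds = 10, seed = 1L) {
  stopifnot(length(feature_groups) >= 1)
  mlab <- vapply(models, function(m) m$label, "")
  grid <- base::matrix(NA_real_, length(feature_groups), length(models),
                       dimnames = list(names(feature_groups), mlab))
  reports <- list()
  for (g in names(feature_groups)) {
    cols <- feature_groups[[g]]
    if (!all(cols %in% colnames(matrix)))
      stop("feature group ", g, " references unknown columns")
    reports[[g]] <- list()
    for (mi in seq_along(models)) {
      rep <- cross_validate(models[[mi]], matrix[, cols, drop = FALSE],
                            labels, folds, seed)
      grid[g, mlab[mi]] <- rep$mean_acc
      reports[[g]][[mlab[mi]]] <- rep
    }
  }
  list(grid = grid, reports = reports)
}
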