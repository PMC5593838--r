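#!/usr/bin/env Rscript
# Step 5 -- cross-validated benchmark of the nine classifier
# configurations over the selected feature groups and subgroups.
#
# 10-fold stratified cross-validation with per-fold standardization.
# Outputs: the mean-accuracy grid (groups x models), per-class
# sensitivity/specificity for the best approaches, and the cumulated
# confusion matrix of linear DFA on the CommonR subgroup.

library(ecgbeats)

seed <- 1L
ft <- read_features("results/03_features.csv")
reg <- feature_registry()
retained <- readLines("results/04_retained_features.txt")

groups <- list()
for (fam in unique(reg$family)) {
  keep <- intersect(retained, reg$name[reg$family == fam])
  if (length(keep) >= 2) groups[[fam]] <- keep
}
for (sg in setdiff(unique(reg$subgroup), unique(reg$family))) {
  keep <- intersect(retained, reg$name[reg$subgroup == sg])
  if (length(keep) >= 2) groups[[sg]] <- keep
}

t0 <- proc.time()["elapsed"]
bench <- run_benchmark(groups, model_specs(), ft$matrix, ft$labels,
                       folds = 10, seed = seed)
cat(sprintf("benchmark: %d groups x %d models in %.0f s\n",
            length(groups), length(model_specs()),
            proc.time()["elapsed"] - t0))

grid_pct <- round(100 * bench$grid, 1)
write.csv(data.frame(group = rownames(grid_pct), grid_pct,
                     check.names = FALSE),
          "results/05_benchmark_grid.csv", row.names = FALSE)
print(grid_pct)

# per-class Se/Sp for the headline approaches
picks <- list(c("AreaD", "kNN_k5"), c("AreaD", "SVM_rbf"),
              c("CommonR", "DFA_linear"))
sesp <- do.call(rbind, lapply(picks, function(p) {
  if (is.null(bench$reports[[p[1]]])) return(NULL)
  r <- bench$reports[[p[1]]][[p[2]]]
  data.frame(group = p[1], model = p[2], class = beat_classes(),
             sensitivity = round(100 * as.numeric(r$sensitivity), 1),
             specificity = round(100 * as.numeric(r$specificity), 1),
             mean_acc = round(100 * r$mean_acc, 1))
}))
write.csv(sesp, "results/05_sensitivity_specificity.csv", row.names = FALSE)
print(sesp)

if (!is.null(bench$reports$CommonR$DFA_linear)) {
  cm <- bench$reports$CommonR$DFA_linear$confusion
  write.csv(as.data.frame.matrix(cm), "results/05_confusion_dfa_commonR.csv")
  cat("\ncumulated confusion matrix, linear DFA on CommonR:\n")
  print(cm)
}
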