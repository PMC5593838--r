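#!/usr/bin/env Rscript
# Step 4 -- filter-method feature selection per family.
#
# Shapiro-Wilk (distribution scan, motivating the non-parametric path),
# Kruskal-Wallis (alpha = 0.05) and Tukey-Kramer all-pairs post-hoc on
# mean ranks; a feature is kept only when every one of the six class
# pairs differs significantly.

library(ecgbeats)

ft <- read_features("results/03_features.csv")
reg <- feature_registry()

rows <- list()
retained_all <- character(0)
for (fam in unique(reg$family)) {
  cols <- reg$name[reg$family == fam]
  sel <- filter_features(ft$matrix[, cols, drop = FALSE], ft$labels)
  retained_all <- c(retained_all, sel$retained)
  # normality: how often is within-class normality rejected?
  swrej <- mean(sel$shapiro$p < 0.05, na.rm = TRUE)
  for (sg in unique(reg$subgroup[reg$family == fam])) {
    keep <- intersect(sel$retained, reg$name[reg$subgroup == sg])
    rows[[length(rows) + 1]] <- data.frame(
      family = fam, subgroup = sg,
      registry_size = sum(reg$subgroup == sg),
      retained = length(keep), shapiro_reject_rate = swrej)
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/04_selection_summary.csv", row.names = FALSE)
writeLines(retained_all, "results/04_retained_features.txt")
print(tab, digits = 3)
cat(sprintf("\nretained %d / %d features overall\n",
            length(retained_all), nrow(reg)))
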