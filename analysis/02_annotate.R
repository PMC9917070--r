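#!/usr/bin/env Rscript
# Stage 2: tiered library annotation.
#
# Assigns every feature against the 46-standard library and its sulfate /
# glucuronide conjugate target space: identified (mass + RT), isomer (mass
# only), conjugate_tentative (mass-shift match), or unassigned.

library(baprofiler)

src <- "results/synthetic"
features <- read_features(file.path(src, "features.csv"))
targets <- build_target_list(ba_library())
ann <- annotate_features(features, targets)
write.csv(ann, file.path(src, "..", "annotations.csv"), row.names = FALSE)

cat("tier counts over all samples:\n")
print(table(ann$tier))

groups <- group_isomers(ann)
cat(sprintf("\n%d formulas with isomer-tier features:\n", length(groups)))
for (fm in names(groups)) {
  g <- groups[[fm]]
  cat(sprintf("  %-10s %-18s %d features at RT %s\n", fm,
              g$target_name[1], nrow(g),
              paste(sort(unique(round(g$rt_min, 1))), collapse = ", ")))
}
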