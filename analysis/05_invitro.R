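#!/usr/bin/env Rscript
# Stage 5: in-vitro metabolite calling and plasma cross-matching.
#
# Calls metabolites of the nine incubated standards against their no-NADP+
# and no-PAPS controls (>= 5-fold over the control floor; cofactor
# dependence from which single control lacks the peak), then matches the
# calls to the significantly increased plasma isomers/conjugates by
# identical formula and retention time.

library(baprofiler)

src <- "results/synthetic"
manifest <- read.csv(file.path(src, "invitro_manifest.csv"),
                     stringsAsFactors = FALSE)
results <- read.csv("results/differential.csv", stringsAsFactors = FALSE)
lib <- analyte_library(ba_library())

calls <- do.call(rbind, lapply(split(manifest, manifest$parent), function(m) {
  feats <- lapply(m$path, read_features)
  names(feats) <- m$condition
  call_metabolites(feats[["full"]],
                   feats[intersect(c("no_NADP", "no_PAPS"), names(feats))],
                   lib[lib$name == m$parent[1], ])
}))
rownames(calls) <- NULL
write.csv(calls, "results/invitro_calls.csv", row.names = FALSE)
cat(sprintf("%d metabolite calls over %d parents\n", nrow(calls),
            length(unique(calls$parent))))
print(table(calls$parent, calls$delta_name))

plasma_sig <- results[results$significant &
                        results$tier %in% c("isomer", "conjugate_tentative"), ]
matches <- cross_match(plasma_sig, calls, rt_tol = 0.3)
write.csv(matches, "results/invitro_matches.csv", row.names = FALSE)

cat(sprintf("\n%d of %d significant plasma isomers/conjugates co-elute with an in-vitro metabolite:\n",
            nrow(matches), nrow(plasma_sig)))
print(matches, row.names = FALSE, digits = 4)
cat(sprintf("sulfate calls matching plasma: %d\n",
            sum(matches$delta_name == "sulfation")))
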