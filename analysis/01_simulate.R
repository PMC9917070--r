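#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Produces the default 4-dose x 3-replicate plasma study (46 standards, 14
# internal standards, 22 isomer placements, 19 phase-II conjugates + 1
# taurine/sulfate reassignment case, 15 decoys) with planted ground truth,
# plus the nine-parent S9 incubation suite with no-cofactor controls.
# Everything downstream reads from results/synthetic/.

library(baprofiler)

seed <- 17L
out <- "results/synthetic"
dir.create(file.path(out, "invitro"), recursive = TRUE, showWarnings = FALSE)

cfg <- default_scenario(seed)
study <- make_plasma_study(cfg)
suite <- make_invitro_suite(cfg)

write.csv(study$features, file.path(out, "features.csv"), row.names = FALSE)
write.csv(study$design, file.path(out, "design.csv"), row.names = FALSE)
write.csv(study$truth, file.path(out, "truth.csv"), row.names = FALSE)
write_mgf(study$spectra, file.path(out, "spectra.mgf"))

manifest <- do.call(rbind, lapply(names(suite$runs), function(p) {
  safe <- gsub("[^A-Za-z0-9]+", "_", p)
  runs <- c(list(full = suite$runs[[p]]$full), suite$runs[[p]]$controls)
  do.call(rbind, lapply(names(runs), function(cond) {
    path <- file.path(out, "invitro", sprintf("%s_%s.csv", safe, cond))
    write.csv(runs[[cond]], path, row.names = FALSE)
    data.frame(run_id = sprintf("%s_%s", safe, cond), parent = p,
               condition = cond, path = path)
  }))
}))
write.csv(manifest, file.path(out, "invitro_manifest.csv"), row.names = FALSE)
write.csv(suite$truth, file.path(out, "invitro_truth.csv"), row.names = FALSE)

cat(sprintf("seed %d: %d features across %d samples, %d MS/MS spectra\n",
            seed, nrow(study$features), nrow(study$design),
            length(study$spectra)))
cat(sprintf("in-vitro suite: %d parents, %d planned metabolites\n",
            length(suite$runs), nrow(suite$truth)))
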