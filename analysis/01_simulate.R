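#!/usr/bin/env Rscript
# Generate example synthetic subjects (one per species) and write them to
# results/subjects/ as GIFTI surfaces, overlays and JSON labels, with a
# parameter sidecar. These bundles are the raw material every later stage
# consumes; the cohort runs regenerate them in memory from seeds.

suppressMessages(library(sulcmap))
SEED <- 1L
out_root <- "results/subjects"

for (sp in c("human", "macaque")) {
  preset <- species_preset(sp)
  patch <- generate_v1_patch(preset, subject_id = paste0(sp, "_demo"),
                             seed = SEED)
  dir <- file.path(out_root, paste0(sp, "_demo"))
  paths <- write_subject(patch, dir, format = "gifti")
  ecc <- patch$truth$true_map$eccentricity$values
  cat(sprintf(
    "%s: %d vertices, V1 %.0f mm2 (pial), eccentricity 0-%.2f deg, rCaS %d vertices (%.2f-%.2f deg), eCaS %d (%.2f-%.2f deg)\n",
    sp, nrow(patch$pial$vertices), surface_area(patch$pial),
    max(ecc),
    length(patch$truth$labels$labels$rCaS),
    min(ecc[patch$truth$labels$labels$rCaS]),
    max(ecc[patch$truth$labels$labels$rCaS]),
    length(patch$truth$labels$labels$eCaS),
    min(ecc[patch$truth$labels$labels$eCaS]),
    max(ecc[patch$truth$labels$labels$eCaS])))
  cat("  wrote", length(paths), "files under", dir, "\n")
}
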