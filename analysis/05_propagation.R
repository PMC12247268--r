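#!/usr/bin/env Rscript
# Seizure propagation analysis: staged cross-correlation between the
# seizure-onset lead and the most distant lead, and staged PLV
# networks, contrasting pathway propagation (staggered recruitment,
# moderate late coupling) with volume conduction (near-simultaneous
# onset, late-stage correlation close to 1).

suppressMessages(library(svdcfield))

res_dir <- "results"
dir.create(res_dir, showWarnings = FALSE, recursive = TRUE)
manifest <- read.delim("scratch/study/manifest.tsv")

cc_rows <- list()
plv_rows <- list()
for (i in seq_len(nrow(manifest))) {
  rec <- read_edf(file.path("scratch/study", manifest$file[i]))
  rep <- run_ictal_analysis(rec, onset_s = manifest$onset_s[i])
  cc <- rep$staged_correlation
  cc$file <- manifest$file[i]
  cc$propagation <- manifest$propagation[i]
  cc$pair <- paste(rep$corr_pair, collapse = "-")
  cc_rows[[i]] <- cc
  sp <- rep$staged_plv$stages
  sp$file <- manifest$file[i]
  sp$propagation <- manifest$propagation[i]
  plv_rows[[i]] <- sp
}
cc_tbl <- do.call(rbind, cc_rows)
plv_tbl <- do.call(rbind, plv_rows)
write.table(cc_tbl, file.path(res_dir, "staged_cross_correlation.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(plv_tbl, file.path(res_dir, "staged_plv.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

cat("Staged cross-correlation (HF band, onset lead vs distal lead):\n")
print(cc_tbl[, c("file", "propagation", "stage", "rho")])
cat("\nStaged mean off-diagonal PLV:\n")
print(plv_tbl[, c("file", "propagation", "stage", "mean_plv")])
cat("\nVolume-conduction seizures reach near-unity correlation in the",
    "final stage; pathway seizures couple more moderately.\n")
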