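#!/usr/bin/env Rscript

# Step 3 -- LOH and copy-number landscape.
# Compares the recovered LOH and CNV tracks against the planted truth for
# each strain: overlap (Jaccard) of LOH with planted tracts, mechanism
# classification (gene conversion vs heterozygous deletion), recovered
# amplifications, and the deleted fraction of each genome.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "00_panel.R"))

panel <- strain_panel()
rows <- list()
for (name in names(panel)) {
  dir <- file.path("results", "strains", name)
  loh <- read_bed(file.path(dir, "loh.bed"))
  cnv <- read_bed(file.path(dir, "cnv.bed"))
  del <- read_bed(file.path(dir, "deletions.bed"))
  truth_loh <- read_bed(file.path(dir, "truth_loh.bed"))
  truth_cnv <- read_bed(file.path(dir, "truth_cnv.bed"))
  truth_del <- read_bed(file.path(dir, "truth_deletions.bed"))
  prof <- jsonlite::read_json(file.path(dir, "profile.json"))

  loh_jac <- if (nrow(truth_loh) > 0) interval_jaccard(loh, truth_loh) else NA
  del_jac <- if (nrow(truth_del) > 0) interval_jaccard(del, truth_del) else NA
  amp <- cnv[cnv$score > prof$base_ploidy, ]
  amp_jac <- if (nrow(truth_cnv) > 0) interval_jaccard(amp, truth_cnv) else NA

  rows[[name]] <- data.frame(
    strain = name,
    pct_loh = round(prof$pct_loh, 2),
    pct_conversion = round(prof$pct_conversion_length, 1),
    pct_deleted = round(prof$pct_deleted, 3),
    loh_jaccard = round(loh_jac, 3),
    deletion_jaccard = round(del_jac, 3),
    amplification_jaccard = round(amp_jac, 3),
    n_amplified_segments = nrow(amp),
    stringsAsFactors = FALSE
  )
}
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)

out <- file.path(results_dir(), "loh_cnv_summary.tsv")
write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", out, "\n")
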