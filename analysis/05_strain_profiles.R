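#!/usr/bin/env Rscript

# Step 5 -- combined strain profiles.
# Collects the per-strain reports into one table: ploidy, allele balance,
# LOH extent and mechanism split, deleted fraction, and nitrate-cluster
# gene presence, in the style of a cross-strain genome-landscape summary.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "00_panel.R"))

panel <- strain_panel()
rows <- list()
for (name in names(panel)) {
  dir <- file.path("results", "strains", name)
  prof <- jsonlite::read_json(file.path(dir, "profile.json"))
  pres <- read.delim(file.path(dir, "gene_presence.tsv"), comment.char = "#")
  cluster <- pres[pres$id %in% c("YNT1", "YNR1", "YNI1"), ]
  rows[[name]] <- data.frame(
    strain = name,
    base_ploidy = prof$base_ploidy,
    genome_mean_maf = round(prof$genome_mean_maf, 3),
    pct_loh = round(prof$pct_loh, 1),
    pct_conversion = round(prof$pct_conversion_length, 1),
    pct_deleted = round(prof$pct_deleted, 3),
    nitrate_cluster = if (all(cluster$presence == "present")) "intact"
                      else "partially or fully lost",
    stringsAsFactors = FALSE
  )
}
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)

out <- file.path(results_dir(), "strain_profiles.tsv")
write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", out, "\n")

lost <- tab$strain[tab$nitrate_cluster != "intact"]
if (length(lost) > 0) {
  cat(sprintf("nitrate-assimilation capacity predicted lost in: %s\n",
              paste(lost, collapse = ", ")))
}
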