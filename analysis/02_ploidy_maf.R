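#!/usr/bin/env Rscript

# Step 2 -- base-ploidy inference from windowed allele balance.
# Reads the per-strain window tables written by 01_simulate_strains.R and
# summarises the genome-wide major-allele-frequency statistic each strain's
# ploidy call rests on (expected ~2/3 for a heterozygous triploid, ~1/2 --
# plus finite-depth sampling bias -- for a diploid).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "00_panel.R"))

panel <- strain_panel()
rows <- lapply(names(panel), function(name) {
  prof <- jsonlite::read_json(file.path("results", "strains", name,
                                        "profile.json"))
  data.frame(
    strain = name,
    base_ploidy = prof$base_ploidy,
    genome_mean_maf = round(prof$genome_mean_maf, 4),
    genome_sd_maf = round(prof$genome_sd_maf, 4),
    ambiguous = prof$ploidy_ambiguous,
    stringsAsFactors = FALSE
  )
})
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)

out <- file.path(results_dir(), "ploidy_summary.tsv")
write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", out, "\n")
cat(sprintf("triploid reference line 0.66: %s sits %s it; diploids read ~0.55\n",
            tab$strain[tab$base_ploidy == 3][1],
            ifelse(abs(tab$genome_mean_maf[tab$base_ploidy == 3][1] - 0.66) < 0.02,
                   "on", "off")))
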