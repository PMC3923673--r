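#!/usr/bin/env Rscript

# Step 4 -- per-locus haplotype assembly from co-occurring SNPs in reads.
# In the allotriploid strain, heterozygous sites come in two kinds: sparse
# core SNPs where the two conserved haplomes differ (~5/kb, typically
# farther apart than a read), and dense divergent-haplome SNPs (~50/kb)
# where the conserved pair is identical.  Phasing with 100 bp reads can
# therefore separate the conserved core sequence from the divergent third
# haplome -- but not the two near-identical core copies from each other,
# whose distinguishing sites reads cannot link.  This script selects a
# locus where the core pair is locally identical, assembles the two
# distinguishable haplotypes, and recovers their 2:1 allelic ratio from
# the site allele fractions.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE)[1])), "00_panel.R"))

panel <- strain_panel()
cfg <- panel$triploid_T1$config
truth <- simulate_genome(cfg)

pileup <- simulate_pileup(truth)
sites <- call_sites(pileup)
het_pos <- sites$pos[sites$zygosity == "heterozygous"]

## pick a ~600 bp locus outside planted events where (i) the two core
## haplomes are identical (no core SNP interrupts the conserved sequence),
## (ii) called heterozygous sites are dense enough that adjacent sites are
## spanned by one read
locus_width <- 600L
candidate_starts <- seq(100000L, 250000L - locus_width, by = 200L)
locus <- NULL
for (s in candidate_starts) {
  idx <- (s + 1L):(s + locus_width)
  if (any(truth$haplomes[1L, idx] != truth$haplomes[2L, idx])) next
  hs <- het_pos[het_pos >= s & het_pos < s + locus_width]
  if (length(hs) >= 6L && max(diff(hs)) < cfg$read_len - 10L) {
    locus <- c(s, s + locus_width)
    break
  }
}
stopifnot(!is.null(locus))
cat(sprintf("selected locus [%d,%d) with %d called het sites (core pair identical)\n",
            locus[1], locus[2], sum(het_pos >= locus[1] & het_pos < locus[2])))

reads <- simulate_reads(truth, locus, depth = 60)
cat(sprintf("simulated %d read observations from %d reads\n",
            nrow(reads), length(unique(reads$read_id))))

locus_sites <- sites[sites$pos >= locus[1] & sites$pos < locus[2] &
                     sites$zygosity == "heterozygous", ]

hapset <- assemble_haplotypes(reads, locus_sites, k_max = 3L)
hapset <- estimate_dosage(hapset, locus_sites, copy_number = 3L)
cat(sprintf("assembled %d haplotypes; dosage %s (support %s)\n",
            nrow(hapset$haplotypes),
            paste(hapset$haplotypes$dosage, collapse = ":"),
            paste(hapset$haplotypes$support, collapse = ",")))

out <- results_dir("haplotypes")
ref_seq <- paste(c("A", "C", "G", "T")[truth$haplomes[1L, (locus[1] + 1L):locus[2]]],
                 collapse = "")
write_haplotypes(hapset, ref_seq, locus, file.path(out, "triploid_T1_locus.fasta"))

report <- data.frame(
  locus = sprintf("%d-%d", locus[1], locus[2]),
  k = nrow(hapset$haplotypes),
  haplotype = hapset$haplotypes$sequence,
  support = hapset$haplotypes$support,
  dosage = hapset$haplotypes$dosage
)
write.table(report, file.path(out, "phasing_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", file.path(out, "triploid_T1_locus.fasta"), "and phasing_report.tsv\n")

## cross-check against the planted haplomes, restricted to the called sites
## (a site can drop from the call set when sampling pushes its minor allele
## under the 20% floor, so the assembled positions are the comparison basis)
planted <- apply(truth$haplomes[, hapset$positions + 1L, drop = FALSE], 1L,
                 function(h) paste(c("A", "C", "G", "T")[h], collapse = ""))
n_match <- sum(unique(planted) %in% hapset$haplotypes$sequence)
cat(sprintf("%d of %d distinct planted haplotypes recovered exactly\n",
            n_match, length(unique(planted))))
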