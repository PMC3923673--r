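---
title: "Inferring ploidy, LOH and copy number from windowed pileup statistics"
author: "ploidyscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ploidy, LOH and copy number from windowed pileup statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Industrial yeasts such as the wine-spoilage species *Dekkera* (*Brettanomyces*)
*bruxellensis* are frequently hybrids: a conserved, moderately heterozygous
diploid pair of chromosome sets, sometimes joined by a third, more divergent
set acquired through hybridisation (an allotriploid).  Short-read resequencing
against a draft reference lets three window-scale signals characterise such a
genome without any assembly:

1. **Allele balance.**  At a heterozygous site in a diploid the major
   (most frequent) allele is carried by one of two copies, so its read
   fraction centres on 1/2; in a triploid with a 2:1 allele dosage it
   centres on 2/3 (~0.66).  The genome-wide average of this statistic
   separates diploids from triploids.
2. **Loss of heterozygosity (LOH).**  Regions with no heterozygous sites in
   an otherwise heterozygous genome arise either by gene conversion (one
   allele overwrites its homolog; copy number preserved) or by deletion of
   a haplome (copy number reduced).  Which mechanism acted is read off the
   co-localised copy-number state.
3. **Read depth.**  Windowed depth, normalised so the genome median sits at
   the base ploidy, segments into integer copy-number states, revealing
   amplifications, heterozygous deletions and complete (homozygous)
   deletions — the latter also drive gene-presence calls such as loss of a
   nitrate-assimilation cluster.

`ploidyscape` implements this windowed analysis over a single concatenated
coordinate (draft-assembly contigs laid end to end), together with a
read-backed per-locus haplotype assembler and a synthetic genome simulator
that provides planted ground truth for every stage.

## Site calling

Sites come from per-position pileup summaries (`read_pileup()` parses the
6-column samtools-style text format; `simulate_pileup()` produces the same
table directly).  The calling rules are deliberately simple:

* minimum depth 10 reads, else no call;
* a site whose major allele exceeds 95% of reads is homozygous;
* a heterozygous call additionally requires the best non-major allele to
  have at least 2 reads *and* at least 20% of the site's reads.

The 20% floor deserves a comment, because it is load-bearing.  Genuine
heterozygous alleles sit at 1/2, 1/3 or 1/4 of reads depending on dosage —
all comfortably above 20%.  Sequencing errors do not: at depth 50 with a
0.5% per-base error rate, a site receives three or more miscalls with
probability ~2×10^-3^, and when two or three of them agree the site slips
under the 95% homozygosity ceiling (e.g. 47/50 = 0.94).  Without the
frequency floor such sites outnumber true heterozygous sites several-fold
in low-heterozygosity genomes and drag the genome-wide allele-balance mean
from ~0.55 to ~0.66 — enough to flip a diploid's ploidy call.  The floor
mirrors the default minimum variant-allele frequency of the classical
pileup SNP callers this analysis style assumes.

## Windowed allele balance and the ploidy call

`window_maf()` averages the major-allele frequency of heterozygous sites in
5 kb windows advancing by 1 kb (values attach to the window centre).
Windows are clipped at contig ends and remnants shorter than half a window
are dropped; no window crosses a contig join, which would be meaningless on
a concatenated coordinate.

`infer_base_ploidy()` averages the per-window means over windows that
contain at least one heterozygous site (windows inside LOH runs carry no
signal and are excluded by construction, so conversion-heavy genomes are
not dragged toward the diploid side) and classifies the result to the
nearest of {1/2, 2/3}.  Exactly at the midpoint (7/12 ≈ 0.583) the diploid
call wins; means within ±0.02 of the midpoint are flagged ambiguous.

One bias is worth understanding.  `max(counts)/depth` is bounded below by
the true allele fraction in expectation: at a balanced diploid site with
depth *n* its mean is 1/2 + √(2·p·q/(π·n)), about 0.556 at depth 50.  The
statistic therefore reads ~0.55–0.58 for genuine diploids at realistic
depths — matching what is observed on real diploid isolates — while
heterozygous triploids read ~0.66, where the asymmetric 2:1 dosage makes
the finite-depth correction negligible.  The classifier boundary sits
between the two regimes, so the call is robust, but the diploid *mean*
should never be expected to equal 0.50 at finite depth.

## LOH detection and mechanism

`loh_regions()` merges maximal runs of windows with zero heterozygous sites
into segments (the union of the overlapping 5 kb spans, so a run of 46
windows yields a 50 kb segment).  `classify_loh()` then assigns each
segment the length-weighted modal copy state over its span: at or above the
base ploidy means gene conversion, below it a heterozygous deletion, zero a
complete deletion.

Two practical refinements: the copy-state track responds with a lag of up
to one smoothing block (below), and a single noisy site can split one
biological LOH event into several detected segments whose leading pieces
then overlap the *previous* copy state.  Segments separated by less than
one window (5 kb) are therefore clustered and classified together — the
split pieces of one event share one mechanism decision.  Both the
length-weighted and the segment-count conversion fractions are reported,
since "fraction of LOH due to conversion" is ambiguous between the two.

## Copy-number segmentation with hysteresis

`window_depth()` mirrors the MAF windows for depth (uncovered positions
count as zero); `normalize_depth()` scales so the genome-median window
equals the base ploidy, which makes the segmentation invariant to global
depth scaling.  `segment_copy_number()` converts the noisy relative-copy
track into integer states with a deliberately conservative rule:

* the level of a segment is the rounded (half-away-from-zero) mean of 21
  adjacent windows;
* scanning left to right with a trailing 21-window rolling mean, the level
  only *changes* when the rolling mean differs from the current level by at
  least 0.75; otherwise the window inherits the previous segment's level.

The ±0.75 threshold is hysteresis: a single aberrant window shifts the
21-window mean by at most its amplitude/21, so isolated spikes (repeats,
collapsed duplications) cannot nucleate a state change, and property tests
confirm that any single-window perturbation smaller than 0.75×21 leaves
the segmentation unchanged once the scan is past its first block.  The
first block's level is a plain rounded mean (initialisation has no
previous level to cling to), so its protection margin is the rounding
half-unit, not 0.75.  Whether the 21-window block should trail or centre
on the current window is not determined by the rule itself; both are
implemented (`mode = "trailing"` is the default, and `"centered"` roughly
halves the breakpoint lag at the cost of symmetric edge effects).

The hysteresis rule cannot reach state 0 for short homozygous deletions:
a 15 kb deletion dips the trailing mean by at most ~2 copy units for a few
windows, which rounds to 1, not 0 — yet near-zero depth across whole
windows is unambiguous under Poisson coverage (a 5 kb window averaging
under a quarter-copy of depth is a >100-sigma event at 30–50× depth).
Runs of at least 2 windows with relative copy ≤ 0.25 are therefore forced
to state 0, taking the full union of their window spans so the recovered
deletion interval matches the event rather than the window tiling.  A
*single* sub-quarter window is deliberately not enough: one window can
never be driven below the threshold by a sub-hysteresis perturbation, so
the robustness guarantee above survives, at the price that deletions
shorter than about `window + step` (~6–7 kb) are absorbed into the
surrounding state.

Deletions then become gene-presence calls: `cluster_presence()` marks a
gene absent when ≥80% of its length lies in deletion intervals.  Complete
ORF loss is the signal of interest; any threshold in (0.5, 1) would do, and
0.8 tolerates breakpoint blur of about one smoothing block.

## Per-locus haplotype assembly

`assemble_haplotypes()` reconstructs the haploid sequences segregating at a
locus from SNPs co-occurring within individual reads: seed with the
most-supported allele pair at the leftmost adjacent site pair, extend
rightward choosing at each site the allele with the strongest summed
linkage to the growing chain, remove the reads the finished haplotype
explains, and repeat — up to 3 haplotypes or until support falls below
max(3 reads, 5% of the locus).  Greedy chaining with support subtraction
was chosen over EM or graph colouring because the intended use is a
handful of small, well-separated loci, where a brute-force enumeration
oracle can bound its behaviour: on error-free loci of ≤8 sites whose
haplotypes are pairwise distinct at every site, the greedy result equals
the enumeration optimum and the planted truth exactly.

Identifiability is the real constraint, not optimisation.  When two
haplotypes share their alleles across a junction that only short reads
span, *no* method can order them — several haplotype sets explain every
read — and the assembler returns one maximally consistent solution.  In an
allotriploid this bites in a specific, predictable way: the two conserved
core haplomes differ only at sparse core SNPs (~5/kb, typically farther
apart than a 100 bp read) while both differ densely from the divergent
third haplome (~50/kb), so read-backed phasing separates *core* from
*divergent* cleanly but cannot phase the two core copies against each
other.  The analysis scripts therefore phase loci where the core pair is
locally identical, recovering the conserved and divergent sequences and —
via `estimate_dosage()`, an exhaustive integer least-squares fit of
predicted to observed allele fractions (ties broken toward the even
split) — their 2:1 allelic ratio; amplified regions distinguish 2:2 from
3:1 the same way.

## The simulator and what it does not emulate

`simulate_genome()` builds the truth: a random core sequence, a second core
haplome mutated at `het_density_core`, optionally a third haplome mutated
at `divergence_third`, then planted events (conversion tracts collapse all
haplomes to the locally modal base; heterozygous-deletion tracts keep one
haplome; CNV segments set per-haplome dosage from an explicit ratio such as
"2:1:1"; homozygous deletions zero all dosages).  `simulate_pileup()` draws
per-position depth as Poisson with mean `mean_depth × copy / base_ploidy`
and allele counts as multinomial in the dosage, with uniform miscalls at
`error_rate`; `simulate_reads()` emits per-read (site, base) observations
for the phaser.  Defaults — 5 SNPs/kb core heterozygosity, 5% third-haplome
divergence, depth 50, 0.5% error, 100 bp reads — are the package's fixed
picture of a moderately heterozygous hybrid resequenced at typical
short-read depth; the heterozygosity of a real core pair is not a measured
constant and 5/kb simply realises "moderate".

The noise model is honest about what it is: positions are independent, so
there is no read-length correlation in coverage, no GC or mappability
waviness, no mapping ambiguity in repeats, no indels, and no base-quality
structure.  Passing recovery tests on these simulations demonstrates that
the *inference rules* are implemented correctly and are robust to sampling
noise at the stated depths; it does not demonstrate robustness to
alignment artefacts, which on real data are handled upstream of the
pileup.  Sub-telomeric amplification artefacts, for instance, would appear
here as genuine planted CNV only.

## Numerical choices and degenerate inputs

* Ties for the major allele break alphabetically (A < C < G < T);
  multi-allelic sites keep `maf = max/depth` and count as heterozygous.
* Rounding of copy levels is half-away-from-zero (2.5 → 3).
* The change threshold comparison is inclusive (≥ 0.75).
* Contigs with fewer than 21 windows get a single rounded-mean state
  flagged low-confidence.
* A genome whose every window is LOH has no allele-balance signal and
  raises an error rather than guessing a ploidy.
* All randomness flows from one integer seed (`simulate_genome` uses it
  directly; the pileup and read stages use seed+1 and seed+2 so stages are
  reproducible in isolation); equal seeds give byte-identical outputs.

## Problem sizes

The bundled end-to-end fixture is a 200 kb two-contig diploid.  Recovery
tests use 100–600 kb genomes (20 seeded replicates for the LOH-mechanism
rates), the allele-balance checks use 2 Mb genomes with ≥10,000
heterozygous sites, and one full-landscape check runs a 5 Mb allotriploid
with ~8% conversion LOH, a 100 kb 4n amplification and a 15 kb homozygous
deletion.  These sizes give standard errors comfortably inside the
assertion tolerances while keeping any single test run to seconds.

## Known limitations

* Deletions shorter than ~6–7 kb are invisible to the window-scale zero
  rule, and copy-state breakpoints lag the truth by up to one smoothing
  block (trailing mode).
* The diploid/triploid classifier assumes those are the only candidate
  base ploidies; a tetraploid with balanced 2:2 dosage is indistinguishable
  from a diploid by allele balance alone.
* Phasing is per-locus, not genome-wide, and cannot separate haplotypes
  that are locally identical (see above).
* The LOH/no-LOH decision is per 5 kb window; conversion tracts much
  shorter than a window dilute into flanking heterozygosity and are missed.
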