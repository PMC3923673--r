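#' Call site zygosity from per-base counts
#'
#' Applies the study's site-calling rules: positions below `min_coverage`
#' reads are dropped; a site whose major (most frequent) allele exceeds
#' `hom_threshold` of the depth is homozygous, otherwise heterozygous.  Two
#' minor-allele floors additionally guard against sequencing errors, in the
#' spirit of the default variant-caller thresholds the study's windowed
#' analysis assumes: a heterozygous call needs at least `min_minor` reads
#' *and* a fraction of at least `min_minor_frac` of the site's reads on its
#' best non-major allele.  Without the frequency floor, three miscalls at
#' depth 50 (major allele 0.94) would pass the `<= 0.95` rule and
#' contaminate the allele-balance statistic; a genuine heterozygous allele
#' sits at 1/2 (diploid), 1/3 (triploid 2:1) or 1/4 (tetraploid 3:1), all
#' above 0.20.  Ties for the major allele break alphabetically
#' (A < C < G < T).  Reference-N positions are excluded from calling (they
#' still contribute to depth windows upstream).
#'
#' @param pileup data.frame from [read_pileup()] or [simulate_pileup()]
#'   (columns `cpos0`, `ref`, `depth`, `A`, `C`, `G`, `T`), sorted by
#'   `cpos0`.
#' @param min_coverage minimum read depth for a site to be called
#'   (default 10).
#' @param hom_threshold major-allele frequency above which a site is
#'   homozygous (default 0.95, i.e. ">95%").
#' @param min_minor minimum reads on the best non-major allele for a
#'   heterozygous call (default 2).
#' @param min_minor_frac minimum frequency of the best non-major allele for
#'   a heterozygous call (default 0.20).
#' @return data.frame of site calls: `pos` (0-based concatenated), `depth`,
#'   `A`, `C`, `G`, `T`, `major`, `maf`, `zygosity`.
#' @export
call_sites <- function(pileup, min_coverage = 10L, hom_threshold = 0.95,
                       min_minor = 2L, min_minor_frac = 0.20) {
  if (is.unsorted(pileup$cpos0, strictly = TRUE)) {
    stopf("pileup records must be sorted by concatenated position")
  }
  keep <- pileup$depth >= min_coverage & pileup$ref %in% BASES &
    (pileup$A + pileup$C + pileup$G + pileup$T) > 0L
  cnt <- as.matrix(pileup[keep, BASES])
  depth_base <- rowSums(cnt)                  # '*' placeholders carry no allele
  mx <- pmax(cnt[, 1L], cnt[, 2L], cnt[, 3L], cnt[, 4L])
  major_idx <- max.col(cnt == mx, ties.method = "first")
  major <- BASES[major_idx]
  maf <- mx / depth_base
  masked <- cnt
  masked[cbind(seq_len(nrow(cnt)), major_idx)] <- -1L
  minor_best <- pmax(masked[, 1L], masked[, 2L], masked[, 3L], masked[, 4L])
  het <- maf <= hom_threshold & minor_best >= min_minor &
    minor_best / depth_base >= min_minor_frac
  data.frame(
    pos = pileup$cpos0[keep],
    depth = pileup$depth[keep],
    A = cnt[, 1L], C = cnt[, 2L], G = cnt[, 3L], T = cnt[, 4L],
    major = major,
    maf = maf,
    zygosity = ifelse(het, "heterozygous", "homozygous"),
    stringsAsFactors = FALSE
  )
}

#' Sliding windows over the concatenated genome
#'
#' Windows advance by `step` within each contig and are clipped at contig
#' ends; clipped windows shorter than half the window size are dropped
#' (cross-contig windows have no biological meaning on a concatenated
#' draft-assembly coordinate).
#'
#' @param contigs contig table from [contig_table()].
#' @param window window size in bases (default 5000).
#' @param step step size in bases (default 1000).
#' @return data.frame with `contig`, `start`, `end` (0-based half-open,
#'   concatenated) and `center` (position the window value is plotted at).
#' @export
make_windows <- function(contigs, window = 5000L, step = 1000L) {
  out <- lapply(seq_len(nrow(contigs)), function(i) {
    off <- contigs$offset[i]
    len <- contigs$length[i]
    starts <- seq.int(0L, max(len - 1L, 0L), by = step)
    ends <- pmin(starts + window, len)
    keep <- (ends - starts) >= window / 2
    data.frame(contig = contigs$contig[i],
               start = off + starts[keep],
               end = off + ends[keep],
               stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, out)
  w$center <- (w$start + w$end) %/% 2L
  w
}

#' Windowed mean major-allele frequency
#'
#' For each sliding window (5 kb window, 1 kb step by default), averages the
#' major-allele frequency over the heterozygous site calls it contains and
#' counts them.  Windows with no heterozygous site get `mean_maf = NA`;
#' those are the raw material for LOH detection.
#'
#' @param sites site calls from [call_sites()], sorted by `pos`.
#' @param contigs contig table.
#' @inheritParams make_windows
#' @return window data.frame (see [make_windows()]) with `n_het` and
#'   `mean_maf` columns added.
#' @export
window_maf <- function(sites, contigs, window = 5000L, step = 1000L) {
  w <- make_windows(contigs, window, step)
  het <- sites[sites$zygosity == "heterozygous", , drop = FALSE]
  if (is.unsorted(het$pos)) het <- het[order(het$pos), , drop = FALSE]
  cummaf <- c(0, cumsum(het$maf))
  n_at <- function(x) findInterval(x, het$pos)   # het sites with pos <= x
  lo <- n_at(w$start - 1L)
  hi <- n_at(w$end - 1L)
  w$n_het <- hi - lo
  w$mean_maf <- ifelse(w$n_het > 0L, (cummaf[hi + 1L] - cummaf[lo + 1L]) / w$n_het, NA_real_)
  w
}

#' Detect loss-of-heterozygosity regions
#'
#' Maximal runs of consecutive windows lacking heterozygous sites are merged
#' (union of the overlapping window spans) into LOH segments, mirroring the
#' classification of windows that "lack heterozygous bases".
#'
#' @param windows window table from [window_maf()].
#' @return data.frame of LOH segments (`contig`, `start`, `end`, `n_windows`)
#'   with attribute `loh_fraction` = merged LOH length / total windowed
#'   genome length.
#' @export
loh_regions <- function(windows) {
  empty <- windows$n_het == 0L
  segs <- list()
  for (ctg in unique(windows$contig)) {
    i <- which(windows$contig == ctg)
    r <- rle(empty[i])
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- i[starts[k]:stops[k]]
      segs[[length(segs) + 1L]] <- data.frame(
        contig = ctg,
        start = windows$start[idx[1L]],
        end = windows$end[idx[length(idx)]],
        n_windows = length(idx),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(segs) > 0L) do.call(rbind, segs) else {
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               n_windows = integer(0), stringsAsFactors = FALSE)
  }
  genome_len <- sum(tapply(windows$end, windows$contig, max) -
                    tapply(windows$start, windows$contig, min))
  attr(out, "loh_fraction") <- if (nrow(out) > 0L) sum(out$end - out$start) / genome_len else 0
  out
}

#' Infer base ploidy from the genome-wide allele balance
#'
#' In a heterozygous triploid the expected major-allele frequency at a
#' heterozygous site is ~2/3 (two identical alleles against one), in a
#' diploid ~1/2.  The genome-wide mean of per-window mean MAF (windows with
#' at least one heterozygous site; LOH windows carry no signal and are
#' excluded by construction) is classified to the nearest of {1/2, 2/3};
#' exactly at the midpoint (7/12 = 0.5833...) the diploid call wins.  Means
#' within `ambiguity_margin` of the midpoint are flagged ambiguous —
#' finite-depth sampling inflates the statistic above its ideal value, so
#' borderline genomes deserve inspection.
#'
#' @param windows window table from [window_maf()].
#' @param ambiguity_margin half-width of the ambiguous zone around the
#'   decision boundary (default 0.02).
#' @return list with `ploidy` (2 or 3), `genome_mean_maf`, `genome_sd_maf`,
#'   `n_windows`, `ambiguous`.
#' @export
infer_base_ploidy <- function(windows, ambiguity_margin = 0.02) {
  v <- windows$mean_maf[windows$n_het > 0L]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stopf("no heterozygous signal: all windows are LOH")
  m <- mean(v)
  boundary <- (1 / 2 + 2 / 3) / 2
  list(
    ploidy = if (m > boundary + 1e-9) 3L else 2L,   # exactly at the midpoint: 2
    genome_mean_maf = m,
    genome_sd_maf = if (length(v) > 1L) sd(v) else NA_real_,
    n_windows = length(v),
    ambiguous = abs(m - boundary) <= ambiguity_margin
  )
}
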