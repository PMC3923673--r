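# Shared fixture builders and independent oracles.  Everything is generated
# in code; no binary data.

extdata <- function(f) system.file("extdata", f, package = "ploidyscape")

## a pileup data.frame row from explicit counts (concat single contig "c1")
pileup_row <- function(cpos0, A = 0L, C = 0L, G = 0L, T = 0L, ref = "A",
                       depth = NULL) {
  d <- if (is.null(depth)) A + C + G + T else depth
  data.frame(contig = "c1", pos = cpos0 + 1L, cpos0 = cpos0, ref = ref,
             depth = d, A = A, C = C, G = G, T = T, stringsAsFactors = FALSE)
}

## site-call data.frame from positions and per-base counts (matrix n x 4)
site_df <- function(pos, counts, zygosity = "heterozygous") {
  counts <- matrix(counts, ncol = 4L)
  mx <- apply(counts, 1L, max)
  data.frame(pos = pos, depth = rowSums(counts),
             A = counts[, 1L], C = counts[, 2L], G = counts[, 3L],
             T = counts[, 4L],
             major = c("A", "C", "G", "T")[apply(counts, 1L, which.max)],
             maf = mx / rowSums(counts),
             zygosity = zygosity, stringsAsFactors = FALSE)
}

## synthetic window frame on one contig: rel_copy given, 5 kb / 1 kb grid
window_df <- function(rel_copy, contig = "w1", window = 5000L, step = 1000L) {
  n <- length(rel_copy)
  start <- (seq_len(n) - 1L) * step
  data.frame(contig = contig, start = start, end = start + window,
             center = start + window %/% 2L, n_het = 1L, mean_maf = NA_real_,
             mean_depth = rel_copy, rel_copy = rel_copy,
             stringsAsFactors = FALSE)
}

## bundled end-to-end fixture: 200 kb diploid with a conversion tract and a
## deletion over the synthetic nitrate-cluster annotation
fixture_config <- function(seed = 7L) {
  list(
    simulate = sim_config(
      genome_length = 2e5, n_contigs = 2L, base_ploidy = 2L,
      mean_depth = 40, error_rate = 0.005,
      loh_tracts = data.frame(start = 120000L, end = 160000L,
                              mechanism = "conversion"),
      deletions = data.frame(start = 34900L, end = 41000L),
      seed = seed),
    gff = extdata("nitrate_cluster_synthetic.gff3")
  )
}

## ---- oracle: naive per-window recomputation --------------------------------

brute_window_maf <- function(sites, windows) {
  het <- sites[sites$zygosity == "heterozygous", ]
  vapply(seq_len(nrow(windows)), function(k) {
    v <- het$maf[het$pos >= windows$start[k] & het$pos < windows$end[k]]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1L))
}

brute_window_depth <- function(pileup, windows) {
  vapply(seq_len(nrow(windows)), function(k) {
    idx <- pileup$cpos0 >= windows$start[k] & pileup$cpos0 < windows$end[k]
    sum(pileup$depth[idx]) / (windows$end[k] - windows$start[k])
  }, numeric(1L))
}

## ---- oracle: exact finite-depth expectation of the major-allele statistic --

## E[max(counts)/depth] at a biallelic het site with allele fractions p, 1-p,
## depth Poisson(lambda) conditioned on depth >= min_coverage
expected_maf_biallelic <- function(p, lambda, min_coverage = 10L) {
  depths <- min_coverage:ceiling(lambda + 10 * sqrt(lambda))
  wd <- dpois(depths, lambda)
  wd <- wd / sum(wd)
  per_depth <- vapply(depths, function(n) {
    x <- 0:n
    sum(pmax(x, n - x) / n * dbinom(x, n, p))
  }, numeric(1L))
  sum(wd * per_depth)
}

## ---- oracle: brute-force haplotype assembly --------------------------------

## reads: list of data.frames (pos, base); sites: positions and allele sets
## returns max number of reads explainable by any set of <= k haplotypes
## drawn from the per-site allele sets, and the argmax sets
brute_force_haplotypes <- function(obs, allele_sets, pos, k) {
  cand <- expand.grid(allele_sets, stringsAsFactors = FALSE)
  cand_seq <- apply(as.matrix(cand), 1L, paste, collapse = "")
  consistent <- vapply(seq_along(cand_seq), function(ci) {
    hap <- as.character(cand[ci, ])
    vapply(obs, function(r) all(r$base == hap[match(r$pos, pos)]), logical(1L))
  }, logical(length(obs)))                 # reads x candidates
  if (length(obs) == 1L) consistent <- matrix(consistent, nrow = 1L)
  sets <- utils::combn(length(cand_seq), k)
  best <- -1L; best_sets <- list()
  for (j in seq_len(ncol(sets))) {
    sc <- sum(apply(consistent[, sets[, j], drop = FALSE], 1L, any))
    if (sc > best) {
      best <- sc; best_sets <- list(sort(cand_seq[sets[, j]]))
    } else if (sc == best) {
      best_sets[[length(best_sets) + 1L]] <- sort(cand_seq[sets[, j]])
    }
  }
  list(score = best, sets = best_sets)
}

## reads (data.frame read_id/pos/base) from planted haplotypes: n_per reads
## per haplotype, each spanning `span` consecutive sites at every offset
reads_from_haplotypes <- function(haps, pos, span = 2L, n_per = 5L,
                                  error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  rid <- 0L
  for (h in seq_along(haps)) {
    alle <- strsplit(haps[h], "")[[1L]]
    for (off in 1:(length(pos) - span + 1L)) {
      for (rep in seq_len(n_per)) {
        rid <- rid + 1L
        idx <- off:(off + span - 1L)
        base <- alle[idx]
        if (error_rate > 0) {
          err <- which(runif(length(idx)) < error_rate)
          for (e in err) {
            base[e] <- sample(setdiff(c("A", "C", "G", "T"), base[e]), 1L)
          }
        }
        rows[[rid]] <- data.frame(read_id = sprintf("h%d_%06d", h, rid),
                                  pos = pos[idx], base = base,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

## k haplotypes pairwise distinct at every site (identifiable from pairwise
## linkage alone, as for clearly separated divergent alleles)
distinct_haplotypes <- function(k, m) {
  vapply(seq_len(m), function(s) {
    sample(c("A", "C", "G", "T"), k)
  }, character(k))
}

distinct_hap_strings <- function(k, m) {
  mat <- matrix(distinct_haplotypes(k, m), nrow = k)
  apply(mat, 1L, paste, collapse = "")
}

## site table implied by a set of read observations (tally of bases)
sites_from_reads <- function(reads, pos) {
  counts <- matrix(0L, nrow = length(pos), ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (k in seq_along(pos)) {
    tab <- table(factor(reads$base[reads$pos == pos[k]],
                        levels = c("A", "C", "G", "T")))
    counts[k, ] <- as.integer(tab)
  }
  site_df(pos, counts)
}

## ---- oracle: independent dosage enumeration --------------------------------

## all positive-integer vectors of length k summing to n, built recursively
## (independent of the package's composition generator)
oracle_compositions <- function(n, k) {
  if (k == 1L) return(list(n))
  out <- list()
  for (v in 1:(n - k + 1L)) {
    for (rest in oracle_compositions(n - v, k - 1L)) {
      out[[length(out) + 1L]] <- c(v, rest)
    }
  }
  out
}

oracle_dosage_objective <- function(d, hap_seqs, obs_frac) {
  copy <- sum(d)
  m <- nchar(hap_seqs[1L])
  alle <- do.call(rbind, strsplit(hap_seqs, ""))
  tot <- 0
  for (s in seq_len(m)) {
    for (b in c("A", "C", "G", "T")) {
      pred <- sum(d[alle[, s] == b]) / copy
      tot <- tot + (obs_frac[s, b] - pred)^2
    }
  }
  tot
}
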