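#' Allele co-occurrence counts between heterozygous sites
#'
#' For every ordered pair of heterozygous sites co-covered by a read,
#' counts the observed allele pair.  Observations whose base is not among
#' the alleles actually seen at the site (sequencing errors against the
#' site's allele set) are dropped; reads spanning fewer than two sites
#' contribute no linkage.
#'
#' @param reads data.frame with `read_id`, `pos` (0-based het-site
#'   position), `base` — as from [simulate_reads()] or a reads TSV.
#' @param sites site calls ([call_sites()]) restricted to the locus; the
#'   allele set of a site is the set of bases with nonzero count.
#' @return data.frame of linkage counts: `pos_i`, `allele_i`, `pos_j`,
#'   `allele_j`, `n` with `pos_i < pos_j`.
#' @export
build_cooccurrence <- function(reads, sites) {
  reads <- filter_read_obs(reads, sites)
  if (nrow(reads) == 0L) {
    return(data.frame(pos_i = integer(0), allele_i = character(0),
                      pos_j = integer(0), allele_j = character(0),
                      n = integer(0), stringsAsFactors = FALSE))
  }
  pieces <- lapply(split(reads, reads$read_id), function(r) {
    r <- r[order(r$pos), , drop = FALSE]
    m <- nrow(r)
    if (m < 2L) return(NULL)
    ij <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    data.frame(pos_i = r$pos[ij[, 1L]], allele_i = r$base[ij[, 1L]],
               pos_j = r$pos[ij[, 2L]], allele_j = r$base[ij[, 2L]],
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pieces)
  if (is.null(pairs)) {
    return(data.frame(pos_i = integer(0), allele_i = character(0),
                      pos_j = integer(0), allele_j = character(0),
                      n = integer(0), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(n = rep(1L, nrow(pairs))),
                          by = pairs[, c("pos_i", "allele_i", "pos_j", "allele_j")],
                          FUN = sum)
  agg <- agg[order(agg$pos_i, agg$pos_j, agg$allele_i, agg$allele_j), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

## keep observations at known het sites whose base is in the site allele set
filter_read_obs <- function(reads, sites) {
  allele_set <- site_allele_sets(sites)
  key <- match(reads$pos, sites$pos)
  ok <- !is.na(key) & mapply(function(k, b) b %in% allele_set[[k]], key, reads$base)
  reads[ok, , drop = FALSE]
}

site_allele_sets <- function(sites) {
  lapply(seq_len(nrow(sites)), function(k) {
    BASES[as.integer(sites[k, BASES]) > 0L]
  })
}

#' Assemble per-locus haplotypes by greedy chain extension
#'
#' Reconstructs the haploid sequences segregating at a locus from SNPs
#' co-occurring within individual reads.  The chain is seeded with the
#' most-supported allele pair at the leftmost adjacent site pair and
#' extended rightward, at each site choosing the allele with the strongest
#' linkage (summed co-occurrence with the alleles already chosen) among the
#' reads not yet explained; reads fully consistent with the finished
#' haplotype are then removed and the procedure repeats, up to `k_max`
#' haplotypes or until the remaining unexplained reads fall below
#' `max(min_support, min_frac * n_reads)` or the seed pair falls below
#' `min_support`.
#'
#' When two haplotypes share their alleles across a junction only spanned
#' by short reads, the phasing across that junction is underdetermined;
#' the greedy chain then returns one of the maximally read-consistent
#' solutions (ties broken alphabetically).
#'
#' @param reads read observations (`read_id`, `pos`, `base`); reads
#'   spanning fewer than two sites are ignored.
#' @param sites site calls at the locus (its phaseable positions), sorted.
#' @param k_max maximum number of haplotypes to assemble (default 3).
#' @param min_support minimum supporting reads per haplotype (default 3).
#' @param min_frac minimum supporting fraction of the locus reads
#'   (default 0.05).
#' @return list of class `haplotype_set`: `positions` (0-based het-site
#'   positions), `haplotypes` (data.frame with `sequence` over the sites,
#'   `support`, `dosage` = NA until [estimate_dosage()]), `n_reads`.
#' @export
assemble_haplotypes <- function(reads, sites, k_max = 3L, min_support = 3L,
                                min_frac = 0.05) {
  sites <- sites[order(sites$pos), , drop = FALSE]
  pos <- sites$pos
  if (length(pos) < 2L) stopf("locus has fewer than 2 heterozygous sites")
  reads <- filter_read_obs(reads, sites)
  obs <- split(reads[, c("pos", "base")], reads$read_id)
  obs <- obs[vapply(obs, nrow, 1L) >= 2L]
  n_reads <- length(obs)

  ## every adjacent site pair must be spanned by some read
  spanned <- rep(FALSE, length(pos) - 1L)
  for (r in obs) {
    j <- match(r$pos, pos)
    j <- sort(j)
    spanned[j[-length(j)][diff(j) == 1L]] <- TRUE
  }
  if (!all(spanned)) {
    gaps <- which(!spanned)
    stopf("unphaseable locus: no read spans adjacent het sites at %s",
          paste(sprintf("%d-%d", pos[gaps], pos[gaps + 1L]), collapse = ", "))
  }

  threshold <- max(min_support, ceiling(min_frac * n_reads))
  haps <- list()
  active <- obs
  while (length(haps) < k_max && length(active) >= threshold) {
    link <- cooccurrence_from_obs(active)
    seed <- link[link$pos_i == pos[1L] & link$pos_j == pos[2L], , drop = FALSE]
    if (nrow(seed) == 0L || max(seed$n) < min_support) break
    seed <- seed[order(-seed$n, seed$allele_i, seed$allele_j), , drop = FALSE]
    hap <- character(length(pos))
    hap[1L] <- seed$allele_i[1L]
    hap[2L] <- seed$allele_j[1L]
    if (length(pos) > 2L) {
      for (j in 3:length(pos)) {
        cand <- link[link$pos_j == pos[j] &
                     link$pos_i %in% pos[1:(j - 1L)], , drop = FALSE]
        if (nrow(cand) > 0L) {
          cand <- cand[hap[match(cand$pos_i, pos)] == cand$allele_i, , drop = FALSE]
        }
        if (nrow(cand) > 0L) {
          score <- tapply(cand$n, cand$allele_j, sum)
          score <- score[order(-score, names(score))]
          hap[j] <- names(score)[1L]
        } else {
          hap[j] <- major_base_at(active, sites, pos[j])
        }
      }
    }
    consistent <- vapply(active, function(r) {
      all(r$base == hap[match(r$pos, pos)])
    }, logical(1L))
    haps[[length(haps) + 1L]] <- list(sequence = paste(hap, collapse = ""),
                                      support = sum(consistent))
    if (!any(consistent)) break      # no read explained: avoid a livelock
    active <- active[!consistent]
  }
  if (length(haps) == 0L) stopf("no haplotype reached the support threshold")
  structure(list(
    positions = pos,
    haplotypes = data.frame(
      sequence = vapply(haps, `[[`, "", "sequence"),
      support = vapply(haps, `[[`, 1L, "support"),
      dosage = NA_integer_,
      stringsAsFactors = FALSE
    ),
    n_reads = n_reads
  ), class = "haplotype_set")
}

cooccurrence_from_obs <- function(obs) {
  pieces <- lapply(obs, function(r) {
    r <- r[order(r$pos), , drop = FALSE]
    m <- nrow(r)
    if (m < 2L) return(NULL)
    ij <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    data.frame(pos_i = r$pos[ij[, 1L]], allele_i = r$base[ij[, 1L]],
               pos_j = r$pos[ij[, 2L]], allele_j = r$base[ij[, 2L]],
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pieces)
  if (is.null(pairs)) {
    return(data.frame(pos_i = integer(0), allele_i = character(0),
                      pos_j = integer(0), allele_j = character(0), n = integer(0)))
  }
  stats::aggregate(list(n = rep(1L, nrow(pairs))),
                   by = pairs[, c("pos_i", "allele_i", "pos_j", "allele_j")],
                   FUN = sum)
}

major_base_at <- function(obs, sites, p) {
  b <- unlist(lapply(obs, function(r) r$base[r$pos == p]))
  if (length(b) > 0L) {
    tab <- sort(table(b), decreasing = TRUE)
    return(names(tab)[1L])
  }
  sites$major[sites$pos == p]
}

#' Estimate integer haplotype dosage from allele fractions
#'
#' Apportions the local copy number over the assembled haplotypes by
#' least squares: the dosage vector `d` (positive integers summing to the
#' copy number) minimising the squared difference between predicted
#' per-site allele fractions (`sum of d over haplotypes carrying the
#' allele / copy`) and the observed fractions from the site counts.  Ties
#' break toward the more even split.  This is how a 2:2 region is told from
#' a 3:1 region at equal total copy.
#'
#' @param hapset a `haplotype_set` from [assemble_haplotypes()].
#' @param sites site calls at the locus positions.
#' @param copy_number local total copy number (from the CNV segmentation).
#' @return the `haplotype_set` with the `dosage` column filled.
#' @export
estimate_dosage <- function(hapset, sites, copy_number) {
  k <- nrow(hapset$haplotypes)
  copy_number <- as.integer(copy_number)
  if (copy_number < k) stopf("copy number %d < %d haplotypes", copy_number, k)
  sites <- sites[match(hapset$positions, sites$pos), , drop = FALSE]
  cnt <- as.matrix(sites[, BASES])
  obs_frac <- cnt / rowSums(cnt)
  hap_alleles <- do.call(rbind, strsplit(hapset$haplotypes$sequence, ""))
  comps <- integer_compositions(copy_number, k)
  best <- NULL; best_obj <- Inf; best_even <- Inf
  for (ci in seq_len(nrow(comps))) {
    d <- comps[ci, ]
    pred <- matrix(0, nrow = length(hapset$positions), ncol = 4L,
                   dimnames = list(NULL, BASES))
    for (h in seq_len(k)) {
      ix <- cbind(seq_len(nrow(pred)), match(hap_alleles[h, ], BASES))
      pred[ix] <- pred[ix] + d[h]
    }
    pred <- pred / copy_number
    objv <- sum((obs_frac - pred)^2)
    evenness <- sum((d - copy_number / k)^2)
    if (objv < best_obj - 1e-12 ||
        (objv < best_obj + 1e-12 && evenness < best_even)) {
      best <- d; best_obj <- objv; best_even <- evenness
    }
  }
  hapset$haplotypes$dosage <- best
  hapset
}

## all vectors of positive integers of length k summing to n (rows)
integer_compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1L))
  out <- list()
  for (first in seq_len(n - k + 1L)) {
    rest <- integer_compositions(n - first, k - 1L)
    out[[first]] <- cbind(first, rest)
  }
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}

#' Write assembled haplotypes as FASTA
#'
#' Emits one record per haplotype over the full locus: heterozygous
#' positions carry the haplotype's alleles, all other positions are filled
#' from the reference sequence.  Record ids are `locus:index:dosage`.
#'
#' @param hapset a `haplotype_set` (dosage filled or NA).
#' @param ref_seq reference sequence of the locus (character string).
#' @param locus integer c(start, end), 0-based half-open; `ref_seq` must
#'   have length `end - start`.
#' @param path output FASTA file.
#' @return invisibly, the [Biostrings::DNAStringSet] written.
#' @export
write_haplotypes <- function(hapset, ref_seq, locus, path) {
  start <- as.integer(locus[1L]); end <- as.integer(locus[2L])
  if (nchar(ref_seq) != end - start) stopf("ref_seq length != locus width")
  offs <- hapset$positions - start + 1L
  seqs <- vapply(seq_len(nrow(hapset$haplotypes)), function(h) {
    s <- strsplit(ref_seq, "", fixed = TRUE)[[1L]]
    s[offs] <- strsplit(hapset$haplotypes$sequence[h], "", fixed = TRUE)[[1L]]
    paste(s, collapse = "")
  }, "")
  ids <- sprintf("%d-%d:%d:%s", start, end, seq_along(seqs),
                 ifelse(is.na(hapset$haplotypes$dosage), ".",
                        hapset$haplotypes$dosage))
  dss <- Biostrings::DNAStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(dss, path)
  invisible(dss)
}
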