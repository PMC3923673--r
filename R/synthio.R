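#' Simulation configuration for a synthetic hybrid genome
#'
#' Describes the architecture of a synthetic allopolyploid yeast genome: a
#' moderately heterozygous diploid core, an optional divergent third haplome
#' (the hybridisation-derived chromosome set), and planted events — LOH
#' tracts (gene conversion or heterozygous deletion), copy-number segments
#' with explicit allelic ratios, and homozygous deletions.  All event
#' intervals are 0-based half-open on the concatenated genome coordinate and
#' must not overlap or cross contig boundaries.
#'
#' @param genome_length total genome length in bases.
#' @param n_contigs number of equal-length contigs the genome is split into.
#' @param base_ploidy 2 (diploid) or 3 (allotriploid).
#' @param het_density_core heterozygous sites per base between the two core
#'   haplomes (default 0.005, i.e. 5 SNPs/kb — a moderately heterozygous
#'   core).
#' @param divergence_third substitutions per site of the third haplome
#'   relative to the core (default 0.05); ignored when `base_ploidy = 2`.
#' @param loh_tracts data.frame with `start`, `end`, `mechanism`
#'   (`"conversion"` or `"deletion"`).
#' @param cnv_segments data.frame with `start`, `end`, `copy` (total copy
#'   number) and `ratio` (colon-separated per-haplome dosage, e.g. `"2:2"`
#'   or `"3:1"`; one field per haplome, summing to `copy`).
#' @param deletions data.frame with `start`, `end`: homozygous deletions
#'   (copy 0 across all haplomes).
#' @param mean_depth expected total read depth where the local copy number
#'   equals `base_ploidy`; local expected depth scales linearly with the
#'   summed haplome dosage.
#' @param error_rate per-base miscall probability (uniform to the three
#'   other bases), in `[0, 0.25)`.
#' @param read_len read length in bases for [simulate_reads()].
#' @param seed integer seed; all simulator randomness derives from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6, n_contigs = 1L, base_ploidy = 3L,
                       het_density_core = 0.005, divergence_third = 0.05,
                       loh_tracts = NULL, cnv_segments = NULL,
                       deletions = NULL, mean_depth = 50, error_rate = 0.005,
                       read_len = 100L, seed = 1L) {
  empty_iv <- function(extra = NULL) {
    df <- data.frame(start = integer(0), end = integer(0))
    for (nm in extra) df[[nm]] <- character(0)
    df
  }
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_contigs = as.integer(n_contigs),
    base_ploidy = as.integer(base_ploidy),
    het_density_core = het_density_core,
    divergence_third = divergence_third,
    loh_tracts = if (is.null(loh_tracts)) empty_iv("mechanism") else loh_tracts,
    cnv_segments = if (is.null(cnv_segments)) {
      data.frame(start = integer(0), end = integer(0), copy = integer(0),
                 ratio = character(0))
    } else cnv_segments,
    deletions = if (is.null(deletions)) empty_iv() else deletions,
    mean_depth = mean_depth,
    error_rate = error_rate,
    read_len = as.integer(read_len),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!cfg$base_ploidy %in% c(2L, 3L)) stopf("base_ploidy must be 2 or 3")
  if (cfg$mean_depth <= 0) stopf("mean_depth must be positive")
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.25) {
    stopf("error_rate must be in [0, 0.25)")
  }
  if (cfg$genome_length < cfg$n_contigs) stopf("genome shorter than n_contigs")
  contigs <- sim_contigs(cfg)
  iv <- rbind(
    cfg$loh_tracts[, c("start", "end")],
    cfg$cnv_segments[, c("start", "end")],
    cfg$deletions[, c("start", "end")]
  )
  if (nrow(iv) == 0L) return(invisible(cfg))
  if (any(iv$start < 0L | iv$end > cfg$genome_length | iv$start >= iv$end)) {
    stopf("event interval outside the genome or empty")
  }
  o <- order(iv$start)
  s <- iv$start[o]; e <- iv$end[o]
  bad <- which(s[-1L] < e[-length(e)])
  if (length(bad) > 0L) {
    stopf("overlapping event intervals: [%d,%d) and [%d,%d)",
          s[bad[1L]], e[bad[1L]], s[bad[1L] + 1L], e[bad[1L] + 1L])
  }
  bnd <- contigs$offset[-1L]
  for (k in seq_len(nrow(iv))) {
    if (any(bnd > iv$start[k] & bnd < iv$end[k])) {
      stopf("event [%d,%d) crosses a contig boundary", iv$start[k], iv$end[k])
    }
  }
  ratio_ok <- vapply(seq_len(nrow(cfg$cnv_segments)), function(k) {
    d <- parse_ratio(cfg$cnv_segments$ratio[k])
    length(d) == cfg$base_ploidy && sum(d) == cfg$cnv_segments$copy[k]
  }, logical(1L))
  if (!all(ratio_ok)) {
    stopf("cnv ratio must have one field per haplome and sum to the copy number")
  }
  invisible(cfg)
}

sim_contigs <- function(cfg) {
  per <- cfg$genome_length %/% cfg$n_contigs
  len <- rep(per, cfg$n_contigs)
  len[cfg$n_contigs] <- cfg$genome_length - per * (cfg$n_contigs - 1L)
  contig_table(sprintf("ctg%02d", seq_len(cfg$n_contigs)), len)
}

parse_ratio <- function(ratio) {
  as.integer(strsplit(as.character(ratio), ":", fixed = TRUE)[[1L]])
}

mutate_bases <- function(base, rate) {
  hit <- which(runif(length(base)) < rate)
  if (length(hit) > 0L) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    base[hit] <- ((base[hit] - 1L + shift) %% 4L) + 1L
  }
  base
}

#' Simulate a hybrid genome with planted events (ground truth)
#'
#' Builds the haplome sequences and per-haplome dosage map: a random core
#' sequence, a second core haplome mutated at `het_density_core`, an
#' optional third haplome mutated at `divergence_third`, then planted
#' events.  Gene-conversion tracts overwrite every haplome with the locally
#' modal base (ties broken toward haplome 1), so no heterozygous site
#' survives inside the tract; heterozygous-deletion LOH tracts zero the
#' dosage of every haplome but the first (copy 1); CNV segments set the
#' per-haplome dosage from their allelic ratio; homozygous deletions zero
#' all dosages.  Heterozygous-site positions are recomputed after events.
#'
#' Randomness: `simulate_genome` seeds the generator with `config$seed`;
#' [simulate_pileup()] and [simulate_reads()] use `seed + 1` and `seed + 2`
#' so each stage is reproducible in isolation.
#'
#' @param config a [sim_config()].
#' @return list of class `truth_set`: `haplomes` (ploidy x L integer matrix,
#'   codes 1..4 = A,C,G,T), `contigs` (contig table), `dosage` (data.frame
#'   of dosage-constant intervals `start`, `end`, `d1`..`dP`, `copy`),
#'   `events` (the planted intervals), `het_sites` (0-based positions
#'   heterozygous across the local non-zero-dosage haplome multiset), and
#'   `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  L <- config$genome_length
  P <- config$base_ploidy
  hap <- matrix(0L, nrow = P, ncol = L)
  hap[1L, ] <- sample.int(4L, L, replace = TRUE)
  hap[2L, ] <- mutate_bases(hap[1L, ], config$het_density_core)
  if (P == 3L) hap[3L, ] <- mutate_bases(hap[1L, ], config$divergence_third)

  ## apply conversion tracts: collapse to the modal base (tie -> haplome 1)
  conv <- config$loh_tracts[config$loh_tracts$mechanism == "conversion", , drop = FALSE]
  for (k in seq_len(nrow(conv))) {
    idx <- (conv$start[k] + 1L):conv$end[k]
    maj <- if (P == 3L) {
      ifelse(hap[2L, idx] == hap[3L, idx], hap[2L, idx], hap[1L, idx])
    } else {
      hap[1L, idx]
    }
    for (h in seq_len(P)) hap[h, idx] <- maj
  }

  ## dosage map: baseline 1 per haplome, overridden inside events
  ev <- rbind(
    if (nrow(config$loh_tracts) > 0L) {
      data.frame(start = config$loh_tracts$start, end = config$loh_tracts$end,
                 kind = ifelse(config$loh_tracts$mechanism == "deletion",
                               "loh_del", "conversion"),
                 copy = NA_integer_, ratio = NA_character_)
    },
    if (nrow(config$cnv_segments) > 0L) {
      data.frame(start = config$cnv_segments$start, end = config$cnv_segments$end,
                 kind = "cnv", copy = config$cnv_segments$copy,
                 ratio = as.character(config$cnv_segments$ratio))
    },
    if (nrow(config$deletions) > 0L) {
      data.frame(start = config$deletions$start, end = config$deletions$end,
                 kind = "deletion", copy = 0L, ratio = NA_character_)
    }
  )
  dosage <- build_dosage_map(ev, L, P)

  truth <- list(
    haplomes = hap,
    contigs = sim_contigs(config),
    dosage = dosage,
    events = list(
      loh = config$loh_tracts,
      cnv = config$cnv_segments,
      deletions = config$deletions
    ),
    het_sites = integer(0),
    config = config
  )
  truth$het_sites <- compute_het_sites(truth)
  class(truth) <- "truth_set"
  truth
}

## dosage-constant intervals covering [0, L)
build_dosage_map <- function(ev, L, P) {
  base_d <- rep(1L, P)
  rows <- list()
  add <- function(start, end, d) {
    data.frame(start = start, end = end,
               t(setNames(d, paste0("d", seq_len(P)))), copy = sum(d))
  }
  if (is.null(ev) || nrow(ev) == 0L) {
    return(add(0L, L, base_d))
  }
  ev <- ev[order(ev$start), , drop = FALSE]
  cur <- 0L
  for (k in seq_len(nrow(ev))) {
    if (ev$start[k] > cur) rows[[length(rows) + 1L]] <- add(cur, ev$start[k], base_d)
    d <- switch(ev$kind[k],
      conversion = base_d,                       # copy preserved
      loh_del = c(1L, rep(0L, P - 1L)),          # keep one haplome
      deletion = rep(0L, P),
      cnv = parse_ratio(ev$ratio[k])
    )
    rows[[length(rows) + 1L]] <- add(ev$start[k], ev$end[k], d)
    cur <- ev$end[k]
  }
  if (cur < L) rows[[length(rows) + 1L]] <- add(cur, L, base_d)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## 0-based positions with >1 distinct base among haplomes with dosage > 0
compute_het_sites <- function(truth) {
  P <- nrow(truth$haplomes)
  het <- logical(ncol(truth$haplomes))
  for (k in seq_len(nrow(truth$dosage))) {
    idx <- (truth$dosage$start[k] + 1L):truth$dosage$end[k]
    d <- as.integer(truth$dosage[k, paste0("d", seq_len(P))])
    active <- which(d > 0L)
    if (length(active) <= 1L) next
    sub <- truth$haplomes[active, idx, drop = FALSE]
    h <- colSums(sub != rep(sub[1L, ], each = length(active))) > 0L
    het[idx] <- h
  }
  which(het) - 1L
}

## dosage-weighted base fractions q (n x 4) for positions idx (1-based)
dosage_base_fractions <- function(truth, idx, d) {
  n <- length(idx)
  q <- matrix(0, nrow = n, ncol = 4L)
  tot <- sum(d)
  for (h in which(d > 0L)) {
    q[cbind(seq_len(n), truth$haplomes[h, idx])] <-
      q[cbind(seq_len(n), truth$haplomes[h, idx])] + d[h]
  }
  q / tot
}

#' Simulate a per-position pileup from a synthetic genome
#'
#' Per position, total depth is Poisson with mean
#' `mean_depth * local_copy / base_ploidy` (so an unaltered region averages
#' `mean_depth` and homozygous deletions emit depth-0 records), and allele
#' counts are multinomial with probabilities proportional to the per-haplome
#' dosage, each draw miscalled to a uniform other base with probability
#' `error_rate`.  The reference base is haplome 1.  Deterministic given the
#' configuration seed.
#'
#' @param truth a `truth_set` from [simulate_genome()].
#' @param config the same [sim_config()] (defaults to `truth$config`).
#' @return data.frame with `contig`, `pos` (1-based in contig), `cpos0`
#'   (0-based concatenated), `ref`, `depth`, `A`, `C`, `G`, `T`, ordered by
#'   position.
#' @export
simulate_pileup <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "truth_set"))
  set.seed(config$seed + 1L)
  L <- config$genome_length
  P <- config$base_ploidy
  e <- config$error_rate
  depth <- integer(L)
  cnt <- matrix(0L, nrow = L, ncol = 4L)
  for (k in seq_len(nrow(truth$dosage))) {
    idx <- (truth$dosage$start[k] + 1L):truth$dosage$end[k]
    d <- as.integer(truth$dosage[k, paste0("d", seq_len(P))])
    copy <- sum(d)
    if (copy == 0L) next                         # depth stays 0
    dep <- rpois(length(idx), config$mean_depth * copy / P)
    q <- dosage_base_fractions(truth, idx, d)
    p <- q * (1 - e) + (1 - q) * (e / 3)
    rem <- dep
    prem <- rep(1, length(idx))
    for (b in 1:3) {
      pb <- pmin(pmax(ifelse(prem > 0, p[, b] / prem, 0), 0), 1)
      draw <- rbinom(length(idx), rem, pb)
      cnt[idx, b] <- draw
      rem <- rem - draw
      prem <- prem - p[, b]
    }
    cnt[idx, 4L] <- rem
    depth[idx] <- dep
  }
  loc <- from_concat(seq_len(L), truth$contigs)
  data.frame(
    contig = loc$contig,
    pos = loc$position,
    cpos0 = 0:(L - 1L),
    ref = BASES[truth$haplomes[1L, ]],
    depth = depth,
    A = cnt[, 1L], C = cnt[, 2L], G = cnt[, 3L], T = cnt[, 4L],
    stringsAsFactors = FALSE
  )
}

#' Simulate read-level SNP observations over a locus
#'
#' Samples fragments of `read_len` uniformly over the locus, assigning each
#' to a haplome in proportion to the local dosage, and emits the (position,
#' base) observations at the heterozygous sites each fragment covers, with
#' `error_rate` miscalls.  These are the "co-occurring SNPs within
#' individual reads" the phaser consumes.  Deterministic given the
#' configuration seed.
#'
#' @param truth a `truth_set`.
#' @param locus integer c(start, end), 0-based half-open, within the genome.
#' @param config the [sim_config()] (defaults to `truth$config`).
#' @param depth target mean read depth over the locus (defaults to the
#'   dosage-scaled `mean_depth`).
#' @return data.frame with `read_id`, `pos` (0-based het-site position),
#'   `base`; positions strictly increasing within a read.  Empty (with a
#'   warning) when the locus contains no heterozygous site.
#' @export
simulate_reads <- function(truth, locus, config = truth$config, depth = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  set.seed(config$seed + 2L)
  start <- as.integer(locus[1L]); end <- as.integer(locus[2L])
  if (start < 0L || end > config$genome_length || start >= end) {
    stopf("locus outside the genome")
  }
  hs <- truth$het_sites[truth$het_sites >= start & truth$het_sites < end]
  if (length(hs) == 0L) {
    warnf("locus [%d,%d) contains no heterozygous site", start, end)
    return(data.frame(read_id = character(0), pos = integer(0),
                      base = character(0), stringsAsFactors = FALSE))
  }
  mid <- (start + end) %/% 2L
  k <- findInterval(mid, truth$dosage$start)
  d <- as.integer(truth$dosage[k, paste0("d", seq_len(config$base_ploidy))])
  if (sum(d) == 0L) {
    warnf("locus [%d,%d) is deleted (copy 0)", start, end)
    return(data.frame(read_id = character(0), pos = integer(0),
                      base = character(0), stringsAsFactors = FALSE))
  }
  rl <- config$read_len
  if (is.null(depth)) depth <- config$mean_depth * sum(d) / config$base_ploidy
  span <- end - start
  n_frag <- max(1L, as.integer(round(depth * (span + rl - 1L) / rl)))
  fstart <- start - rl + 1L + floor(runif(n_frag) * (span + rl - 1L))
  hap_of <- sample.int(config$base_ploidy, n_frag, replace = TRUE, prob = d)
  out <- vector("list", n_frag)
  for (i in seq_len(n_frag)) {
    cov <- hs[hs >= fstart[i] & hs < fstart[i] + rl]
    if (length(cov) == 0L) next
    base <- truth$haplomes[hap_of[i], cov + 1L]
    err <- which(runif(length(cov)) < config$error_rate)
    if (length(err) > 0L) {
      base[err] <- ((base[err] - 1L + sample.int(3L, length(err), replace = TRUE)) %% 4L) + 1L
    }
    out[[i]] <- data.frame(read_id = sprintf("r%06d", i), pos = cov,
                           base = BASES[base], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(res)) {
    res <- data.frame(read_id = character(0), pos = integer(0),
                      base = character(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Write the planted truth as BED files
#'
#' One BED per event class (`truth_loh.bed`, `truth_cnv.bed`,
#' `truth_deletions.bed`), 0-based half-open on the concatenated coordinate;
#' round-trips with [read_bed()].
#'
#' @param truth a `truth_set`.
#' @param dir output directory (created if needed).
#' @param header optional `#`-prefixed provenance line(s).
#' @return invisibly, the paths written.
#' @export
write_truth <- function(truth, dir, header = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  loh <- truth$events$loh
  cnv <- truth$events$cnv
  del <- truth$events$deletions
  paths <- c(
    loh = file.path(dir, "truth_loh.bed"),
    cnv = file.path(dir, "truth_cnv.bed"),
    deletions = file.path(dir, "truth_deletions.bed")
  )
  write_bed(data.frame(start = loh$start, end = loh$end,
                       name = if (nrow(loh)) loh$mechanism else character(0),
                       score = rep(0L, nrow(loh))),
            paths["loh"], header)
  write_bed(data.frame(start = cnv$start, end = cnv$end,
                       name = if (nrow(cnv)) as.character(cnv$ratio) else character(0),
                       score = if (nrow(cnv)) cnv$copy else integer(0)),
            paths["cnv"], header)
  write_bed(data.frame(start = del$start, end = del$end,
                       name = rep("deletion", nrow(del)),
                       score = rep(0L, nrow(del))),
            paths["deletions"], header)
  invisible(paths)
}
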