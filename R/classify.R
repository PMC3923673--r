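#' Classify LOH mechanism by co-localisation with copy number
#'
#' A region can lose heterozygosity either by gene conversion (one allele
#' overwrites its homolog; copy number preserved) or by deletion of one or
#' more haplomes (copy number reduced).  Each LOH segment is assigned the
#' length-weighted modal copy state over its span: state at or above the
#' base ploidy implies `gene_conversion`, a nonzero state below it
#' `het_deletion`, state 0 `deletion`; segments with no overlapping copy
#' state are flagged `unknown`.
#'
#' The hysteresis smoother responds with a lag of up to a block of windows,
#' and a single noisy site can split one biological LOH event into several
#' detected segments whose early pieces then co-localise with the *previous*
#' copy state.  LOH segments separated by less than `cluster_gap` are
#' therefore clustered and classified together over the cluster's span, so
#' the split pieces of one event share one mechanism decision.
#'
#' @param loh LOH segments from [loh_regions()].
#' @param cnv copy-number segments from [segment_copy_number()].
#' @param base_ploidy 2 or 3.
#' @param cluster_gap maximum gap in bases between LOH segments treated as
#'   one event for classification (default 5000, one window).
#' @return the LOH segments with `state` (modal copy) and `mechanism`
#'   columns, plus attributes `conversion_fraction_length` and
#'   `conversion_fraction_count` (fraction of LOH classified as gene
#'   conversion, length-weighted and by segment count).
#' @export
classify_loh <- function(loh, cnv, base_ploidy, cluster_gap = 5000L) {
  n <- nrow(loh)
  loh$state <- rep(NA_integer_, n)
  loh$mechanism <- rep("unknown", n)
  ## cluster segments separated by less than cluster_gap (segments arrive
  ## sorted within contig)
  cluster <- integer(n)
  if (n > 0L) {
    cluster[1L] <- 1L
    for (k in seq_len(n)[-1L]) {
      same <- loh$contig[k] == loh$contig[k - 1L] &&
        (loh$start[k] - loh$end[k - 1L]) < cluster_gap
      cluster[k] <- if (same) cluster[k - 1L] else cluster[k - 1L] + 1L
    }
  }
  for (cl in unique(cluster)) {
    idx <- which(cluster == cl)
    span_s <- min(loh$start[idx]); span_e <- max(loh$end[idx])
    ov_s <- pmax(cnv$start, span_s)
    ov_e <- pmin(cnv$end, span_e)
    ov <- pmax(ov_e - ov_s, 0L)
    if (sum(ov) == 0L) {
      warnf("LOH segment [%d,%d) has no overlapping copy-number segment",
            span_s, span_e)
      next
    }
    wt <- tapply(ov, cnv$state, sum)
    modal <- as.integer(names(wt)[which.max(wt)])
    loh$state[idx] <- modal
    loh$mechanism[idx] <- if (modal == 0L) "deletion"
      else if (modal < base_ploidy) "het_deletion"
      else "gene_conversion"
  }
  len <- loh$end - loh$start
  classified <- loh$mechanism != "unknown"
  attr(loh, "conversion_fraction_length") <-
    if (any(classified)) {
      sum(len[loh$mechanism == "gene_conversion"]) / sum(len[classified])
    } else NA_real_
  attr(loh, "conversion_fraction_count") <-
    if (any(classified)) {
      sum(loh$mechanism == "gene_conversion") / sum(classified)
    } else NA_real_
  loh
}

#' Detect strain-specific (homozygous) deletions
#'
#' Copy-0 segments of at least `min_len` are merged (abutting intervals
#' joined) and reported with the percent of the genome lost.
#'
#' @param cnv copy-number segments from [segment_copy_number()].
#' @param genome_length total genome length in bases.
#' @param min_len minimum deletion length in bases (default 2000, two
#'   window steps).
#' @return data.frame of deletion intervals (`start`, `end`) with attribute
#'   `pct_deleted` (percent of the genome).
#' @export
detect_deletions <- function(cnv, genome_length, min_len = 2000L) {
  zero <- cnv[cnv$state == 0L, c("start", "end"), drop = FALSE]
  merged <- merge_intervals(zero)
  merged <- merged[merged$end - merged$start >= min_len, , drop = FALSE]
  rownames(merged) <- NULL
  attr(merged, "pct_deleted") <-
    sum(merged$end - merged$start) / genome_length * 100
  merged
}

#' Gene presence/absence against deletion intervals
#'
#' A gene is called absent when at least `min_overlap` of its length lies
#' inside deletion intervals — the criterion behind calling a
#' strain-specific loss of, e.g., a nitrate-assimilation gene cluster.
#'
#' @param deletions deletion intervals from [detect_deletions()].
#' @param genes gene intervals from [read_gff()] (concatenated 0-based
#'   half-open), with `id`, `start`, `end`.
#' @param genome_length total genome length (bounds check).
#' @param min_overlap minimum deleted fraction of the gene length for an
#'   absent call (default 0.8).
#' @return data.frame with `id`, `start`, `end`, `deleted_fraction`,
#'   `presence` (`"present"`/`"absent"`).
#' @export
cluster_presence <- function(deletions, genes, genome_length,
                             min_overlap = 0.8) {
  if (nrow(genes) > 0L &&
      any(genes$start < 0L | genes$end > genome_length)) {
    stopf("gene outside genome bounds")
  }
  merged <- merge_intervals(deletions)
  frac <- vapply(seq_len(nrow(genes)), function(k) {
    overlap_length(genes$start[k], genes$end[k], merged) /
      (genes$end[k] - genes$start[k])
  }, numeric(1L))
  data.frame(
    id = genes$id,
    start = genes$start,
    end = genes$end,
    deleted_fraction = frac,
    presence = ifelse(frac >= min_overlap, "absent", "present"),
    stringsAsFactors = FALSE
  )
}

#' Summarise a strain's genome landscape
#'
#' Aggregates the pipeline outputs into one profile: base ploidy and the
#' genome-wide allele-balance statistic, percent of the genome in LOH and
#' the fraction attributed to gene conversion, percent deleted, and segment
#' counts by copy state.
#'
#' @param ploidy result of [infer_base_ploidy()].
#' @param loh classified LOH segments from [classify_loh()].
#' @param cnv copy-number segments.
#' @param deletions deletion intervals from [detect_deletions()].
#' @param genome_length total genome length.
#' @param params list of parameters used (recorded verbatim in the report).
#' @param seed seed used (recorded in the report).
#' @return list of class `strain_profile`.
#' @export
strain_profile <- function(ploidy, loh, cnv, deletions, genome_length,
                           params = list(), seed = NA_integer_) {
  for (nm in c("ploidy", "loh", "cnv", "deletions")) {
    if (is.null(get(nm))) stopf("missing upstream output: %s", nm)
  }
  loh_merged <- merge_intervals(loh)
  stopifnot(all(diff(loh_merged$start) > 0))
  pct_loh <- sum(loh_merged$end - loh_merged$start) / genome_length * 100
  n_by_state <- table(factor(cnv$state, levels = sort(unique(cnv$state))))
  prof <- list(
    base_ploidy = ploidy$ploidy,
    genome_mean_maf = ploidy$genome_mean_maf,
    genome_sd_maf = ploidy$genome_sd_maf,
    ploidy_ambiguous = ploidy$ambiguous,
    pct_loh = pct_loh,
    pct_conversion_length = 100 * attr(loh, "conversion_fraction_length"),
    pct_conversion_count = 100 * attr(loh, "conversion_fraction_count"),
    pct_deleted = attr(deletions, "pct_deleted"),
    n_loh_segments = nrow(loh),
    n_segments_by_state = as.list(setNames(as.integer(n_by_state),
                                           names(n_by_state))),
    genome_length = genome_length,
    params = params,
    seed = seed
  )
  class(prof) <- "strain_profile"
  prof
}

#' Write a strain profile as JSON and TSV
#'
#' Deterministic output: identical inputs produce byte-identical files.
#'
#' @param profile a `strain_profile`.
#' @param json_path,tsv_path output files (NULL to skip either).
#' @return invisibly, the profile.
#' @export
write_profile <- function(profile, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(profile), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null", na = "null")
  }
  if (!is.null(tsv_path)) {
    scalar <- profile[!vapply(profile, is.list, logical(1L))]
    df <- data.frame(field = names(scalar),
                     value = vapply(scalar, function(x) format(x, digits = 10), ""),
                     stringsAsFactors = FALSE)
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(profile)
}
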