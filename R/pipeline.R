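#' Run the full genome-landscape pipeline
#'
#' Wires the stages in dependency order: input (simulate a synthetic genome
#' or load a pileup), site calling, MAF and depth windows, base-ploidy
#' inference, copy-number segmentation, LOH detection and mechanism
#' classification, deletion detection, optional gene presence/absence, and
#' the strain profile.  Every output file starts with a `#` header line
#' recording the package version, parameters and seed; given the same seed
#' and inputs the outputs are byte-identical.
#'
#' @param config list with either a `simulate` element (a [sim_config()])
#'   or `pileup`/`contig_table` paths, optionally `gff` (gene annotations)
#'   and `ploidy` (override of the inferred base ploidy); stage parameters
#'   `window`, `step`, `min_coverage`, `hom_threshold`, `span`, `delta`,
#'   `min_overlap` default to the study values.
#' @param outdir output directory (created).
#' @return invisibly, a list with the in-memory stage outputs (`windows`,
#'   `ploidy`, `cnv`, `loh`, `deletions`, `genes`, `profile`).
#' @export
run_pipeline <- function(config, outdir) {
  p <- function(name, default) if (!is.null(config[[name]])) config[[name]] else default
  window <- p("window", 5000L); step <- p("step", 1000L)
  min_coverage <- p("min_coverage", 10L); hom_threshold <- p("hom_threshold", 0.95)
  span <- p("span", 21L); delta <- p("delta", 0.75)
  min_overlap <- p("min_overlap", 0.8)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  if (!is.null(config$simulate)) {
    simcfg <- config$simulate
    truth <- simulate_genome(simcfg)
    pileup <- simulate_pileup(truth)
    contigs <- truth$contigs
    seed <- simcfg$seed
    write_truth(truth, outdir, header = run_header(config, seed))
  } else {
    if (is.null(config$pileup) || is.null(config$contig_table)) {
      stopf("config needs either a 'simulate' block or 'pileup' + 'contig_table' paths")
    }
    if (!file.exists(config$pileup)) stopf("missing input file: %s", config$pileup)
    if (!file.exists(config$contig_table)) stopf("missing input file: %s", config$contig_table)
    contigs <- read_contig_table(config$contig_table,
                                 genome_length = config$genome_length)
    pileup <- read_pileup(config$pileup, contigs)
    truth <- NULL
    seed <- p("seed", NA_integer_)
  }
  genome_length <- sum(contigs$length)
  hdr <- run_header(config, seed)

  sites <- call_sites(pileup, min_coverage = min_coverage,
                      hom_threshold = hom_threshold)
  wmaf <- window_maf(sites, contigs, window = window, step = step)
  wdep <- window_depth(pileup, contigs, window = window, step = step)
  windows <- wmaf
  windows$mean_depth <- wdep$mean_depth

  ploidy <- infer_base_ploidy(windows)
  base_ploidy <- if (!is.null(config$ploidy)) as.integer(config$ploidy) else ploidy$ploidy
  windows <- normalize_depth(windows, base_ploidy)
  cnv <- segment_copy_number(windows, base_ploidy, span = span, delta = delta)
  loh <- loh_regions(windows)
  loh <- classify_loh(loh, cnv, base_ploidy)
  deletions <- detect_deletions(cnv, genome_length)

  genes <- NULL
  presence <- NULL
  if (!is.null(config$gff)) {
    if (!file.exists(config$gff)) stopf("missing input file: %s", config$gff)
    genes <- read_gff(config$gff, contigs)
    presence <- cluster_presence(deletions, genes, genome_length,
                                 min_overlap = min_overlap)
    write_tsv(presence, file.path(outdir, "gene_presence.tsv"), hdr)
  }

  profile <- strain_profile(
    ploidy, loh, cnv, deletions, genome_length,
    params = list(window = window, step = step, min_coverage = min_coverage,
                  hom_threshold = hom_threshold, span = span, delta = delta,
                  min_overlap = min_overlap, base_ploidy = base_ploidy),
    seed = seed
  )

  write_tsv(format_sites(sites), file.path(outdir, "sites.tsv"), hdr)
  write_tsv(format_windows(windows), file.path(outdir, "windows.tsv"), hdr)
  write_bed(data.frame(start = loh$start, end = loh$end, name = loh$mechanism,
                       score = ifelse(is.na(loh$state), 0L, loh$state)),
            file.path(outdir, "loh.bed"), hdr)
  write_bed(data.frame(start = cnv$start, end = cnv$end, name = cnv$mechanism,
                       score = cnv$state),
            file.path(outdir, "cnv.bed"), hdr)
  write_bed(data.frame(start = deletions$start, end = deletions$end,
                       name = rep("deletion", nrow(deletions)),
                       score = rep(0L, nrow(deletions))),
            file.path(outdir, "deletions.bed"), hdr)
  write_profile(profile, file.path(outdir, "profile.json"),
                file.path(outdir, "profile.tsv"))

  invisible(list(contigs = contigs, truth = truth, sites = sites,
                 windows = windows, ploidy = ploidy, cnv = cnv, loh = loh,
                 deletions = deletions, genes = genes, presence = presence,
                 profile = profile))
}

run_header <- function(config, seed) {
  prm <- config[!vapply(config, function(x) is.list(x) || inherits(x, "sim_config"),
                        logical(1L))]
  sprintf("# ploidyscape %s; seed=%s; %s",
          as.character(utils::packageVersion("ploidyscape")),
          as.character(seed),
          paste(sprintf("%s=%s", names(prm), vapply(prm, as.character, "")),
                collapse = " "))
}

write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

format_sites <- function(sites) {
  sites$maf <- sprintf("%.6f", sites$maf)
  sites
}

format_windows <- function(windows) {
  windows$mean_maf <- ifelse(is.na(windows$mean_maf), "NA",
                             sprintf("%.6f", windows$mean_maf))
  windows$mean_depth <- sprintf("%.4f", windows$mean_depth)
  if (!is.null(windows$rel_copy)) windows$rel_copy <- sprintf("%.4f", windows$rel_copy)
  windows
}
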