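#' Build a contig-offset table
#'
#' The analysis runs on a single linear "concatenated genome" coordinate in
#' which draft-assembly contigs are laid end to end at fixed start offsets
#' (gap-free).  The table maps contig-local positions into that coordinate
#' and back.
#'
#' @param contig character vector of contig identifiers.
#' @param length integer vector of contig lengths in bases.
#' @return data.frame with columns `contig`, `offset` (0-based concatenated
#'   start) and `length`, one row per contig, in genome order.
#' @export
contig_table <- function(contig, length) {
  if (length(contig) != length(length)) {
    stopf("contig and length differ in length")
  }
  if (anyDuplicated(contig)) stopf("duplicated contig ids")
  length <- as.integer(length)
  if (any(length <= 0L)) stopf("contig lengths must be positive")
  data.frame(
    contig = as.character(contig),
    offset = c(0L, cumsum(length)[-base::length(length)]),
    length = length,
    stringsAsFactors = FALSE
  )
}

#' Read a contig-offset table from a two-column TSV
#'
#' Expects columns `contig` and `start` (0-based concatenated start
#' coordinate, strictly increasing, first = 0) plus optional `length`; when
#' `length` is absent it is inferred from consecutive offsets and
#' `genome_length`.
#'
#' @param path TSV file with a header line.
#' @param genome_length total concatenated length, required to infer the last
#'   contig's length when no `length` column is present.
#' @return contig table as from [contig_table()].
#' @export
read_contig_table <- function(path, genome_length = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  if (!all(c("contig", "start") %in% names(df))) {
    stopf("contig table needs 'contig' and 'start' columns: %s", path)
  }
  if (is.unsorted(df$start, strictly = TRUE) || df$start[1L] != 0L) {
    stopf("contig offsets must start at 0 and be strictly increasing")
  }
  if (!"length" %in% names(df)) {
    if (is.null(genome_length)) {
      stopf("genome_length required when the table has no 'length' column")
    }
    df$length <- diff(c(df$start, as.integer(genome_length)))
  }
  contig_table(df$contig, df$length)
}

#' Convert contig-local to concatenated coordinates (and back)
#'
#' Both sides are 1-based (as in pileup output); internal 0-based half-open
#' intervals subtract 1 from the concatenated position at the call site.
#'
#' @param contig contig identifier(s).
#' @param position 1-based position(s) within the contig.
#' @param contigs contig table from [contig_table()].
#' @return `to_concat`: 1-based concatenated position(s).
#' @export
to_concat <- function(contig, position, contigs) {
  i <- match(contig, contigs$contig)
  if (anyNA(i)) stopf("unknown contig: %s", paste(unique(contig[is.na(i)]), collapse = ", "))
  position <- as.integer(position)
  bad <- position < 1L | position > contigs$length[i]
  if (any(bad)) {
    stopf("position out of range for contig %s: %d",
          contig[bad][1L], position[bad][1L])
  }
  contigs$offset[i] + position
}

#' @rdname to_concat
#' @param cpos 1-based concatenated position(s).
#' @return `from_concat`: data.frame with `contig` and `position` (1-based).
#' @export
from_concat <- function(cpos, contigs) {
  cpos <- as.integer(cpos)
  total <- sum(contigs$length)
  if (any(cpos < 1L | cpos > total)) stopf("concatenated position out of range")
  i <- findInterval(cpos - 1L, contigs$offset)
  data.frame(
    contig = contigs$contig[i],
    position = cpos - contigs$offset[i],
    stringsAsFactors = FALSE
  )
}

## Tally one mpileup base string into counts of A/C/G/T.
## Handles: . , (ref match), ACGTacgt (mismatch), ^X (read start; X is a
## mapping-quality byte and is consumed, never counted), $ (read end),
## * (deleted base: depth only), +n<seq>/-n<seq> (indels: skipped).
parse_pileup_bases <- function(bases, ref) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  chars <- strsplit(bases, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  i <- 1L
  star <- 0L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L            # skip the mapping-quality character
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] >= "0" && chars[j] <= "9") j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len           # skip the inserted/deleted sequence
    } else if (ch == "." || ch == ",") {
      if (ref %in% BASES) counts[ref] <- counts[ref] + 1L
      i <- i + 1L
    } else if (ch == "*") {
      star <- star + 1L
      i <- i + 1L
    } else {
      up <- toupper(ch)
      if (up %in% BASES) counts[up] <- counts[up] + 1L
      i <- i + 1L
    }
  }
  list(counts = counts, deleted = star)
}

#' Read a samtools-style pileup TSV
#'
#' Parses the 6-column text pileup (contig, 1-based position, reference
#' base, depth, base string, qualities) into per-base counts on the
#' concatenated coordinate.  `'.'`/`','` count toward the reference base,
#' `ACGTacgt` toward the mismatch base, `^X` consumes the following
#' mapping-quality character, `'$'` is ignored, `'*'` counts toward depth
#' but no base, and `+n`/`-n` indel tokens are skipped (the SNP analysis is
#' substitution-only).
#'
#' @param path pileup TSV.
#' @param contigs contig table from [contig_table()].
#' @param check_depth when TRUE (default), report lines whose declared depth
#'   column disagrees with the tallied base counts.
#' @return data.frame with columns `contig`, `pos` (1-based in contig),
#'   `cpos0` (0-based concatenated), `ref`, `depth`, `A`, `C`, `G`, `T`.
#'   `depth` is the tallied count (matched bases + deleted-base `*`
#'   placeholders).
#' @export
read_pileup <- function(path, contigs, check_depth = TRUE) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  n <- length(lines)
  out <- data.frame(
    contig = character(n), pos = integer(n), cpos0 = integer(n),
    ref = character(n), depth = integer(n),
    A = integer(n), C = integer(n), G = integer(n), T = integer(n),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(n)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 6L) stopf("malformed pileup line %d: fewer than 6 fields", k)
    pos <- suppressWarnings(as.integer(f[2L]))
    dep <- suppressWarnings(as.integer(f[4L]))
    if (is.na(pos) || is.na(dep)) stopf("malformed pileup line %d", k)
    ref <- toupper(f[3L])
    tallied <- parse_pileup_bases(f[5L], ref)
    total <- sum(tallied$counts) + tallied$deleted
    if (check_depth && total != dep) {
      warnf("pileup line %d: declared depth %d but tallied %d", k, dep, total)
    }
    out$contig[k] <- f[1L]
    out$pos[k] <- pos
    out$ref[k] <- ref
    out$depth[k] <- total
    out[k, BASES] <- as.list(tallied$counts)
  }
  out$cpos0 <- to_concat(out$contig, out$pos, contigs) - 1L
  out
}

#' Write per-position allele counts as a pileup-style TSV
#'
#' Emits the 6-column text pileup the reader consumes (reference-matching
#' reads as `'.'`, mismatches as upper-case bases, constant quality), for
#' fixtures and round-trip checks.  Zero-depth positions are omitted, as in
#' real pileup output.
#'
#' @param pileup data.frame as returned by [simulate_pileup()] / [read_pileup()].
#' @param path output file.
#' @param header optional `#`-prefixed provenance line(s).
#' @export
write_pileup <- function(pileup, path, header = NULL) {
  pileup <- pileup[pileup$depth > 0L, , drop = FALSE]
  base_str <- character(nrow(pileup))
  for (k in seq_len(nrow(pileup))) {
    cnt <- as.integer(pileup[k, BASES])
    ref <- pileup$ref[k]
    s <- ""
    for (b in seq_along(BASES)) {
      if (cnt[b] == 0L) next
      sym <- if (BASES[b] == ref) "." else BASES[b]
      s <- paste0(s, strrep(sym, cnt[b]))
    }
    base_str[k] <- s
  }
  qual <- strrep("I", pileup$depth)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  writeLines(paste(pileup$contig, pileup$pos, pileup$ref, pileup$depth,
                   base_str, qual, sep = "\t"), con)
}

#' Write genomic segments as BED
#'
#' Standard 0-based half-open BED on the concatenated coordinate (chrom
#' column `"concat"` unless the segments carry a `contig` column).  The name
#' column carries the segment state/mechanism label, the score column the
#' integer copy state where present.  Comment (`#`) header lines record
#' provenance and are skipped by [read_bed()].
#'
#' @param segments data.frame with `start`, `end` and optionally `name`
#'   (or `mechanism`), `score` (or `state`).
#' @param path output file.
#' @param header optional `#`-prefixed provenance line(s).
#' @export
write_bed <- function(segments, path, header = NULL) {
  name <- if (!is.null(segments$name)) segments$name
          else if (!is.null(segments$mechanism)) segments$mechanism
          else rep(".", nrow(segments))
  score <- if (!is.null(segments$score)) segments$score
           else if (!is.null(segments$state)) segments$state
           else rep(0L, nrow(segments))
  chrom <- if (!is.null(segments$contig)) segments$contig else rep("concat", nrow(segments))
  if (nrow(segments) > 1L) {
    o <- order(segments$start)
    ovl <- any(segments$start[o][-1L] < segments$end[o][-nrow(segments)])
    if (ovl) warnf("writing overlapping segments as-is: %s", path)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  if (nrow(segments) > 0L) {
    writeLines(paste(chrom, segments$start, segments$end, name, score,
                     sep = "\t"), con)
  }
}

#' @rdname write_bed
#' @return `read_bed`: data.frame with `contig`, `start`, `end`, `name`,
#'   `score` (0-based half-open, as written).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(
    contig = f[, 1L],
    start = as.integer(f[, 2L]),
    end = as.integer(f[, 3L]),
    name = if (ncol(f) >= 4L) f[, 4L] else ".",
    score = if (ncol(f) >= 5L) suppressWarnings(as.numeric(f[, 5L])) else 0,
    stringsAsFactors = FALSE
  )
}

#' Read gene annotations from GFF3
#'
#' Imports a GFF3 file (1-based inclusive coordinates) and converts features
#' to the internal 0-based half-open concatenated coordinate.  Lines that do
#' not have the 9-column GFF shape are skipped with a warning giving their
#' count.
#'
#' @param path GFF3 file.
#' @param contigs contig table from [contig_table()].
#' @param feature feature types to keep (default `"gene"`; NULL keeps all).
#' @return data.frame with `id`, `contig`, `start`, `end` (concatenated,
#'   0-based half-open), `strand`.
#' @export
read_gff <- function(path, contigs, feature = "gene") {
  lines <- readLines(path)
  keep <- startsWith(lines, "#") | !nzchar(lines) |
    vapply(strsplit(lines, "\t", fixed = TRUE), length, 1L) == 9L
  if (any(!keep)) {
    warnf("skipped %d unparseable GFF line(s) in %s", sum(!keep), path)
    tmp <- tempfile(fileext = ".gff3")
    writeLines(lines[keep], tmp)
    path <- tmp
    on.exit(unlink(tmp))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  if (!is.null(feature) && "type" %in% names(df)) {
    df <- df[as.character(df$type) %in% feature, , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    return(data.frame(id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  id <- if ("ID" %in% names(df)) as.character(df$ID) else as.character(seq_len(nrow(df)))
  id[is.na(id)] <- paste0("feature_", which(is.na(id)))
  cstart <- to_concat(as.character(df$seqnames), df$start, contigs)
  data.frame(
    id = id,
    contig = as.character(df$seqnames),
    start = cstart - 1L,                        # 1-based inclusive -> 0-based half-open
    end = cstart - 1L + (df$end - df$start + 1L),
    strand = as.character(df$strand),
    stringsAsFactors = FALSE
  )
}
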