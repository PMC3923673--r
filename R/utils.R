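BASES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Arithmetic rounding used by the copy-number smoother: 2.5 rounds to 3,
#' unlike [base::round()]'s banker's rounding.
#'
#' @param x numeric vector (copy-number levels are non-negative).
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

## merged (disjoint) intervals from a start/end data.frame, 0-based half-open
merge_intervals <- function(df) {
  if (nrow(df) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

## total length of the union of intervals
interval_union_length <- function(df) {
  sum(merge_intervals(df)$end - merge_intervals(df)$start)
}

#' Jaccard index between two interval sets
#'
#' Overlap statistic used to score recovery of planted events:
#' `|A intersect B| / |A union B|` over genomic intervals (0-based half-open).
#'
#' @param a,b data.frames with `start` and `end` columns.
#' @return numeric in \[0, 1\] (0 when both sets are empty).
#' @export
interval_jaccard <- function(a, b) {
  ia <- IRanges::reduce(IRanges::IRanges(start = a$start + 1L, end = a$end))
  ib <- IRanges::reduce(IRanges::IRanges(start = b$start + 1L, end = b$end))
  inter <- sum(IRanges::width(IRanges::intersect(ia, ib)))
  uni <- sum(IRanges::width(IRanges::union(ia, ib)))
  if (uni == 0L) return(0)
  inter / uni
}

## overlap length of one interval with a set of merged intervals
overlap_length <- function(start, end, df) {
  if (nrow(df) == 0L || end <= start) return(0L)
  s <- pmax(df$start, start)
  e <- pmin(df$end, end)
  sum(pmax(e - s, 0L))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
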