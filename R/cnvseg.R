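#' Windowed mean read depth
#'
#' Average depth per sliding window (5 kb window, 1 kb step by default),
#' counting positions absent from the pileup as depth 0.
#'
#' @param pileup data.frame with `cpos0` and `depth` (from [read_pileup()]
#'   or [simulate_pileup()]).
#' @param contigs contig table.
#' @inheritParams make_windows
#' @return window data.frame with a `mean_depth` column.
#' @export
window_depth <- function(pileup, contigs, window = 5000L, step = 1000L) {
  w <- make_windows(contigs, window, step)
  L <- sum(contigs$length)
  d <- numeric(L)
  d[pileup$cpos0 + 1L] <- pileup$depth
  cum <- c(0, cumsum(d))
  w$mean_depth <- (cum[w$end + 1L] - cum[w$start + 1L]) / (w$end - w$start)
  w
}

#' Normalise windowed depth to relative copy number
#'
#' Scales window depth so the genome-median window sits at the inferred (or
#' supplied) base ploidy: `rel_copy = mean_depth / median(mean_depth) *
#' base_ploidy`.  Scaling every depth by a constant therefore leaves
#' `rel_copy` unchanged.
#'
#' @param windows window table with `mean_depth`.
#' @param base_ploidy 2 or 3, from [infer_base_ploidy()] or a user override.
#' @return windows with a `rel_copy` column.
#' @export
normalize_depth <- function(windows, base_ploidy) {
  med <- median(windows$mean_depth)
  if (med <= 0) stopf("genome median depth is zero")
  windows$rel_copy <- windows$mean_depth / med * base_ploidy
  windows
}

#' Segment relative copy number by 21-window smoothing with hysteresis
#'
#' Implements the segmental-smoothing rule: the predicted integer level for
#' a genomic segment is the rounded mean of `span` (21) adjacent windows,
#' and a change of predicted level is only triggered when the rolling
#' `span`-window mean differs from the current level by at least `delta`
#' (0.75); otherwise the window inherits the previous segment's level.  The
#' rolling mean trails (the current window is the block's right edge) by
#' default; `mode = "centered"` centres the block on the current window.
#' Rounding is half-away-from-zero (2.5 rounds to 3).
#'
#' In addition, maximal runs of at least `zero_run` windows whose
#' `rel_copy` is at most `zero_max` are forced to copy 0: homozygous
#' deletions shorter than the hysteresis response length would otherwise be
#' absorbed into a nonzero level, yet near-zero depth across several
#' windows is unambiguous under Poisson coverage.  Zero segments take the
#' full union of their window spans; other segment boundaries fall on
#' window starts.
#'
#' Contigs are segmented independently; a contig with fewer than `span`
#' windows is assigned a single rounded-mean level flagged low-confidence.
#'
#' @param windows window table with `rel_copy` (see [normalize_depth()]),
#'   ordered by position.
#' @param base_ploidy base ploidy used to annotate mechanisms.
#' @param span number of windows in the smoothing block (odd; default 21).
#' @param delta minimum difference of rolling mean vs current level that
#'   triggers a level change (inclusive; default 0.75).
#' @param mode `"trailing"` (default) or `"centered"` rolling block.
#' @param zero_max rel_copy at or below which a window counts as zero-depth
#'   (default 0.25).
#' @param zero_run minimum run of zero-depth windows forced to copy 0
#'   (default 2; a single window can never be driven below `zero_max` by a
#'   sub-threshold perturbation, so the hysteresis robustness guarantee is
#'   preserved while deletions from about `window + step * zero_run` bases
#'   up remain detectable).
#' @return data.frame of segments: `contig`, `start`, `end`, `state`
#'   (integer copy number), `mechanism` (`amplification`, `het_deletion`,
#'   `deletion` or `none` relative to `base_ploidy`), `support` (windows),
#'   `low_conf`.
#' @export
segment_copy_number <- function(windows, base_ploidy, span = 21L,
                                delta = 0.75, mode = c("trailing", "centered"),
                                zero_max = 0.25, zero_run = 2L) {
  mode <- match.arg(mode)
  if (span %% 2L == 0L) stopf("span must be odd")
  out <- list()
  for (ctg in unique(windows$contig)) {
    w <- windows[windows$contig == ctg, , drop = FALSE]
    n <- nrow(w)
    x <- w$rel_copy
    if (n < span) {
      level <- rep(round_half_up(mean(x)), n)
      low <- TRUE
    } else {
      low <- FALSE
      rm <- if (mode == "trailing") {
        data.table::frollmean(x, span, align = "right")
      } else {
        data.table::frollmean(x, span, align = "center")
      }
      level <- integer(n)
      cur <- round_half_up(mean(x[1:span]))
      level[1:span] <- cur
      first <- if (mode == "trailing") span + 1L else span %/% 2L + 2L
      idx <- seq.int(first, n)
      for (i in idx) {
        m <- rm[i]
        if (!is.na(m) && abs(m - cur) >= delta) cur <- round_half_up(m)
        level[i] <- cur
      }
    }
    ## hard-zero rule for homozygous deletions
    zr <- rle(x <= zero_max)
    zstop <- cumsum(zr$lengths)
    zstart <- zstop - zr$lengths + 1L
    zero_runs <- which(zr$values & zr$lengths >= zero_run)
    for (k in zero_runs) level[zstart[k]:zstop[k]] <- 0L

    ## merge equal-level runs into segments
    r <- rle(level)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    seg <- data.frame(
      contig = ctg,
      start = w$start[starts],
      end = c(w$start[starts[-1L]], w$end[n]),
      state = r$values,
      support = r$lengths,
      low_conf = low,
      stringsAsFactors = FALSE
    )
    ## zero segments take the union of their window spans
    for (k in which(seg$state == 0L)) {
      seg$end[k] <- max(seg$end[k], w$end[stops[k]])
      if (k < nrow(seg)) seg$start[k + 1L] <- max(seg$start[k + 1L], seg$end[k])
    }
    seg <- seg[seg$end > seg$start, , drop = FALSE]
    out[[length(out) + 1L]] <- seg
  }
  seg <- do.call(rbind, out)
  rownames(seg) <- NULL
  seg$mechanism <- ifelse(seg$state == 0L, "deletion",
                   ifelse(seg$state > base_ploidy, "amplification",
                   ifelse(seg$state < base_ploidy, "het_deletion", "none")))
  seg
}
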