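two_site_reads <- function(n_at = 10L, n_gc = 10L, extra = NULL) {
  rows <- list()
  for (i in seq_len(n_at)) {
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = sprintf("at%03d", i), pos = c(100L, 150L), base = c("A", "T"))
  }
  for (i in seq_len(n_gc)) {
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = sprintf("gc%03d", i), pos = c(100L, 150L), base = c("G", "C"))
  }
  if (!is.null(extra)) rows[[length(rows) + 1L]] <- extra
  do.call(rbind, rows)
}

two_site_sites <- function() {
  site_df(c(100L, 150L), rbind(c(10L, 0L, 10L, 0L), c(0L, 10L, 0L, 10L)))
}

test_that("co-occurrence counts tally allele pairs per read", {
  link <- build_cooccurrence(two_site_reads(), two_site_sites())
  expect_equal(nrow(link), 2L)
  expect_equal(link$n[link$allele_i == "A" & link$allele_j == "T"], 10L)
  expect_equal(link$n[link$allele_i == "G" & link$allele_j == "C"], 10L)
  ## a read covering one site contributes nothing
  single <- data.frame(read_id = "s1", pos = 100L, base = "A")
  link2 <- build_cooccurrence(rbind(two_site_reads(), single), two_site_sites())
  expect_equal(sum(link2$n), 20L)
  ## an erroneous A-C read is still counted when both alleles exist at the sites
  err <- data.frame(read_id = "err1", pos = c(100L, 150L), base = c("A", "C"))
  link3 <- build_cooccurrence(two_site_reads(extra = err), two_site_sites())
  expect_equal(link3$n[link3$allele_i == "A" & link3$allele_j == "C"], 1L)
  expect_equal(link3$n[link3$allele_i == "A" & link3$allele_j == "T"], 10L)
})

test_that("observations with alleles absent from the site set are dropped", {
  ## T at site 100 never observed in the site counts: dropped
  phantom <- data.frame(read_id = "ph1", pos = c(100L, 150L), base = c("T", "T"))
  link <- build_cooccurrence(two_site_reads(extra = phantom), two_site_sites())
  expect_equal(sum(link$allele_i == "T"), 0L)
})

test_that("a two-haplotype locus assembles exactly", {
  hs <- assemble_haplotypes(two_site_reads(), two_site_sites())
  expect_equal(sort(hs$haplotypes$sequence), c("AT", "GC"))
  expect_equal(hs$haplotypes$support, c(10L, 10L))
})

test_that("a conversion locus yields a single haplotype", {
  ## all reads identical: LOH by gene conversion leaves one haplotype
  reads <- two_site_reads(n_at = 20L, n_gc = 0L)
  sites <- site_df(c(100L, 150L), rbind(c(20L, 0L, 0L, 0L), c(0L, 0L, 0L, 20L)))
  hs <- assemble_haplotypes(reads, sites)
  expect_equal(nrow(hs$haplotypes), 1L)
  expect_equal(hs$haplotypes$sequence, "AT")
})

test_that("an unphaseable locus reports the uncovered gap", {
  ## no read spans sites 150 and 200
  reads <- rbind(two_site_reads(),
                 data.frame(read_id = "x1", pos = 200L, base = "A"),
                 data.frame(read_id = "x2", pos = 200L, base = "C"))
  sites <- site_df(c(100L, 150L, 200L),
                   rbind(c(10L, 0L, 10L, 0L), c(0L, 10L, 0L, 10L),
                         c(10L, 10L, 0L, 0L)))
  expect_error(assemble_haplotypes(reads, sites), "150-200")
})

test_that("error-free planted haplotypes are recovered exactly for k in 1..3", {
  set.seed(5)
  for (k in 1:3) {
    for (m in c(2L, 4L, 6L, 8L)) {
      pos <- sort(sample(1000L, m)) * 10L
      ## haplotypes distinct at every site: identifiable from pairwise linkage
      haps <- distinct_hap_strings(k, m)
      reads <- reads_from_haplotypes(haps, pos, span = 2L, n_per = 5L)
      sites <- sites_from_reads(reads, pos)
      hs <- assemble_haplotypes(reads, sites, k_max = 3L)
      expect_setequal(hs$haplotypes$sequence, haps)
      ## every read is explained by some assembled haplotype
      obs <- split(reads[, c("pos", "base")], reads$read_id)
      explained <- vapply(obs, function(r) {
        any(vapply(hs$haplotypes$sequence, function(h) {
          alle <- strsplit(h, "")[[1L]]
          all(r$base == alle[match(r$pos, pos)])
        }, logical(1L)))
      }, logical(1L))
      expect_true(all(explained))
    }
  }
})

test_that("greedy assembly attains the brute-force optimum on small loci", {
  set.seed(11)
  for (trial in 1:6) {
    k <- sample(2:3, 1L)
    m <- sample(3:5, 1L)
    pos <- sort(sample(500L, m)) * 10L
    repeat {
      haps <- vapply(seq_len(k), function(i) {
        paste(sample(c("A", "G"), m, replace = TRUE), collapse = "")
      }, "")
      if (length(unique(haps)) == k) break
    }
    reads <- reads_from_haplotypes(haps, pos, span = 3L, n_per = 4L)
    sites <- sites_from_reads(reads, pos)
    hs <- assemble_haplotypes(reads, sites, k_max = k)
    obs <- split(reads[, c("pos", "base")], reads$read_id)
    allele_sets <- lapply(seq_len(m), function(s) {
      b <- c("A", "C", "G", "T")[which(as.integer(sites[s, c("A", "C", "G", "T")]) > 0L)]
      b
    })
    bf <- brute_force_haplotypes(obs, allele_sets, pos, k)
    greedy_explained <- sum(vapply(obs, function(r) {
      any(vapply(hs$haplotypes$sequence, function(h) {
        alle <- strsplit(h, "")[[1L]]
        all(r$base == alle[match(r$pos, pos)])
      }, logical(1L)))
    }, logical(1L)))
    expect_equal(greedy_explained, bf$score)
    expect_true(list(sort(hs$haplotypes$sequence)) %in% bf$sets ||
                greedy_explained == length(obs))
  }
})

test_that("dosage estimation recovers allelic ratios from site fractions", {
  mk_sites <- function(frac_major, depth = 100L) {
    n1 <- round(depth * frac_major)
    site_df(c(100L, 150L),
            rbind(c(n1, 0L, depth - n1, 0L), c(0L, n1, 0L, depth - n1)))
  }
  hs <- structure(list(
    positions = c(100L, 150L),
    haplotypes = data.frame(sequence = c("AC", "GT"), support = c(10L, 5L),
                            dosage = NA_integer_),
    n_reads = 15L), class = "haplotype_set")
  d3 <- estimate_dosage(hs, mk_sites(0.67), 3L)
  expect_equal(d3$haplotypes$dosage, c(2L, 1L))
  d4 <- estimate_dosage(hs, mk_sites(0.75), 4L)
  expect_equal(d4$haplotypes$dosage, c(3L, 1L))
  d22 <- estimate_dosage(hs, mk_sites(0.5), 4L)
  expect_equal(d22$haplotypes$dosage, c(2L, 2L))
  expect_error(estimate_dosage(hs, mk_sites(0.5), 1L), "copy number")
})

test_that("dosage estimation equals the exhaustive arg-min for copy <= 6", {
  set.seed(31)
  for (trial in 1:10) {
    k <- sample(2:3, 1L)
    copy <- sample(k:6, 1L)
    m <- 4L
    pos <- (1:m) * 50L
    repeat {
      haps <- vapply(seq_len(k), function(i) {
        paste(sample(c("A", "C", "G", "T"), m, replace = TRUE), collapse = "")
      }, "")
      if (length(unique(haps)) == k) break
    }
    truth_d <- as.integer(rmultinom(1L, copy - k, rep(1 / k, k))) + 1L
    ## observed fractions = true dosage fractions + noise
    alle <- do.call(rbind, strsplit(haps, ""))
    counts <- matrix(0L, nrow = m, ncol = 4L,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
    for (s in seq_len(m)) {
      for (h in seq_len(k)) {
        b <- match(alle[h, s], c("A", "C", "G", "T"))
        counts[s, b] <- counts[s, b] + truth_d[h] * 30L
      }
      counts[s, ] <- counts[s, ] + sample(0:3, 4L, replace = TRUE)
    }
    sites <- site_df(pos, counts)
    hs <- structure(list(
      positions = pos,
      haplotypes = data.frame(sequence = haps, support = rep(10L, k),
                              dosage = NA_integer_),
      n_reads = 30L), class = "haplotype_set")
    est <- estimate_dosage(hs, sites, copy)
    obs_frac <- counts / rowSums(counts)
    objs <- vapply(oracle_compositions(copy, k), function(d) {
      oracle_dosage_objective(d, haps, obs_frac)
    }, numeric(1L))
    got_obj <- oracle_dosage_objective(est$haplotypes$dosage, haps, obs_frac)
    expect_equal(unname(got_obj), unname(min(objs)), tolerance = 1e-12)
  }
})

test_that("haplotype FASTA round-trips with reference fill", {
  hs <- structure(list(
    positions = c(105L, 110L),
    haplotypes = data.frame(sequence = c("AT", "GC"), support = c(10L, 10L),
                            dosage = c(2L, 1L)),
    n_reads = 20L), class = "haplotype_set")
  ref <- strrep("A", 20L)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_haplotypes(hs, ref, c(100L, 120L), f)
  back <- Biostrings::readDNAStringSet(f)
  expect_equal(names(back), c("100-120:1:2", "100-120:2:1"))
  s1 <- as.character(back[[1L]])
  expect_equal(substr(s1, 6L, 6L), "A")
  expect_equal(substr(s1, 11L, 11L), "T")
  s2 <- as.character(back[[2L]])
  expect_equal(substr(s2, 6L, 6L), "G")
  expect_equal(substr(s2, 11L, 11L), "C")
  expect_equal(nchar(s1), 20L)
})

test_that("noisy reads still recover planted haplotypes at high rate", {
  ## 1% per-base error, ~depth 60, 6 sites: aggregate recovery over replicates
  set.seed(77)
  n_rep <- 100L
  recovered <- 0L
  total <- 0L
  for (rep in seq_len(n_rep)) {
    k <- sample(2:3, 1L)
    pos <- (1:6) * 30L
    haps <- distinct_hap_strings(k, 6L)
    reads <- reads_from_haplotypes(haps, pos, span = 3L,
                                   n_per = max(2L, 60L %/% (k * 4L)),
                                   error_rate = 0.01)
    sites <- sites_from_reads(reads, pos)
    hs <- try(assemble_haplotypes(reads, sites, k_max = 3L), silent = TRUE)
    total <- total + k
    if (!inherits(hs, "try-error")) {
      recovered <- recovered + sum(haps %in% hs$haplotypes$sequence)
    }
  }
  expect_gte(recovered / total, 0.95)
})
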