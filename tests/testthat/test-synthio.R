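test_that("zero het density with no third haplome yields zero het sites", {
  cfg <- sim_config(genome_length = 2e4, base_ploidy = 2,
                    het_density_core = 0, error_rate = 0, seed = 1)
  truth <- simulate_genome(cfg)
  expect_length(truth$het_sites, 0L)
  pp <- simulate_pileup(truth)
  cnt <- as.matrix(pp[, c("A", "C", "G", "T")])
  expect_true(all(apply(cnt, 1L, max) == rowSums(cnt)))
})

test_that("third-haplome divergence matches the binomial expectation", {
  L <- 1e5
  cfg <- sim_config(genome_length = L, base_ploidy = 3,
                    het_density_core = 0.005, divergence_third = 0.05, seed = 7)
  truth <- simulate_genome(cfg)
  frac_div <- mean(truth$haplomes[3L, ] != truth$haplomes[1L, ])
  se <- sqrt(0.05 * 0.95 / L)
  expect_lt(abs(frac_div - 0.05), 4 * se)
  ## sites with a third-haplome-specific base (differs from both core copies)
  spec3 <- mean(truth$haplomes[3L, ] != truth$haplomes[1L, ] &
                truth$haplomes[3L, ] != truth$haplomes[2L, ])
  expect_lt(abs(spec3 - 0.05), 5 * se + 0.005 * 0.05)
})

test_that("a planted conversion tract contains no heterozygous site", {
  for (bp in c(2L, 3L)) {
    cfg <- sim_config(genome_length = 1e5, base_ploidy = bp,
                      loh_tracts = data.frame(start = 30000L, end = 80000L,
                                              mechanism = "conversion"),
                      seed = 5)
    truth <- simulate_genome(cfg)
    inside <- truth$het_sites >= 30000L & truth$het_sites < 80000L
    expect_equal(sum(inside), 0L)
    expect_gt(sum(!inside), 0L)
    ## copy number is preserved inside the tract
    k <- findInterval(50000L, truth$dosage$start)
    expect_equal(truth$dosage$copy[k], bp)
  }
})

test_that("overlapping event intervals are rejected naming both intervals", {
  expect_error(
    sim_config(genome_length = 1e5,
               loh_tracts = data.frame(start = 1000L, end = 20000L,
                                       mechanism = "conversion"),
               cnv_segments = data.frame(start = 15000L, end = 30000L,
                                         copy = 4L, ratio = "2:1:1")),
    "overlapping.*\\[1000,20000\\).*\\[15000,30000\\)"
  )
})

test_that("depth scales with summed haplome dosage and deletions are depth 0", {
  cfg <- sim_config(genome_length = 2e5, base_ploidy = 3, mean_depth = 60,
                    cnv_segments = data.frame(start = 50000L, end = 100000L,
                                              copy = 4L, ratio = "2:1:1"),
                    deletions = data.frame(start = 150000L, end = 160000L),
                    error_rate = 0, seed = 9)
  truth <- simulate_genome(cfg)
  pp <- simulate_pileup(truth)
  base_idx <- pp$cpos0 < 50000L
  cnv_idx <- pp$cpos0 >= 50000L & pp$cpos0 < 100000L
  del_idx <- pp$cpos0 >= 150000L & pp$cpos0 < 160000L
  se <- function(lambda, n) sqrt(lambda / n)
  expect_lt(abs(mean(pp$depth[base_idx]) - 60), 2 * se(60, sum(base_idx)) + 0.05)
  expect_lt(abs(mean(pp$depth[cnv_idx]) - 80), 3 * se(80, sum(cnv_idx)) + 0.05)
  expect_true(all(pp$depth[del_idx] == 0L))
})

test_that("triploid 2:1 het site allele fractions follow the dosage", {
  ## dosage 2:1 at error 0: expected major fraction 2/3 of the depth
  cfg <- sim_config(genome_length = 5e4, base_ploidy = 3, mean_depth = 60,
                    het_density_core = 0.01, divergence_third = 0,
                    error_rate = 0, seed = 13)
  truth <- simulate_genome(cfg)
  pp <- simulate_pileup(truth)
  hs <- truth$het_sites
  cnt <- as.matrix(pp[hs + 1L, c("A", "C", "G", "T")])
  frac_major <- apply(cnt, 1L, max) / rowSums(cnt)
  expect_lt(abs(mean(frac_major) - 2 / 3), 0.01)
})

test_that("no phantom alleles at error rate 0", {
  cfg <- sim_config(genome_length = 3e4, base_ploidy = 3, error_rate = 0,
                    seed = 21)
  truth <- simulate_genome(cfg)
  pp <- simulate_pileup(truth)
  cnt <- as.matrix(pp[, c("A", "C", "G", "T")])
  ok <- vapply(seq_len(nrow(pp)), function(i) {
    seen <- which(cnt[i, ] > 0L)
    all(seen %in% truth$haplomes[, i])
  }, logical(1L))
  expect_true(all(ok))
})

test_that("major-allele frequency converges to max dosage / total at high depth", {
  cfg2 <- sim_config(genome_length = 2000, base_ploidy = 2, mean_depth = 10000,
                     het_density_core = 0.01, error_rate = 0, seed = 17)
  t2 <- simulate_genome(cfg2)
  p2 <- simulate_pileup(t2)
  m2 <- {
    cnt <- as.matrix(p2[t2$het_sites + 1L, c("A", "C", "G", "T")])
    mean(apply(cnt, 1L, max) / rowSums(cnt))
  }
  expect_lt(abs(m2 - 0.5), 0.008)
  cfg3 <- sim_config(genome_length = 2000, base_ploidy = 3, mean_depth = 10000,
                     het_density_core = 0.01, divergence_third = 0,
                     error_rate = 0, seed = 18)
  t3 <- simulate_genome(cfg3)
  p3 <- simulate_pileup(t3)
  m3 <- {
    cnt <- as.matrix(p3[t3$het_sites + 1L, c("A", "C", "G", "T")])
    mean(apply(cnt, 1L, max) / rowSums(cnt))
  }
  expect_lt(abs(m3 - 2 / 3), 0.008)
})

test_that("pileup simulation is byte-deterministic given the seed", {
  cfg <- sim_config(genome_length = 2e4, base_ploidy = 3, seed = 33)
  a <- simulate_pileup(simulate_genome(cfg))
  b <- simulate_pileup(simulate_genome(cfg))
  expect_identical(a, b)
})

test_that("simulated reads report consistent haplotypes at error 0", {
  ## diploid locus, het sites only where planted
  cfg <- sim_config(genome_length = 5000, base_ploidy = 2,
                    het_density_core = 0, error_rate = 0, read_len = 100,
                    mean_depth = 40, seed = 41)
  truth <- simulate_genome(cfg)
  ## plant two het sites 20 bp apart by editing haplome 2
  truth$haplomes[2L, 2001L] <- (truth$haplomes[1L, 2001L] %% 4L) + 1L
  truth$haplomes[2L, 2021L] <- (truth$haplomes[1L, 2021L] %% 4L) + 1L
  truth$het_sites <- c(2000L, 2020L)
  reads <- simulate_reads(truth, c(1900L, 2100L))
  both <- split(reads, reads$read_id)
  both <- both[vapply(both, nrow, 1L) == 2L]
  expect_gt(length(both), 10L)
  h1 <- paste(ploidyscape:::BASES[truth$haplomes[1L, c(2001L, 2021L)]], collapse = "")
  h2 <- paste(ploidyscape:::BASES[truth$haplomes[2L, c(2001L, 2021L)]], collapse = "")
  obs <- vapply(both, function(r) paste(r$base[order(r$pos)], collapse = ""), "")
  expect_true(all(obs %in% c(h1, h2)))
})

test_that("triploid reads partition into three balanced co-occurrence classes", {
  cfg <- sim_config(genome_length = 5000, base_ploidy = 3,
                    het_density_core = 0, divergence_third = 0,
                    error_rate = 0, read_len = 100, mean_depth = 200, seed = 43)
  truth <- simulate_genome(cfg)
  ## three distinguishable haplotypes over two sites
  truth$haplomes[, 2001L] <- c(1L, 2L, 3L)
  truth$haplomes[, 2021L] <- c(1L, 2L, 4L)
  truth$het_sites <- c(2000L, 2020L)
  reads <- simulate_reads(truth, c(1950L, 2070L))
  both <- split(reads, reads$read_id)
  both <- both[vapply(both, nrow, 1L) == 2L]
  obs <- vapply(both, function(r) paste(r$base[order(r$pos)], collapse = ""), "")
  tab <- table(obs)
  expect_setequal(names(tab), c("AA", "CC", "GT"))
  expect_gt(min(tab) / max(tab), 0.5)   # ~1:1:1 at equal dosage
})

test_that("a locus without het sites yields an empty read list with a warning", {
  cfg <- sim_config(genome_length = 10000, base_ploidy = 2,
                    het_density_core = 0, error_rate = 0, seed = 45)
  truth <- simulate_genome(cfg)
  expect_warning(reads <- simulate_reads(truth, c(1000L, 2000L)),
                 "no heterozygous site")
  expect_equal(nrow(reads), 0L)
})

test_that("truth BED files round-trip through the reader", {
  cfg <- sim_config(genome_length = 1e5, base_ploidy = 3,
                    loh_tracts = data.frame(start = 10000L, end = 20000L,
                                            mechanism = "conversion"),
                    cnv_segments = data.frame(start = 1000L, end = 6000L,
                                              copy = 4L, ratio = "2:1:1"),
                    deletions = data.frame(start = 90000L, end = 95000L),
                    seed = 2)
  truth <- simulate_genome(cfg)
  dir <- withr::local_tempdir()
  paths <- write_truth(truth, dir)
  cnv <- read_bed(paths[["cnv"]])
  expect_equal(cnv$start, 1000L)
  expect_equal(cnv$end, 6000L)
  expect_equal(cnv$score, 4)
  loh <- read_bed(paths[["loh"]])
  expect_equal(loh$name, "conversion")
  ## empty event class still writes a valid (empty) BED
  cfg0 <- sim_config(genome_length = 1e4, seed = 3)
  p0 <- write_truth(simulate_genome(cfg0), withr::local_tempdir())
  expect_equal(nrow(read_bed(p0[["deletions"]])), 0L)
})
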