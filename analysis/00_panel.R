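# Shared definition of the synthetic strain panel used by the numbered
# analysis scripts.  Three 1 Mb strains mirror the study design: one
# allotriploid with modest LOH and a 4n amplification, and two diploids
# with extensive conversion-driven LOH, one of which has lost the
# nitrate-assimilation gene cluster.

library(ploidyscape)

strain_panel <- function() {
  list(
    triploid_T1 = list(
      description = "allotriploid; 3% conversion LOH; one 100 kb 4n amplification",
      config = sim_config(
        genome_length = 1e6, n_contigs = 4L, base_ploidy = 3L,
        het_density_core = 0.005, divergence_third = 0.05,
        loh_tracts = data.frame(start = 300000L, end = 330000L,
                                mechanism = "conversion"),
        cnv_segments = data.frame(start = 600000L, end = 700000L,
                                  copy = 4L, ratio = "2:1:1"),
        mean_depth = 50, error_rate = 0.005, seed = 501L)),
    diploid_D1 = list(
      description = "diploid; ~18% LOH (conversion + one het deletion); nitrate cluster deleted",
      config = sim_config(
        genome_length = 1e6, n_contigs = 4L, base_ploidy = 2L,
        het_density_core = 0.005,
        loh_tracts = data.frame(
          start = c(50000L, 300000L, 520000L, 800000L),
          end = c(120000L, 360000L, 560000L, 830000L),
          mechanism = c("conversion", "conversion", "conversion", "deletion")),
        deletions = data.frame(start = 34900L, end = 41000L),
        mean_depth = 50, error_rate = 0.005, seed = 502L)),
    diploid_D2 = list(
      description = "diploid; ~16% conversion LOH; two amplified regions",
      config = sim_config(
        genome_length = 1e6, n_contigs = 4L, base_ploidy = 2L,
        het_density_core = 0.005,
        loh_tracts = data.frame(
          start = c(400000L, 600000L, 900000L),
          end = c(450000L, 680000L, 930000L),
          mechanism = "conversion"),
        cnv_segments = data.frame(start = c(200000L, 700000L),
                                  end = c(240000L, 740000L),
                                  copy = c(3L, 4L), ratio = c("2:1", "2:2")),
        mean_depth = 50, error_rate = 0.005, seed = 503L))
  )
}

panel_gff <- function() {
  system.file("extdata", "nitrate_cluster_synthetic.gff3",
              package = "ploidyscape")
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}
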