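# A scaled-down simulation configuration for unit tests (the acceptance
# tests use the full default configuration).
small_config <- function(seed = 1, ...) {
  args <- list(
    seed = seed,
    n_chroms = 3L, chrom_length_bp = 5e6, markers_per_mb = 100,
    n_local_controls = 60L, n_global_controls = 400L,
    injections = list(
      list(type = "DIGENIC_PAIR", chrom = c("1", "2"), pos = c(2.5e6, 2.5e6),
           gene = c("GENE_R1", "GENE_R2"), impact = c("MODERATE", "HIGH"),
           carrier_freq_in_controls = c(0.01, 0.01),
           screen_freq = c(0.05, 0.02)),
      list(type = "PATERNAL_DENOVO", chrom = "3", pos = 2.5e6,
           gene = "GENE_D1", impact = "MODERATE",
           carrier_freq_in_controls = 0)),
    n_screened = 100L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
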