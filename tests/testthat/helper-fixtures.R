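# Shared in-code fixtures for the test suite.

# Long counts row constructor.
cnt <- function(pool, pos, ref, nonref, chrom = "chr10") {
  data.frame(pool = pool, chrom = chrom, pos = pos, ref_base = "A",
             ref = ref, nonref = nonref, nonref_base = "G",
             depth = ref + nonref, stringsAsFactors = FALSE)
}

# The five-SC / six-WGS pool layout used throughout.
test_pools <- function() sim_config()$pool_specs

test_scheme <- function() phenotype_scheme(test_pools())

# Classification row constructor (one cutoff).
clrow <- function(pool, class, pos = 100, cutoff = 0.99) {
  data.frame(pool = pool, chrom = "chr10", pos = pos, class = class,
             fraction = NA_real_, depth = 1000, cutoff = cutoff,
             stringsAsFactors = FALSE)
}

# Noise-free study-condition config: degenerate drift, no read error,
# phenotype-matched haplotypes exactly fixed.
noise_free_config <- function(seed = 1, n_snps = 200) {
  sim_config(n_snps = n_snps, error_rate = 0, drift_strength = Inf,
             causal_major_freq = 1, recomb_prob = 0, mass_noise_sd = 0,
             seed = seed)
}

# Path to the shipped breed panel (Table-1-style fixture).
panel_path <- function() {
  system.file("extdata", "gwas_breed_panel.tsv", package = "breedscan")
}

pool_panel_path <- function() {
  system.file("extdata", "resequencing_pools.tsv", package = "breedscan")
}
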