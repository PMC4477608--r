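test_that("identical configurations reproduce identical simulations", {
  cfg <- sim_config(n_snps = 40, seed = 9)
  p1 <- simulate_breed_panel(cfg); p2 <- simulate_breed_panel(cfg)
  expect_identical(p1, p2)
  t1 <- simulate_haplotype_pools(cfg, p1)
  t2 <- simulate_haplotype_pools(cfg, p2)
  expect_identical(t1$breed_freq, t2$breed_freq)
  expect_identical(t1$genotypes, t2$genotypes)
  s1 <- simulate_pool_pileups(t1, cfg); s2 <- simulate_pool_pileups(t2, cfg)
  expect_identical(s1$counts, s2$counts)
})

test_that("breed mass follows baseline + effect x S-haplotype dosage", {
  cfg0 <- sim_config(mass_effect_kg = 0, mass_noise_sd = 0, seed = 1)
  p0 <- simulate_breed_panel(cfg0)
  expect_true(all(p0$body_mass_kg == cfg0$mass_baseline_kg))

  cfg <- sim_config(mass_effect_kg = -8, mass_noise_sd = 0, seed = 1)
  p <- simulate_breed_panel(cfg)
  small <- p$body_mass_kg[p$s_dosage == 2][1]
  large <- p$body_mass_kg[p$s_dosage == 0][1]
  expect_equal(large - small, 16)
})

test_that("config validation rejects bad designs", {
  expect_error(sim_config(ear_block_span = c(11.4e6, 11.5e6),
                          mass_block_span = c(11.0e6, 11.1e6)),
               "5'->3'")
  expect_error(sim_config(error_rate = 0.6), "error_rate")
  b <- sim_config()$breeds[1, ]
  expect_error(sim_config(breeds = b), "2 breeds|members")
})

test_that("degenerate drift fixes drop breeds for the D haplotype", {
  cfg <- noise_free_config(seed = 3, n_snps = 10)
  panel <- simulate_breed_panel(cfg)
  truth <- simulate_haplotype_pools(cfg, panel)
  drop_breeds <- panel$breed[panel$ear_type == "drop" & !panel$is_wolf]
  ear_snps <- truth$causal$ear
  for (b in drop_breeds) {
    g <- truth$genotypes[truth$samples$breed == b, ear_snps, drop = FALSE]
    expect_true(all(g == 2), info = b)   # every individual D/D
  }
  # no recombination: no chromosome carries both D-ear and S-mass alleles
  hap_lbl <- as.vector(truth$hap_pairs)
  expect_false(any(grepl("/", hap_lbl)))
})

test_that("sampled genotype frequencies recover breed truth (binomial oracle)", {
  cfg <- sim_config(n_snps = 5, samples_per_breed = 10000,
                    breeds = sim_config()$breeds[c(1, 4), ],
                    pool_specs = data.frame(
                      pool = c("p1", "p2"), members = c("terrier_a", "pointer"),
                      kind = "SC", mean_depth = 1000,
                      size_class = c("small", "large"),
                      ear_class = c("non-drop", "drop"), is_wolf = FALSE),
                    seed = 5)
  panel <- simulate_breed_panel(cfg)
  truth <- simulate_haplotype_pools(cfg, panel)
  bg <- truth$map$snp[truth$map$role == "background"]
  for (b in panel$breed) {
    g <- truth$genotypes[truth$samples$breed == b, bg, drop = FALSE]
    est <- colMeans(g) / 2
    f <- truth$breed_freq[b, bg]
    se <- sqrt(pmax(f * (1 - f), 1e-12) / (2 * 10000))
    expect_true(all(abs(est - f) <= 3 * se + 1e-9), info = b)
  }
})

test_that("pooled reads are error-free copies of truth when e = 0", {
  cfg <- noise_free_config(seed = 2, n_snps = 30)
  panel <- simulate_breed_panel(cfg)
  truth <- simulate_haplotype_pools(cfg, panel)
  sim <- simulate_pool_pileups(truth, cfg)
  # conservation: ref + nonref = depth always
  expect_true(all(sim$counts$ref + sim$counts$nonref == sim$counts$depth))
  for (p in sim$pools$pool) {
    f <- truth$pool_freq[p, ]
    x <- sim$counts[sim$counts$pool == p, ]
    fixed1 <- names(f)[f == 1]
    fixed0 <- names(f)[f == 0]
    key <- sprintf("%s:%d", x$chrom, x$pos)
    expect_true(all(x$ref[key %in% fixed1] == 0))
    expect_true(all(x$nonref[key %in% fixed0] == 0))
  }
})

test_that("read error biases the frequency estimate by e(1 - 2f)", {
  e <- 0.05
  cfg <- sim_config(n_snps = 0, error_rate = e, drift_strength = Inf,
                    causal_major_freq = 1, recomb_prob = 0, seed = 8,
                    n_dogwolf = 0)
  panel <- simulate_breed_panel(cfg)
  truth <- simulate_haplotype_pools(cfg, panel)
  sim <- simulate_pool_pileups(truth, cfg)
  x <- sim$counts[sim$counts$pool == "GS", ]   # deep pool, f known per site
  f <- truth$pool_freq["GS", sprintf("%s:%d", x$chrom, x$pos)]
  est <- x$nonref / x$depth
  expected <- f + e * (1 - 2 * f)
  se <- sqrt(expected * (1 - expected) / x$depth)
  expect_true(all(abs(est - expected) <= 4 * se + 1e-9))
})

test_that("binomial concentration holds at f = 0.5 and depth 5000", {
  set.seed(11)
  depth <- 5000
  p <- 0.5 * (1 - 0.01) + 0.5 * 0.01
  frac <- rbinom(50, depth, p) / depth
  expect_true(all(abs(frac - 0.5) <= 3 * sqrt(0.25 / depth) + 1e-12))
})

test_that("plant_cnv scales depths only where and for whom requested", {
  cfg <- sim_config(n_snps = 50, seed = 4)
  panel <- simulate_breed_panel(cfg)
  truth <- simulate_haplotype_pools(cfg, panel)
  sim <- simulate_pool_pileups(truth, cfg)
  same <- plant_cnv(sim$counts, c(10e6, 10.1e6), fold = 1, pools = "BT")
  expect_equal(same$depth, sim$counts$depth)

  gone <- plant_cnv(sim$counts, c(10e6, 10.1e6), fold = 0, pools = "BT")
  sel <- gone$pool == "BT" & gone$pos >= 10e6 & gone$pos <= 10.1e6
  expect_true(any(sel))
  expect_true(all(gone$depth[sel] == 0))
  expect_equal(gone$depth[!sel], sim$counts$depth[!sel])

  expect_error(plant_cnv(sim$counts, c(1, 100), 2, "BT"), "outside")
  expect_error(plant_cnv(sim$counts, c(10e6, 10.1e6), 2, "nope"), "unknown")
})

test_that("fold-2.5 duplication shifts mean depth by ~2.5x in the target pool", {
  cfg <- sim_config(seed = 6)
  d <- simulate_depth_windows(cfg, window = 100)
  iv <- c(10e6 + 1, 10e6 + 5000)
  d2 <- plant_cnv(d, iv, fold = 2.5, pools = "BT")
  sel <- d2$start >= iv[1] & d2$start <= iv[2]
  r <- mean(d2$depth[sel & d2$pool == "BT"]) /
    mean(d2$depth[sel & d2$pool == "GS"]) *
    (cfg$pool_specs$mean_depth[3] / cfg$pool_specs$mean_depth[1])
  expect_equal(r, 2.5, tolerance = 0.02)
})

test_that("true pool frequencies are member-breed averages and truth writes out", {
  cfg <- sim_config(n_snps = 20, seed = 12)
  panel <- simulate_breed_panel(cfg)
  truth <- simulate_haplotype_pools(cfg, panel)
  # per-breed haplotype frequencies sum to 1
  expect_true(all(abs(rowSums(truth$hap_freq) - 1) < 1e-9))
  w2 <- truth$pool_freq["W2", ]
  expect_equal(w2, colMeans(truth$breed_freq[c("spitz", "collie"), ]),
               tolerance = 1e-12)
  d <- withr::local_tempdir()
  write_truth_set(truth, d)
  expect_true(all(file.exists(file.path(d, c("snp_map.tsv", "breed_freq.tsv",
                                             "genotypes.tsv")))))
})
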