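# Synthetic breed-pool data generator.
#
# Emulates the study design the pipeline was built for: a ~3 Mb region
# resequenced in high-coverage single-breed sequence-capture (SC) pools and
# low-coverage multi-breed whole-genome (WGS) pools including one wolf pool,
# with two linked causal haplotype blocks (a 5' ear block and a 3' body-mass
# block) riding on three founder haplotypes:
#   D - carries the drop-ear alleles,
#   S - carries the small-body-mass alleles,
#   L - carries neither (large, non-drop; the wolf-like arrangement).
# Breed allele-frequency structure is created by beta-distributed drift
# around phenotype-consistent haplotype frequencies.

#' Configuration for the synthetic breed-pool simulator
#'
#' All downstream randomness is controlled by \code{seed}: the same
#' configuration yields byte-identical outputs.
#'
#' @param n_snps Number of background (non-causal) SNPs in the region.
#' @param region Two-element numeric, 1-based inclusive bounds of the
#'   simulated region. Default \code{c(9.5e6, 12.5e6)} (3 Mb).
#' @param chrom Chromosome name for emitted sites.
#' @param ear_block_span,mass_block_span Position intervals of the two causal
#'   blocks; must be disjoint and ordered 5' to 3' within the region.
#' @param n_causal_ear,n_causal_mass Number of causal SNPs planted in each
#'   block.
#' @param n_dogwolf Number of planted dog-wolf fixed differences.
#' @param dogwolf_span Interval in which dog-wolf fixations cluster.
#' @param breeds Data.frame describing the breed panel design: columns
#'   \code{breed}, \code{ear_type} (drop/intermediate/prick),
#'   \code{size_class} (small/large), \code{is_wolf}. Defaults mirror the
#'   pool design: two small and one large non-drop breed and two large drop
#'   breeds backing the SC pools, further large breeds backing the WGS pools,
#'   and one wolf population.
#' @param pool_specs Data.frame describing pools: \code{pool},
#'   \code{members} (breed names, ';'-separated), \code{kind} (SC/WGS),
#'   \code{mean_depth}, \code{size_class} (small/large),
#'   \code{ear_class} (drop/non-drop/mixed), \code{is_wolf}.
#' @param samples_per_breed Individuals genotyped per breed.
#' @param error_rate Per-read probability of a symmetric base flip
#'   (default 0.002).
#' @param drift_strength Beta concentration parameter for breed drift around
#'   target frequencies; \code{Inf} gives the target exactly.
#' @param causal_major_freq Frequency at which the phenotype-matched founder
#'   haplotype is centred in the breeds carrying it (default 1, i.e. fixed).
#' @param recomb_prob Probability that a transmitted haplotype recombines
#'   between the two causal blocks (default 0.005, matching the rarity of
#'   observed recombinants).
#' @param mass_baseline_kg Baseline breed-average body mass (kg).
#' @param mass_effect_kg Additive effect (kg) on breed-average mass per copy
#'   of the S haplotype (default -8: two copies make a ~9 kg breed from a
#'   25 kg baseline).
#' @param mass_noise_sd Log-normal SD of the breed mass baseline.
#' @param seed Integer seed fixing all randomness.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_snps = 200,
                       region = c(9.5e6, 12.5e6),
                       chrom = "chr10",
                       ear_block_span = c(11.02e6, 11.08e6),
                       mass_block_span = c(11.34e6, 11.43e6),
                       n_causal_ear = 7,
                       n_causal_mass = 8,
                       n_dogwolf = 12,
                       dogwolf_span = c(10916652, 10943326),
                       breeds = NULL,
                       pool_specs = NULL,
                       samples_per_breed = 12,
                       error_rate = 0.002,
                       drift_strength = 50,
                       causal_major_freq = 1,
                       recomb_prob = 0.005,
                       mass_baseline_kg = 25,
                       mass_effect_kg = -8,
                       mass_noise_sd = 0.15,
                       seed = 1L) {
  if (is.null(breeds)) breeds <- default_sim_breeds()
  if (is.null(pool_specs)) pool_specs <- default_sim_pools()
  cfg <- list(n_snps = n_snps, region = region, chrom = chrom,
              ear_block_span = ear_block_span,
              mass_block_span = mass_block_span,
              n_causal_ear = n_causal_ear, n_causal_mass = n_causal_mass,
              n_dogwolf = n_dogwolf, dogwolf_span = dogwolf_span,
              breeds = breeds, pool_specs = pool_specs,
              samples_per_breed = samples_per_breed,
              error_rate = error_rate, drift_strength = drift_strength,
              causal_major_freq = causal_major_freq,
              recomb_prob = recomb_prob,
              mass_baseline_kg = mass_baseline_kg,
              mass_effect_kg = mass_effect_kg,
              mass_noise_sd = mass_noise_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

default_sim_breeds <- function() {
  data.frame(
    breed = c("terrier_a", "terrier_b", "shepherd", "pointer", "spaniel",
              "retriever", "hound", "spitz", "collie", "pinscher", "wolf"),
    ear_type = c("prick", "prick", "prick", "drop", "drop",
                 "drop", "drop", "prick", "intermediate", "intermediate",
                 "prick"),
    size_class = c("small", "small", "large", "large", "large",
                   "large", "large", "large", "large", "large", "large"),
    is_wolf = c(rep(FALSE, 10), TRUE),
    stringsAsFactors = FALSE)
}

default_sim_pools <- function() {
  data.frame(
    pool = c("BT", "JR", "GS", "WEI", "ESS",
             "W1", "W2", "W3", "W4", "W5", "W6"),
    members = c("terrier_a", "terrier_b", "shepherd", "pointer", "spaniel",
                "wolf", "spitz;collie", "retriever;hound", "retriever",
                "spitz", "collie;pinscher"),
    kind = c(rep("SC", 5), rep("WGS", 6)),
    mean_depth = c(4748, 4910, 5182, 4305, 1990,
                   7.5, 6.9, 6.1, 8.0, 8.1, 7.9),
    size_class = c("small", "small", "large", "large", "large",
                   rep("large", 6)),
    ear_class = c("non-drop", "non-drop", "non-drop", "drop", "drop",
                  "non-drop", "mixed", "drop", "drop", "non-drop", "mixed"),
    is_wolf = c(rep(FALSE, 5), TRUE, rep(FALSE, 5)),
    stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_snps >= 0, length(cfg$region) == 2,
            cfg$region[2] > cfg$region[1])
  e <- cfg$ear_block_span; m <- cfg$mass_block_span
  if (!(e[1] < e[2] && m[1] < m[2] && e[2] < m[1])) {
    stop("ear_block_span and mass_block_span must be disjoint and ordered 5'->3'")
  }
  if (e[1] < cfg$region[1] || m[2] > cfg$region[2]) {
    stop("causal blocks must lie within the region")
  }
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.5) {
    stop("error_rate must be in [0, 0.5)")
  }
  if (any(cfg$pool_specs$mean_depth <= 0)) stop("all pool depths must be > 0")
  if (nrow(cfg$breeds) < 2) stop("need at least 2 breeds")
  unknown <- setdiff(unlist(strsplit(cfg$pool_specs$members, ";")),
                     cfg$breeds$breed)
  if (length(unknown) > 0) {
    stop("pool members not in breed table: ", paste(unknown, collapse = ", "))
  }
  invisible(cfg)
}

# Draw from Beta with mean m and concentration k; degenerate cases return m.
rbeta_mean <- function(n, m, k) {
  if (length(m) == 1L) m <- rep(m, n)
  stopifnot(length(m) == n)
  if (!is.finite(k)) return(m)
  out <- m
  idx <- m > 0 & m < 1
  out[idx] <- stats::rbeta(sum(idx), m[idx] * k, (1 - m[idx]) * k)
  out
}

#' Simulate a breed panel with phenotype-linked body mass
#'
#' Assigns each breed its ear class, a breed-average body mass drawn from a
#' log-normal baseline plus \code{mass_effect_kg} per expected copy of the
#' small (S) haplotype, and a fixed number of samples. The S-haplotype dosage
#' used for the mass effect is the design dosage (2 for small breeds, 0
#' otherwise), so with zero noise and zero effect all masses equal the
#' baseline.
#'
#' @param cfg A [sim_config()].
#' @return Data.frame (class \code{breed_panel}) with columns \code{breed},
#'   \code{n}, \code{ear_type}, \code{ear_code}, \code{size_class},
#'   \code{is_wolf}, \code{s_dosage}, \code{body_mass_kg}.
#' @export
simulate_breed_panel <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  b <- cfg$breeds
  b$n <- cfg$samples_per_breed
  b$ear_code <- c(prick = 1, intermediate = 2, drop = 3)[b$ear_type]
  b$s_dosage <- ifelse(b$size_class == "small", 2, 0)
  noise <- if (cfg$mass_noise_sd > 0) {
    exp(stats::rnorm(nrow(b), 0, cfg$mass_noise_sd))
  } else rep(1, nrow(b))
  b$body_mass_kg <- cfg$mass_baseline_kg * noise +
    cfg$mass_effect_kg * b$s_dosage
  b$body_mass_kg <- pmax(b$body_mass_kg, 1)
  class(b) <- c("breed_panel", "data.frame")
  b
}

#' Simulate founder haplotypes, breed frequencies and individual genotypes
#'
#' Plants the two-block causal architecture: founder haplotype D carries the
#' non-reference alleles at all ear-block causal SNPs, S carries them at all
#' mass-block causal SNPs, and L carries neither. Breed haplotype frequencies
#' are drawn from a beta distribution centred on phenotype-consistent values
#' (drop breeds near-fixed for D, small breeds for S, other dog breeds and
#' the wolf for L), background SNP frequencies drift per breed around a
#' shared ancestral frequency, and planted dog-wolf sites are fixed
#' non-reference in every dog breed and reference in the wolf. Individuals
#' receive two haplotypes sampled from their breed's frequencies, with
#' between-block recombinants at rate \code{recomb_prob}.
#'
#' @param cfg A [sim_config()].
#' @param panel Output of [simulate_breed_panel()].
#' @return A \code{truth_set} list: \code{map} (SNP map with \code{role}
#'   ear/mass/dogwolf/background and \code{causal} flag), \code{breed_freq}
#'   (breeds x SNPs non-reference allele frequency), \code{hap_freq}
#'   (breeds x 3 founder haplotype frequencies), \code{genotypes} (samples x
#'   SNPs dosage matrix), \code{samples} (sample, breed), \code{hap_pairs}
#'   (founder labels per sample chromosome), \code{pool_freq} (pools x SNPs
#'   true pool frequencies), \code{causal} (SNP ids per trait), \code{cnv}
#'   (planted CNV table, empty here).
#' @export
simulate_haplotype_pools <- function(cfg, panel) {
  stopifnot(inherits(panel, "breed_panel"))
  set.seed(cfg$seed + 1L)
  map <- build_snp_map(cfg)
  nb <- nrow(panel)
  nsnp <- nrow(map)

  # founder haplotypes over causal-block SNPs (1 = non-reference allele)
  founders <- c("D", "L", "S")
  hap_alleles <- matrix(0L, nrow = 3, ncol = nsnp,
                        dimnames = list(founders, map$snp))
  hap_alleles["D", map$role == "ear"] <- 1L
  hap_alleles["S", map$role == "mass"] <- 1L

  # phenotype-consistent target haplotype frequencies per breed
  target <- matrix(0, nrow = nb, ncol = 3,
                   dimnames = list(panel$breed, founders))
  hi <- cfg$causal_major_freq
  for (i in seq_len(nb)) {
    if (panel$is_wolf[i]) {
      target[i, ] <- c(0, 1, 0)
    } else if (panel$ear_type[i] == "drop") {
      target[i, ] <- c(hi, 1 - hi, 0)
    } else if (panel$size_class[i] == "small") {
      target[i, ] <- c(0, 1 - hi, hi)
    } else {
      target[i, ] <- c((1 - hi) / 2, hi, (1 - hi) / 2)
    }
  }
  hap_freq <- target
  if (is.finite(cfg$drift_strength)) {
    for (i in seq_len(nb)) {
      d <- ifelse(target[i, ] > 0, target[i, ] * cfg$drift_strength, 0.05)
      hap_freq[i, ] <- stats::rgamma(3, shape = d)
      hap_freq[i, ] <- hap_freq[i, ] / sum(hap_freq[i, ])
    }
  }

  # per-breed non-reference allele frequencies
  breed_freq <- matrix(0, nrow = nb, ncol = nsnp,
                       dimnames = list(panel$breed, map$snp))
  causal_idx <- map$role %in% c("ear", "mass")
  breed_freq[, causal_idx] <- hap_freq %*% hap_alleles[, causal_idx]
  bg_idx <- which(map$role == "background")
  if (length(bg_idx) > 0) {
    anc <- stats::runif(length(bg_idx), 0.05, 0.95)
    for (i in seq_len(nb)) {
      breed_freq[i, bg_idx] <-
        rbeta_mean(length(bg_idx), anc, cfg$drift_strength)
    }
  }
  dw_idx <- which(map$role == "dogwolf")
  if (length(dw_idx) > 0) {
    breed_freq[, dw_idx] <- 1
    breed_freq[panel$is_wolf, dw_idx] <- 0
  }

  # individual haplotype pairs at causal blocks + genotypes
  samples <- data.frame(
    sample = sprintf("%s_%02d", rep(panel$breed, panel$n),
                     unlist(lapply(panel$n, seq_len))),
    breed = rep(panel$breed, panel$n), stringsAsFactors = FALSE)
  ns <- nrow(samples)
  geno <- matrix(0L, nrow = ns, ncol = nsnp,
                 dimnames = list(samples$sample, map$snp))
  hap_pairs <- matrix("", nrow = ns, ncol = 2,
                      dimnames = list(samples$sample, c("hap1", "hap2")))
  ear_idx <- which(map$role == "ear")
  mass_idx <- which(map$role == "mass")
  for (s in seq_len(ns)) {
    bi <- match(samples$breed[s], panel$breed)
    for (h in 1:2) {
      f5 <- sample(founders, 1, prob = hap_freq[bi, ])
      f3 <- if (stats::runif(1) < cfg$recomb_prob) {
        sample(founders, 1, prob = hap_freq[bi, ])
      } else f5
      hap_pairs[s, h] <- if (f5 == f3) f5 else paste0(f5, "/", f3)
      geno[s, ear_idx] <- geno[s, ear_idx] + hap_alleles[f5, ear_idx]
      geno[s, mass_idx] <- geno[s, mass_idx] + hap_alleles[f3, mass_idx]
    }
    other <- c(bg_idx, dw_idx)
    if (length(other) > 0) {
      geno[s, other] <- stats::rbinom(length(other), 2, breed_freq[bi, other])
    }
  }

  # true pool allele frequencies: unweighted mean over member breeds
  ps <- cfg$pool_specs
  pool_freq <- matrix(0, nrow = nrow(ps), ncol = nsnp,
                      dimnames = list(ps$pool, map$snp))
  for (p in seq_len(nrow(ps))) {
    members <- strsplit(ps$members[p], ";")[[1]]
    pool_freq[p, ] <- colMeans(breed_freq[members, , drop = FALSE])
  }

  structure(list(
    map = map, breed_freq = breed_freq, hap_freq = hap_freq,
    hap_alleles = hap_alleles, genotypes = geno, samples = samples,
    hap_pairs = hap_pairs, pool_freq = pool_freq,
    causal = list(ear = map$snp[ear_idx], mass = map$snp[mass_idx],
                  dogwolf = map$snp[dw_idx]),
    cnv = data.frame(start = integer(0), end = integer(0),
                     pool = character(0), fold = numeric(0)),
    cfg = cfg), class = "truth_set")
}

build_snp_map <- function(cfg) {
  pick <- function(n, span) {
    if (n == 0) return(integer(0))
    sort(sample(seq(span[1], span[2]), n))
  }
  ear_pos <- pick(cfg$n_causal_ear, cfg$ear_block_span)
  mass_pos <- pick(cfg$n_causal_mass, cfg$mass_block_span)
  dw_pos <- pick(cfg$n_dogwolf, cfg$dogwolf_span)
  bg_pos <- if (cfg$n_snps > 0) {
    sort(sample(seq(cfg$region[1], cfg$region[2]), cfg$n_snps))
  } else integer(0)
  map <- data.frame(
    pos = c(ear_pos, mass_pos, dw_pos, bg_pos),
    role = c(rep("ear", length(ear_pos)), rep("mass", length(mass_pos)),
             rep("dogwolf", length(dw_pos)),
             rep("background", length(bg_pos))),
    stringsAsFactors = FALSE)
  map <- map[!duplicated(map$pos), ]
  map <- map[order(map$pos), ]
  map$chrom <- cfg$chrom
  map$snp <- sprintf("%s:%d", map$chrom, map$pos)
  map$causal <- map$role %in% c("ear", "mass")
  rownames(map) <- NULL
  map[, c("snp", "chrom", "pos", "role", "causal")]
}

#' Simulate pooled read counts from true pool frequencies
#'
#' Per site and pool, read depth is Poisson with the pool's mean depth and
#' the non-reference read count is binomial with success probability
#' \eqn{f (1 - e) + (1 - f) e}, where \eqn{f} is the true pool frequency and
#' \eqn{e} the symmetric per-read error rate.
#'
#' @param truth A \code{truth_set} from [simulate_haplotype_pools()].
#' @param cfg The same [sim_config()].
#' @return List with \code{counts} (long data.frame: pool, chrom, pos,
#'   ref_base, ref, nonref, nonref_base, depth) and \code{pools} (pool
#'   metadata incl. kind and phenotype labels). The region bounds are kept
#'   in \code{attr(counts, "region")}.
#' @export
simulate_pool_pileups <- function(truth, cfg) {
  stopifnot(inherits(truth, "truth_set"))
  set.seed(cfg$seed + 2L)
  ps <- cfg$pool_specs
  map <- truth$map
  nsnp <- nrow(map)
  e <- cfg$error_rate
  out <- vector("list", nrow(ps))
  for (p in seq_len(nrow(ps))) {
    depth <- stats::rpois(nsnp, ps$mean_depth[p])
    f <- truth$pool_freq[ps$pool[p], ]
    pr <- f * (1 - e) + (1 - f) * e
    nonref <- stats::rbinom(nsnp, depth, pr)
    out[[p]] <- data.frame(
      pool = ps$pool[p], chrom = map$chrom, pos = map$pos,
      ref_base = "A", ref = depth - nonref, nonref = nonref,
      nonref_base = "G", depth = depth, stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, out)
  rownames(counts) <- NULL
  attr(counts, "region") <- cfg$region
  list(counts = counts, pools = ps)
}

#' Plant a copy-number variant into pooled counts
#'
#' Scales read counts within an interval by \code{fold} for the listed pools
#' (deterministically: counts are multiplied and rounded), emulating a
#' duplication (\code{fold > 1}) or deletion (\code{fold = 0}).
#'
#' @param counts Long counts data.frame (from [simulate_pool_pileups()] or
#'   [simulate_depth_windows()]).
#' @param interval Two-element 1-based inclusive interval.
#' @param fold Non-negative depth multiplier.
#' @param pools Character vector of pool names to modify.
#' @return The counts with scaled depths; the planted event is appended to
#'   \code{attr(counts, "cnv")}.
#' @export
plant_cnv <- function(counts, interval, fold, pools) {
  stopifnot(fold >= 0, length(interval) == 2)
  region <- attr(counts, "region")
  if (!is.null(region) &&
      (interval[1] < region[1] || interval[2] > region[2])) {
    stop("CNV interval lies outside the simulated region")
  }
  bad <- setdiff(pools, unique(counts$pool))
  if (length(bad) > 0) stop("unknown pools: ", paste(bad, collapse = ", "))
  pos <- if ("pos" %in% names(counts)) counts$pos else counts$start
  sel <- counts$pool %in% pools & pos >= interval[1] & pos <= interval[2]
  if ("ref" %in% names(counts)) {
    counts$ref[sel] <- as.integer(round(counts$ref[sel] * fold))
    counts$nonref[sel] <- as.integer(round(counts$nonref[sel] * fold))
    counts$depth[sel] <- counts$ref[sel] + counts$nonref[sel]
  } else {
    counts$depth[sel] <- counts$depth[sel] * fold
  }
  attr(counts, "cnv") <- rbind(
    attr(counts, "cnv"),
    data.frame(start = interval[1], end = interval[2],
               pool = paste(pools, collapse = ";"), fold = fold))
  counts
}

#' Simulate per-window read-depth tracks for the CNV scan
#'
#' Generates non-overlapping fixed-width windows tiling the region with
#' per-pool mean depths: each window's total read coverage is Poisson with
#' mean \code{window * mean_depth} and is reported as mean per-bp depth.
#'
#' @param cfg A [sim_config()]; only the SC pools are used by default since
#'   the read-depth scan targets high-coverage data.
#' @param window Window width in bp (default 100).
#' @param kinds Pool kinds to include (default \code{"SC"}).
#' @return Long data.frame: pool, chrom, start, end, depth (mean per-bp),
#'   with region bounds in \code{attr(, "region")}.
#' @export
simulate_depth_windows <- function(cfg, window = 100, kinds = "SC") {
  stopifnot(window > 0)
  set.seed(cfg$seed + 3L)
  ps <- cfg$pool_specs[cfg$pool_specs$kind %in% kinds, ]
  starts <- seq(cfg$region[1], cfg$region[2] - window + 1, by = window)
  out <- vector("list", nrow(ps))
  for (p in seq_len(nrow(ps))) {
    out[[p]] <- data.frame(
      pool = ps$pool[p], chrom = cfg$chrom,
      start = starts, end = starts + window - 1,
      depth = stats::rpois(length(starts), window * ps$mean_depth[p]) / window,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "region") <- cfg$region
  res
}

#' Simulate genome-scale dog/wolf site frequencies with planted sweeps
#'
#' Generates variable-site non-reference frequencies for a combined dog pool
#' and a wolf pool across a long stretch of genome, for exercising the
#' windowed heterozygosity/FST sweep scan. At neutral sites the two
#' populations are drawn from a shared ancestral frequency: identical by
#' default (\code{divergence = Inf}, per-site FST exactly 0, the canonical
#' neutral condition), or each beta-drifted around the ancestral value with
#' concentration \code{divergence} (Balding-Nichols-style drift, expected
#' per-population FST about 1/(1 + divergence)). Within swept windows dog
#' frequencies are pushed to near-fixation while wolf frequencies keep the
#' ancestral value, producing the low-heterozygosity/high-FST sweep
#' signature.
#'
#' @param n_windows Number of windows tiled.
#' @param window Window width in bp (default 40000).
#' @param sites_per_window Variable sites per window.
#' @param sweep_windows Integer indices of windows carrying a planted sweep.
#' @param sweep_dog_freq Dog frequency at swept sites (default 0.995).
#' @param divergence Beta concentration of neutral dog/wolf drift around the
#'   ancestral frequency; \code{Inf} (default) keeps both at the ancestral
#'   value.
#' @param seed Integer seed.
#' @return List with \code{dog} and \code{wolf} site-frequency data.frames
#'   (chrom, pos, p), \code{window}, and \code{sweep_windows}.
#' @export
simulate_sweep_frequencies <- function(n_windows = 1000, window = 40000,
                                       sites_per_window = 10,
                                       sweep_windows = integer(0),
                                       sweep_dog_freq = 0.995,
                                       divergence = Inf, seed = 1L) {
  stopifnot(n_windows >= 1, window > 0, sites_per_window >= 1)
  set.seed(as.integer(seed))
  n <- n_windows * sites_per_window
  win <- rep(seq_len(n_windows), each = sites_per_window)
  pos <- (win - 1) * window + as.integer(stats::runif(n, 1, window))
  anc <- stats::runif(n, 0.15, 0.85)
  clamp <- function(x) pmin(pmax(x, 0.001), 0.999)
  dog <- clamp(rbeta_mean(n, anc, divergence))
  wolf <- clamp(rbeta_mean(n, anc, divergence))
  swept <- win %in% sweep_windows
  dog[swept] <- sweep_dog_freq
  ord <- order(pos)
  list(dog = data.frame(chrom = "chr10", pos = pos[ord], p = dog[ord]),
       wolf = data.frame(chrom = "chr10", pos = pos[ord], p = wolf[ord]),
       window = window, n_windows = n_windows,
       sweep_windows = sweep_windows)
}

#' Write a simulated truth set to TSV files
#'
#' @param truth A \code{truth_set}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_truth_set <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(truth$map, file.path(dir, "snp_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bf <- data.frame(breed = rownames(truth$breed_freq),
                   truth$breed_freq, check.names = FALSE)
  utils::write.table(bf, file.path(dir, "breed_freq.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_genotype_table(truth$genotypes, truth$samples,
                       file.path(dir, "genotypes.tsv"))
  invisible(dir)
}
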