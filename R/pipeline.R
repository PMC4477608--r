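# Pipeline orchestration: runs the analysis stages over a flat YAML-style
# configuration with a single seed, writing deterministic TSV/BED artifacts
# per stage. A thin command-line wrapper around run_pipeline() ships in
# inst/scripts/breedscan.

#' Default pipeline configuration
#'
#' Every threshold defaults to the published analysis value: Q20 base
#' quality, 100x SC site depth, 10 % minor-read screen, fixation tiers
#' 70/90/99 % (all reads for WGS pools), dog-wolf thresholds 3000x / 3x /
#' 1 % discordance, 100 bp CNV windows with the twofold rule, 40 kb sweep
#' windows with 1 % / 99 % percentiles, 1.5 % major-haplotype floor, and
#' the FST > 0.55 / MAF > 15 % differentiation screen.
#'
#' @return Named list of configuration defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "breedscan_out",
    min_base_qual = 20,
    min_site_depth = 100,
    min_minor_fraction = 0.10,
    fixation_cutoffs = c(0.70, 0.90, 0.99),
    candidate_cutoff = 0.99,
    low_cov_pool = "ESS",
    low_cov_partner = "WEI",
    dogwolf_min_dog_depth = 3000,
    dogwolf_min_wolf_depth = 3,
    dogwolf_max_discordance = 0.01,
    cnv_window = 100,
    cnv_fold_threshold = 2,
    sweep_window = 40000,
    sweep_low_pct = 1,
    sweep_high_pct = 99,
    sweep_n_windows = 1000,
    sweep_planted = integer(0),
    hap_min_freq = 0.015,
    fst_min = 0.55,
    maf_min = 0.15,
    n_perm = 200,
    sim = list()   # overrides passed to sim_config()
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [default_run_config()].
#'
#' @param path Path to a YAML file.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(user)] <- user
  cfg
}

pipeline_stages <- function() {
  c("simulate", "callpool", "candidates", "cnv", "gwas", "phase", "sweep")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order over a single synthetic dataset
#' defined by the configuration seed, writing each stage's artifacts as TSV
#' and BED files under \code{out_dir}. All randomness flows from
#' \code{config$seed}, so a rerun with the same configuration reproduces
#' the artifact set byte for byte. Thresholds actually used are logged to
#' stderr when \code{verbose}.
#'
#' @param config Configuration list (see [default_run_config()] /
#'   [read_run_config()]).
#' @param stages Character vector of stages among
#'   \code{simulate, callpool, candidates, cnv, gwas, phase, sweep}, or
#'   \code{"all"}.
#' @param out_dir Output directory (overrides the config entry).
#' @param verbose Log progress and thresholds to stderr.
#' @return Invisibly, a named list of the artifact file paths written.
#' @export
run_pipeline <- function(config = default_run_config(), stages = "all",
                         out_dir = NULL, verbose = FALSE) {
  if (identical(stages, "all")) stages <- pipeline_stages()
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad) > 0) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(pipeline_stages(), collapse = ", "), ")")
  }
  if (is.null(out_dir)) out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (verbose) message("[breedscan] ", ...)

  scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  panel <- simulate_breed_panel(scfg)
  truth <- simulate_haplotype_pools(scfg, panel)
  sim <- simulate_pool_pileups(truth, scfg)
  scheme <- phenotype_scheme(sim$pools)
  fcfg <- fixation_config(
    min_site_depth = config$min_site_depth,
    min_minor_fraction = config$min_minor_fraction,
    fixation_cutoffs = config$fixation_cutoffs)
  artifacts <- list()
  tsv <- function(x, name) {
    path <- file.path(out_dir, name)
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts[[name]] <<- path
    path
  }

  if ("simulate" %in% stages) {
    log("simulate: seed ", scfg$seed, ", ", nrow(truth$map), " SNPs, ",
        nrow(sim$pools), " pools")
    tsv(truth$map, "snp_map.tsv")
    tsv(sim$counts, "pool_counts.tsv")
    tsv(sim$pools, "pools.tsv")
    tsv(as.data.frame(panel), "breed_panel.tsv")
    write_genotype_table(truth$genotypes, truth$samples,
                         file.path(out_dir, "genotypes.tsv"))
    artifacts[["genotypes.tsv"]] <- file.path(out_dir, "genotypes.tsv")
  }

  sites <- detect_variable_sites(sim$counts, fcfg)
  var_counts <- sim$counts[
    paste(sim$counts$chrom, sim$counts$pos) %in%
      paste(sites$chrom, sites$pos)[sites$variable], ]
  sc_counts <- var_counts[var_counts$pool %in%
                            sim$pools$pool[sim$pools$kind == "SC"], ]
  wgs_counts <- var_counts[var_counts$pool %in%
                             sim$pools$pool[sim$pools$kind == "WGS"], ]

  if ("callpool" %in% stages) {
    log("callpool: ", sum(sites$variable), " variable sites; cutoffs ",
        paste(config$fixation_cutoffs, collapse = "/"),
        "; SC depth floor ", config$min_site_depth)
    cls_all <- do.call(rbind, lapply(config$fixation_cutoffs, function(ct) {
      cl <- classify_pool_sites(var_counts, sim$pools, ct, fcfg)
      if (!is.null(config$low_cov_pool) &&
          config$low_cov_pool %in% sim$pools$pool) {
        cl <- apply_ess_rule(cl, config$low_cov_pool,
                             config$low_cov_partner)
      }
      cl
    }))
    tsv(sites, "variable_sites.tsv")
    tsv(cls_all, "classifications.tsv")
    tsv(classification_summary(
      cls_all[cls_all$cutoff == config$candidate_cutoff, ]),
      "classification_summary.tsv")
  }

  if ("candidates" %in% stages) {
    ct <- config$candidate_cutoff
    log("candidates: cutoff ", ct, "; dog-wolf thresholds ",
        config$dogwolf_min_dog_depth, "x/", config$dogwolf_min_wolf_depth,
        "x/", config$dogwolf_max_discordance)
    cl_sc <- classify_pool_sites(sc_counts, sim$pools, ct, fcfg)
    if (!is.null(config$low_cov_pool) &&
        config$low_cov_pool %in% sim$pools$pool) {
      cl_sc <- apply_ess_rule(cl_sc, config$low_cov_pool,
                              config$low_cov_partner)
    }
    cl_wgs <- classify_pool_sites(wgs_counts, sim$pools, ct, fcfg)
    cands <- rbind(
      sc_candidates(cl_sc, scheme, "ear",
                    low_cov_pool = config$low_cov_pool),
      sc_candidates(cl_sc, scheme, "mass",
                    low_cov_pool = config$low_cov_pool))
    cands <- wgs_consistency_filter(cands, cl_wgs, scheme)
    tsv(cands, "candidates.tsv")
    wolf <- sim$pools$pool[sim$pools$is_wolf]
    dw <- dog_wolf_fixations(
      sim$counts, wolf_pool = wolf,
      min_dog_depth = config$dogwolf_min_dog_depth,
      min_wolf_depth = config$dogwolf_min_wolf_depth,
      max_discordance = config$dogwolf_max_discordance)
    tsv(dw, "dog_wolf_fixations.tsv")
    keep <- cands[cands$status == "retained", ]
    if (nrow(keep) > 0) {
      write_bed(data.frame(chrom = keep$chrom, start = keep$pos,
                           end = keep$pos, name = keep$trait, score = 0),
                file.path(out_dir, "candidates.bed"))
      artifacts[["candidates.bed"]] <- file.path(out_dir, "candidates.bed")
    }
  }

  if ("cnv" %in% stages) {
    log("cnv: ", config$cnv_window, " bp windows, fold threshold ",
        config$cnv_fold_threshold)
    depths <- simulate_depth_windows(scfg, window = config$cnv_window)
    norm <- normalized_window_depths(depths)
    flags <- flag_cnv_windows(norm, scheme,
                              fold_threshold = config$cnv_fold_threshold)
    tsv(flags$windows, "cnv_windows.tsv")
    tsv(flags$regions, "cnv_regions.tsv")
  }

  if ("gwas" %in% stages) {
    log("gwas: ", config$n_perm, " breed permutations; FST > ",
        config$fst_min, ", MAF > ", config$maf_min)
    dogs <- !panel$is_wolf[match(truth$samples$breed, panel$breed)]
    geno <- truth$genotypes[dogs, , drop = FALSE]
    smp <- truth$samples[dogs, ]
    res <- lapply(c("ear", "mass"), function(tr) {
      tv <- trait_vector(smp, panel, tr)
      r <- breed_permutation_test(geno, tv, n_perm = config$n_perm,
                                  seed = config$seed)
      r$trait <- tr
      r
    })
    gw <- do.call(rbind, res)
    gw <- merge(gw, truth$map[, c("snp", "chrom", "pos")], by = "snp",
                sort = FALSE)
    fst <- amongbreed_fst_scan(geno, smp$breed, map = truth$map,
                               fst_min = config$fst_min,
                               maf_min = config$maf_min)
    tsv(gw[order(gw$trait, gw$chrom, gw$pos), ], "gwas.tsv")
    tsv(fst$snps, "fst_snps.tsv")
    tsv(fst$runs, "fst_runs.tsv")
  }

  if ("phase" %in% stages) {
    snp_panel <- truth$map$snp[truth$map$causal]
    log("phase: EM over ", length(snp_panel),
        " panel SNPs; major-haplotype floor ", config$hap_min_freq)
    dogs <- !panel$is_wolf[match(truth$samples$breed, panel$breed)]
    hs <- em_phase(truth$genotypes[dogs, snp_panel, drop = FALSE])
    enum <- enumerate_breed_haplotypes(hs, truth$samples$breed[dogs],
                                       min_freq = config$hap_min_freq)
    tsv(hs$haplotypes, "haplotypes.tsv")
    tsv(hs$assignments, "hap_assignments.tsv")
    tsv(data.frame(breed = rownames(enum$by_breed),
                   as.data.frame.matrix(enum$by_breed),
                   check.names = FALSE), "hap_by_breed.tsv")
    tsv(ld_matrix(hs), "ld_pairs.tsv")
  }

  if ("sweep" %in% stages) {
    log("sweep: ", config$sweep_window, " bp windows, percentiles ",
        config$sweep_low_pct, "%/", config$sweep_high_pct, "%")
    sw <- simulate_sweep_frequencies(
      n_windows = config$sweep_n_windows, window = config$sweep_window,
      sweep_windows = config$sweep_planted, seed = config$seed)
    ws <- window_stats(sw$dog, sw$wolf, window = config$sweep_window)
    outl <- percentile_outlier_regions(ws, low_pct = config$sweep_low_pct,
                                       high_pct = config$sweep_high_pct)
    tsv(outl$windows, "sweep_windows.tsv")
    tsv(outl$regions, "sweep_regions.tsv")
  }

  invisible(artifacts)
}
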