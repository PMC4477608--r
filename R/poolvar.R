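# Pooled SNP caller: variable-site detection across pools and per-pool
# classification as fixed_ref / fixed_nonref / polymorphic / missing under
# configurable fixation cutoffs.

#' Configuration for the pooled caller
#'
#' Defaults follow the published filtering rules: sites below 100x coverage
#' in a sequence-capture pool are missing; a site is variable only if minor
#' reads exceed 10 % of all reads summed across pools; fixation is assessed
#' at 70 %, 90 % and 99 % tiers; and low-coverage whole-genome pools call a
#' site fixed only when every read supports the same allele.
#'
#' @param min_site_depth Minimum QC-passing depth for an SC pool call
#'   (default 100).
#' @param min_minor_fraction Minor-read fraction a site must strictly exceed,
#'   summed across pools, to be variable (default 0.10).
#' @param fixation_cutoffs Fractions defining the fixed-call tiers
#'   (default \code{c(0.70, 0.90, 0.99)}); each must be in (0.5, 1].
#' @param wgs_fixed_requires_all_reads If TRUE (default), WGS pools are fixed
#'   only at supporting fraction exactly 1.
#' @return Object of class \code{fixation_config}.
#' @export
fixation_config <- function(min_site_depth = 100,
                            min_minor_fraction = 0.10,
                            fixation_cutoffs = c(0.70, 0.90, 0.99),
                            wgs_fixed_requires_all_reads = TRUE) {
  if (any(fixation_cutoffs <= 0.5) || any(fixation_cutoffs > 1)) {
    stop("fixation cutoffs must lie in (0.5, 1]")
  }
  if (min_minor_fraction >= 0.5) stop("min_minor_fraction must be < 0.5")
  structure(list(min_site_depth = min_site_depth,
                 min_minor_fraction = min_minor_fraction,
                 fixation_cutoffs = sort(fixation_cutoffs),
                 wgs_fixed_requires_all_reads = wgs_fixed_requires_all_reads),
            class = "fixation_config")
}

#' Detect variable sites across pools
#'
#' A site is variable iff its minor-allele reads, summed over all pools,
#' strictly exceed \code{min_minor_fraction} of the summed total reads
#' (e.g. 110 of 1000 qualifies at the 10 % default; exactly 100 of 1000 does
#' not). All reads are summed regardless of per-pool depth filters, which
#' only affect classification.
#'
#' @param counts Long counts data.frame (\code{pool}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{nonref}).
#' @param cfg A [fixation_config()].
#' @return Data.frame per site: \code{chrom}, \code{pos}, \code{ref_total},
#'   \code{nonref_total}, \code{minor_fraction}, \code{variable}.
#' @export
detect_variable_sites <- function(counts, cfg = fixation_config()) {
  if (nrow(counts) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref_total = integer(0), nonref_total = integer(0),
                      minor_fraction = numeric(0), variable = logical(0)))
  }
  key <- paste(counts$chrom, counts$pos, sep = ":")
  ref_total <- tapply(counts$ref, key, sum)
  nonref_total <- tapply(counts$nonref, key, sum)
  first <- !duplicated(key)
  ord <- key[first]
  site <- data.frame(chrom = counts$chrom[first], pos = counts$pos[first],
                     ref_total = as.integer(ref_total[ord]),
                     nonref_total = as.integer(nonref_total[ord]),
                     stringsAsFactors = FALSE)
  total <- site$ref_total + site$nonref_total
  minor <- pmin(site$ref_total, site$nonref_total)
  site$minor_fraction <- ifelse(total > 0, minor / total, 0)
  site$variable <- total > 0 & minor > cfg$min_minor_fraction * total
  site <- site[order(site$chrom, site$pos), ]
  rownames(site) <- NULL
  site
}

#' Classify every (pool, site) at one fixation cutoff
#'
#' Sequence-capture (SC) pools: a site with QC depth below
#' \code{min_site_depth} is \code{missing}; otherwise it is fixed for the
#' majority allele when the majority fraction is at least the cutoff, else
#' \code{polymorphic}. Whole-genome (WGS) pools: zero depth is
#' \code{missing}; with \code{wgs_fixed_requires_all_reads} a call is fixed
#' only when all reads agree, else \code{polymorphic}.
#'
#' @param counts Long counts data.frame (\code{pool}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{nonref}).
#' @param pools Pool metadata data.frame with \code{pool} and \code{kind}
#'   (\code{"SC"} or \code{"WGS"}).
#' @param cutoff One fixation cutoff; must be among
#'   \code{cfg$fixation_cutoffs}.
#' @param cfg A [fixation_config()].
#' @return Long data.frame: \code{pool}, \code{chrom}, \code{pos},
#'   \code{class} (fixed_ref/fixed_nonref/polymorphic/missing),
#'   \code{fraction} (majority-allele support), \code{depth}, \code{cutoff}.
#' @export
classify_pool_sites <- function(counts, pools, cutoff,
                                cfg = fixation_config()) {
  if (!any(abs(cfg$fixation_cutoffs - cutoff) < 1e-12)) {
    stop("cutoff ", cutoff, " is not among the configured fixation cutoffs")
  }
  kind <- pools$kind[match(counts$pool, pools$pool)]
  if (anyNA(kind)) {
    stop("pools missing from metadata: ",
         paste(unique(counts$pool[is.na(kind)]), collapse = ", "))
  }
  depth <- counts$ref + counts$nonref
  maj <- pmax(counts$ref, counts$nonref)
  fraction <- ifelse(depth > 0, maj / depth, NA_real_)
  maj_allele <- ifelse(counts$ref >= counts$nonref, "fixed_ref",
                       "fixed_nonref")
  cls <- rep("polymorphic", nrow(counts))
  sc <- kind == "SC"
  cls[sc & depth < cfg$min_site_depth] <- "missing"
  cls[!sc & depth == 0] <- "missing"
  fixed_sc <- sc & depth >= cfg$min_site_depth & fraction >= cutoff
  wgs_cut <- if (cfg$wgs_fixed_requires_all_reads) 1 else cutoff
  fixed_wgs <- !sc & depth > 0 & fraction >= wgs_cut
  cls[fixed_sc | fixed_wgs] <- maj_allele[fixed_sc | fixed_wgs]
  data.frame(pool = counts$pool, chrom = counts$chrom, pos = counts$pos,
             class = cls, fraction = fraction, depth = depth,
             cutoff = cutoff, stringsAsFactors = FALSE)
}

#' Mask a low-coverage pool's calls where its phenotype partner is missing
#'
#' For a pool with noticeably lower and more variable coverage than the
#' others, a call is kept only if the partner pool sharing its phenotype
#' could also be called: wherever the partner is \code{missing}, the
#' low-coverage pool's call becomes \code{missing} too, so that its
#' phenotype class is never represented by the unreliable pool alone.
#'
#' @param classifications Output of [classify_pool_sites()].
#' @param low_cov_pool Name of the low-coverage pool.
#' @param partner_pool Name of the same-phenotype partner pool.
#' @return The classifications with the masked calls.
#' @export
apply_ess_rule <- function(classifications, low_cov_pool, partner_pool) {
  have <- unique(classifications$pool)
  missing_pools <- setdiff(c(low_cov_pool, partner_pool), have)
  if (length(missing_pools) > 0) {
    stop("unknown pool(s): ", paste(missing_pools, collapse = ", "))
  }
  part <- classifications[classifications$pool == partner_pool, ]
  masked_sites <- paste(part$chrom[part$class == "missing"],
                        part$pos[part$class == "missing"], sep = ":")
  idx <- classifications$pool == low_cov_pool &
    paste(classifications$chrom, classifications$pos, sep = ":") %in%
      masked_sites
  classifications$class[idx] <- "missing"
  classifications
}

#' Tabulate per-pool classification counts
#'
#' Summarises a classification table into one row per pool with counts of
#' fixed-reference, polymorphic, fixed-non-reference and missing calls,
#' mirroring how pooled resequencing panels are usually reported.
#'
#' @param classifications Output of [classify_pool_sites()].
#' @return Data.frame: pool, fixed_ref, polymorphic, fixed_nonref, missing.
#' @export
classification_summary <- function(classifications) {
  tab <- table(classifications$pool,
               factor(classifications$class,
                      levels = c("fixed_ref", "polymorphic",
                                 "fixed_nonref", "missing")))
  out <- as.data.frame.matrix(tab)
  data.frame(pool = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}
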