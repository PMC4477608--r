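# Trait-candidate identification from per-pool classifications, consistency
# filtering against low-coverage whole-genome pools, dog-wolf fixed
# differences, and the clustered-SNP density statistic.

#' Build a phenotype scheme for a set of pools
#'
#' Maps each pool to its size class (small/large) and ear class
#' (drop/non-drop/mixed) and records which pool is the wolf pool. The wolf
#' pool is labelled large and non-drop, matching the wild-type phenotype.
#'
#' @param pools Data.frame with \code{pool}, \code{size_class},
#'   \code{ear_class}, \code{kind} and \code{is_wolf} columns (the pool
#'   panel shipped in
#'   \code{system.file("extdata", "resequencing_pools.tsv", package = "breedscan")}
#'   has this layout).
#' @return Object of class \code{phenotype_scheme} (a data.frame).
#' @export
phenotype_scheme <- function(pools) {
  need <- c("pool", "size_class", "ear_class", "kind", "is_wolf")
  if (!all(need %in% names(pools))) {
    stop("pool table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(pools$size_class %in% c("small", "large"))) {
    stop("size_class must be small/large")
  }
  if (!all(pools$ear_class %in% c("drop", "non-drop", "mixed"))) {
    stop("ear_class must be drop/non-drop/mixed")
  }
  if (any(pools$is_wolf &
          (pools$size_class != "large" | pools$ear_class != "non-drop"))) {
    stop("the wolf pool must be labelled large and non-drop")
  }
  structure(pools[, need], class = c("phenotype_scheme", "data.frame"))
}

# The two phenotype groups a trait contrasts, as pool-name vectors.
trait_groups <- function(scheme, trait, kind) {
  s <- scheme[scheme$kind == kind, ]
  if (trait == "ear") {
    list(a = s$pool[s$ear_class == "drop"],
         b = s$pool[s$ear_class == "non-drop"],
         a_label = "drop", b_label = "non-drop")
  } else if (trait == "mass") {
    list(a = s$pool[s$size_class == "small"],
         b = s$pool[s$size_class == "large"],
         a_label = "small", b_label = "large")
  } else stop("trait must be 'ear' or 'mass'")
}

#' Identify trait candidates from sequence-capture classifications
#'
#' A site is a candidate for a trait iff the pools of one phenotype class are
#' all fixed for one allele and the pools of the other class are all fixed
#' for the opposite allele. A polymorphic call in any pool blocks candidacy.
#' A missing call blocks candidacy too, except in the designated low-coverage
#' pool (\code{low_cov_pool}), whose missing call is tolerated as long as at
#' least one other pool in its phenotype class is informative -- this is what
#' gives the low-coverage masking rule of [apply_ess_rule()] its effect.
#'
#' @param classifications Output of [classify_pool_sites()] at one cutoff
#'   for the SC pools (after [apply_ess_rule()] if applicable).
#' @param scheme A [phenotype_scheme()].
#' @param trait \code{"ear"} or \code{"mass"}.
#' @param low_cov_pool Optional name of the pool whose missing calls do not
#'   block candidacy (default \code{NULL}: every missing call blocks).
#' @return Data.frame of candidates: \code{chrom}, \code{pos}, \code{trait},
#'   \code{cutoff}, \code{allele_a} (allele fixed in the first phenotype
#'   class: drop or small), \code{status} (\code{"retained"}).
#' @export
sc_candidates <- function(classifications, scheme, trait,
                          low_cov_pool = NULL) {
  stopifnot(inherits(scheme, "phenotype_scheme"))
  g <- trait_groups(scheme, trait, kind = "SC")
  if (length(g$a) == 0 || length(g$b) == 0) {
    warning("a phenotype class has no SC pools; no candidates callable")
    return(empty_candidates())
  }
  cl <- classifications[classifications$pool %in% c(g$a, g$b), ]
  key <- paste(cl$chrom, cl$pos, sep = ":")
  out <- lapply(split(cl, key), function(site) {
    a_ok <- group_fixed_allele(site, g$a, low_cov_pool)
    b_ok <- group_fixed_allele(site, g$b, low_cov_pool)
    if (is.null(a_ok) || is.null(b_ok) || a_ok == b_ok) return(NULL)
    data.frame(chrom = site$chrom[1], pos = site$pos[1], trait = trait,
               cutoff = site$cutoff[1],
               allele_a = sub("fixed_", "", a_ok),
               status = "retained", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_candidates())
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(chrom = character(0), pos = integer(0), trait = character(0),
             cutoff = numeric(0), allele_a = character(0),
             status = character(0), stringsAsFactors = FALSE)
}

# The single allele ("fixed_ref"/"fixed_nonref") a phenotype group is
# concordantly fixed for, or NULL if the group does not qualify.
group_fixed_allele <- function(site, group, low_cov_pool) {
  rows <- site[site$pool %in% group, ]
  if (nrow(rows) < length(group)) return(NULL)  # pool absent at site
  if (any(rows$class == "polymorphic")) return(NULL)
  miss <- rows$pool[rows$class == "missing"]
  tolerated <- !is.null(low_cov_pool) && identical(miss, low_cov_pool)
  if (length(miss) > 0 && !tolerated) return(NULL)
  fixed <- rows$class[rows$class != "missing"]
  if (length(fixed) == 0) return(NULL)          # nothing informative
  if (length(unique(fixed)) != 1) return(NULL)  # discordant within group
  unique(fixed)
}

#' Filter candidates against whole-genome pool segregation
#'
#' A candidate is rejected iff a WGS pool with an informative phenotype label
#' is fixed for the allele inconsistent with the candidate's orientation.
#' For the ear trait, drop and non-drop pools are informative (the wolf pool
#' counts as non-drop) and mixed-ear pools are not; for the mass trait every
#' WGS pool is informative since all are large (the wolf counts as large).
#' Missing or polymorphic WGS calls never reject.
#'
#' @param cands Output of [sc_candidates()].
#' @param wgs_classifications [classify_pool_sites()] output for the WGS
#'   pools (all-reads fixation).
#' @param scheme A [phenotype_scheme()].
#' @return The candidates with \code{status} set to \code{"retained"} or
#'   \code{"rejected_by_wgs"}.
#' @export
wgs_consistency_filter <- function(cands, wgs_classifications, scheme) {
  if (nrow(cands) == 0) return(cands)
  stopifnot(inherits(scheme, "phenotype_scheme"))
  w <- scheme[scheme$kind == "WGS", ]
  wcl <- wgs_classifications[wgs_classifications$pool %in% w$pool, ]
  wkey <- paste(wcl$chrom, wcl$pos, sep = ":")
  for (i in seq_len(nrow(cands))) {
    trait <- cands$trait[i]
    g <- trait_groups(scheme, trait, kind = "WGS")
    site <- wcl[wkey == paste(cands$chrom[i], cands$pos[i], sep = ":"), ]
    if (nrow(site) == 0) next
    allele_a <- paste0("fixed_", cands$allele_a[i])
    allele_b <- setdiff(c("fixed_ref", "fixed_nonref"), allele_a)
    bad_a <- site$pool %in% g$a & site$class == allele_b  # class-a pool on b allele
    bad_b <- site$pool %in% g$b & site$class == allele_a
    if (any(bad_a) || any(bad_b)) cands$status[i] <- "rejected_by_wgs"
  }
  cands
}

#' Detect sites fixed for alternative alleles in dogs versus wolves
#'
#' Pools all dog reads (SC and WGS combined) against the wolf pool. A site
#' is reported iff the dog total depth exceeds \code{min_dog_depth} reads,
#' the wolf depth exceeds \code{min_wolf_depth} reads, the two majority
#' alleles differ, and on each side no more than \code{max_discordance} of
#' reads support a different allele.
#'
#' @param counts Long counts for all pools (\code{pool}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{nonref}).
#' @param wolf_pool Name of the wolf pool.
#' @param min_dog_depth Dog total depth must strictly exceed this
#'   (default 3000).
#' @param min_wolf_depth Wolf depth must strictly exceed this (default 3).
#' @param max_discordance Maximum discordant-read fraction on each side
#'   (default 0.01).
#' @return Data.frame of fixed differences: \code{chrom}, \code{pos},
#'   \code{dog_allele}, \code{wolf_allele}, \code{dog_depth},
#'   \code{wolf_depth}.
#' @export
dog_wolf_fixations <- function(counts, wolf_pool,
                               min_dog_depth = 3000, min_wolf_depth = 3,
                               max_discordance = 0.01) {
  is_wolf <- counts$pool == wolf_pool
  if (!any(is_wolf)) stop("wolf pool '", wolf_pool, "' not found in counts")
  agg <- function(x) {
    key <- paste(x$chrom, x$pos, sep = ":")
    first <- !duplicated(key)
    data.frame(key = key[first], chrom = x$chrom[first], pos = x$pos[first],
               ref = as.integer(tapply(x$ref, key, sum)[key[first]]),
               nonref = as.integer(tapply(x$nonref, key, sum)[key[first]]),
               stringsAsFactors = FALSE)
  }
  dog <- agg(counts[!is_wolf, ])
  wolf <- agg(counts[is_wolf, ])
  m <- merge(dog, wolf, by = c("key", "chrom", "pos"),
             suffixes = c("_dog", "_wolf"))
  dog_depth <- m$ref_dog + m$nonref_dog
  wolf_depth <- m$ref_wolf + m$nonref_wolf
  dog_allele <- ifelse(m$ref_dog >= m$nonref_dog, "ref", "nonref")
  wolf_allele <- ifelse(m$ref_wolf >= m$nonref_wolf, "ref", "nonref")
  dog_disc <- pmin(m$ref_dog, m$nonref_dog) / pmax(dog_depth, 1)
  wolf_disc <- pmin(m$ref_wolf, m$nonref_wolf) / pmax(wolf_depth, 1)
  keep <- dog_depth > min_dog_depth & wolf_depth > min_wolf_depth &
    dog_allele != wolf_allele &
    dog_disc <= max_discordance & wolf_disc <= max_discordance
  out <- data.frame(chrom = m$chrom[keep], pos = m$pos[keep],
                    dog_allele = dog_allele[keep],
                    wolf_allele = wolf_allele[keep],
                    dog_depth = dog_depth[keep],
                    wolf_depth = wolf_depth[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' SNP density inside a cluster versus the surrounding region
#'
#' Reports density as interval span (kb) per SNP for the cluster and for the
#' remainder of the background interval, with a two-sided Fisher's exact
#' test on the 2x2 table (SNP bp vs non-SNP bp, inside vs outside the
#' cluster). The p-value is descriptive: the choice of bp as the unit of
#' trials is a modelling convention, not part of any published definition.
#'
#' @param positions SNP positions (1-based).
#' @param cluster_interval Two-element 1-based inclusive interval; must lie
#'   within \code{background_interval}.
#' @param background_interval Two-element interval containing the cluster.
#' @return List: \code{density_in}, \code{density_out} (kb/SNP; \code{Inf}
#'   when an interval holds no SNPs), \code{n_in}, \code{n_out},
#'   \code{fisher_p}.
#' @export
snp_density <- function(positions, cluster_interval, background_interval) {
  ci <- cluster_interval; bi <- background_interval
  if (ci[1] < bi[1] || ci[2] > bi[2]) {
    stop("cluster interval must lie within the background interval")
  }
  inside <- positions >= ci[1] & positions <= ci[2]
  n_in <- sum(inside)
  n_out <- sum(positions >= bi[1] & positions <= bi[2]) - n_in
  span_in <- (ci[2] - ci[1] + 1) / 1000
  span_out <- (bi[2] - bi[1] + 1) / 1000 - span_in
  tab <- matrix(c(n_in, round(span_in * 1000) - n_in,
                  n_out, round(span_out * 1000) - n_out),
                nrow = 2, byrow = TRUE)
  list(density_in = if (n_in > 0) span_in / n_in else Inf,
       density_out = if (n_out > 0) span_out / n_out else Inf,
       n_in = n_in, n_out = n_out,
       fisher_p = stats::fisher.test(tab)$p.value)
}
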