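# Across-breed quantitative association with breed-permutation significance,
# the ear-type vs body-mass Kruskal-Wallis check, and the among-breed FST
# stretch scan.
#
# The trait vector is breed-averaged: every sample of a breed carries the
# identical breed-level value (ear code prick = 1, intermediate = 2,
# drop = 3, or breed-average mass in kg). Permutations therefore shuffle
# values between breeds, never between samples, which preserves the breed
# block structure under the null.

#' Build a breed-averaged trait vector for a set of samples
#'
#' @param samples Data.frame with \code{sample} and \code{breed}.
#' @param panel A breed panel (e.g. [read_breed_panel()] output or
#'   [simulate_breed_panel()]).
#' @param trait \code{"ear"} (numeric ear code) or \code{"mass"}
#'   (breed-average kg).
#' @return Data.frame \code{sample}, \code{breed}, \code{value}.
#' @export
trait_vector <- function(samples, panel, trait = c("ear", "mass")) {
  trait <- match.arg(trait)
  idx <- match(samples$breed, panel$breed)
  if (anyNA(idx)) {
    stop("samples from breeds absent from the panel: ",
         paste(unique(samples$breed[is.na(idx)]), collapse = ", "))
  }
  value <- if (trait == "ear") panel$ear_code[idx] else panel$body_mass_kg[idx]
  data.frame(sample = samples$sample, breed = samples$breed, value = value,
             stringsAsFactors = FALSE)
}

#' Quantitative association chi-squared statistic per SNP
#'
#' For each SNP the statistic is \eqn{n r^2}, where \eqn{r} is the Pearson
#' correlation between allele dosage and the trait over non-missing samples
#' and \eqn{n} their count -- the 1-df score statistic of the regression of
#' trait on dosage. Monomorphic SNPs (or a constant trait) give NA.
#'
#' @param genotypes Samples x SNPs dosage matrix (0/1/2, NA allowed).
#' @param trait_values Numeric trait vector aligned with the rows.
#' @return Data.frame per SNP: \code{snp}, \code{chi2}, \code{p_raw}
#'   (1-df chi-squared upper tail).
#' @export
assoc_chi2 <- function(genotypes, trait_values) {
  stopifnot(nrow(genotypes) == length(trait_values))
  chi2 <- chi2_vector(genotypes, trait_values)
  data.frame(snp = colnames(genotypes) %||% seq_len(ncol(genotypes)),
             chi2 = chi2,
             p_raw = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vectorized n * cor(dosage, trait)^2 per SNP column, NA-aware.
# Monomorphic SNPs give NA; a zero-variance trait carries no association
# signal and gives 0 (so a permutation-invariant trait yields EMP = 1,
# not NA).
chi2_vector <- function(genotypes, trait_values) {
  if (anyNA(genotypes)) {
    apply(genotypes, 2, function(g) {
      ok <- !is.na(g)
      n <- sum(ok)
      if (n < 2 || stats::var(g[ok]) == 0) return(NA_real_)
      if (stats::var(trait_values[ok]) == 0) return(0)
      n * stats::cor(g[ok], trait_values[ok])^2
    })
  } else {
    n <- nrow(genotypes)
    gc <- scale(genotypes, center = TRUE, scale = FALSE)
    tc <- trait_values - mean(trait_values)
    ss_g <- colSums(gc^2)
    ss_t <- sum(tc^2)
    if (ss_t == 0) {
      out <- rep(0, ncol(genotypes))
    } else {
      out <- n * drop(crossprod(gc, tc))^2 / (ss_g * ss_t)
    }
    out[ss_g == 0] <- NA_real_
    out
  }
}

#' Breed-permutation empirical p-values (pointwise and genome-wide)
#'
#' Each permutation shuffles the breed-level trait values among breeds,
#' broadcasts them back to every sample of each breed, and recomputes the
#' association statistic at every SNP. With P permutations,
#' \code{EMP1 = (1 + #\{perm stat >= observed\}) / (P + 1)} per SNP, and
#' \code{EMP2} counts permutations whose maximum statistic over all SNPs
#' reaches the SNP's observed value, giving max-statistic genome-wide
#' significance. Ties count against significance.
#'
#' @param genotypes Samples x SNPs dosage matrix.
#' @param trait Output of [trait_vector()] (one identical value per breed).
#' @param n_perm Number of permutations P (default 1000, supporting a
#'   genome-wide floor of 1/1001).
#' @param seed Integer seed.
#' @return Data.frame per SNP: \code{snp}, \code{chi2}, \code{p_raw},
#'   \code{emp1}, \code{emp2}.
#' @export
breed_permutation_test <- function(genotypes, trait, n_perm = 1000,
                                   seed = 1L) {
  stopifnot(n_perm >= 1)
  # canonical breed order: results must not depend on sample ordering
  breeds <- sort(unique(trait$breed))
  if (length(breeds) < 2) stop("breed permutation needs at least 2 breeds")
  breed_value <- trait$value[match(breeds, trait$breed)]
  if (any(tapply(trait$value, trait$breed, function(v)
    length(unique(v))) != 1)) {
    stop("trait values must be identical within each breed")
  }
  obs <- chi2_vector(genotypes, trait$value)
  set.seed(as.integer(seed))
  ge1 <- integer(length(obs))   # perms with stat >= obs, per SNP
  max_ge <- integer(length(obs))
  breed_of <- match(trait$breed, breeds)
  for (p in seq_len(n_perm)) {
    perm_vals <- sample(breed_value)
    stat <- chi2_vector(genotypes, perm_vals[breed_of])
    ge1 <- ge1 + as.integer(!is.na(stat) & !is.na(obs) & stat >= obs)
    mx <- suppressWarnings(max(stat, na.rm = TRUE))
    if (is.finite(mx)) max_ge <- max_ge + as.integer(!is.na(obs) & mx >= obs)
  }
  emp1 <- (1 + ge1) / (n_perm + 1)
  emp2 <- (1 + max_ge) / (n_perm + 1)
  emp1[is.na(obs)] <- NA_real_
  emp2[is.na(obs)] <- NA_real_
  data.frame(snp = colnames(genotypes) %||% seq_along(obs),
             chi2 = obs,
             p_raw = stats::pchisq(obs, df = 1, lower.tail = FALSE),
             emp1 = emp1, emp2 = emp2, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis test of body mass across ear classes
#'
#' Tests, at the breed level, whether breed-average body mass differs
#' between ear-type classes (tie-corrected H statistic), and reports the
#' per-class mean masses and breed counts. This is the standard check that
#' a mass association is not an artefact of ear-type sampling.
#'
#' @param panel Breed panel data.frame with \code{ear_type} and
#'   \code{body_mass_kg} (one row per breed).
#' @return List: \code{H}, \code{df}, \code{p}, \code{group_means} (named,
#'   kg), \code{group_sizes}.
#' @export
kruskal_wallis_mass_by_ear <- function(panel) {
  if (length(unique(panel$ear_type)) < 2) {
    stop("need at least 2 ear classes")
  }
  kw <- stats::kruskal.test(panel$body_mass_kg, factor(panel$ear_type))
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value,
       group_means = tapply(panel$body_mass_kg, panel$ear_type, mean),
       group_sizes = tapply(panel$body_mass_kg, panel$ear_type, length))
}

#' Among-breed FST scan with minor-allele-frequency screen
#'
#' Per SNP, breed allele frequencies are the mean dosage / 2 within each
#' breed, and differentiation is the unweighted Nei-style
#' \eqn{F_{ST} = (H_T - H_S) / H_T} with \eqn{H_T = 2 \bar p (1 - \bar p)}
#' (\eqn{\bar p} the unweighted mean breed frequency) and \eqn{H_S} the mean
#' within-breed expected heterozygosity. SNPs exceeding both the FST and
#' overall minor-allele-frequency thresholds are reported together with the
#' maximal consecutive runs of qualifying SNPs along the map, ranked by
#' length -- long runs mark regions of extreme breed differentiation.
#'
#' @param genotypes Samples x SNPs dosage matrix.
#' @param breed Breed label per sample.
#' @param map SNP map (\code{snp}, \code{chrom}, \code{pos}) ordering the
#'   SNPs; defaults to column order.
#' @param fst_min Qualifying threshold on FST (strictly greater;
#'   default 0.55).
#' @param maf_min Qualifying threshold on overall MAF (strictly greater;
#'   default 0.15).
#' @return List: \code{snps} (per-SNP \code{fst}, \code{maf},
#'   \code{qualifies}), \code{runs} (maximal consecutive qualifying runs:
#'   chrom, start, end, n_snps), ranked by n_snps.
#' @export
amongbreed_fst_scan <- function(genotypes, breed, map = NULL,
                                fst_min = 0.55, maf_min = 0.15) {
  if (length(unique(breed)) < 2) stop("need at least 2 breeds")
  stopifnot(nrow(genotypes) == length(breed))
  p_breed <- apply(genotypes, 2, function(g)
    tapply(g, breed, function(x) mean(x, na.rm = TRUE) / 2))
  p_bar <- colMeans(p_breed, na.rm = TRUE)
  h_t <- 2 * p_bar * (1 - p_bar)
  h_s <- colMeans(2 * p_breed * (1 - p_breed), na.rm = TRUE)
  fst <- ifelse(h_t > 0, (h_t - h_s) / h_t, NA_real_)
  p_all <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(p_all, 1 - p_all)
  snps <- data.frame(
    snp = colnames(genotypes) %||% seq_along(fst),
    fst = fst, maf = maf,
    qualifies = !is.na(fst) & fst > fst_min & maf > maf_min,
    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    snps <- merge(snps, map[, c("snp", "chrom", "pos")], by = "snp",
                  sort = FALSE)
    snps <- snps[order(snps$chrom, snps$pos), ]
  } else {
    snps$chrom <- "."
    snps$pos <- seq_len(nrow(snps))
  }
  rownames(snps) <- NULL
  runs <- qualifying_runs(snps)
  list(snps = snps, runs = runs)
}

qualifying_runs <- function(snps) {
  q <- snps$qualifies
  if (!any(q)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0)))
  }
  r <- rle(paste(snps$chrom, q))
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1
  keep <- q[idx_start]
  out <- data.frame(chrom = snps$chrom[idx_start[keep]],
                    start = snps$pos[idx_start[keep]],
                    end = snps$pos[idx_end[keep]],
                    n_snps = r$lengths[keep], stringsAsFactors = FALSE)
  out[order(-out$n_snps), , drop = FALSE]
}
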