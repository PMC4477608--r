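# EM haplotype-frequency estimation over a small SNP panel, most-probable
# pair assignment, per-breed haplotype enumeration, and pairwise LD.
#
# Haplotypes are 0/1 strings over the panel SNPs (1 = non-reference allele).
# The EM assumes random mating: a sample's genotype likelihood is the sum of
# f_a * f_b over ordered compatible haplotype pairs (a, b), which absorbs
# the factor 2 for heterozygous pairs. Missing genotypes are marginalized
# by letting the pair carry any alleles at the missing sites.

# All haplotype pairs (ordered) compatible with a dosage vector g.
# Returns a list of two character matrices is overkill; we return a
# data.frame of hap-a and hap-b strings.
compatible_pairs <- function(g) {
  opts <- lapply(g, function(d) {
    if (is.na(d)) rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
    else if (d == 0) rbind(c(0L, 0L))
    else if (d == 2) rbind(c(1L, 1L))
    else rbind(c(0L, 1L), c(1L, 0L))
  })
  n_comb <- prod(vapply(opts, nrow, 1L))
  if (n_comb > 2^20) stop("too many compatible pairs; reduce panel size")
  if (n_comb == 0) stop("no compatible pairs")
  idx <- expand.grid(lapply(opts, function(o) seq_len(nrow(o))),
                     KEEP.OUT.ATTRS = FALSE)
  a <- mapply(function(o, i) o[i, 1], opts, idx)
  b <- mapply(function(o, i) o[i, 2], opts, idx)
  if (n_comb == 1L) {
    a <- matrix(a, nrow = 1); b <- matrix(b, nrow = 1)
  }
  data.frame(a = apply(a, 1, paste, collapse = ""),
             b = apply(b, 1, paste, collapse = ""),
             stringsAsFactors = FALSE)
}

#' EM haplotype-frequency estimation with most-probable pair assignment
#'
#' Estimates population haplotype frequencies over a panel of up to ~15 SNPs
#' by expectation-maximization under random mating, then assigns each sample
#' its most probable (posterior-maximal) haplotype pair. The E-step weights
#' each compatible ordered pair of a sample by the product of current
#' frequencies; the M-step sets each frequency to its expected count over
#' 2n chromosomes. The log-likelihood is non-decreasing across iterations
#' and is returned as a trace.
#'
#' @param genotypes Samples x SNPs dosage matrix (0/1/2/NA); at most 20
#'   SNPs.
#' @param tol Convergence tolerance on the log-likelihood gain
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500).
#' @param min_posterior Confidence floor: samples whose best-pair posterior
#'   falls below it are reported unassigned (default 0, i.e. always assign;
#'   all-missing samples are always unassigned).
#' @return Object of class \code{hapset}: list with \code{haplotypes}
#'   (data.frame \code{hap}, \code{freq}, decreasing), \code{assignments}
#'   (per sample: \code{hap1}, \code{hap2}, \code{posterior},
#'   \code{assigned}), \code{loglik} trace, \code{n_iter},
#'   \code{converged}, \code{snps}.
#' @export
em_phase <- function(genotypes, tol = 1e-8, max_iter = 500,
                     min_posterior = 0) {
  stopifnot(ncol(genotypes) <= 20, nrow(genotypes) >= 1)
  snps <- colnames(genotypes) %||% paste0("snp", seq_len(ncol(genotypes)))
  n <- nrow(genotypes)
  all_missing <- apply(genotypes, 1, function(g) all(is.na(g)))
  pairs <- lapply(seq_len(n), function(s) {
    if (all_missing[s]) return(NULL)
    compatible_pairs(genotypes[s, ])
  })
  universe <- sort(unique(unlist(lapply(pairs, function(p)
    if (is.null(p)) NULL else c(p$a, p$b)))))
  if (length(universe) == 0) stop("no sample has any typed site")
  freq <- stats::setNames(rep(1 / length(universe), length(universe)),
                          universe)
  pa_idx <- lapply(pairs, function(p)
    if (is.null(p)) NULL else match(p$a, universe))
  pb_idx <- lapply(pairs, function(p)
    if (is.null(p)) NULL else match(p$b, universe))
  informative <- which(!all_missing)
  n_inf <- length(informative)

  loglik <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    counts <- numeric(length(universe))
    ll <- 0
    for (s in informative) {
      w <- freq[pa_idx[[s]]] * freq[pb_idx[[s]]]
      tot <- sum(w)
      if (tot <= 0) {  # degenerate start; re-seed uniformly over this sample
        w <- rep(1, length(w)); tot <- length(w)
      }
      ll <- ll + log(tot)
      w <- w / tot
      counts <- counts + tabulate_add(pa_idx[[s]], w, length(universe)) +
        tabulate_add(pb_idx[[s]], w, length(universe))
    }
    freq_new <- counts / (2 * n_inf)
    loglik <- c(loglik, ll)
    if (iter > 1 && (ll - loglik[iter - 1]) < tol) {
      freq <- freq_new
      converged <- TRUE
      break
    }
    freq <- stats::setNames(freq_new, universe)
  }

  assign <- assign_pairs(pairs, pa_idx, pb_idx, freq, universe,
                         rownames(genotypes) %||% seq_len(n),
                         min_posterior)
  hap_df <- data.frame(hap = universe, freq = as.numeric(freq),
                       stringsAsFactors = FALSE)
  hap_df <- hap_df[order(-hap_df$freq, hap_df$hap), ]
  rownames(hap_df) <- NULL
  structure(list(haplotypes = hap_df, assignments = assign,
                 loglik = loglik, n_iter = length(loglik),
                 converged = converged, snps = snps),
            class = "hapset")
}

tabulate_add <- function(idx, w, nbins) {
  out <- numeric(nbins)
  for (k in seq_along(idx)) out[idx[k]] <- out[idx[k]] + w[k]
  out
}

assign_pairs <- function(pairs, pa_idx, pb_idx, freq, universe, ids,
                         min_posterior) {
  n <- length(pairs)
  out <- data.frame(sample = as.character(ids), hap1 = NA_character_,
                    hap2 = NA_character_, posterior = NA_real_,
                    assigned = FALSE, stringsAsFactors = FALSE)
  for (s in seq_len(n)) {
    p <- pairs[[s]]
    if (is.null(p)) next
    w <- freq[pa_idx[[s]]] * freq[pb_idx[[s]]]
    tot <- sum(w)
    if (tot <= 0) next
    # fold ordered pairs into unordered, tie-break lexicographically
    h1 <- pmin(p$a, p$b); h2 <- pmax(p$a, p$b)
    key <- paste(h1, h2)
    post <- tapply(w / tot, key, sum)
    post <- post[order(-post, names(post))]
    best <- names(post)[1]
    if (post[1] < min_posterior) next
    hh <- strsplit(best, " ")[[1]]
    out$hap1[s] <- hh[1]; out$hap2[s] <- hh[2]
    out$posterior[s] <- as.numeric(post[1])
    out$assigned[s] <- TRUE
  }
  out
}

#' Per-breed haplotype counts and the major-haplotype table
#'
#' Counts each haplotype twice per assigned sample within each breed, names
#' the haplotypes whose overall frequency exceeds \code{min_freq} (in
#' decreasing frequency order: H1, H2, ...) and pools the remainder as
#' \code{Other}.
#'
#' @param hapset Output of [em_phase()].
#' @param breed Breed label per sample (aligned with the phased samples).
#' @param min_freq Frequency above which a haplotype is reported as major
#'   (default 0.015).
#' @return List: \code{major} (data.frame \code{name}, \code{hap},
#'   \code{count}, \code{freq}), \code{by_breed} (breeds x (majors + Other)
#'   count matrix), \code{n_assigned}.
#' @export
enumerate_breed_haplotypes <- function(hapset, breed, min_freq = 0.015) {
  a <- hapset$assignments
  stopifnot(length(breed) == nrow(a))
  ok <- a$assigned
  haps <- c(a$hap1[ok], a$hap2[ok])
  brd <- rep(breed[ok], 2)
  tot <- sort(table(haps), decreasing = TRUE)
  freq <- tot / sum(tot)
  major_haps <- names(freq)[freq > min_freq]
  major <- data.frame(name = paste0("H", seq_along(major_haps)),
                      hap = major_haps,
                      count = as.integer(tot[major_haps]),
                      freq = as.numeric(freq[major_haps]),
                      stringsAsFactors = FALSE)
  lab <- ifelse(haps %in% major_haps,
                major$name[match(haps, major$hap)], "Other")
  lab <- factor(lab, levels = c(major$name, "Other"))
  by_breed <- table(factor(brd, levels = unique(breed)), lab)
  list(major = major, by_breed = unclass(by_breed),
       n_assigned = sum(ok))
}

#' Pairwise linkage disequilibrium from haplotype frequencies
#'
#' Computes, for SNPs i and j of a phased set, the classical coefficients
#' from the estimated haplotype frequencies: \eqn{D = p_{AB} - p_A p_B}
#' (alleles coded by the non-reference allele "1"), the normalized
#' \eqn{|D'|} with \eqn{D_{max} = \min(p_A p_b, p_a p_B)} for positive D
#' and \eqn{\min(p_A p_B, p_a p_b)} otherwise, and
#' \eqn{r^2 = D^2 / (p_A p_a p_B p_b)}.
#'
#' @param hapset Output of [em_phase()] (or a data.frame with \code{hap}
#'   and \code{freq}).
#' @param i,j SNP indices (columns of the haplotype strings).
#' @return One-row data.frame: \code{snp_i}, \code{snp_j}, \code{pA},
#'   \code{pB}, \code{D}, \code{Dprime}, \code{r2}; NA when either SNP is
#'   monomorphic.
#' @export
ld_pair <- function(hapset, i, j) {
  hf <- if (inherits(hapset, "hapset")) hapset$haplotypes else hapset
  ai <- as.integer(substr(hf$hap, i, i))
  aj <- as.integer(substr(hf$hap, j, j))
  pA <- sum(hf$freq[ai == 1])
  pB <- sum(hf$freq[aj == 1])
  pAB <- sum(hf$freq[ai == 1 & aj == 1])
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    return(data.frame(snp_i = i, snp_j = j, pA = pA, pB = pB,
                      D = NA_real_, Dprime = NA_real_, r2 = NA_real_))
  }
  D <- pAB - pA * pB
  d_max <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
           else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (d_max > 0) abs(D) / d_max else 0
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  data.frame(snp_i = i, snp_j = j, pA = pA, pB = pB, D = D,
             Dprime = dprime, r2 = r2)
}

#' LD matrix in long format for all SNP pairs of a phased set
#'
#' @param hapset Output of [em_phase()].
#' @return Data.frame with one row per unordered SNP pair (i < j), columns
#'   as in [ld_pair()].
#' @export
ld_matrix <- function(hapset) {
  L <- nchar(hapset$haplotypes$hap[1])
  combos <- utils::combn(L, 2)
  out <- lapply(seq_len(ncol(combos)), function(k)
    ld_pair(hapset, combos[1, k], combos[2, k]))
  do.call(rbind, out)
}
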