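# Windowed heterozygosity (dogs) and dog-wolf FST with percentile-based
# outlier-region calling: the classical low-diversity / high-differentiation
# signature of a selective sweep accompanying domestication.

#' Windowed dog heterozygosity and dog-wolf FST
#'
#' Sites carry pooled non-reference allele frequencies (read fraction
#' estimates). Per window, dog heterozygosity is the mean of
#' \eqn{2p(1 - p)} over variable sites using the combined-dog frequency, and
#' FST is the mean over sites of the per-site \eqn{(H_T - H_S)/H_T} for the
#' dog/wolf frequency pair (\eqn{H_T} from the mean of the two frequencies,
#' \eqn{H_S} the mean of the two within-population heterozygosities).
#' Windows without variable sites report heterozygosity 0 and FST NA.
#'
#' @param dog_freq Data.frame \code{chrom}, \code{pos}, \code{p} for the
#'   combined dog pools.
#' @param wolf_freq Same layout for the wolf pool; merged on (chrom, pos).
#' @param window Window width in bp (default 40000).
#' @param fst_aggregate \code{"mean"} (default, average of per-site ratios)
#'   or \code{"ratio"} (ratio of summed components).
#' @param per_bp If TRUE, divide the window heterozygosity sum by the window
#'   width instead of the number of variable sites.
#' @return Data.frame per window: \code{chrom}, \code{start}, \code{end},
#'   \code{n_sites}, \code{het}, \code{fst} (negative per-site estimates
#'   are kept; a clamped-to-zero copy is in \code{fst_clamped}).
#' @export
window_stats <- function(dog_freq, wolf_freq, window = 40000,
                         fst_aggregate = c("mean", "ratio"),
                         per_bp = FALSE) {
  if (window <= 0) stop("window must be > 0")
  fst_aggregate <- match.arg(fst_aggregate)
  m <- merge(dog_freq, wolf_freq, by = c("chrom", "pos"),
             suffixes = c("_dog", "_wolf"))
  if (nrow(m) == 0) stop("no shared sites between dog and wolf tables")
  m$win <- (m$pos - 1) %/% window
  hd <- 2 * m$p_dog * (1 - m$p_dog)
  hw <- 2 * m$p_wolf * (1 - m$p_wolf)
  p_bar <- (m$p_dog + m$p_wolf) / 2
  h_t <- 2 * p_bar * (1 - p_bar)
  h_s <- (hd + hw) / 2
  fst_site <- ifelse(h_t > 0, (h_t - h_s) / h_t, NA_real_)
  key <- paste(m$chrom, m$win)
  first <- !duplicated(key)
  agg <- function(x, f) as.numeric(tapply(x, key, f)[key[first]])
  out <- data.frame(
    chrom = m$chrom[first],
    start = m$win[first] * window + 1,
    end = (m$win[first] + 1) * window,
    n_sites = agg(rep(1, nrow(m)), sum),
    stringsAsFactors = FALSE)
  out$het <- if (per_bp) agg(hd, sum) / window else agg(hd, mean)
  out$fst <- if (fst_aggregate == "mean") {
    agg(fst_site, function(v) mean(v, na.rm = TRUE))
  } else {
    agg(h_t - h_s, sum) / pmax(agg(h_t, sum), .Machine$double.eps)
  }
  out$fst[is.nan(out$fst)] <- NA_real_
  out$fst_clamped <- pmax(out$fst, 0)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Joint percentile outliers: low heterozygosity and high FST
#'
#' Computes genome-wide percentile thresholds over all windows (linear
#' interpolation) and flags windows strictly below the low heterozygosity
#' percentile AND strictly above the high FST percentile. Adjacent flagged
#' windows are merged into regions. Windows with NA FST are never flagged.
#'
#' @param windows Output of [window_stats()].
#' @param low_pct Heterozygosity percentile (default 1).
#' @param high_pct FST percentile (default 99).
#' @return List: \code{thresholds} (\code{het_low}, \code{fst_high}),
#'   \code{windows} (with \code{low_het}, \code{high_fst}, \code{joint}
#'   flags), \code{regions} (merged joint-flagged regions).
#' @export
percentile_outlier_regions <- function(windows, low_pct = 1,
                                       high_pct = 99) {
  n <- nrow(windows)
  min_needed <- ceiling(100 / min(low_pct, 100 - high_pct))
  if (n < min_needed) {
    stop("too few windows (", n, ") for ", low_pct, "%/", high_pct,
         "% percentiles; need at least ", min_needed)
  }
  het_low <- stats::quantile(windows$het, low_pct / 100, na.rm = TRUE,
                             names = FALSE)
  fst_high <- stats::quantile(windows$fst, high_pct / 100, na.rm = TRUE,
                              names = FALSE)
  windows$low_het <- windows$het < het_low
  windows$high_fst <- !is.na(windows$fst) & windows$fst > fst_high
  windows$joint <- windows$low_het & windows$high_fst
  flagged <- windows[windows$joint, c("chrom", "start", "end")]
  regions <- if (nrow(flagged) == 0) {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_windows = integer(0), stringsAsFactors = FALSE)
  } else {
    flagged <- flagged[order(flagged$chrom, flagged$start), ]
    new_run <- c(TRUE,
                 flagged$chrom[-1] != flagged$chrom[-nrow(flagged)] |
                   flagged$start[-1] != flagged$end[-nrow(flagged)] + 1)
    run <- cumsum(new_run)
    parts <- lapply(split(flagged, run), function(r)
      data.frame(chrom = r$chrom[1], start = min(r$start),
                 end = max(r$end), n_windows = nrow(r),
                 stringsAsFactors = FALSE))
    res <- do.call(rbind, parts)
    rownames(res) <- NULL
    res
  }
  list(thresholds = c(het_low = het_low, fst_high = fst_high),
       windows = windows, regions = regions)
}

#' Pooled allele-frequency estimates from read counts
#'
#' The non-reference read fraction per site; counts from several pools are
#' summed first. Useful to feed [window_stats()] from pooled pileups.
#'
#' @param counts Long counts data.frame (\code{pool}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{nonref}).
#' @param pools Pool names to combine (default: all present).
#' @return Data.frame \code{chrom}, \code{pos}, \code{p}, \code{depth}.
#' @export
pool_frequencies <- function(counts, pools = NULL) {
  if (!is.null(pools)) counts <- counts[counts$pool %in% pools, ]
  key <- paste(counts$chrom, counts$pos, sep = ":")
  first <- !duplicated(key)
  ref <- tapply(counts$ref, key, sum)[key[first]]
  nonref <- tapply(counts$nonref, key, sum)[key[first]]
  depth <- ref + nonref
  out <- data.frame(chrom = counts$chrom[first], pos = counts$pos[first],
                    p = ifelse(depth > 0, nonref / depth, NA_real_),
                    depth = as.integer(depth), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}
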