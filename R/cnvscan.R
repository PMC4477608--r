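# Windowed read-depth scan for pool-asymmetric coverage suggestive of copy
# number variation.

#' Per-window normalized relative read depths
#'
#' For each pool, window depth is first expressed relative to that pool's
#' mean depth over all windows (removing pool-level scale such as library
#' size); each window's relative depths are then normalized by their
#' cross-pool mean, so the normalized values average exactly 1 within every
#' covered window and deviations isolate pool-specific coverage changes.
#'
#' @param depths Long window-depth data.frame (\code{pool}, \code{chrom},
#'   \code{start}, \code{end}, \code{depth}), e.g. from
#'   [simulate_depth_windows()] or [window_depths_from_sites()].
#' @return Data.frame per (window, pool): \code{chrom}, \code{start},
#'   \code{end}, \code{pool}, \code{depth}, \code{relative},
#'   \code{normalized}. Pools with zero total coverage are dropped with a
#'   warning.
#' @export
normalized_window_depths <- function(depths) {
  pools <- unique(depths$pool)
  if (length(pools) < 2) stop("need at least 2 pools to normalize depths")
  pool_mean <- tapply(depths$depth, depths$pool, mean)
  dead <- names(pool_mean)[pool_mean == 0]
  if (length(dead) > 0) {
    warning("dropping pools with zero total coverage: ",
            paste(dead, collapse = ", "))
    depths <- depths[!(depths$pool %in% dead), ]
    pool_mean <- pool_mean[setdiff(names(pool_mean), dead)]
    if (length(pool_mean) < 2) stop("fewer than 2 pools with coverage")
  }
  depths$relative <- depths$depth / pool_mean[depths$pool]
  wkey <- paste(depths$chrom, depths$start, sep = ":")
  wmean <- tapply(depths$relative, wkey, mean)
  depths$normalized <- ifelse(wmean[wkey] > 0,
                              depths$relative / wmean[wkey], 0)
  rownames(depths) <- NULL
  depths[, c("chrom", "start", "end", "pool", "depth", "relative",
             "normalized")]
}

#' Aggregate per-site depths into fixed windows
#'
#' Means the QC depth of covered sites within each non-overlapping window.
#' Intended for pileups with dense per-bp coverage; windows without any
#' covered site are reported with depth 0.
#'
#' @param counts Long site counts (\code{pool}, \code{chrom}, \code{pos},
#'   \code{depth}).
#' @param window Window width in bp.
#' @param region Two-element interval to tile; defaults to
#'   \code{attr(counts, "region")} or the observed position range.
#' @return Long window-depth data.frame as consumed by
#'   [normalized_window_depths()].
#' @export
window_depths_from_sites <- function(counts, window = 100, region = NULL) {
  if (window <= 0) stop("window must be > 0")
  if (is.null(region)) region <- attr(counts, "region")
  if (is.null(region)) region <- range(counts$pos)
  starts <- seq(region[1], region[2], by = window)
  win_of <- function(pos) starts[findInterval(pos, starts)]
  out <- lapply(split(counts, counts$pool), function(x) {
    ws <- win_of(x$pos)
    depth <- tapply(x$depth, ws, mean)
    full <- setNames(rep(0, length(starts)), starts)
    full[names(depth)] <- depth
    data.frame(pool = x$pool[1], chrom = x$chrom[1], start = starts,
               end = pmin(starts + window - 1, region[2]),
               depth = as.numeric(full), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag windows with pool-asymmetric coverage and merge them into regions
#'
#' A window is flagged when one pool's coverage deviates more than twofold
#' from the others: under the default leave-one-out rule, when some pool's
#' relative depth exceeds \code{fold_threshold} times the mean relative
#' depth of the remaining pools (or, symmetrically, falls below its
#' reciprocal), or when some pool completely lacks coverage while another
#' has it. Adjacent flagged windows are merged, and each merged region is
#' annotated with whether the set of deviating pools coincides with an ear
#' or size phenotype class -- a programmatic stand-in for manual inspection
#' of candidate regions.
#'
#' @param windows Output of [normalized_window_depths()].
#' @param scheme Optional [phenotype_scheme()] for the phenotype-consistency
#'   annotation.
#' @param fold_threshold Fold-change defining asymmetry (default 2).
#' @param rule \code{"loo"} (default): compare each pool to the mean of the
#'   others; \code{"normalized"}: threshold the normalized relative depth
#'   directly.
#' @param symmetric Also flag reductions below 1/\code{fold_threshold}
#'   (default TRUE).
#' @return List with \code{windows} (per-window flags and the deviating
#'   pools) and \code{regions} (merged flagged regions with
#'   \code{phenotype_partition} annotation: \code{"ear"}, \code{"size"} or
#'   \code{"none"}).
#' @export
flag_cnv_windows <- function(windows, scheme = NULL, fold_threshold = 2,
                             rule = c("loo", "normalized"),
                             symmetric = TRUE) {
  rule <- match.arg(rule)
  wkey <- paste(windows$chrom, windows$start, sep = ":")
  k <- stats::ave(windows$relative, wkey, FUN = length)
  if (rule == "loo" && all(k >= 2)) {
    sum_rel <- stats::ave(windows$relative, wkey, FUN = sum)
    others <- (sum_rel - windows$relative) / (k - 1)
    high <- others > 0 & windows$relative > fold_threshold * others
    low <- symmetric & others > 0 &
      windows$relative < others / fold_threshold & windows$depth > 0
  } else {
    high <- windows$normalized > fold_threshold
    low <- symmetric & windows$normalized < 1 / fold_threshold &
      windows$depth > 0
  }
  max_depth <- stats::ave(windows$depth, wkey, FUN = max)
  zero <- windows$depth == 0 & max_depth > 0
  dev <- high | low | zero
  win_flagged <- stats::ave(as.numeric(dev), wkey, FUN = max) > 0
  first <- !duplicated(wkey)
  dev_pools <- vapply(
    split(windows$pool[dev], wkey[dev]),
    function(p) paste(sort(unique(p)), collapse = ";"), "")
  flags <- data.frame(chrom = windows$chrom[first],
                      start = windows$start[first],
                      end = windows$end[first],
                      flagged = win_flagged[first],
                      stringsAsFactors = FALSE)
  flags$pools <- ifelse(flags$flagged, dev_pools[wkey[first]], "")
  flags$pools[is.na(flags$pools)] <- ""
  flags <- flags[order(flags$chrom, flags$start), ]
  rownames(flags) <- NULL
  regions <- merge_flagged(flags[flags$flagged, ])
  scanned <- unique(windows$pool)
  if (nrow(regions) > 0) {
    regions$phenotype_partition <- vapply(
      regions$pools, partition_label, "", scheme = scheme,
      scanned = scanned)
  } else {
    regions$phenotype_partition <- character(0)
  }
  list(windows = flags, regions = regions)
}

merge_flagged <- function(flagged) {
  if (nrow(flagged) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      pools = character(0), stringsAsFactors = FALSE))
  }
  flagged <- flagged[order(flagged$chrom, flagged$start), ]
  new_run <- c(TRUE, flagged$chrom[-1] != flagged$chrom[-nrow(flagged)] |
                 flagged$start[-1] != flagged$end[-nrow(flagged)] + 1)
  run <- cumsum(new_run)
  out <- lapply(split(flagged, run), function(r) {
    data.frame(chrom = r$chrom[1], start = min(r$start), end = max(r$end),
               n_windows = nrow(r),
               pools = paste(sort(unique(unlist(
                 strsplit(r$pools, ";")))), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Does the set of deviating pools coincide with one side of a phenotype
# contrast among the scanned pools?
partition_label <- function(pools_str, scheme, scanned) {
  if (is.null(scheme) || !nzchar(pools_str)) return("none")
  dev <- strsplit(pools_str, ";")[[1]]
  s <- scheme[scheme$pool %in% scanned, ]
  for (contrast in c("ear_class", "size_class")) {
    classes <- split(s$pool, s[[contrast]])
    for (side in classes) {
      if (setequal(dev, side)) {
        return(if (contrast == "ear_class") "ear" else "size")
      }
    }
  }
  "none"
}
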