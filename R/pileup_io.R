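# Pileup and table input/output.
#
# Internal coordinates are 1-based inclusive throughout the package; BED
# output converts to 0-based half-open on the way out.

#' Parse samtools pileup text into per-site allele counts
#'
#' Reads 6-column pileup text (chrom, pos, ref base, depth, base calls, base
#' qualities) and reduces each site to reference / non-reference read counts
#' after base-quality filtering. Read-start markers (\code{^} plus the mapping
#' quality character), read-end markers (\code{$}) and inserted/deleted
#' sequence runs (\code{+n}/\code{-n} followed by n bases) are stripped before
#' counting, so only the bases aligned to the site itself are counted.
#'
#' \code{.} and \code{,} count as reference; \code{ACGT} (either case) count
#' toward the non-reference base; \code{*} (deletion placeholder) and \code{N}
#' count as neither. Bases whose phred quality (phred+33 encoding) is below
#' \code{min_base_qual} are dropped. Only the dominant non-reference base is
#' tracked per site; reads supporting a tertiary allele are tallied in
#' \code{other} and excluded from the ref/nonref counts, reflecting a
#' biallelic model.
#'
#' @param file Path to a pileup file, or a character vector of pileup lines
#'   via \code{text}.
#' @param min_base_qual Minimum phred base quality; bases below it are not
#'   counted. Default 20.
#' @param text Optional character vector of lines (overrides \code{file}).
#' @return A data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref_base}, \code{ref}, \code{nonref}, \code{nonref_base},
#'   \code{other}, \code{depth} (= ref + nonref after QC) and
#'   \code{raw_depth} (depth column of the pileup).
#' @examples
#' lines <- "chr1\t10\tA\t5\t..Tt.\tIIIII"
#' read_pileup(text = lines)
#' @export
read_pileup <- function(file = NULL, min_base_qual = 20, text = NULL) {
  stopifnot(min_base_qual >= 0)
  lines <- if (!is.null(text)) text else readLines(file)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 6L) {
      stop(sprintf("pileup parse error at line %d: expected 6 columns, got %d",
                   i, length(fields)))
    }
    depth_col <- as.integer(fields[4])
    calls <- strip_pileup_markers(fields[5])
    if (nchar(calls) != nchar(fields[6])) {
      stop(sprintf(
        "pileup parse error at line %d: %d base calls vs %d qualities after stripping markers",
        i, nchar(calls), nchar(fields[6])))
    }
    if (!is.na(depth_col) && nchar(calls) != depth_col) {
      stop(sprintf(
        "pileup parse error at line %d: %d base calls vs reported depth %d",
        i, nchar(calls), depth_col))
    }
    cnt <- count_pileup_bases(calls, fields[6], min_base_qual)
    out[[i]] <- data.frame(
      chrom = fields[1], pos = as.integer(fields[2]),
      ref_base = toupper(fields[3]),
      ref = cnt$ref, nonref = cnt$nonref, nonref_base = cnt$nonref_base,
      other = cnt$other, depth = cnt$ref + cnt$nonref,
      raw_depth = depth_col, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Remove ^X (read start + mapq char), $ (read end) and [+-]n<bases> indel
# runs from a pileup call string, leaving one character per aligned read.
strip_pileup_markers <- function(calls) {
  chars <- strsplit(calls, "", fixed = TRUE)[[1]]
  keep <- character(length(chars))
  k <- 0L
  i <- 1L
  nc <- length(chars)
  while (i <= nc) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L                     # caret + mapping-quality char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= nc && chars[j] >= "0" && chars[j] <= "9") j <- j + 1L
      if (j == i + 1L) {
        stop("pileup parse error: '+'/'-' not followed by an indel length")
      }
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len                    # skip the inserted/deleted bases
    } else {
      k <- k + 1L
      keep[k] <- ch
      i <- i + 1L
    }
  }
  paste(keep[seq_len(k)], collapse = "")
}

count_pileup_bases <- function(calls, quals, min_base_qual) {
  if (nchar(calls) == 0L) {
    return(list(ref = 0L, nonref = 0L, nonref_base = NA_character_, other = 0L))
  }
  cc <- strsplit(calls, "", fixed = TRUE)[[1]]
  qq <- utf8ToInt(quals) - 33L
  ok <- qq >= min_base_qual
  cc <- toupper(cc[ok])
  ref <- sum(cc == "." | cc == ",")
  alt <- cc[cc %in% c("A", "C", "G", "T")]
  if (length(alt) == 0L) {
    return(list(ref = ref, nonref = 0L, nonref_base = NA_character_,
                other = 0L))
  }
  tab <- sort(table(alt), decreasing = TRUE)
  list(ref = ref, nonref = as.integer(tab[1]),
       nonref_base = names(tab)[1],
       other = as.integer(sum(tab) - tab[1]))
}

#' Read a pool's pileup file into pool allele counts
#'
#' Convenience wrapper around [read_pileup()] that attaches the pool name,
#' giving the long per-(pool, site) count format used by the pooled caller.
#'
#' @inheritParams read_pileup
#' @param pool Pool name to attach.
#' @return Data.frame with a leading \code{pool} column.
#' @export
read_pool_pileup <- function(file = NULL, pool, min_base_qual = 20,
                             text = NULL) {
  x <- read_pileup(file = file, min_base_qual = min_base_qual, text = text)
  cbind(pool = pool, x, stringsAsFactors = FALSE)
}

#' Write pool allele counts as mpileup-like text
#'
#' Inverse of [read_pileup()] for QC-passing counts: reference reads are
#' written as \code{.}, non-reference reads as the alternate base, all with a
#' single high quality character, so a parse round-trip recovers the counts.
#'
#' @param counts Data.frame with \code{chrom}, \code{pos}, \code{ref_base},
#'   \code{ref}, \code{nonref}, \code{nonref_base}.
#' @param file Output path.
#' @param qual_char Quality character to emit (default \code{"I"}, phred 40).
#' @return Invisibly, the path written.
#' @export
write_pool_pileup <- function(counts, file, qual_char = "I") {
  depth <- counts$ref + counts$nonref
  alt <- ifelse(is.na(counts$nonref_base), "A", counts$nonref_base)
  bases <- paste0(strrep(".", counts$ref), strrep(alt, counts$nonref))
  lines <- sprintf("%s\t%d\t%s\t%d\t%s\t%s",
                   counts$chrom, counts$pos, counts$ref_base, depth,
                   bases, strrep(qual_char, depth))
  writeLines(lines, file)
  invisible(file)
}

#' Read a sample-by-SNP genotype table
#'
#' Expects a TSV whose first two columns are \code{sample} and \code{breed},
#' followed by one column per SNP holding non-reference allele dosages in
#' \{0, 1, 2, NA\}.
#'
#' @param file Path to the TSV (or \code{text}).
#' @param map Optional SNP map data.frame with columns \code{snp},
#'   \code{chrom}, \code{pos} (1-based) and optionally \code{ref}/\code{alt}.
#'   If omitted, SNP ids of the form \code{chrom:pos} are decoded into a map.
#' @param text Optional literal TSV text.
#' @return List with \code{genotypes} (numeric matrix, samples x SNPs,
#'   rownames = samples), \code{samples} (data.frame sample, breed) and
#'   \code{map}.
#' @export
read_genotype_table <- function(file = NULL, map = NULL, text = NULL) {
  tab <- if (!is.null(text)) {
    utils::read.delim(text = text, check.names = FALSE,
                      stringsAsFactors = FALSE)
  } else {
    utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (ncol(tab) < 3L || !identical(names(tab)[1:2], c("sample", "breed"))) {
    stop("genotype table must start with 'sample' and 'breed' columns")
  }
  geno <- as.matrix(tab[, -(1:2), drop = FALSE])
  mode(geno) <- "numeric"
  rownames(geno) <- tab$sample
  bad <- which(!(is.na(geno) | geno %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("invalid dosage %s at sample '%s', SNP '%s' (must be 0/1/2/NA)",
                 format(geno[bad[1, 1], bad[1, 2]]),
                 rownames(geno)[bad[1, 1]], colnames(geno)[bad[1, 2]]))
  }
  if (is.null(map)) {
    parts <- strsplit(colnames(geno), ":", fixed = TRUE)
    if (all(lengths(parts) == 2L)) {
      map <- data.frame(snp = colnames(geno),
                        chrom = vapply(parts, `[`, "", 1L),
                        pos = as.integer(vapply(parts, `[`, "", 2L)),
                        stringsAsFactors = FALSE)
    } else {
      map <- data.frame(snp = colnames(geno), chrom = NA_character_,
                        pos = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  monomorphic <- apply(geno, 2, function(g) length(unique(g[!is.na(g)])) < 2L)
  list(genotypes = geno,
       samples = tab[, 1:2],
       map = map,
       monomorphic = monomorphic)
}

#' Write a genotype table in the format read by [read_genotype_table()]
#'
#' @param genotypes Samples x SNPs dosage matrix with rownames.
#' @param samples Data.frame with \code{sample} and \code{breed}.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_genotype_table <- function(genotypes, samples, file) {
  stopifnot(nrow(genotypes) == nrow(samples))
  out <- cbind(samples[, c("sample", "breed")],
               as.data.frame(genotypes, check.names = FALSE))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a breed panel table
#'
#' A breed panel lists one row per breed: breed name, number of genotyped
#' samples, ear-carriage class (\code{drop}, \code{intermediate},
#' \code{prick}) and breed-average body mass in kg. The panel used in the
#' across-breed association analyses ships with the package
#' (\code{system.file("extdata", "gwas_breed_panel.tsv", package = "breedscan")}).
#'
#' @param file Path to the TSV.
#' @return Data.frame with columns \code{breed}, \code{n}, \code{ear_type},
#'   \code{body_mass_kg} and the numeric ear code (\code{ear_code}: prick = 1,
#'   intermediate = 2, drop = 3).
#' @export
read_breed_panel <- function(file) {
  p <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("breed", "n", "ear_type", "body_mass_kg")
  if (!all(need %in% names(p))) {
    stop("breed panel must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(p$ear_type %in% c("drop", "intermediate", "prick"))) {
    stop("ear_type must be one of drop/intermediate/prick")
  }
  p$ear_code <- c(prick = 1, intermediate = 2, drop = 3)[p$ear_type]
  p
}

#' Export regions as BED text
#'
#' Internal 1-based inclusive intervals \code{[start, end]} are emitted as
#' 0-based half-open BED intervals \code{(start - 1, end)}.
#'
#' @param regions Data.frame with \code{chrom}, \code{start}, \code{end} and
#'   optionally \code{name} and \code{score}.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_bed <- function(regions, file) {
  if (nrow(regions) > 0 && any(regions$end < regions$start)) {
    stop("write_bed: end < start")
  }
  if (nrow(regions) == 0L) {
    writeLines(character(0), file)
    return(invisible(file))
  }
  name <- if ("name" %in% names(regions)) regions$name else "."
  score <- if ("score" %in% names(regions)) regions$score else 0
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", regions$chrom,
                   as.integer(regions$start) - 1L, as.integer(regions$end),
                   name, format(score, trim = TRUE))
  writeLines(lines, file)
  invisible(file)
}
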