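## Empirical mappability: the same strict unique-alignment contract applied
## to whole-genome DNA-seq measures how many unique reads each L1 locus can
## collect at all. Loci at the full-coverage plateau collect ~400 reads
## (the default), so FPKM is rescaled by 400 / observed unique DNA reads.

#' Per-base coverage of a region by filtered fragments
#'
#' @param pairs Aligned-pair data.frame ([filter_alignments()] `kept`).
#' @param chrom,start,end Region, 0-based half-open.
#' @param strand If non-NULL, only fragments with this `fragment_strand`
#'   contribute (sense-restricted RNA coverage); DNA coverage uses `NULL`.
#' @return Integer vector of length `end - start`, left-to-right genomic.
#' @export
region_coverage <- function(pairs, chrom, start, end, strand = NULL) {
  stopifnot(end > start)
  sel <- pairs$chrom == chrom & pairs$frag_end > start & pairs$frag_start < end
  if (!is.null(strand)) sel <- sel & pairs$fragment_strand == strand
  p <- pairs[sel, , drop = FALSE]
  if (nrow(p) == 0) return(integer(end - start))
  ir <- IRanges::IRanges(start = pmax(p$frag_start, start) + 1L,
                         end = pmin(p$frag_end, end))
  ir <- IRanges::shift(ir, -start)
  as.integer(IRanges::coverage(ir, width = end - start))
}

#' Profile per-locus unique mappability from filtered DNA-seq fragments
#'
#' Counts uniquely mapped whole-genome DNA-seq fragments overlapping each
#' locus by >= 1 bp (both strands: genomic DNA has no sense) and records the
#' per-base unique coverage, the fraction of mappable bases, and the
#' correction factor `full_coverage_reads / dna_unique_reads`. Also returns
#' the loci ranked from highest to lowest unique DNA read count -- the curve
#' whose plateau motivates the default `full_coverage_reads = 400`.
#'
#' @param dna_pairs `kept` data.frame from filtering DNA-seq alignments
#'   under the same contract as RNA.
#' @param catalog L1 catalog.
#' @param full_coverage_reads Unique DNA read count corresponding to a fully
#'   mappable locus (default 400).
#' @param mappable_fraction_min Fraction of covered bases at or above which
#'   a locus is called fully mappable (default 0.95).
#' @return List with `profiles` (data.frame: `uid`, `dna_unique_reads`,
#'   `fraction_bases_mappable`, `fully_mappable`, `correction_factor`;
#'   the factor is `NA` for loci with zero unique DNA reads, which are
#'   flagged unmappable rather than given an infinite factor), `coverage`
#'   (named list of per-base unique coverage vectors), and `ranked_curve`
#'   (data.frame `rank`, `uid`, `dna_unique_reads`, non-increasing).
#' @export
profile_mappability <- function(dna_pairs, catalog, full_coverage_reads = 400,
                                mappable_fraction_min = 0.95) {
  validate_l1_catalog(catalog)
  n <- nrow(catalog)
  counts <- integer(n)
  covs <- vector("list", n)
  names(covs) <- catalog$uid
  for (i in seq_len(n)) {
    cv <- region_coverage(dna_pairs, catalog$chrom[i],
                          catalog$start[i], catalog$end[i], strand = NULL)
    covs[[i]] <- cv
    counts[i] <- sum(dna_pairs$chrom == catalog$chrom[i] &
                       dna_pairs$frag_end > catalog$start[i] &
                       dna_pairs$frag_start < catalog$end[i])
  }
  frac <- vapply(covs, function(v) mean(v > 0), numeric(1))
  profiles <- data.frame(
    uid = catalog$uid,
    dna_unique_reads = counts,
    fraction_bases_mappable = unname(frac),
    fully_mappable = unname(frac) >= mappable_fraction_min,
    correction_factor = vapply(counts, correction_factor, numeric(1),
                               full_coverage_reads = full_coverage_reads),
    stringsAsFactors = FALSE
  )
  ord <- order(-counts, catalog$uid)
  ranked <- data.frame(rank = seq_len(n), uid = catalog$uid[ord],
                       dna_unique_reads = counts[ord],
                       stringsAsFactors = FALSE)
  list(profiles = profiles, coverage = covs, ranked_curve = ranked)
}

#' Mappability correction factor for one locus
#'
#' @param dna_unique_reads Uniquely mapped DNA-seq fragments over the locus.
#' @param full_coverage_reads Full-coverage plateau count (default 400).
#' @return `full_coverage_reads / dna_unique_reads`; `NA` when
#'   `dna_unique_reads` is 0 (the locus is unmappable and its corrected FPKM
#'   is reported missing, never infinite).
#' @export
correction_factor <- function(dna_unique_reads, full_coverage_reads = 400) {
  stopifnot(length(dna_unique_reads) == 1, dna_unique_reads >= 0,
            full_coverage_reads > 0)
  if (dna_unique_reads == 0) return(NA_real_)
  full_coverage_reads / dna_unique_reads
}

#' Re-estimate the full-coverage plateau from a mappability profile
#'
#' The plateau is the mean unique DNA read count among loci whose per-base
#' unique coverage is positive over at least `mappable_fraction_min` of
#' their length.
#'
#' @param profile Output of [profile_mappability()].
#' @param mappable_fraction_min Coverage-fraction threshold (default 0.95).
#' @return Mean count among fully mappable loci (`NA` if none).
#' @export
estimate_full_coverage_reads <- function(profile,
                                         mappable_fraction_min = 0.95) {
  p <- profile$profiles
  full <- p$fraction_bases_mappable >= mappable_fraction_min
  if (!any(full)) return(NA_real_)
  mean(p$dna_unique_reads[full])
}
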