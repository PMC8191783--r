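## Locus-level expression. The FPKM variant here uses a fixed ~6 kb length
## surrogate for every full-length locus (elements are all about the same
## size), so FPKM = fragments / (million mapped fragments x 6). "Reads"
## means fragments (read pairs) throughout; the mapped-read denominator is
## all fragments surviving the filter genome-wide, not only L1-assigned
## ones. Both conventions halve-or-double absolute FPKM if changed, but no
## comparative result depends on them.

#' Locus FPKM with the fixed 6 kb length surrogate
#'
#' @param raw_reads Uniquely mapped fragments assigned to the locus.
#' @param million_mapped_reads Millions of uniquely mapped fragments in the
#'   sample (genome-wide, post-filter); must be > 0.
#' @return `raw_reads / (million_mapped_reads * 6)`.
#' @export
locus_fpkm <- function(raw_reads, million_mapped_reads) {
  if (any(raw_reads < 0)) stop("raw_reads must be non-negative")
  stopifnot(million_mapped_reads > 0)
  raw_reads / (million_mapped_reads * 6)
}

#' Mappability-corrected FPKM
#'
#' @param fpkm Locus FPKM ([locus_fpkm()]).
#' @param correction_factor Factor from [correction_factor()]; `NA` (an
#'   unmappable locus) propagates to a missing corrected value.
#' @return `fpkm * correction_factor`, elementwise.
#' @export
corrected_fpkm <- function(fpkm, correction_factor) {
  if (any(fpkm < 0, na.rm = TRUE)) stop("fpkm must be non-negative")
  fpkm * correction_factor
}

#' Build the per-locus expression table of one sample
#'
#' @param assigned Assigned pair data.frame ([assign_to_loci()]).
#' @param catalog L1 catalog.
#' @param evidence Curation evidence ([curate_sample()]); loci absent from
#'   it (at or below the candidate gate) are labeled `background`.
#' @param million_mapped_reads Millions of uniquely mapped fragments in the
#'   sample.
#' @param mappability Optional [profile_mappability()] output for corrected
#'   FPKM.
#' @param sample_id Sample identifier stored in the table.
#' @return data.frame with one row per catalog locus: `uid`, `sample_id`,
#'   `raw_reads`, `fpkm`, `corrected_fpkm`, `verdict`, `subfamily`,
#'   `monomer_count`.
#' @export
locus_expression_table <- function(assigned, catalog, evidence,
                                   million_mapped_reads,
                                   mappability = NULL,
                                   sample_id = "sample") {
  counts <- locus_read_counts(assigned, catalog)
  verdict <- rep("background", nrow(catalog))
  if (NROW(evidence) > 0) {
    m <- match(catalog$uid, evidence$uid)
    verdict[!is.na(m)] <- evidence$verdict[m[!is.na(m)]]
  }
  fpkm <- locus_fpkm(counts$raw_reads, million_mapped_reads)
  cf <- rep(NA_real_, nrow(catalog))
  if (!is.null(mappability)) {
    m <- match(catalog$uid, mappability$profiles$uid)
    cf <- mappability$profiles$correction_factor[m]
  }
  data.frame(
    uid = catalog$uid, sample_id = sample_id,
    raw_reads = counts$raw_reads, fpkm = fpkm,
    corrected_fpkm = corrected_fpkm(fpkm, cf),
    verdict = verdict, subfamily = catalog$subfamily,
    monomer_count = catalog$monomer_count,
    stringsAsFactors = FALSE
  )
}

#' Total FPKM of a sample over a verdict class
#'
#' Sums locus FPKM over authentic loci, background loci, or all, and
#' reports the authentic share of the total -- the fraction of total L1
#' FPKM that is genuine L1 mRNA rather than passive background.
#'
#' @param expressions Per-locus expression data.frame
#'   ([locus_expression_table()]); all rows must share `sample_id`.
#' @param only `"authentic"`, `"background"`, or `"all"`.
#' @return List: `total` (summed FPKM over the selected class) and
#'   `authentic_share` (authentic total / overall total, `NA` when nothing
#'   is expressed).
#' @export
sample_total_expression <- function(expressions,
                                    only = c("all", "authentic", "background")) {
  only <- match.arg(only)
  if (NROW(expressions) == 0) return(list(total = 0, authentic_share = NA_real_))
  if (length(unique(expressions$sample_id)) > 1)
    stop("expressions mix multiple samples")
  tot_all <- sum(expressions$fpkm)
  tot_auth <- sum(expressions$fpkm[expressions$verdict == "authentic"])
  total <- switch(only, all = tot_all, authentic = tot_auth,
                  background = tot_all - tot_auth)
  list(total = total,
       authentic_share = if (tot_all > 0) tot_auth / tot_all else NA_real_)
}

#' Subfamily composition of a set of expressed loci
#'
#' @param expressed Catalog-style data.frame with a `subfamily` column.
#' @return Named numeric vector of proportions summing to 1 over labeled
#'   loci (empty for an empty input).
#' @export
subfamily_composition <- function(expressed) {
  sf <- expressed$subfamily[!is.na(expressed$subfamily)]
  if (length(sf) == 0) return(setNames(numeric(0), character(0)))
  tab <- table(sf)
  prop <- as.numeric(tab) / sum(tab)
  setNames(prop, names(tab))
}

#' Promoter monomer-count summary per subfamily
#'
#' @param expressed Catalog-style data.frame with `subfamily` and
#'   `monomer_count` columns; rows with missing counts are excluded with a
#'   warning.
#' @return data.frame `subfamily`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
monomer_distribution <- function(expressed) {
  miss <- is.na(expressed$monomer_count)
  if (any(miss)) {
    warning(sum(miss), " loci without monomer counts excluded")
    expressed <- expressed[!miss, , drop = FALSE]
  }
  if (nrow(expressed) == 0)
    return(data.frame(subfamily = character(0), n = integer(0),
                      mean = numeric(0), sd = numeric(0),
                      min = integer(0), max = integer(0),
                      stringsAsFactors = FALSE))
  sp <- split(expressed$monomer_count, expressed$subfamily)
  data.frame(
    subfamily = names(sp),
    n = vapply(sp, length, integer(1)),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(x) if (length(x) > 1) sd(x) else 0, numeric(1)),
    min = vapply(sp, min, numeric(1)),
    max = vapply(sp, max, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
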