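## Automated promoter-origin curation. A candidate locus (> min_reads
## assigned sense fragments) is authentic L1 mRNA only if the evidence says
## its transcript initiates at the element's own 5' promoter:
##   R1 no upstream same-strand read-through into the locus
##   R2 at least one fragment initiating in the 5' promoter window
##   R3 no splice junction entering the locus from outside
##   R4 RNA coverage concordant with DNA unique-mappability (or the locus
##      is fully mappable) -- screens artifactual pile-ups on poorly
##      mappable stretches.

#' Default curation parameters
#'
#' @param upstream_flank Width in bp of the same-strand flank screened
#'   upstream of the locus 5' end (default 1000).
#' @param upstream_max Maximum ratio of mean upstream sense coverage to mean
#'   in-locus sense coverage (default 0.1); above it the locus is called
#'   passive read-through.
#' @param promoter_window Width in bp of the 5' window in which a fragment
#'   must initiate (default 500, spanning the promoter monomer region).
#' @param concordance_min Minimum Pearson correlation between RNA coverage
#'   and DNA unique coverage for partially mappable loci (default 0).
#' @param min_reads Candidate gate: loci with strictly more than this many
#'   assigned fragments are curated (default 10).
#' @return Named list of parameters.
#' @export
curation_params <- function(upstream_flank = 1000, upstream_max = 0.1,
                            promoter_window = 500, concordance_min = 0,
                            min_reads = 10) {
  list(upstream_flank = upstream_flank, upstream_max = upstream_max,
       promoter_window = promoter_window, concordance_min = concordance_min,
       min_reads = min_reads)
}

## rule tags recorded in `reasons`
R1_TAG <- "R1_upstream_readthrough"
R2_TAG <- "R2_no_promoter_initiation"
R3_TAG <- "R3_incoming_splice"
R4_TAG <- "R4_mappability_discordant"
R4_SKIP_TAG <- "R4_skipped_no_mappability"

#' Curate one candidate L1 locus
#'
#' @param locus One-row catalog data.frame.
#' @param rna_pairs Assigned pair data.frame ([assign_to_loci()]); fragments
#'   with `locus_uid` equal to the locus uid count as assigned.
#' @param mappability Output of [profile_mappability()], or `NULL` (the
#'   mappability rule is then skipped with a warning and recorded).
#' @param junctions Splice-junction data.frame ([read_star_sj()]) or `NULL`.
#' @param params [curation_params()].
#' @return One-row data.frame of curation evidence: `uid`, `assigned_reads`,
#'   `upstream_sense_coverage_ratio`, `five_prime_coverage`,
#'   `incoming_splice_junctions`, `mappability_concordance`, `verdict`
#'   (`authentic`/`background`), `reasons` (comma-separated failed rules).
#' @export
curate_locus <- function(locus, rna_pairs, mappability = NULL,
                         junctions = NULL, params = curation_params()) {
  uid <- locus$uid
  assigned <- rna_pairs[!is.na(rna_pairs$locus_uid) &
                          rna_pairs$locus_uid == uid, , drop = FALSE]
  n_assigned <- nrow(assigned)
  if (n_assigned <= params$min_reads)
    stop("locus ", uid, " has ", n_assigned, " assigned fragments; only ",
         "candidates with more than ", params$min_reads, " are curated")
  strand <- locus$strand
  reasons <- character(0)

  ## R1: upstream same-strand read-through
  in_cov <- region_coverage(rna_pairs, locus$chrom, locus$start, locus$end,
                            strand = strand)
  if (strand == "+") {
    up_start <- max(0L, locus$start - params$upstream_flank)
    up_end <- locus$start
  } else {
    up_start <- locus$end
    up_end <- locus$end + params$upstream_flank
  }
  up_ratio <- if (up_end > up_start) {
    up_cov <- region_coverage(rna_pairs, locus$chrom, up_start, up_end,
                              strand = strand)
    mean(up_cov) / mean(in_cov)
  } else 0
  if (up_ratio > params$upstream_max) reasons <- c(reasons, R1_TAG)

  ## R2: a fragment must initiate within the 5' promoter window
  if (strand == "+") {
    starts5 <- assigned$frag_start
    five_prime <- any(starts5 >= locus$start &
                        starts5 < locus$start + params$promoter_window)
  } else {
    starts5 <- assigned$frag_end          # 5' end of a minus-strand fragment
    five_prime <- any(starts5 <= locus$end &
                        starts5 > locus$end - params$promoter_window)
  }
  if (!five_prime) reasons <- c(reasons, R2_TAG)

  ## R3: splice junctions entering the locus from outside reject it
  incoming <- 0L
  if (!is.null(junctions) && NROW(junctions) > 0) {
    jl <- junctions_per_locus(junctions, locus)
    incoming <- jl$per_locus$incoming_junctions[1]
  }
  if (incoming > 0) reasons <- c(reasons, R3_TAG)

  ## R4: coverage / mappability concordance
  concordance <- NA_real_
  if (is.null(mappability)) {
    warning("no mappability profile for locus ", uid,
            "; concordance rule skipped")
    reasons <- c(reasons, R4_SKIP_TAG)
  } else {
    prof <- mappability$profiles[mappability$profiles$uid == uid, , drop = FALSE]
    dna_cov <- mappability$coverage[[uid]]
    pos <- which(dna_cov > 0)
    if (length(pos) >= 3 && stats::sd(in_cov[pos]) > 0 &&
        stats::sd(dna_cov[pos]) > 0)
      concordance <- stats::cor(in_cov[pos], dna_cov[pos])
    fully <- nrow(prof) == 1 && isTRUE(prof$fully_mappable)
    if (!fully && !is.na(concordance) &&
        concordance < params$concordance_min)
      reasons <- c(reasons, R4_TAG)
  }

  verdict <- if (any(reasons %in% c(R1_TAG, R2_TAG, R3_TAG, R4_TAG)))
    "background" else "authentic"
  data.frame(
    uid = uid, assigned_reads = n_assigned,
    upstream_sense_coverage_ratio = up_ratio,
    five_prime_coverage = five_prime,
    incoming_splice_junctions = incoming,
    mappability_concordance = concordance,
    verdict = verdict,
    reasons = paste(reasons, collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Curate all candidate loci of one sample
#'
#' Applies the strict candidate gate (strictly more than `params$min_reads`
#' assigned fragments) and [curate_locus()] to each candidate.
#'
#' @param rna_pairs Assigned pair data.frame ([assign_to_loci()]).
#' @param catalog L1 catalog.
#' @inheritParams curate_locus
#' @return Curation evidence data.frame, one row per candidate locus (zero
#'   rows when no locus passes the gate).
#' @export
curate_sample <- function(rna_pairs, catalog, mappability = NULL,
                          junctions = NULL, params = curation_params()) {
  counts <- locus_read_counts(rna_pairs, catalog)
  cand <- counts$uid[counts$raw_reads > params$min_reads]
  rows <- lapply(cand, function(u) {
    curate_locus(catalog[catalog$uid == u, , drop = FALSE], rna_pairs,
                 mappability = mappability, junctions = junctions,
                 params = params)
  })
  if (length(rows) == 0) return(empty_curation())
  do.call(rbind, rows)
}

empty_curation <- function() {
  data.frame(uid = character(0), assigned_reads = integer(0),
             upstream_sense_coverage_ratio = numeric(0),
             five_prime_coverage = logical(0),
             incoming_splice_junctions = integer(0),
             mappability_concordance = numeric(0),
             verdict = character(0), reasons = character(0),
             stringsAsFactors = FALSE)
}

#' Summarise curation verdicts
#'
#' @param evidence Curation evidence data.frame ([curate_sample()]).
#' @return List: `n_candidates`, `n_authentic`, `fraction_authentic`
#'   (`NA` when there are no candidates), and `reason_counts` (named tally
#'   over rejection rule tags).
#' @export
curation_summary <- function(evidence) {
  n <- nrow(evidence)
  n_auth <- sum(evidence$verdict == "authentic")
  tags <- unlist(strsplit(evidence$reasons[nzchar(evidence$reasons)], ","))
  list(
    n_candidates = n,
    n_authentic = n_auth,
    fraction_authentic = if (n == 0) NA_real_ else n_auth / n,
    reason_counts = if (length(tags)) table(tags) else
      table(factor(character(0)))
  )
}
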