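## Reads rejected by the unique-placement filter are not all noise: pairs
## from the youngest subfamily promoters multi-map because monomers are
## near-identical across loci. Realigning the discarded pool to subfamily
## consensus sequences (each with two promoter monomers 5' of the body)
## quantifies promoter-consistent signal the locus-level analysis cannot
## place.

#' Build a subfamily consensus reference
#'
#' @param subfamily Label (e.g. `"T_f"`, `"G_f"`, `"A"`).
#' @param monomer Promoter monomer sequence (~200 bp); two tandem copies
#'   form the 5' promoter of the consensus.
#' @param body Element body sequence downstream of the promoter.
#' @return List with `subfamily`, `sequence`, `promoter_start`,
#'   `promoter_end` (0-based half-open two-monomer interval at the 5' end).
#' @export
subfamily_consensus <- function(subfamily, monomer, body) {
  stopifnot(nzchar(monomer), nzchar(body))
  seqn <- paste0(monomer, monomer, body)
  list(subfamily = subfamily, sequence = seqn,
       promoter_start = 0L, promoter_end = 2L * nchar(monomer))
}

#' Realign discarded read pairs to subfamily promoter consensi
#'
#' Each discarded pair is exhaustively aligned (ungapped full scan, both
#' strands) against all consensi simultaneously. A pair is counted for a
#' subfamily iff it has at least one placement overlapping that consensus's
#' promoter interval in the sense orientation, at most `max_alignments`
#' placements in total across all consensi, and at most
#' `max_mismatch_pair` mismatches summed over both mates. A pair placing on
#' several consensi within the cap can count for each of them.
#'
#' @param discarded `discarded` data.frame from [filter_alignments()] or
#'   [brute_force_unique_map()] (must retain `seq1`/`seq2`).
#' @param consensi List of [subfamily_consensus()] objects.
#' @param max_alignments Maximum total placements per pair (default 2).
#' @param max_mismatch_pair Maximum mismatches per pair, summed over mates
#'   (default 25).
#' @param max_insert Maximum fragment span (default 600).
#' @param strandedness Library protocol as in [filter_alignments()].
#' @return data.frame `subfamily`, `read_pairs`, `fraction_of_discarded`
#'   (denominator: all discarded pairs).
#' @export
realign_discarded <- function(discarded, consensi, max_alignments = 2,
                              max_mismatch_pair = 25, max_insert = 600,
                              strandedness = c("fr", "rf")) {
  strandedness <- match.arg(strandedness)
  subfams <- vapply(consensi, `[[`, character(1), "subfamily")
  n_disc <- NROW(discarded)
  zero <- data.frame(subfamily = subfams,
                     read_pairs = 0L,
                     fraction_of_discarded = if (n_disc > 0) 0 else NA_real_,
                     stringsAsFactors = FALSE)
  ok <- !is.na(discarded$seq1) & !is.na(discarded$seq2)
  d <- discarded[ok, , drop = FALSE]
  if (nrow(d) == 0 || length(consensi) == 0) return(zero)
  seqs <- vapply(consensi, `[[`, character(1), "sequence")
  res <- cpp_map_pairs_scan(unname(seqs), d$seq1, d$seq2,
                            as.integer(max_mismatch_pair),
                            as.integer(max_mismatch_pair),
                            as.integer(max_insert),
                            as.integer(max_alignments) + 1L)
  keep <- which(res$n_placements >= 1 & res$n_placements <= max_alignments)
  pl <- res$placements
  pl <- pl[pl$pair %in% keep, , drop = FALSE]
  counts <- setNames(integer(length(consensi)), subfams)
  if (nrow(pl) > 0) {
    frag_strand <- fragment_strand_from_m1(
      ifelse(pl$m1_forward == 1, "+", "-"), strandedness)
    frag_start <- pmin(pl$m1_start, pl$m2_start)
    ps <- vapply(consensi, `[[`, integer(1), "promoter_start")
    pe <- vapply(consensi, `[[`, integer(1), "promoter_end")
    frag_end <- pmax(pl$m1_end, pl$m2_end)
    sense_prom <- frag_strand == "+" &
      frag_start < pe[pl$chrom_idx] & frag_end > ps[pl$chrom_idx]
    hit <- unique(data.frame(pair = pl$pair[sense_prom],
                             cons = pl$chrom_idx[sense_prom]))
    if (nrow(hit) > 0) {
      tab <- table(factor(hit$cons, levels = seq_along(consensi)))
      counts[] <- as.integer(tab)
    }
  }
  data.frame(subfamily = subfams, read_pairs = as.integer(counts),
             fraction_of_discarded = as.integer(counts) / n_disc,
             stringsAsFactors = FALSE)
}
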