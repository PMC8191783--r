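## Alignment contract: concordant strand-specific read pairs, fragment span
## <= max_insert, <= max_mismatch per mate, exactly one valid placement.
## Pairs failing any clause are collected with a single discard reason so
## they can be realigned to subfamily promoter consensi later.

DISCARD_REASONS <- c("multi_mapped", "discordant", "too_many_mismatches")

empty_pairs <- function() {
  data.frame(read_id = character(0), chrom = character(0),
             m1_start = integer(0), m1_end = integer(0),
             m2_start = integer(0), m2_end = integer(0),
             frag_start = integer(0), frag_end = integer(0),
             fragment_strand = character(0),
             mismatches_m1 = integer(0), mismatches_m2 = integer(0),
             n_valid_placements = integer(0), stringsAsFactors = FALSE)
}

empty_discarded <- function() {
  data.frame(read_id = character(0), seq1 = character(0), seq2 = character(0),
             reason = character(0), stringsAsFactors = FALSE)
}

## library protocol -> strand of the RNA fragment given mate-1 strand
fragment_strand_from_m1 <- function(m1_strand, strandedness = c("fr", "rf")) {
  strandedness <- match.arg(strandedness)
  if (strandedness == "fr") m1_strand else ifelse(m1_strand == "+", "-", "+")
}

#' Filter externally produced paired-end alignments to the strict contract
#'
#' Enforces the alignment contract on a SAM/BAM file: a pair is kept iff it
#' is concordant (mates on opposite strands, fragment span <=
#' `max_insert`), each mate carries at most `max_mismatch` mismatches (NM
#' tag), and it has exactly one reported placement (NH tag, when present).
#' Everything else is discarded with one reason: `multi_mapped` (NH > 1),
#' `too_many_mismatches`, or `discordant` (unpaired mate, same-strand mates,
#' or over-long fragment).
#'
#' @param path SAM or BAM file of paired-end alignments with NM tags.
#' @param max_insert Maximum fragment span in bp (default 600).
#' @param max_mismatch Maximum mismatches per mate (default 3).
#' @param strandedness Library protocol: `"fr"` (fragment strand is mate-1
#'   strand, default) or `"rf"` (dUTP-style, reversed).
#' @return A list with `kept` (data.frame of aligned pairs: `read_id`,
#'   `chrom`, mate and fragment intervals in 0-based half-open coordinates,
#'   `fragment_strand`, per-mate mismatches, `n_valid_placements`) and
#'   `discarded` (data.frame `read_id`, `seq1`, `seq2`, `reason`). Every
#'   input pair appears in exactly one of the two.
#' @export
filter_alignments <- function(path, max_insert = 600, max_mismatch = 3,
                              strandedness = c("fr", "rf")) {
  strandedness <- match.arg(strandedness)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand", "seq"),
    tag = c("NM", "NH"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$qname)
  if (n == 0) return(list(kept = empty_pairs(), discarded = empty_discarded()))
  if (all(is.na(b$tag$NM)) && n > 0)
    stop("alignments lack NM mismatch tags; recompute mismatches from the ",
         "aligned sequence (e.g. samtools calmd) before filtering")
  flag <- b$flag
  rec <- data.frame(
    qname = b$qname,
    first = bitwAnd(flag, 64L) > 0,
    unmapped = bitwAnd(flag, 4L) > 0,
    secondary = bitwAnd(flag, 256L) > 0 | bitwAnd(flag, 2048L) > 0,
    chrom = as.character(b$rname),
    start = b$pos - 1L,                       # SAM is 1-based
    width = GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar),
    strand = as.character(b$strand),
    nm = if (is.null(b$tag$NM)) NA_integer_ else b$tag$NM,
    nh = if (is.null(b$tag$NH)) NA_integer_ else b$tag$NH,
    seq = as.character(b$seq),
    stringsAsFactors = FALSE
  )
  rec <- rec[!rec$secondary, , drop = FALSE]

  kept <- list(); disc <- list()
  for (d in split(rec, rec$qname)) {
    m1 <- d[d$first, , drop = FALSE]
    m2 <- d[!d$first, , drop = FALSE]
    rid <- d$qname[1]
    s1 <- if (nrow(m1)) m1$seq[1] else NA_character_
    s2 <- if (nrow(m2)) m2$seq[1] else NA_character_
    drop <- function(reason) {
      disc[[length(disc) + 1]] <<- data.frame(
        read_id = rid, seq1 = s1, seq2 = s2, reason = reason,
        stringsAsFactors = FALSE)
    }
    if (nrow(m1) != 1 || nrow(m2) != 1 || m1$unmapped || m2$unmapped ||
        is.na(m1$chrom) || is.na(m2$chrom) || m1$chrom != m2$chrom) {
      drop("discordant"); next
    }
    nh <- c(m1$nh, m2$nh)
    nplace <- if (all(is.na(nh))) 1L else max(nh, na.rm = TRUE)
    if (nplace > 1) { drop("multi_mapped"); next }
    if (is.na(m1$nm) || is.na(m2$nm))
      stop("pair ", rid, " lacks an NM tag; recompute mismatches from the ",
           "aligned sequence before filtering")
    if (m1$nm > max_mismatch || m2$nm > max_mismatch) {
      drop("too_many_mismatches"); next
    }
    if (m1$strand == m2$strand) { drop("discordant"); next }
    frag_start <- min(m1$start, m2$start)
    frag_end <- max(m1$start + m1$width, m2$start + m2$width)
    if (frag_end - frag_start > max_insert) { drop("discordant"); next }
    kept[[length(kept) + 1]] <- data.frame(
      read_id = rid, chrom = m1$chrom,
      m1_start = m1$start, m1_end = m1$start + m1$width,
      m2_start = m2$start, m2_end = m2$start + m2$width,
      frag_start = frag_start, frag_end = frag_end,
      fragment_strand = fragment_strand_from_m1(m1$strand, strandedness),
      mismatches_m1 = m1$nm, mismatches_m2 = m2$nm,
      n_valid_placements = as.integer(nplace), stringsAsFactors = FALSE)
  }
  list(
    kept = if (length(kept)) do.call(rbind, kept) else empty_pairs(),
    discarded = if (length(disc)) do.call(rbind, disc) else empty_discarded()
  )
}

normalize_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    g <- as.character(genome)
  } else if (is.character(genome) && length(genome) == 1 &&
             file.exists(genome)) {
    g <- as.character(Biostrings::readDNAStringSet(genome))
    names(g) <- sub("\\s.*$", "", names(g))
  } else if (is.character(genome)) {
    g <- genome
  } else stop("genome must be a FASTA path, DNAStringSet or named character vector")
  if (is.null(names(g)) || any(!nzchar(names(g))))
    stop("genome sequences must be named")
  g
}

read_fastq_seqs <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    s <- Biostrings::readDNAStringSet(x, format = "fastq")
    setNames(as.character(s), sub("\\s.*$", "", names(s)))
  } else if (is.character(x)) x
  else stop("reads must be a FASTQ path or a character vector")
}

#' Exhaustively map read pairs to a toy genome, keeping unique placements
#'
#' Reference implementation of the unique-alignment contract for small
#' genomes: every concordant ungapped placement of a pair with at most `v`
#' mismatches per mate and fragment span at most `max_insert` is enumerated
#' over both strands of all sequences, and a pair is kept iff exactly one
#' such placement exists. Pairs with two or more placements are discarded as
#' `multi_mapped`; pairs with none are `too_many_mismatches` when a mate has
#' no placement at all, otherwise `discordant`. Uniqueness is therefore
#' "exactly one valid placement", not "one best placement among many".
#'
#' @param r1,r2 FASTQ paths or named character vectors of mate sequences
#'   (mate 2 as sequenced, i.e. reverse-complement of the fragment for a
#'   forward fragment).
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @param v Maximum mismatches per mate (default 3); non-ACGT reference
#'   characters never match.
#' @param max_insert Maximum fragment span (default 600).
#' @param strandedness `"fr"` or `"rf"` as in [filter_alignments()].
#' @return As [filter_alignments()]: list of `kept` and `discarded`.
#' @details Intended for toy genomes (up to a few megabases); the search is
#'   exhaustive via a pigeonhole seed index, so results are identical to a
#'   full positional scan.
#' @export
brute_force_unique_map <- function(r1, r2, genome, v = 3, max_insert = 600,
                                   strandedness = c("fr", "rf")) {
  strandedness <- match.arg(strandedness)
  g <- normalize_genome(genome)
  s1 <- read_fastq_seqs(r1); s2 <- read_fastq_seqs(r2)
  if (length(s1) != length(s2)) stop("mate files differ in read count")
  ids <- names(s1)
  if (is.null(ids)) ids <- paste0("read", seq_along(s1))
  if (length(s1) == 0)
    return(list(kept = empty_pairs(), discarded = empty_discarded()))
  res <- cpp_map_pairs_indexed(unname(g), unname(s1), unname(s2),
                               as.integer(v), as.integer(2 * v),
                               as.integer(max_insert), 1L)
  finalize_mapping(res, ids, s1, s2, names(g), strandedness)
}

finalize_mapping <- function(res, ids, s1, s2, chrom_names, strandedness) {
  np <- res$n_placements
  keep_idx <- which(np == 1)
  pl <- res$placements
  pl <- pl[pl$pair %in% keep_idx, , drop = FALSE]
  kept <- if (nrow(pl)) {
    m1s <- ifelse(pl$m1_forward == 1, "+", "-")
    data.frame(
      read_id = ids[pl$pair],
      chrom = chrom_names[pl$chrom_idx],
      m1_start = pl$m1_start, m1_end = pl$m1_end,
      m2_start = pl$m2_start, m2_end = pl$m2_end,
      frag_start = pmin(pl$m1_start, pl$m2_start),
      frag_end = pmax(pl$m1_end, pl$m2_end),
      fragment_strand = fragment_strand_from_m1(m1s, strandedness),
      mismatches_m1 = pl$mm1, mismatches_m2 = pl$mm2,
      n_valid_placements = 1L, stringsAsFactors = FALSE)
  } else empty_pairs()
  disc_idx <- which(np != 1)
  discarded <- if (length(disc_idx)) {
    reason <- ifelse(np[disc_idx] >= 2, "multi_mapped",
                     ifelse(res$n_hits_m1[disc_idx] == 0 |
                              res$n_hits_m2[disc_idx] == 0,
                            "too_many_mismatches", "discordant"))
    data.frame(read_id = ids[disc_idx], seq1 = unname(s1[disc_idx]),
               seq2 = unname(s2[disc_idx]), reason = reason,
               stringsAsFactors = FALSE)
  } else empty_discarded()
  list(kept = kept, discarded = discarded)
}

#' Assign filtered fragments to full-length L1 loci, sense orientation only
#'
#' A fragment is assigned to a locus iff its interval overlaps the locus by
#' at least 1 bp and its strand equals the locus strand (the sense
#' requirement: antisense coverage is not L1 mRNA). A fragment overlapping
#' several same-strand loci is assigned to the one with the largest overlap
#' (ties break lexicographically by uid), so each fragment counts once.
#'
#' @param pairs `kept` data.frame from [filter_alignments()] or
#'   [brute_force_unique_map()].
#' @param catalog L1 catalog ([load_l1_catalog()]).
#' @return `pairs` with an added `locus_uid` column (`NA` for unassigned
#'   fragments).
#' @seealso [locus_read_counts()]
#' @export
assign_to_loci <- function(pairs, catalog) {
  validate_l1_catalog(catalog)
  pairs$locus_uid <- rep(NA_character_, NROW(pairs))
  if (NROW(pairs) == 0 || nrow(catalog) == 0) return(pairs)
  frag_gr <- GenomicRanges::GRanges(
    seqnames = pairs$chrom,
    ranges = IRanges::IRanges(start = pairs$frag_start + 1L,
                              end = pairs$frag_end),
    strand = pairs$fragment_strand)
  ov <- GenomicRanges::findOverlaps(frag_gr, catalog_granges(catalog),
                                    ignore.strand = FALSE)
  if (length(ov) == 0) return(pairs)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  ovlen <- pmin(pairs$frag_end[q], catalog$end[s]) -
    pmax(pairs$frag_start[q], catalog$start[s])
  ord <- order(q, -ovlen, catalog$uid[s])
  first <- !duplicated(q[ord])
  pairs$locus_uid[q[ord][first]] <- catalog$uid[s[ord][first]]
  pairs
}

#' Count assigned fragments per locus
#'
#' @param assigned Output of [assign_to_loci()].
#' @param catalog L1 catalog; loci with no fragments get count 0.
#' @return data.frame `uid`, `raw_reads`.
#' @export
locus_read_counts <- function(assigned, catalog) {
  counts <- table(factor(assigned$locus_uid, levels = catalog$uid))
  data.frame(uid = catalog$uid, raw_reads = as.integer(counts),
             stringsAsFactors = FALSE)
}
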