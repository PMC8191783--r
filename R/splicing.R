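## STAR-format splice junction tables (SJ.out.tab dialect): 9 columns,
## intron coordinates 1-based inclusive, strand coded 0/1/2 for
## undefined/+/-. Internally coordinates become 0-based half-open and the
## strand becomes "+", "-" or "*".

#' Read a STAR-format splice junction table
#'
#' @param path Path to a 9-column tab-separated SJ.out.tab-style file.
#' @return data.frame with `chrom`, `intron_start`, `intron_end` (0-based
#'   half-open intron interval), `strand` (`+`, `-`, `*` for undefined),
#'   `motif`, `annotated`, `unique_reads`, `multi_reads`, `max_overhang`.
#' @export
read_star_sj <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  colClasses = c("character", rep("integer", 8)))
  names(d) <- c("chrom", "intron_start", "intron_end", "strand_code",
                "motif", "annotated", "unique_reads", "multi_reads",
                "max_overhang")
  if (any(d$intron_start > d$intron_end))
    stop("junction with intron_start > intron_end")
  if (any(d$unique_reads < 0 | d$multi_reads < 0))
    stop("negative junction read count")
  d$intron_start <- d$intron_start - 1L        # to 0-based half-open
  d$strand <- c("*", "+", "-")[d$strand_code + 1L]
  d[c("chrom", "intron_start", "intron_end", "strand", "motif",
      "annotated", "unique_reads", "multi_reads", "max_overhang")]
}

#' Write a splice junction table back in STAR dialect
#'
#' Inverse of [read_star_sj()]; the round trip is bit-identical on
#' coordinates and counts.
#'
#' @param sj data.frame from [read_star_sj()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_star_sj <- function(sj, path) {
  out <- data.frame(
    sj$chrom, sj$intron_start + 1L, sj$intron_end,
    match(sj$strand, c("*", "+", "-")) - 1L,
    sj$motif, sj$annotated, sj$unique_reads, sj$multi_reads, sj$max_overhang)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-sample normalized spliced reads
#'
#' Total spliced reads divided by uniquely mapped reads; scale-invariant, so
#' samples of different depth are comparable.
#'
#' @param total_spliced Total spliced read count (e.g.
#'   [total_spliced_reads()]).
#' @param uniquely_mapped Uniquely mapped reads in the sample; must be > 0.
#' @return The ratio.
#' @export
normalized_spliced_reads <- function(total_spliced, uniquely_mapped) {
  stopifnot(total_spliced >= 0)
  if (uniquely_mapped <= 0)
    stop("uniquely_mapped must be positive")
  total_spliced / uniquely_mapped
}

#' Total spliced reads of a junction table
#'
#' Sums `unique_reads` over junctions; multi-mapped junction reads are
#' excluded, matching the uniquely-mapped denominator of
#' [normalized_spliced_reads()].
#'
#' @param sj Junction data.frame ([read_star_sj()]).
#' @return Integer total.
#' @export
total_spliced_reads <- function(sj) {
  sum(sj$unique_reads)
}

#' Count splice junctions per L1 locus
#'
#' A junction counts toward a locus iff either splice site (the first or
#' the last intron base) lies within the locus and the junction strand
#' matches the locus strand; undefined-strand junctions (`*`) count for
#' either strand. A counted junction is *incoming* when exactly one splice
#' site is inside the locus and the strand is defined -- the configuration
#' in which a host transcript is spliced into the element, which rejects
#' the locus during curation. Junctions wholly inside the locus are counted
#' but never mark it incoming.
#'
#' @param junctions Junction data.frame ([read_star_sj()]).
#' @param loci Catalog data.frame (one or more rows).
#' @return List with `per_locus` (data.frame `uid`, `n_junctions`,
#'   `incoming_junctions`) and `fraction_with_junction` (fraction of loci
#'   with at least one counted junction).
#' @export
junctions_per_locus <- function(junctions, loci) {
  n <- NROW(loci)
  nj <- integer(n); inc <- integer(n)
  for (i in seq_len(n)) {
    l <- loci[i, , drop = FALSE]
    same_chrom <- junctions$chrom == l$chrom
    strand_ok <- junctions$strand == "*" | junctions$strand == l$strand
    donor_in <- junctions$intron_start >= l$start &
      junctions$intron_start < l$end
    acceptor_in <- (junctions$intron_end - 1L) >= l$start &
      (junctions$intron_end - 1L) < l$end
    counted <- same_chrom & strand_ok & (donor_in | acceptor_in)
    nj[i] <- sum(counted)
    inc[i] <- sum(counted & junctions$strand != "*" &
                    xor(donor_in, acceptor_in))
  }
  list(
    per_locus = data.frame(uid = loci$uid, n_junctions = nj,
                           incoming_junctions = inc,
                           stringsAsFactors = FALSE),
    fraction_with_junction = if (n == 0) NA_real_ else mean(nj > 0)
  )
}
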