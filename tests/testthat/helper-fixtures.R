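# Shared fixture builders. Everything is generated in code; no binary data.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## a minimal valid L1 catalog data.frame
toy_catalog <- function(uid = c("UID-1", "UID-2"),
                        chrom = "chr1",
                        start = c(1000L, 20000L),
                        end = c(7000L, 26000L),
                        strand = c("+", "-"),
                        subfamily = "T_f",
                        monomer_count = 3L) {
  data.frame(uid = uid, chrom = chrom, start = start, end = end,
             strand = strand, subfamily = subfamily,
             monomer_count = monomer_count, intactness = "intact",
             stringsAsFactors = FALSE)
}

## aligned-pair rows from fragment intervals (coordinates 0-based half-open)
make_pairs <- function(frag_start, frag_end, strand = "+", chrom = "chr1",
                       read_len = 100L, id_prefix = "p") {
  n <- length(frag_start)
  strand <- rep_len(strand, n)
  m1s <- ifelse(strand == "+", frag_start, frag_end - read_len)
  m1e <- m1s + read_len
  m2s <- ifelse(strand == "+", frag_end - read_len, frag_start)
  m2e <- m2s + read_len
  data.frame(
    read_id = paste0(id_prefix, seq_len(n)), chrom = chrom,
    m1_start = as.integer(m1s), m1_end = as.integer(m1e),
    m2_start = as.integer(m2s), m2_end = as.integer(m2e),
    frag_start = as.integer(frag_start), frag_end = as.integer(frag_end),
    fragment_strand = strand,
    mismatches_m1 = 0L, mismatches_m2 = 0L, n_valid_placements = 1L,
    stringsAsFactors = FALSE)
}

## write a small SAM file; each record is a list of fields
write_sam <- function(records, chrom_lengths = c(chr1 = 100000L)) {
  path <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths), chrom_lengths))
  writeLines(c(hdr, records), path)
  path
}

sam_record <- function(qname, flag, chrom, pos1, cigar, seq,
                       nm = 0L, nh = NULL) {
  tags <- sprintf("NM:i:%d", nm)
  if (!is.null(nh)) tags <- c(tags, sprintf("NH:i:%d", nh))
  paste(c(qname, flag, chrom, pos1, 60, cigar, "=", 1, 0, seq, "*", tags),
        collapse = "\t")
}

## one proper FR pair: mate1 forward at p1, mate2 reverse at p2 (1-based)
sam_pair <- function(qname, chrom, p1, p2, read_len = 50L,
                     nm1 = 0L, nm2 = 0L, nh = NULL, same_strand = FALSE) {
  seq <- strrep("A", read_len)
  f1 <- 1L + 2L + 32L + 64L              # paired, proper, mate rev, first
  f2 <- 1L + 2L + 16L + 128L             # paired, proper, rev, second
  if (same_strand) f2 <- 1L + 2L + 128L
  cig <- sprintf("%dM", read_len)
  c(sam_record(qname, f1, chrom, p1, cig, seq, nm1, nh),
    sam_record(qname, f2, chrom, p2, cig, seq, nm2, nh))
}

## independent exhaustive mapper: full positional scan in plain R.
## Enumerates every concordant FR placement with <= v mismatches per mate
## and fragment span <= max_insert; keeps a pair iff exactly one exists.
naive_unique_map <- function(r1, r2, genome, v = 3, max_insert = 600) {
  gch <- strsplit(unname(genome), "")[[1]]
  G <- length(gch)
  mate_hits <- function(seq) {
    hits <- list()
    for (orient in c("+", "-")) {
      s <- if (orient == "+") seq else rc(seq)
      sch <- strsplit(s, "")[[1]]
      L <- length(sch)
      for (pos in 0:(G - L)) {
        mm <- sum(gch[(pos + 1):(pos + L)] != sch)
        if (mm <= v)
          hits[[length(hits) + 1]] <- list(pos = pos, end = pos + L,
                                           fwd = orient == "+", mm = mm)
      }
    }
    hits
  }
  out <- integer(length(r1))
  placements <- vector("list", length(r1))
  for (i in seq_along(r1)) {
    h1 <- mate_hits(r1[i]); h2 <- mate_hits(r2[i])
    pls <- list()
    for (a in h1) for (b in h2) {
      if (a$fwd == b$fwd) next
      plus <- if (a$fwd) a else b
      minus <- if (a$fwd) b else a
      if (plus$pos > minus$pos) next
      if (minus$end < plus$end) next
      if (minus$end - plus$pos > max_insert) next
      pls[[length(pls) + 1]] <- list(
        m1_start = a$pos, m1_end = a$end, m2_start = b$pos, m2_end = b$end,
        m1_strand = if (a$fwd) "+" else "-")
    }
    out[i] <- length(pls)
    placements[[i]] <- pls
  }
  list(n_placements = out, placements = placements)
}

## small pipeline configuration used by several test files (fast: ~2 s)
fast_sim_config <- function(seed = 11, ...) {
  args <- list(seed = seed, depth = 2e4, dna_depth = 5e3)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
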