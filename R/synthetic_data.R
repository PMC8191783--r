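## Deterministic toy-genome and read simulator. It emulates the statistical
## structure the pipeline assumes: full-length L1 loci with tandem 5'
## promoter monomers (~200 bp each) on either strand, subfamily labels,
## truncated L1 fragments buried in gene introns and 3'UTRs, authentic
## promoter-initiated L1 transcripts, passive carrier transcripts (intronic
## and 3'UTR carriers, plus upstream read-through across full-length loci)
## up to ~100-fold more abundant, and strand-specific paired-end reads with
## configurable fragment length, depth and error rate. Every fragment gets
## a ground-truth label. One integer seed governs everything: genome
## construction uses `seed`, RNA reads `seed + 1`, DNA reads `seed + 2`.

#' Simulation configuration
#'
#' Defaults describe the standard study conditions used throughout the test
#' suite: a 200 kb toy chromosome, 10 full-length L1 loci, 20 gene-embedded
#' truncated fragments, passive background 100-fold more abundant than
#' authentic L1 mRNA, error-free 2 x 100 bp strand-specific pairs at a depth
#' of 2e5 fragments.
#'
#' @param seed Integer seed; the sole source of randomness.
#' @param genome_length Chromosome length in bp.
#' @param n_full_length_l1 Number of full-length L1 loci.
#' @param subfamily_mix Named sampling weights over subfamilies.
#' @param monomer_length Promoter monomer unit length in bp (~200 for
#'   rodent L1 monomers).
#' @param monomer_range Inclusive range the per-locus monomer count is
#'   drawn from.
#' @param body_length Element body length in bp (monomers + body give the
#'   ~6-7 kb element).
#' @param monomer_divergence Per-base substitution rate applied
#'   independently to each monomer copy (promoter copies are near-identical
#'   across loci, so low values make promoter reads multi-map as in real
#'   genomes).
#' @param body_divergence Per-base substitution rate of each locus body
#'   from its subfamily ancestral body.
#' @param n_genes Number of genes.
#' @param n_truncated_l1_in_genes Truncated L1 fragments embedded in gene
#'   introns / 3'UTRs (alternating), at most 2 per gene.
#' @param truncated_length_range Length range of embedded fragments.
#' @param authentic_fraction Fraction of full-length loci transcribed from
#'   their own promoter.
#' @param n_readthrough Non-authentic full-length loci covered by an
#'   upstream same-strand read-through carrier.
#' @param background_ratio Total passive-carrier abundance as a multiple of
#'   total authentic L1 mRNA abundance.
#' @param plain_gene_ratio Total abundance of genes without L1 content,
#'   as a multiple of total authentic abundance.
#' @param depth Number of RNA fragments to simulate.
#' @param dna_depth Number of whole-genome DNA fragments for the
#'   mappability profile.
#' @param read_length Read length in bp.
#' @param fragment_mean,fragment_sd Fragment length distribution
#'   (truncated to `[read_length, 600]`).
#' @param error_rate Per-base substitution error rate.
#' @param strandedness Library protocol (`"fr"` or `"rf"`).
#' @param duplicate_locus_pair If `TRUE`, one extra silent locus duplicates
#'   another silent locus exactly, exercising zero mappability.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       genome_length = 200000,
                       n_full_length_l1 = 10,
                       subfamily_mix = c(T_f = 0.4, G_f = 0.3, A = 0.3),
                       monomer_length = 200,
                       monomer_range = c(1, 6),
                       body_length = 6000,
                       monomer_divergence = 0.03,
                       body_divergence = 0.10,
                       n_genes = 20,
                       n_truncated_l1_in_genes = 20,
                       truncated_length_range = c(500, 1000),
                       authentic_fraction = 0.3,
                       n_readthrough = 2,
                       background_ratio = 100,
                       plain_gene_ratio = 50,
                       depth = 2e5,
                       dna_depth = 1.2e4,
                       read_length = 100,
                       fragment_mean = 300,
                       fragment_sd = 50,
                       error_rate = 0,
                       strandedness = "fr",
                       duplicate_locus_pair = FALSE) {
  cfg <- as.list(environment())
  stopifnot(cfg$background_ratio >= 1, cfg$depth >= 0,
            cfg$error_rate >= 0, cfg$error_rate < 1,
            cfg$fragment_mean <= 600, cfg$read_length > 0,
            cfg$authentic_fraction >= 0, cfg$authentic_fraction <= 1)
  class(cfg) <- "sim_config"
  cfg
}

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) {
  paste0(sample(BASES, n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit)) {
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(BASES, b), 1),
                     character(1))
    s <- paste0(v, collapse = "")
  }
  s
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build a toy genome with annotated L1 loci, genes and ground truth
#'
#' Places genes (three exons, two introns; some carrying a truncated L1
#' fragment in intron 2 or the 3'UTR) and full-length L1 loci (k tandem
#' monomer copies plus a body derived from a subfamily ancestral sequence)
#' in shuffled order along one chromosome with random intergenic gaps, then
#' defines the transcript population: authentic L1 transcripts (promoter to
#' element end, sense strand), passive carriers (gene pre-mRNAs containing
#' embedded fragments, and read-through transcripts spanning 1 kb upstream
#' flank + locus + 0.5 kb downstream of selected silent loci), and plain
#' gene transcripts. Abundance weights: authentic loci get geometrically
#' spread weights; passive carriers share `background_ratio` times the
#' total authentic weight; plain genes share `plain_gene_ratio` times.
#'
#' @param config A [sim_config()].
#' @return List: `genome` (named character vector, one chromosome),
#'   `catalog` (L1 catalog data.frame), `genes` (gene table),
#'   `truncated` (data.frame of embedded fragment intervals),
#'   `transcripts` (truth transcript table: `transcript_id`, `class`,
#'   `source`, `chrom`, `start`, `end`, `strand`, `weight`, `share`),
#'   `locus_truth` (per-locus flags `authentic`, `readthrough_target`,
#'   `duplicated`), `config`.
#' @export
build_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  chrom <- "chrT"
  ml <- config$monomer_length

  ## subfamily ancestral sequences
  subfams <- names(config$subfamily_mix)
  anc_monomer <- setNames(vapply(subfams, function(s) rand_seq(ml),
                                 character(1)), subfams)
  anc_body <- setNames(vapply(subfams, function(s)
    rand_seq(config$body_length), character(1)), subfams)

  n_l1 <- config$n_full_length_l1
  n_l1_total <- n_l1 + as.integer(isTRUE(config$duplicate_locus_pair))

  ## feature blueprints ------------------------------------------------
  feats <- list()
  if (n_l1 > 0) {
    sf <- sample(subfams, n_l1, replace = TRUE, prob = config$subfamily_mix)
    k <- sample(seq(config$monomer_range[1], config$monomer_range[2]),
                n_l1, replace = TRUE)
    for (i in seq_len(n_l1)) {
      monos <- vapply(seq_len(k[i]), function(j)
        mutate_seq(anc_monomer[[sf[i]]], config$monomer_divergence),
        character(1))
      body <- mutate_seq(anc_body[[sf[i]]], config$body_divergence)
      feats[[length(feats) + 1]] <- list(
        type = "l1", uid = sprintf("UID-%04d", i), subfamily = sf[i],
        monomer_count = k[i], strand = sample(c("+", "-"), 1),
        seq_sense = paste0(paste0(monos, collapse = ""), body))
    }
  }
  n_frag <- config$n_truncated_l1_in_genes
  if (n_frag > 2 * config$n_genes)
    stop("at most 2 truncated fragments per gene: reduce ",
         "n_truncated_l1_in_genes or add genes")
  frag_gene <- if (n_frag > 0)
    rep(seq_len(config$n_genes), length.out = n_frag) else integer(0)
  frag_site <- rep(c("intron", "utr3"), length.out = n_frag)
  for (g in seq_len(config$n_genes)) {
    sites <- frag_site[frag_gene == g]
    frags <- lapply(sites, function(site) {
      sfg <- sample(subfams, 1)
      len <- sample(seq(config$truncated_length_range[1],
                        config$truncated_length_range[2]), 1)
      off <- sample(seq_len(config$body_length - len), 1)
      list(site = site, subfamily = sfg,
           seq = mutate_seq(substr(anc_body[[sfg]], off, off + len - 1),
                            config$body_divergence))
    })
    feats[[length(feats) + 1]] <- list(
      type = "gene", gene_id = sprintf("gene%03d", g),
      strand = sample(c("+", "-"), 1), frags = frags)
  }
  feats <- feats[sample(length(feats))]

  ## assemble the chromosome -------------------------------------------
  chunks <- character(0); cursor <- 0L
  add <- function(s) {
    chunks[[length(chunks) + 1]] <<- s
    start <- cursor
    cursor <<- cursor + nchar(s)
    c(start, cursor)
  }
  catalog_rows <- list(); gene_rows <- list(); trunc_rows <- list()
  dup_source <- NULL
  prev_l1 <- FALSE
  for (f in feats) {
    ## intergenic gap; full-length loci get clear >= 1.2 kb flanks so a
    ## neighboring transcript cannot masquerade as upstream read-through
    wide <- prev_l1 || f$type == "l1"
    add(rand_seq(if (wide) sample(1200:1800, 1) else sample(400:1000, 1)))
    prev_l1 <- f$type == "l1"
    if (f$type == "l1") {
      s <- if (f$strand == "+") f$seq_sense else revcomp_chr(f$seq_sense)
      iv <- add(s)
      catalog_rows[[length(catalog_rows) + 1]] <- data.frame(
        uid = f$uid, chrom = chrom, start = iv[1], end = iv[2],
        strand = f$strand, subfamily = f$subfamily,
        monomer_count = f$monomer_count, intactness = "intact",
        stringsAsFactors = FALSE)
    } else {
      ## gene: e1 - i1 - e2 - i2(+frag?) - e3(+utr3 frag?)
      e1 <- rand_seq(300)
      i1 <- rand_seq(1000)
      e2 <- rand_seq(300)
      i2 <- rand_seq(1000)
      e3 <- rand_seq(800)
      frag_iv <- list()
      intron_frag <- Filter(function(x) x$site == "intron", f$frags)
      utr_frag <- Filter(function(x) x$site == "utr3", f$frags)
      gs <- cursor
      iv1 <- add(e1); add(i1); iv2 <- add(e2)
      add(substr(i2, 1, 500))
      for (fr in intron_frag) {
        fs <- if (f$strand == "+") fr$seq else revcomp_chr(fr$seq)
        frag_iv[[length(frag_iv) + 1]] <-
          c(add(fs), sub = fr$subfamily)
      }
      add(substr(i2, 501, 1000))
      iv3a <- add(substr(e3, 1, 400))
      for (fr in utr_frag) {
        fs <- if (f$strand == "+") fr$seq else revcomp_chr(fr$seq)
        frag_iv[[length(frag_iv) + 1]] <- c(add(fs), sub = fr$subfamily)
      }
      iv3b <- add(substr(e3, 401, 800))
      ge <- cursor
      gene_rows[[length(gene_rows) + 1]] <- data.frame(
        gene_id = f$gene_id, chrom = chrom,
        start = c(iv1[1], iv2[1], iv3a[1]),
        end = c(iv1[2], iv2[2], ge),
        strand = f$strand, stringsAsFactors = FALSE)
      for (fi in frag_iv)
        trunc_rows[[length(trunc_rows) + 1]] <- data.frame(
          gene_id = f$gene_id, chrom = chrom,
          start = as.integer(fi[1]), end = as.integer(fi[2]),
          strand = f$strand, subfamily = fi["sub"],
          stringsAsFactors = FALSE)
      attr(gene_rows[[length(gene_rows)]], "span") <- c(gs, ge)
    }
  }
  ## optional exact duplicate of a (later-forced-silent) locus
  if (isTRUE(config$duplicate_locus_pair) && length(catalog_rows) > 0) {
    src <- catalog_rows[[length(catalog_rows)]]
    add(rand_seq(1000))
    seq_src <- substr(paste0(chunks, collapse = ""), src$start + 1, src$end)
    iv <- add(seq_src)
    dup_source <- src$uid
    catalog_rows[[length(catalog_rows) + 1]] <- data.frame(
      uid = sprintf("UID-%04d", n_l1 + 1), chrom = chrom,
      start = iv[1], end = iv[2], strand = src$strand,
      subfamily = src$subfamily, monomer_count = src$monomer_count,
      intactness = "intact", stringsAsFactors = FALSE)
  }
  add(rand_seq(1000))
  if (cursor > config$genome_length)
    stop("features need ", cursor, " bp but genome_length is ",
         config$genome_length, ": infeasible placement")
  add(rand_seq(config$genome_length - cursor))
  genome <- setNames(paste0(chunks, collapse = ""), chrom)

  catalog <- if (length(catalog_rows)) do.call(rbind, catalog_rows)
  else empty_l1_catalog()
  genes <- if (length(gene_rows))
    build_gene_table(do.call(rbind, gene_rows)) else empty_gene_table()
  truncated <- if (length(trunc_rows)) do.call(rbind, trunc_rows)
  else data.frame(gene_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0), subfamily = character(0),
                  stringsAsFactors = FALSE)
  rownames(truncated) <- NULL

  ## transcript population ---------------------------------------------
  n_auth <- round(config$authentic_fraction * n_l1)
  auth_idx <- if (n_auth > 0) sample(seq_len(n_l1), n_auth) else integer(0)
  silent_idx <- setdiff(seq_len(nrow(catalog)), auth_idx)
  if (!is.null(dup_source))   # duplicated pair stays silent
    silent_idx <- setdiff(silent_idx, nrow(catalog))
  rt_idx <- if (config$n_readthrough > 0 && length(silent_idx) > 0)
    sample(silent_idx, min(config$n_readthrough, length(silent_idx)))
  else integer(0)

  tr <- list()
  if (length(auth_idx)) {
    w <- 1.5^(seq_along(auth_idx) - 1)    # geometric spread of levels
    for (j in seq_along(auth_idx)) {
      i <- auth_idx[j]
      tr[[length(tr) + 1]] <- data.frame(
        transcript_id = paste0("tx_auth_", catalog$uid[i]),
        class = "authentic_l1", source = catalog$uid[i],
        chrom = chrom, start = catalog$start[i], end = catalog$end[i],
        strand = catalog$strand[i], weight = w[j],
        stringsAsFactors = FALSE)
    }
  }
  w_auth_total <- sum(vapply(tr, function(x) x$weight, numeric(1)))
  if (w_auth_total == 0) w_auth_total <- 1   # passive-only configurations
  carrier_genes <- unique(truncated$gene_id)
  n_passive <- length(carrier_genes) + length(rt_idx)
  w_passive <- if (n_passive > 0)
    config$background_ratio * w_auth_total / n_passive else 0
  for (g in carrier_genes) {
    gi <- genes[genes$gene_id == g, , drop = FALSE]
    tr[[length(tr) + 1]] <- data.frame(
      transcript_id = paste0("tx_carrier_", g), class = "passive_carrier",
      source = g, chrom = chrom, start = gi$start, end = gi$end,
      strand = gi$strand, weight = w_passive, stringsAsFactors = FALSE)
  }
  for (i in rt_idx) {
    up <- 1000L; down <- 500L
    st <- if (catalog$strand[i] == "+") catalog$start[i] - up
    else catalog$start[i] - down
    en <- if (catalog$strand[i] == "+") catalog$end[i] + down
    else catalog$end[i] + up
    tr[[length(tr) + 1]] <- data.frame(
      transcript_id = paste0("tx_readthrough_", catalog$uid[i]),
      class = "passive_carrier", source = catalog$uid[i],
      chrom = chrom, start = max(0L, st),
      end = min(en, config$genome_length),
      strand = catalog$strand[i], weight = w_passive,
      stringsAsFactors = FALSE)
  }
  plain_genes <- setdiff(genes$gene_id, carrier_genes)
  w_plain <- if (length(plain_genes) > 0)
    config$plain_gene_ratio * w_auth_total / length(plain_genes) else 0
  for (g in plain_genes) {
    gi <- genes[genes$gene_id == g, , drop = FALSE]
    tr[[length(tr) + 1]] <- data.frame(
      transcript_id = paste0("tx_gene_", g), class = "plain_gene",
      source = g, chrom = chrom, start = gi$start, end = gi$end,
      strand = gi$strand, weight = w_plain, stringsAsFactors = FALSE)
  }
  transcripts <- if (length(tr)) do.call(rbind, tr) else
    data.frame(transcript_id = character(0), class = character(0),
               source = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               weight = numeric(0), stringsAsFactors = FALSE)
  transcripts$share <- if (nrow(transcripts) > 0)
    transcripts$weight / sum(transcripts$weight) else numeric(0)
  rownames(transcripts) <- NULL

  locus_truth <- data.frame(
    uid = catalog$uid,
    authentic = seq_len(nrow(catalog)) %in% auth_idx,
    readthrough_target = seq_len(nrow(catalog)) %in% rt_idx,
    duplicated = if (is.null(dup_source)) rep(FALSE, nrow(catalog))
    else catalog$uid == dup_source |
      seq_len(nrow(catalog)) == nrow(catalog),
    stringsAsFactors = FALSE)

  list(genome = genome, catalog = catalog, genes = genes,
       truncated = truncated, transcripts = transcripts,
       locus_truth = locus_truth,
       ancestral = list(monomer = anc_monomer, body = anc_body),
       config = config)
}

#' Simulate strand-specific paired-end RNA fragments with truth labels
#'
#' Fragments are multinomially allocated to transcripts by their abundance
#' share; positions are uniform along the transcript; fragment length is
#' normal (`fragment_mean`, `fragment_sd`) truncated to
#' `[read_length, min(600, transcript length)]`. Mate 1 reads the 5' end of
#' the fragment on the fragment (sense) strand, mate 2 the reverse
#' complement of the 3' end; substitution errors are i.i.d. at
#' `error_rate`.
#'
#' @param bundle Genome bundle from [build_genome()].
#' @param config Defaults to `bundle$config`.
#' @return List: `r1`, `r2` (named character vectors of mate sequences) and
#'   `truth` (data.frame: `read_id`, `transcript_id`, `class`, `source`,
#'   `chrom`, `frag_start`, `frag_end`, `strand`, `overlaps_l1` -- whether
#'   the fragment touches any full-length locus or embedded fragment).
#' @export
simulate_reads <- function(bundle, config = bundle$config) {
  set.seed(config$seed + 1L)
  tx <- bundle$transcripts
  empty <- list(r1 = character(0), r2 = character(0),
                truth = data.frame(read_id = character(0),
                                   transcript_id = character(0),
                                   class = character(0), source = character(0),
                                   chrom = character(0),
                                   frag_start = integer(0),
                                   frag_end = integer(0),
                                   strand = character(0),
                                   overlaps_l1 = logical(0),
                                   stringsAsFactors = FALSE))
  if (config$depth <= 0 || nrow(tx) == 0) return(empty)
  n <- as.integer(config$depth)
  ti <- sample.int(nrow(tx), n, replace = TRUE, prob = tx$share)
  tlen <- tx$end[ti] - tx$start[ti]
  flen <- pmin(pmax(round(rnorm(n, config$fragment_mean, config$fragment_sd)),
                    config$read_length), pmin(600L, tlen))
  off <- floor(runif(n) * (tlen - flen + 1))
  plus <- tx$strand[ti] == "+"
  gs <- ifelse(plus, tx$start[ti] + off, tx$end[ti] - off - flen)
  ge <- gs + flen
  genome_str <- bundle$genome[[1]]
  frag_fwd <- substring(genome_str, gs + 1, ge)
  frag <- frag_fwd
  if (any(!plus)) frag[!plus] <- revcomp_chr(frag_fwd[!plus])
  rl <- config$read_length
  r1 <- substring(frag, 1, rl)
  r2 <- revcomp_chr(substring(frag, flen - rl + 1, flen))
  if (config$error_rate > 0) {
    r1 <- vapply(r1, mutate_seq, character(1), rate = config$error_rate,
                 USE.NAMES = FALSE)
    r2 <- vapply(r2, mutate_seq, character(1), rate = config$error_rate,
                 USE.NAMES = FALSE)
  }
  ids <- sprintf("frag%07d", seq_len(n))
  names(r1) <- ids; names(r2) <- ids

  l1_iv <- rbind(
    data.frame(start = bundle$catalog$start, end = bundle$catalog$end),
    data.frame(start = bundle$truncated$start, end = bundle$truncated$end))
  overlaps_l1 <- if (nrow(l1_iv) > 0) {
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = gs + 1, end = ge),
      IRanges::IRanges(start = l1_iv$start + 1, end = l1_iv$end))
    seq_len(n) %in% S4Vectors::queryHits(ov)
  } else rep(FALSE, n)

  truth <- data.frame(
    read_id = ids, transcript_id = tx$transcript_id[ti],
    class = tx$class[ti], source = tx$source[ti],
    chrom = tx$chrom[ti], frag_start = as.integer(gs),
    frag_end = as.integer(ge), strand = tx$strand[ti],
    overlaps_l1 = overlaps_l1, stringsAsFactors = FALSE)
  list(r1 = r1, r2 = r2, truth = truth)
}

#' Subfamily promoter consensi for a synthetic bundle
#'
#' Builds one [subfamily_consensus()] (two ancestral promoter monomers plus
#' the ancestral body) per subfamily of the bundle, for realigning
#' filter-discarded reads.
#'
#' @param bundle Genome bundle from [build_genome()].
#' @return List of [subfamily_consensus()] objects.
#' @export
bundle_consensi <- function(bundle) {
  subfams <- names(bundle$ancestral$monomer)
  lapply(subfams, function(sf)
    subfamily_consensus(sf, bundle$ancestral$monomer[[sf]],
                        bundle$ancestral$body[[sf]]))
}

#' Simulate whole-genome DNA-seq fragments (uniform, both strands)
#'
#' @param bundle Genome bundle from [build_genome()].
#' @param depth Number of fragments (default `bundle$config$dna_depth`).
#' @param config Defaults to `bundle$config`.
#' @return List `r1`, `r2` as in [simulate_reads()].
#' @export
simulate_dna_reads <- function(bundle, depth = bundle$config$dna_depth,
                               config = bundle$config) {
  set.seed(config$seed + 2L)
  n <- as.integer(depth)
  empty <- list(r1 = character(0), r2 = character(0))
  if (n <= 0) return(empty)
  glen <- nchar(bundle$genome[[1]])
  flen <- pmin(pmax(round(rnorm(n, config$fragment_mean, config$fragment_sd)),
                    config$read_length), 600L)
  gs <- floor(runif(n) * (glen - flen))
  ge <- gs + flen
  frag <- substring(bundle$genome[[1]], gs + 1, ge)
  minus <- runif(n) < 0.5
  frag[minus] <- revcomp_chr(frag[minus])
  rl <- config$read_length
  r1 <- substring(frag, 1, rl)
  r2 <- revcomp_chr(substring(frag, flen - rl + 1, flen))
  ids <- sprintf("dna%07d", seq_len(n))
  names(r1) <- ids; names(r2) <- ids
  list(r1 = r1, r2 = r2)
}
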