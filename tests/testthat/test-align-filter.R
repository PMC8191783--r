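# The unique-alignment contract: concordant FR pairs, fragment span <= 600,
# <= 3 mismatches per mate, exactly one valid placement.

mutate_at <- function(s, pos, to = NULL) {
  v <- strsplit(s, "")[[1]]
  for (p in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), v[p])
    v[p] <- if (is.null(to)) alt[1] else to
  }
  paste0(v, collapse = "")
}

pair_from <- function(genome, start, frag_len, read_len = 50) {
  frag <- substr(unname(genome), start + 1, start + frag_len)
  list(r1 = substr(frag, 1, read_len),
       r2 = rc(substr(frag, frag_len - read_len + 1, frag_len)))
}

test_that("brute-force mapper keeps unique pairs and rejects boundary cases", {
  set.seed(42)
  genome <- c(chrA = rand_dna(8000))
  p <- pair_from(genome, 1000, 300)

  res <- brute_force_unique_map(c(a = p$r1), c(a = p$r2), genome)
  expect_equal(nrow(res$kept), 1)
  expect_equal(res$kept$frag_start, 1000L)
  expect_equal(res$kept$frag_end, 1300L)
  expect_equal(res$kept$fragment_strand, "+")
  expect_equal(res$kept$n_valid_placements, 1L)

  ## fragment span 601 -> no concordant placement -> discarded
  p601 <- pair_from(genome, 1000, 601)
  res <- brute_force_unique_map(c(a = p601$r1), c(a = p601$r2), genome)
  expect_equal(nrow(res$kept), 0)
  expect_equal(res$discarded$reason, "discordant")
  ## span 600 exactly is still concordant
  p600 <- pair_from(genome, 1000, 600)
  res <- brute_force_unique_map(c(a = p600$r1), c(a = p600$r2), genome)
  expect_equal(nrow(res$kept), 1)

  ## 4 mismatches on one mate -> zero placements at v = 3
  r1_4mm <- mutate_at(p$r1, c(5, 15, 25, 35))
  res <- brute_force_unique_map(c(a = r1_4mm), c(a = p$r2), genome)
  expect_equal(nrow(res$kept), 0)
  expect_equal(res$discarded$reason, "too_many_mismatches")
  ## 3 mismatches are tolerated
  r1_3mm <- mutate_at(p$r1, c(5, 15, 25))
  res <- brute_force_unique_map(c(a = r1_3mm), c(a = p$r2), genome)
  expect_equal(nrow(res$kept), 1)
  expect_equal(res$kept$mismatches_m1, 3L)
})

test_that("pairs from duplicated sequence are discarded as multi-mapped", {
  set.seed(43)
  core <- rand_dna(1000)
  genome <- c(chrA = paste0(rand_dna(2000), core, rand_dna(2000), core,
                            rand_dna(1000)))
  p <- pair_from(c(x = core), 100, 400)
  res <- brute_force_unique_map(c(a = p$r1), c(a = p$r2), genome)
  expect_equal(nrow(res$kept), 0)
  expect_equal(res$discarded$reason, "multi_mapped")
  expect_equal(res$discarded$seq1, unname(p$r1))
})

test_that("minus-strand fragments are recovered with correct strand", {
  set.seed(44)
  genome <- c(chrA = rand_dna(5000))
  frag <- substr(unname(genome), 2001, 2300)
  frag_rc <- rc(frag)                       # fragment transcribed from -
  r1 <- substr(frag_rc, 1, 60)
  r2 <- rc(substr(frag_rc, 241, 300))
  res <- brute_force_unique_map(c(a = r1), c(a = r2), genome)
  expect_equal(nrow(res$kept), 1)
  expect_equal(res$kept$fragment_strand, "-")
  expect_equal(res$kept$frag_start, 2000L)
  ## dUTP-style protocol flips the reported fragment strand
  res_rf <- brute_force_unique_map(c(a = r1), c(a = r2), genome,
                                   strandedness = "rf")
  expect_equal(res_rf$kept$fragment_strand, "+")
})

test_that("kept/discarded partition the input and the contract holds", {
  set.seed(45)
  genome <- c(chrA = rand_dna(10000))
  n <- 40
  starts <- sample(0:9300, n)
  lens <- sample(200:550, n, replace = TRUE)
  ps <- mapply(function(s, l) pair_from(genome, s, l), starts, lens,
               SIMPLIFY = FALSE)
  r1 <- vapply(ps, `[[`, character(1), "r1")
  r2 <- vapply(ps, `[[`, character(1), "r2")
  names(r1) <- names(r2) <- paste0("rd", seq_len(n))
  res <- brute_force_unique_map(r1, r2, genome)
  expect_equal(sort(c(res$kept$read_id, res$discarded$read_id)), sort(names(r1)))
  expect_true(all(res$kept$frag_end - res$kept$frag_start <= 600))
  expect_true(all(res$kept$mismatches_m1 <= 3))
  expect_true(all(res$kept$mismatches_m2 <= 3))
  expect_true(all(res$kept$n_valid_placements == 1))
})

test_that("placement count is monotone in the mismatch allowance", {
  set.seed(46)
  genome <- c(chrA = rand_dna(6000))
  n <- 15
  starts <- sample(0:5500, n)
  ps <- lapply(starts, function(s) pair_from(genome, s, 300))
  r1 <- vapply(ps, `[[`, character(1), "r1")
  r2 <- vapply(ps, function(p) mutate_at(p$r2, c(3, 13)), character(1))
  names(r1) <- names(r2) <- paste0("rd", seq_len(n))
  kept_v0 <- brute_force_unique_map(r1, r2, genome, v = 0)$kept$read_id
  kept_v3 <- brute_force_unique_map(r1, r2, genome, v = 3)$kept$read_id
  ## v = 0 keeps nothing here (mate 2 carries 2 mismatches); v = 3 keeps all
  expect_equal(length(kept_v0), 0)
  expect_equal(sort(kept_v3), sort(names(r1)))
})

test_that("SAM filtering applies every clause with a single discard reason", {
  recs <- c(
    sam_pair("ok", "chr1", 1001, 1201),                     # frag 250
    sam_pair("multi", "chr1", 2001, 2201, nh = 2),
    sam_pair("mm4", "chr1", 3001, 3201, nm1 = 4),
    sam_pair("longfrag", "chr1", 4001, 4552),               # span 601
    sam_pair("samestrand", "chr1", 5001, 5201, same_strand = TRUE),
    sam_record("orphan", 73, "chr1", 6001, "50M", strrep("A", 50)))
  path <- write_sam(recs)
  res <- filter_alignments(path)
  expect_equal(res$kept$read_id, "ok")
  expect_equal(res$kept$frag_start, 1000L)
  expect_equal(res$kept$frag_end, 1250L)
  expect_equal(res$kept$fragment_strand, "+")
  d <- res$discarded
  expect_equal(d$reason[d$read_id == "multi"], "multi_mapped")
  expect_equal(d$reason[d$read_id == "mm4"], "too_many_mismatches")
  expect_equal(d$reason[d$read_id == "longfrag"], "discordant")
  expect_equal(d$reason[d$read_id == "samestrand"], "discordant")
  expect_equal(d$reason[d$read_id == "orphan"], "discordant")
  expect_equal(nrow(res$kept) + nrow(d), 6)

  ## exact boundary: span 600 is kept (mate2 at 4551 -> end 4600)
  res600 <- filter_alignments(write_sam(sam_pair("edge", "chr1", 4001, 4551)))
  expect_equal(res600$kept$read_id, "edge")
  expect_equal(res600$kept$frag_end - res600$kept$frag_start, 600L)
})

test_that("SAM records without NM tags trigger the recompute error", {
  rec <- paste(c("noNM", 99, "chr1", 1001, 60, "50M", "=", 1201, 250,
                 strrep("A", 50), "*"), collapse = "\t")
  rec2 <- paste(c("noNM", 147, "chr1", 1201, 60, "50M", "=", 1001, -250,
                  strrep("A", 50), "*"), collapse = "\t")
  expect_error(filter_alignments(write_sam(c(rec, rec2))), "NM")
})

test_that("locus assignment is sense-only, >= 1 bp overlap, largest wins", {
  cat <- toy_catalog(uid = c("L1", "L2"), start = c(1000L, 8000L),
                     end = c(7000L, 14000L), strand = c("+", "+"))
  pairs <- rbind(
    make_pairs(2000, 2300, "+", id_prefix = "sense_in"),
    make_pairs(2000, 2300, "-", id_prefix = "antisense"),
    make_pairs(900, 1001, "+", id_prefix = "one_bp"),     # 1 bp in L1
    make_pairs(6900, 7200, "+", id_prefix = "spill"),     # mate2 outside
    make_pairs(6800, 8300, "+", id_prefix = "bridge"),    # L1:200, L2:300
    make_pairs(20000, 20300, "+", id_prefix = "outside"))
  a <- assign_to_loci(pairs, cat)
  uid_of <- function(p) a$locus_uid[grepl(p, a$read_id)]
  expect_equal(uid_of("sense_in"), "L1")
  expect_true(is.na(uid_of("antisense")))
  expect_equal(uid_of("one_bp"), "L1")
  expect_equal(uid_of("spill"), "L1")
  expect_equal(uid_of("bridge"), "L2")      # larger overlap wins
  expect_true(is.na(uid_of("outside")))

  counts <- locus_read_counts(a, cat)
  expect_equal(counts$raw_reads[counts$uid == "L1"], 3L)
  expect_equal(counts$raw_reads[counts$uid == "L2"], 1L)
})
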