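# Hand-built coverage scenarios exercising each curation rule in isolation.
# Catalog: one plus-strand locus [5000, 11000) on chr1.

cur_locus <- function() {
  toy_catalog(uid = "LOC", start = 5000L, end = 11000L, strand = "+")
}

## n fragments starting in the promoter window plus body coverage; all sense
authentic_pairs <- function(n_promoter = 5, n_body = 20) {
  rbind(
    make_pairs(seq(5000, 5400, length.out = n_promoter),
               seq(5300, 5700, length.out = n_promoter), "+",
               id_prefix = "prom"),
    make_pairs(seq(5600, 10600, length.out = n_body),
               seq(5900, 10900, length.out = n_body), "+",
               id_prefix = "body"))
}

flat_mappability <- function(locus, reads = 400L) {
  list(profiles = data.frame(
    uid = locus$uid, dna_unique_reads = reads,
    fraction_bases_mappable = 1.0, fully_mappable = TRUE,
    correction_factor = 400 / reads, stringsAsFactors = FALSE),
    coverage = setNames(list(rep(3L, locus$end - locus$start)), locus$uid))
}

test_that("an authentic-looking locus passes all four rules", {
  cat <- cur_locus()
  pairs <- assign_to_loci(authentic_pairs(), cat)
  ev <- curate_locus(cat, pairs, mappability = flat_mappability(cat))
  expect_equal(ev$verdict, "authentic")
  expect_equal(ev$reasons, "")
  expect_equal(ev$assigned_reads, 25L)
  expect_equal(ev$upstream_sense_coverage_ratio, 0)
  expect_true(ev$five_prime_coverage)
  expect_equal(ev$incoming_splice_junctions, 0L)
})

test_that("R1 rejects loci with upstream same-strand read-through", {
  cat <- cur_locus()
  ## read-through: coverage continues across the 1 kb upstream flank
  rt <- make_pairs(seq(4000, 10600, by = 300),
                   seq(4300, 10900, by = 300), "+", id_prefix = "rt")
  pairs <- assign_to_loci(rt, cat)
  ev <- curate_locus(cat, pairs, mappability = flat_mappability(cat))
  expect_equal(ev$verdict, "background")
  expect_match(ev$reasons, "R1_upstream_readthrough")
  expect_gt(ev$upstream_sense_coverage_ratio, 0.1)

  ## antisense upstream coverage does not trip R1
  anti <- rbind(authentic_pairs(),
                make_pairs(seq(4000, 4600, by = 100),
                           seq(4300, 4900, by = 100), "-", id_prefix = "as"))
  ev2 <- curate_locus(cat, assign_to_loci(anti, cat),
                      mappability = flat_mappability(cat))
  expect_equal(ev2$verdict, "authentic")
})

test_that("R1 threshold is sharp and monotone in upstream_max", {
  cat <- cur_locus()
  base <- authentic_pairs(n_promoter = 5, n_body = 25)
  up <- make_pairs(seq(4020, 4620, by = 100),
                   seq(4320, 4920, by = 100), "+", id_prefix = "up")
  pairs <- assign_to_loci(rbind(base, up), cat)
  mp <- flat_mappability(cat)
  ev <- curate_locus(cat, pairs, mappability = mp)
  r <- ev$upstream_sense_coverage_ratio
  expect_gt(r, 0)
  ## just above the observed ratio -> pass; just below -> fail
  above <- curate_locus(cat, pairs, mappability = mp,
                        params = curation_params(upstream_max = r + 1e-9))
  below <- curate_locus(cat, pairs, mappability = mp,
                        params = curation_params(upstream_max = r - 1e-9))
  expect_equal(above$verdict, "authentic")
  expect_equal(below$verdict, "background")
})

test_that("R2 rejects loci lacking promoter-window fragment starts", {
  cat <- cur_locus()
  body_only <- make_pairs(seq(5600, 10600, length.out = 20),
                          seq(5900, 10900, length.out = 20), "+")
  ev <- curate_locus(cat, assign_to_loci(body_only, cat),
                     mappability = flat_mappability(cat))
  expect_equal(ev$verdict, "background")
  expect_match(ev$reasons, "R2_no_promoter_initiation")
  expect_false(ev$five_prime_coverage)

  ## window boundary: a start at 5499 counts, at 5500 it does not
  edge_in <- rbind(body_only, make_pairs(5499, 5799, "+", id_prefix = "e"))
  expect_equal(curate_locus(cat, assign_to_loci(edge_in, cat),
                            mappability = flat_mappability(cat))$verdict,
               "authentic")
  edge_out <- rbind(body_only, make_pairs(5500, 5800, "+", id_prefix = "e"))
  expect_match(curate_locus(cat, assign_to_loci(edge_out, cat),
                            mappability = flat_mappability(cat))$reasons,
               "R2")
})

test_that("R2 uses the fragment 5' end on minus-strand loci", {
  cat <- toy_catalog(uid = "LOC", start = 5000L, end = 11000L, strand = "-")
  ## 5' of a minus locus is at end 11000; promoter window (10500, 11000]
  pairs <- rbind(
    make_pairs(seq(10400, 10700, length.out = 5),
               seq(10700, 11000, length.out = 5), "-", id_prefix = "prom"),
    make_pairs(seq(5100, 10100, length.out = 20),
               seq(5400, 10400, length.out = 20), "-", id_prefix = "body"))
  ev <- curate_locus(cat, assign_to_loci(pairs, cat),
                     mappability = flat_mappability(cat))
  expect_equal(ev$verdict, "authentic")
  ## fragments whose 3' (not 5') end sits in the window do not count
  pairs_wrong <- rbind(
    make_pairs(seq(10600, 10900, length.out = 5),
               seq(10900, 11200, length.out = 5), "-", id_prefix = "past"),
    make_pairs(seq(5100, 9800, length.out = 20),
               seq(5400, 10100, length.out = 20), "-", id_prefix = "body"))
  ev2 <- curate_locus(cat, assign_to_loci(pairs_wrong, cat),
                      mappability = flat_mappability(cat))
  ## frag_end of "past" pairs is 10900..11200; ends > 11000 are outside
  expect_true(ev2$five_prime_coverage)  # 10900, 10975 are inside the window
})

test_that("R3 rejects loci with an incoming splice junction", {
  cat <- cur_locus()
  pairs <- assign_to_loci(authentic_pairs(), cat)
  sj_in <- data.frame(chrom = "chr1", intron_start = 3000L, intron_end = 6000L,
                      strand = "+", motif = 1L, annotated = 0L,
                      unique_reads = 8L, multi_reads = 0L, max_overhang = 40L,
                      stringsAsFactors = FALSE)
  ev <- curate_locus(cat, pairs, mappability = flat_mappability(cat),
                     junctions = sj_in)
  expect_equal(ev$verdict, "background")
  expect_match(ev$reasons, "R3_incoming_splice")
  expect_equal(ev$incoming_splice_junctions, 1L)

  ## a junction wholly inside the locus does not reject
  sj_internal <- sj_in
  sj_internal$intron_start <- 6000L; sj_internal$intron_end <- 8000L
  ev2 <- curate_locus(cat, pairs, mappability = flat_mappability(cat),
                      junctions = sj_internal)
  expect_equal(ev2$verdict, "authentic")
})

test_that("R4 rejects coverage discordant with mappability", {
  cat <- cur_locus()
  L <- cat$end - cat$start
  ## RNA coverage concentrated where DNA mappability is lowest
  pairs <- assign_to_loci(rbind(
    make_pairs(seq(5000, 5400, length.out = 4),
               seq(5300, 5700, length.out = 4), "+", id_prefix = "prom"),
    make_pairs(rep(seq(9000, 10000, length.out = 10), 3),
               rep(seq(9300, 10300, length.out = 10), 3), "+",
               id_prefix = "pile")), cat)
  ## DNA coverage high at the 5' half, low at the 3' half -> negative cor
  dna_cov <- c(rep(10L, L / 2), rep(1L, L / 2))
  mp <- flat_mappability(cat)
  mp$coverage[[cat$uid]] <- dna_cov
  mp$profiles$fully_mappable <- FALSE
  mp$profiles$fraction_bases_mappable <- 0.9
  ev <- curate_locus(cat, pairs, mappability = mp)
  expect_equal(ev$verdict, "background")
  expect_match(ev$reasons, "R4_mappability_discordant")
  expect_lt(ev$mappability_concordance, 0)

  ## the same discordance on a FULLY mappable locus is tolerated
  mp$profiles$fully_mappable <- TRUE
  mp$profiles$fraction_bases_mappable <- 1.0
  ev2 <- curate_locus(cat, pairs, mappability = mp)
  expect_equal(ev2$verdict, "authentic")

  ## no mappability profile at all: rule skipped with a warning, recorded
  expect_warning(ev3 <- curate_locus(cat, pairs, mappability = NULL),
                 "concordance rule skipped")
  expect_match(ev3$reasons, "R4_skipped_no_mappability")
  expect_equal(ev3$verdict, "authentic")   # skip is not a rejection
})

test_that("candidate gate is strict: 10 reads error, 11 curate", {
  cat <- cur_locus()
  ten <- assign_to_loci(make_pairs(seq(5000, 5900, by = 100),
                                   seq(5300, 6200, by = 100), "+"), cat)
  expect_equal(sum(!is.na(ten$locus_uid)), 10)
  expect_error(curate_locus(cat, ten, mappability = flat_mappability(cat)),
               "more than 10")
  ## curate_sample silently skips the sub-threshold locus
  expect_equal(nrow(curate_sample(ten, cat,
                                  mappability = flat_mappability(cat))), 0)
  eleven <- assign_to_loci(make_pairs(seq(5000, 6000, by = 100),
                                      seq(5300, 6300, by = 100), "+"), cat)
  ev <- curate_sample(eleven, cat, mappability = flat_mappability(cat))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$assigned_reads, 11L)
})

test_that("curation is deterministic and summary fractions are exact", {
  cat <- cur_locus()
  pairs <- assign_to_loci(authentic_pairs(), cat)
  mp <- flat_mappability(cat)
  e1 <- curate_locus(cat, pairs, mappability = mp)
  e2 <- curate_locus(cat, pairs, mappability = mp)
  expect_identical(e1, e2)

  bg <- e1[rep(1, 17), ]
  bg$uid <- paste0("BG", 1:17)
  bg$verdict <- "background"
  bg$reasons <- "R1_upstream_readthrough"
  s <- curation_summary(rbind(e1, bg))
  expect_equal(s$n_candidates, 18)
  expect_equal(s$n_authentic, 1)
  expect_equal(s$fraction_authentic, 1 / 18)
  expect_equal(unname(s$reason_counts["R1_upstream_readthrough"]), 17L)

  ## zero candidates (all loci at or below the gate) -> NA fraction
  few <- assign_to_loci(make_pairs(5000, 5300, "+"), cat)
  s0 <- curation_summary(curate_sample(few, cat, mappability = mp))
  expect_equal(s0$n_candidates, 0)
  expect_true(is.na(s0$fraction_authentic))
})
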