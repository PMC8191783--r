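## Full-length L1 catalogs and gene annotations.
## All coordinates are BED convention (0-based, half-open) internally;
## 1-based inputs (SAM, STAR junction tables) are converted on ingest.

#' Load a full-length L1 catalog from a BED-like table
#'
#' Reads a BED6+ table of full-length L1 annotations (L1Base-2 style). The
#' first six columns are chrom, start, end, uid, subfamily (or a numeric
#' score, stored as-is), strand; optional columns 7 and 8 are the number of
#' 5' promoter monomers and the intactness flag (`intact`/`non-intact`).
#'
#' @param path Path to a tab-separated BED6+ file, no header. Lines starting
#'   with `#` or `track` are skipped.
#' @return A `data.frame` with columns `uid`, `chrom`, `start`, `end`,
#'   `strand`, `subfamily`, `monomer_count`, `intactness`. Coordinates are
#'   0-based half-open as in the input BED.
#' @details Malformed rows are a hard error naming the offending row:
#'   `start >= end`, a strand other than `+`/`-`, or a duplicated uid all
#'   abort the load, because strand and uid are load-bearing for every
#'   downstream step.
#' @seealso [write_l1_catalog()], [intersect_with_monomer_hits()]
#' @export
load_l1_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_l1_catalog())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- vapply(fields, length, integer(1))
  if (any(ncols < 6)) {
    stop("row ", which(ncols < 6)[1],
         ": expected >= 6 tab-separated columns (chrom, start, end, uid, ",
         "subfamily/score, strand); strand is required")
  }
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, character(1))
  cat <- data.frame(
    uid = get(4),
    chrom = get(1),
    start = suppressWarnings(as.integer(get(2))),
    end = suppressWarnings(as.integer(get(3))),
    strand = get(6),
    subfamily = get(5),
    monomer_count = suppressWarnings(as.integer(get(7))),
    intactness = get(8),
    stringsAsFactors = FALSE
  )
  cat$intactness[is.na(cat$intactness)] <- "non-intact"
  validate_l1_catalog(cat)
  cat
}

empty_l1_catalog <- function() {
  data.frame(uid = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             subfamily = character(0), monomer_count = integer(0),
             intactness = character(0), stringsAsFactors = FALSE)
}

validate_l1_catalog <- function(cat) {
  bad <- which(is.na(cat$start) | is.na(cat$end))
  if (length(bad)) stop("row ", bad[1], ": non-numeric coordinates")
  bad <- which(cat$start >= cat$end)
  if (length(bad)) stop("row ", bad[1], " (uid ", cat$uid[bad[1]],
                        "): start >= end")
  bad <- which(!cat$strand %in% c("+", "-"))
  if (length(bad)) stop("row ", bad[1], ": strand must be '+' or '-' ",
                        "(strand-specific assignment depends on it)")
  dup <- cat$uid[duplicated(cat$uid)]
  if (length(dup)) stop("duplicate uid in catalog: ", dup[1])
  bad <- which(!is.na(cat$monomer_count) & cat$monomer_count < 0)
  if (length(bad)) stop("row ", bad[1], ": negative monomer_count")
  invisible(cat)
}

#' Write an L1 catalog back to BED6+ format
#'
#' Inverse of [load_l1_catalog()]; a written catalog reloads with identical
#' coordinates, strands and uids.
#'
#' @param catalog Catalog `data.frame` as returned by [load_l1_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_l1_catalog <- function(catalog, path) {
  out <- data.frame(catalog$chrom, catalog$start, catalog$end, catalog$uid,
                    catalog$subfamily, catalog$strand,
                    catalog$monomer_count, catalog$intactness)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

catalog_granges <- function(catalog) {
  GenomicRanges::GRanges(
    seqnames = catalog$chrom,
    ranges = IRanges::IRanges(start = catalog$start + 1L, end = catalog$end),
    strand = catalog$strand,
    uid = catalog$uid
  )
}

#' Restrict a catalog to loci overlapping promoter-monomer search hits
#'
#' Used to build a rat-style annotation: the full-length element list is
#' intersected with coordinates of a sequence-similarity search for the
#' active-subfamily promoter monomer, keeping loci whose promoter carries at
#' least one same-strand monomer hit (>= 1 bp overlap).
#'
#' @param catalog Catalog `data.frame` ([load_l1_catalog()]).
#' @param monomer_hits A `data.frame` with columns `chrom`, `start`, `end`,
#'   `strand` (0-based half-open), e.g. loaded from a BED6 of search hits.
#' @return The subset of `catalog` with a same-strand overlapping hit, in
#'   the original catalog order.
#' @export
intersect_with_monomer_hits <- function(catalog, monomer_hits) {
  validate_l1_catalog(catalog)
  if (nrow(catalog) == 0 || NROW(monomer_hits) == 0)
    return(catalog[integer(0), , drop = FALSE])
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(monomer_hits)))
  hits_gr <- GenomicRanges::GRanges(
    seqnames = monomer_hits$chrom,
    ranges = IRanges::IRanges(start = monomer_hits$start + 1L,
                              end = monomer_hits$end),
    strand = monomer_hits$strand
  )
  ov <- GenomicRanges::findOverlaps(catalog_granges(catalog), hits_gr,
                                    ignore.strand = FALSE)
  keep <- sort(unique(S4Vectors::queryHits(ov)))
  catalog[keep, , drop = FALSE]
}

#' Build a gene table from a GTF file or from exon coordinates
#'
#' @param path Path to a GTF file; `exon` features grouped by `gene_id`.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open gene span), `strand`, and a list-column `exons` of
#'   two-column matrices (0-based half-open exon intervals, sorted).
#' @export
load_genes_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) return(empty_gene_table())
  ids <- as.character(gr$gene_id)
  build_gene_table(data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  ))
}

empty_gene_table <- function() {
  g <- data.frame(gene_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0), stringsAsFactors = FALSE)
  g$exons <- list()
  g
}

#' Assemble a validated gene table from per-exon rows
#'
#' @param exon_df `data.frame` with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand`; one row per exon, 0-based half-open.
#' @return Gene table as described in [load_genes_gtf()].
#' @export
build_gene_table <- function(exon_df) {
  if (NROW(exon_df) == 0) return(empty_gene_table())
  sp <- split(exon_df, exon_df$gene_id)
  rows <- lapply(sp, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (any(d$start >= d$end)) stop("gene ", d$gene_id[1], ": exon start >= end")
    if (length(unique(d$chrom)) != 1 || length(unique(d$strand)) != 1)
      stop("gene ", d$gene_id[1], ": exons on multiple chromosomes/strands")
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop("gene ", d$gene_id[1], ": overlapping exons")
    list(gene_id = d$gene_id[1], chrom = d$chrom[1],
         start = min(d$start), end = max(d$end), strand = d$strand[1],
         exons = cbind(start = d$start, end = d$end))
  })
  g <- data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, function(r) as.integer(r$start), integer(1)),
    end = vapply(rows, function(r) as.integer(r$end), integer(1)),
    strand = vapply(rows, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE
  )
  g$exons <- lapply(rows, `[[`, "exons")
  rownames(g) <- NULL
  g
}

#' Classify the genomic context of an L1 locus relative to genes
#'
#' Determines whether a locus midpoint falls in a gene and, if so, whether it
#' lies in an exon or an intron and whether the locus is oriented with or
#' against the host gene. When the midpoint falls in several overlapping
#' genes, the gene with the longest overlap with the locus wins; ties break
#' lexicographically by `gene_id`, so the result does not depend on gene
#' table order.
#'
#' @param locus One-row catalog `data.frame` (or a list with `chrom`,
#'   `start`, `end`, `strand`).
#' @param genes Gene table ([build_gene_table()]).
#' @return One of `"intergenic"`, `"intronic_same"`, `"intronic_opposite"`,
#'   `"exonic_same"`, `"exonic_opposite"`.
#' @export
classify_gene_context <- function(locus, genes) {
  mid <- floor((locus$start + locus$end) / 2)
  if (NROW(genes) == 0) return("intergenic")
  cand <- which(genes$chrom == locus$chrom &
                  genes$start <= mid & mid < genes$end)
  if (length(cand) == 0) return("intergenic")
  if (length(cand) > 1) {
    ov <- pmin(genes$end[cand], locus$end) - pmax(genes$start[cand], locus$start)
    ord <- order(-ov, genes$gene_id[cand])
    cand <- cand[ord[1]]
  }
  g <- genes[cand, , drop = FALSE]
  ex <- g$exons[[1]]
  in_exon <- any(ex[, "start"] <= mid & mid < ex[, "end"])
  same <- identical(as.character(g$strand), as.character(locus$strand))
  if (in_exon) {
    if (same) "exonic_same" else "exonic_opposite"
  } else {
    if (same) "intronic_same" else "intronic_opposite"
  }
}
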