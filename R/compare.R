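## Atlas layer: set overlap of expressed-locus identities across samples,
## organs, sexes and ages, plus the simple statistics used alongside them.
## Percent overlap is 100 * |intersection of all sets| / |union of all
## sets|, displayed rounded half-up to an integer.

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Overlap of 2-4 sets of expressed locus identifiers
#'
#' @param sets List of 2-4 character vectors of uids.
#' @param labels Optional group labels (defaults to list names or `set1..`).
#' @return List of class `l1_overlap`: `labels`, `sets`,
#'   `intersection_all`, `union_all`, `percent_overlap` (unrounded;
#'   0 when the union is empty), `percent_display` (rounded half-up to
#'   integer), and `regions`, a data.frame of exclusive Venn region counts
#'   keyed by membership pattern (e.g. `"110"` = in sets 1 and 2 only).
#' @export
overlap <- function(sets, labels = NULL) {
  if (length(sets) < 2 || length(sets) > 4)
    stop("overlap requires 2-4 sets")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(labels)) {
    labels <- names(sets)
    if (is.null(labels)) labels <- paste0("set", seq_along(sets))
  }
  inter <- Reduce(intersect, sets)
  uni <- Reduce(union, sets)
  pct <- if (length(uni) == 0) 0 else 100 * length(inter) / length(uni)
  k <- length(sets)
  membership <- vapply(uni, function(u)
    paste0(as.integer(vapply(sets, function(s) u %in% s, logical(1))),
           collapse = ""), character(1))
  patterns <- apply(expand.grid(rep(list(c(1L, 0L)), k))[, k:1, drop = FALSE],
                    1, paste0, collapse = "")
  patterns <- patterns[patterns != paste0(rep("0", k), collapse = "")]
  regions <- data.frame(
    pattern = patterns,
    count = vapply(patterns, function(p) sum(membership == p), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(labels = labels, sets = sets,
                 intersection_all = inter, union_all = uni,
                 percent_overlap = pct,
                 percent_display = round_half_up(pct),
                 regions = regions),
            class = "l1_overlap")
}

#' @export
print.l1_overlap <- function(x, ...) {
  cat("Overlap of", length(x$sets), "sets (",
      paste(x$labels, collapse = ", "), ")\n")
  cat("  shared by all:", length(x$intersection_all),
      " union:", length(x$union_all),
      " percent overlap:", x$percent_display, "%\n")
  invisible(x)
}

#' Chi-square comparison of two shared-over-union proportions
#'
#' Tests whether the proportion of shared loci differs between two
#' comparisons, using an uncorrected chi-square on the 2x2 table
#' `[[shared1, union1 - shared1], [shared2, union2 - shared2]]` (df = 1).
#'
#' @param shared1,union1 Shared and union counts of the first comparison.
#' @param shared2,union2 Same for the second.
#' @return List `statistic` (X^2), `p_value`, `df` (= 1).
#' @export
shared_chi_square <- function(shared1, union1, shared2, union2) {
  stopifnot(shared1 <= union1, shared2 <= union2,
            shared1 >= 0, shared2 >= 0)
  tab <- rbind(c(shared1, union1 - shared1),
               c(shared2, union2 - shared2))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("a margin of the 2x2 table is zero; use an exact test instead")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, df = 1L)
}

#' Two-tailed two-sample Student's t-test (pooled variance)
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return List `t`, `p_value`, `df`. When both groups are constant with
#'   equal means the convention `t = 0, p = 1` is returned.
#' @export
group_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p_value = 1, df = length(a) + length(b) - 2L))
    stop("both groups constant with different means: t is undefined")
  }
  tt <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Pearson correlation between L1 and host-gene expression
#'
#' @param l1_fpkm,gene_fpkm Paired expression values (>= 3 pairs) for
#'   expressed L1 loci residing in genes.
#' @return List `r`, `p_value` (t-approximation), `df` (n - 2), `n`, and
#'   `n_l1_in_unexpressed_genes` (expressed loci whose host gene has zero
#'   expression). With zero variance in either vector `r` is `NA` and
#'   flagged via `degenerate = TRUE`.
#' @export
l1_gene_correlation <- function(l1_fpkm, gene_fpkm) {
  stopifnot(length(l1_fpkm) == length(gene_fpkm))
  if (length(l1_fpkm) < 3) stop("need at least 3 pairs")
  n_unexpr <- sum(l1_fpkm > 0 & gene_fpkm == 0)
  if (sd(l1_fpkm) == 0 || sd(gene_fpkm) == 0)
    return(list(r = NA_real_, p_value = NA_real_, df = length(l1_fpkm) - 2L,
                n = length(l1_fpkm), n_l1_in_unexpressed_genes = n_unexpr,
                degenerate = TRUE))
  ct <- stats::cor.test(l1_fpkm, gene_fpkm, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       df = unname(ct$parameter), n = length(l1_fpkm),
       n_l1_in_unexpressed_genes = n_unexpr, degenerate = FALSE)
}

#' Atlas summaries: counts, means and shared-locus structure
#'
#' Computes, from a long-format atlas of expressed loci (one row per sample
#' and expressed locus), the per-sample locus counts, group mean counts,
#' within-group overlap (shared and union over the group's samples with the
#' percent-overlap convention), and the between-group shared-locus matrix
#' on group union sets.
#'
#' @param atlas data.frame with columns `sample_id`, `uid`, and the
#'   grouping column named by `group_by` (e.g. `organ`, `sex`,
#'   `age_group`).
#' @param group_by Name of the grouping column (default `"organ"`).
#' @return List: `per_sample` (data.frame `sample_id`, group, `n_loci`),
#'   `group_means` (group, `mean_loci`, `n_samples`), `within_group`
#'   (group, `shared`, `union`, `percent_overlap`, `percent_display`; only
#'   groups with >= 2 samples), `group_sets` (named list of union uid sets
#'   per group), `shared_matrix` (pairwise |intersection| of group union
#'   sets).
#' @export
atlas_summaries <- function(atlas, group_by = "organ") {
  stopifnot(all(c("sample_id", "uid", group_by) %in% names(atlas)))
  grp <- as.character(atlas[[group_by]])
  per_sample_sets <- split(atlas$uid, atlas$sample_id)
  sample_grp <- vapply(split(grp, atlas$sample_id), `[`, character(1), 1)
  per_sample <- data.frame(
    sample_id = names(per_sample_sets),
    group = unname(sample_grp),
    n_loci = vapply(per_sample_sets, function(s) length(unique(s)), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  names(per_sample)[2] <- group_by

  gm <- split(per_sample$n_loci, per_sample[[group_by]])
  group_means <- data.frame(
    group = names(gm),
    mean_loci = vapply(gm, mean, numeric(1)),
    n_samples = vapply(gm, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  names(group_means)[1] <- group_by

  groups <- unique(per_sample[[group_by]])
  within <- lapply(groups, function(g) {
    sids <- per_sample$sample_id[per_sample[[group_by]] == g]
    if (length(sids) < 2) return(NULL)
    sets <- lapply(per_sample_sets[sids], unique)
    inter <- Reduce(intersect, sets)
    uni <- Reduce(union, sets)
    pct <- if (length(uni) == 0) 0 else 100 * length(inter) / length(uni)
    data.frame(group = g, shared = length(inter), union = length(uni),
               percent_overlap = pct, percent_display = round_half_up(pct),
               stringsAsFactors = FALSE)
  })
  within <- do.call(rbind, within[!vapply(within, is.null, logical(1))])
  if (!is.null(within)) names(within)[1] <- group_by

  group_sets <- lapply(groups, function(g)
    unique(atlas$uid[grp == g]))
  names(group_sets) <- groups
  shared_matrix <- outer(groups, groups, Vectorize(function(a, b)
    length(intersect(group_sets[[a]], group_sets[[b]]))))
  dimnames(shared_matrix) <- list(groups, groups)

  list(per_sample = per_sample, group_means = group_means,
       within_group = within, group_sets = group_sets,
       shared_matrix = shared_matrix)
}
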