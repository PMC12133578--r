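# Differential abundance: per-sample cluster proportions with rank-sum
# tests, and KNN-neighborhood enrichment between disease conditions.

#' Per-sample cluster proportions within a parent compartment
#'
#' @param annotation a `celiac_annotation` with clusters assigned.
#' @param clusters optional character vector restricting the parent
#'   compartment (e.g. the CD4 clusters); default: all clusters.
#' @return data.frame (`sample_id`, `condition`, `cluster`, `n_cells`,
#'   `fraction`), completed with zero rows so every sample covers every
#'   cluster; fractions per sample sum to 1. Samples with no parent cells
#'   are excluded with a warning.
#' @export
cluster_proportions <- function(annotation, clusters = NULL) {
  ann <- as.data.frame(annotation)
  if (all(is.na(ann$cluster))) abort_format("clusters not assigned")
  if (!is.null(clusters)) ann <- ann[ann$cluster %in% clusters, , drop = FALSE]
  all_samples <- unique(as.data.frame(annotation)[, c("sample_id", "condition")])
  empty <- setdiff(all_samples$sample_id, unique(ann$sample_id))
  if (length(empty) > 0L)
    warning(sprintf("excluding %d sample(s) with zero parent cells: %s",
                    length(empty), paste(empty, collapse = ", ")), call. = FALSE)
  cl_levels <- sort(unique(ann$cluster))
  tab <- as.data.frame(table(sample_id = ann$sample_id, cluster = ann$cluster),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n_cells"
  tot <- tapply(tab$n_cells, tab$sample_id, sum)
  tab$fraction <- tab$n_cells / as.numeric(tot[tab$sample_id])
  tab$condition <- all_samples$condition[match(tab$sample_id, all_samples$sample_id)]
  tab <- tab[order(tab$sample_id, match(tab$cluster, cl_levels)),
             c("sample_id", "condition", "cluster", "n_cells", "fraction")]
  rownames(tab) <- NULL
  tab
}

#' Mann-Whitney tests on per-sample cluster fractions
#'
#' Exact two-sided rank-sum test per cluster comparing per-sample fractions
#' between two condition groups; with ties the normal approximation with
#' continuity correction is used and flagged. No cross-cluster correction
#' by default (each cluster is its own panel), optional BH.
#'
#' @param proportions output of [cluster_proportions()].
#' @param groupA,groupB condition labels to compare (default ACD vs HC).
#' @param adjust apply BH across clusters.
#' @return data.frame per cluster: group medians, `p`, `approx` flag, and
#'   `q` when `adjust = TRUE`.
#' @export
test_proportions <- function(proportions, groupA = "ACD", groupB = "HC",
                             adjust = FALSE) {
  pa <- proportions[proportions$condition == groupA, , drop = FALSE]
  pb <- proportions[proportions$condition == groupB, , drop = FALSE]
  if (length(unique(pa$sample_id)) < 2L || length(unique(pb$sample_id)) < 2L)
    abort_format("both groups need >= 2 samples")
  out <- do.call(rbind, lapply(sort(unique(proportions$cluster)), function(cl) {
    xa <- pa$fraction[pa$cluster == cl]
    xb <- pb$fraction[pb$cluster == cl]
    ties <- anyDuplicated(c(xa, xb)) > 0L
    wt <- suppressWarnings(
      wilcox.test(xa, xb, alternative = "two.sided", exact = !ties,
                  correct = TRUE))
    data.frame(cluster = cl, medianA = stats::median(xa), medianB = stats::median(xb),
               p = wt$p.value, approx = ties, stringsAsFactors = FALSE)
  }))
  if (adjust) out$q <- bh(out$p)
  rownames(out) <- NULL
  out
}

#' KNN-neighborhood differential abundance between two conditions
#'
#' Neighborhoods are closed KNN neighborhoods of index units sampled
#' uniformly without replacement. For each neighborhood with condition
#' member counts `a` (first condition, total `A`) and `b` (second, total
#' `B`), the enrichment is
#' `lfc = log2((a+p)/(A-a+p)) - log2((b+p)/(B-b+p))` with pseudocount `p`,
#' and the p-value is the two-sided (doubling rule) hypergeometric tail of
#' `a` among a draw of size `a+b` from the `A + B` population. BH across
#' neighborhoods gives `q`.
#'
#' @param knn a `knn_graph` (symmetrized).
#' @param annotation paired annotation (unit order = graph order).
#' @param conditions length-2 character vector, enrichment of the first
#'   versus the second (default `c("ACD", "HC")`).
#' @param n_neighborhoods number of index units (default 10% of units,
#'   at least 1); must not exceed the number of units.
#' @param min_size drop neighborhoods with fewer in-condition members.
#' @param pseudocount `p` in the lfc.
#' @param seed RNG seed for index sampling.
#' @return data.frame of class `da_result`: `index_unit`, `size`, `a`,
#'   `b`, `lfc`, `p`, `q`; attribute `members` holds the per-neighborhood
#'   member id lists.
#' @export
neighborhood_enrichment <- function(knn, annotation, conditions = c("ACD", "HC"),
                                    n_neighborhoods = NULL, min_size = 10L,
                                    pseudocount = 0.5, seed = 1L) {
  ann <- as.data.frame(annotation)
  stopifnot(length(conditions) == 2L)
  if (!all(conditions %in% ann$condition))
    abort_format("both conditions must be present in the annotation")
  n <- length(knn$idx)
  if (!is.null(knn$unit_ids) &&
      !identical(knn$unit_ids, ann$unit_id))
    ann <- ann[match(knn$unit_ids, ann$unit_id), , drop = FALSE]
  cond <- ann$condition
  in1 <- cond == conditions[1L]; in2 <- cond == conditions[2L]
  A <- sum(in1); B <- sum(in2)
  if (is.null(n_neighborhoods)) n_neighborhoods <- max(1L, floor(0.1 * n))
  if (n_neighborhoods > n)
    abort_format("n_neighborhoods = %d exceeds the number of units (%d)",
                 n_neighborhoods, n)
  set.seed(seed)
  index <- sort(sample.int(n, n_neighborhoods))
  members <- lapply(index, function(i) sort(unique(c(i, knn$idx[[i]]))))
  a <- vapply(members, function(m) sum(in1[m]), integer(1L))
  b <- vapply(members, function(m) sum(in2[m]), integer(1L))
  keep <- (a + b) >= min_size
  index <- index[keep]; members <- members[keep]; a <- a[keep]; b <- b[keep]
  p <- pseudocount
  lfc <- log2((a + p) / (A - a + p)) - log2((b + p) / (B - b + p))
  draw <- a + b
  p_lo <- phyper(a, A, B, draw)
  p_hi <- phyper(a - 1L, A, B, draw, lower.tail = FALSE)
  pval <- pmin(1, 2 * pmin(p_lo, p_hi))
  out <- data.frame(index_unit = ann$unit_id[index], size = draw + 0L,
                    a = a, b = b, lfc = lfc, p = pval, q = bh(pval),
                    stringsAsFactors = FALSE)
  attr(out, "members") <- lapply(members, function(m) ann$unit_id[m])
  attr(out, "conditions") <- conditions
  attr(out, "totals") <- c(A = A, B = B)
  class(out) <- c("da_result", "data.frame")
  out
}
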