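# Receptor-ligand pair scoring between cell types (permutation null by
# label shuffling) and within spatial regions, plus susceptibility
# gene-set scoring per cell type.

#' Receptor-ligand scoring between cell types
#'
#' For each pair and ordered (sender, receiver) type combination:
#' score = mean log-normalized ligand expression in the sender times mean
#' receptor expression in the receiver. The null shuffles cell-type labels
#' `n_perm` times; `p = (1 + #null >= obs) / (1 + n_perm)`, BH within each
#' pair across combinations. Pairs with a partner gene absent from the
#' matrix are skipped and reported.
#'
#' @param counts genes x cells count matrix.
#' @param annotation paired annotation with clusters (cell types).
#' @param pairs an [rl_pairs()] table.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @param target_sum normalization total.
#' @return data.frame (`pair_name`, `sender`, `receiver`, `score`,
#'   `detection`, `p`, `q`); attribute `skipped` lists dropped pairs.
#' @export
score_celltype_pairs <- function(counts, annotation, pairs, n_perm = 999L,
                                 seed = 1L, target_sum = 1e4) {
  ann <- as.data.frame(annotation)
  types <- sort(unique(ann$cluster))
  if (length(types) < 2L) abort_format("need >= 2 cell types")
  have <- pairs$ligand %in% rownames(counts) & pairs$receptor %in% rownames(counts)
  skipped <- pairs$pair_name[!have]
  if (length(skipped) > 0L)
    warning(sprintf("skipping %d pair(s) with absent partner gene(s): %s",
                    length(skipped), paste(head(skipped, 3L), collapse = ", ")),
            call. = FALSE)
  pairs <- pairs[have, , drop = FALSE]
  if (nrow(pairs) == 0L) abort_format("no scorable pairs")
  genes <- unique(c(pairs$ligand, pairs$receptor))
  norm <- normalize_log(counts, target_sum)
  norm <- as.matrix(norm[genes, ann$unit_id, drop = FALSE])
  cl <- ann$cluster
  group_means <- function(labels) {
    vapply(types, function(t)
      rowMeans(norm[, labels == t, drop = FALSE]), numeric(nrow(norm)))
  }
  gm <- group_means(cl)
  det <- vapply(types, function(t) {
    sub <- counts[genes, ann$unit_id[cl == t], drop = FALSE]
    Matrix::rowSums(sub > 0) / ncol(sub)
  }, numeric(length(genes)))
  rownames(det) <- genes

  combos <- expand.grid(sender = types, receiver = types,
                        stringsAsFactors = FALSE)
  score_of <- function(m) {
    # pairs x combos matrix of scores for a given type-mean matrix
    lig <- m[pairs$ligand, combos$sender, drop = FALSE]
    rec <- m[pairs$receptor, combos$receiver, drop = FALSE]
    lig * rec
  }
  obs <- score_of(gm)
  set.seed(seed)
  exceed <- matrix(0L, nrow(obs), ncol(obs))
  for (b in seq_len(n_perm)) {
    perm <- group_means(sample(cl))
    exceed <- exceed + (score_of(perm) >= obs)
  }
  pval <- (1 + exceed) / (1 + n_perm)
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    data.frame(pair_name = pairs$pair_name[i], sender = combos$sender,
               receiver = combos$receiver, score = obs[i, ],
               detection = pmin(det[pairs$ligand[i], combos$sender],
                                det[pairs$receptor[i], combos$receiver]),
               p = pval[i, ], q = bh(pval[i, ]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Receptor-ligand scoring within spatial regions
#'
#' Per (pair, region): score = the minimum (default) or product of the two
#' partners' mean scaled expressions in the region; detection fraction =
#' share of the region's spots detecting both partners (count > 0).
#' Scores are additionally z-scaled across regions per pair (`scaled`
#' column) for bubble-plot parity.
#'
#' @param sp a `spatial_dataset` with regions assigned.
#' @param pairs an [rl_pairs()] table.
#' @param scheme `"min"` (default) or `"product"`.
#' @param target_sum normalization total.
#' @return data.frame (`pair_name`, `region`, `score`, `scaled`,
#'   `detection`); attribute `skipped` lists dropped pairs.
#' @export
score_region_pairs <- function(sp, pairs, scheme = c("min", "product"),
                               target_sum = 1e4) {
  scheme <- match.arg(scheme)
  if (is.null(sp$region)) abort_format("regions not assigned")
  have <- pairs$ligand %in% rownames(sp$counts) &
    pairs$receptor %in% rownames(sp$counts)
  skipped <- pairs$pair_name[!have]
  pairs <- pairs[have, , drop = FALSE]
  if (nrow(pairs) == 0L) abort_format("no scorable pairs")
  z <- scale_genes(normalize_log(sp$counts, target_sum))
  regions <- sort(unique(sp$region))
  zm <- vapply(regions, function(r)
    rowMeans(z[, sp$region == r, drop = FALSE]), numeric(nrow(z)))
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    lg <- zm[pairs$ligand[i], ]; rc <- zm[pairs$receptor[i], ]
    sc <- if (scheme == "min") pmin(lg, rc) else lg * rc
    det <- vapply(regions, function(r) {
      spots <- sp$region == r
      mean(sp$counts[pairs$ligand[i], spots] > 0 &
             sp$counts[pairs$receptor[i], spots] > 0)
    }, numeric(1L))
    scaled <- if (sd(sc) > 0) (sc - mean(sc)) / sd(sc) else rep(0, length(sc))
    data.frame(pair_name = pairs$pair_name[i], region = regions, score = sc,
               scaled = scaled, detection = det, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Gene-set enrichment per cell type (permutation null)
#'
#' Mean scaled expression of the set per cell type against expression-
#' matched random sets — the cell-type twin of
#' [region_set_enrichment()], used e.g. for susceptibility (GWAS
#' candidate) gene sets.
#'
#' @param counts genes x cells count matrix.
#' @param annotation paired annotation with clusters.
#' @param set a [gene_set()].
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @param target_sum normalization total.
#' @return data.frame per type: `score`, `z`, `p`, `q`.
#' @export
celltype_set_score <- function(counts, annotation, set, n_perm = 999L,
                               seed = 1L, target_sum = 1e4) {
  ann <- as.data.frame(annotation)
  if (all(is.na(ann$cluster))) abort_format("clusters not assigned")
  z <- scale_genes(normalize_log(counts, target_sum))
  keep <- intersect(colnames(z), ann$unit_id)
  z2 <- z[, keep, drop = FALSE]
  attr(z2, "gene_means") <- attr(z, "gene_means")
  out <- set_score_perm(z2, ann$cluster[match(keep, ann$unit_id)], set,
                        n_perm = n_perm, seed = seed)
  names(out)[1L] <- "cell_type"
  out
}
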