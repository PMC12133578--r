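# Spot-level region analysis: lattice neighbor geometry, region
# clustering, region proportions, adjacency networks, signature
# deconvolution by non-negative least squares, colocalization networks,
# region markers and permutation gene-set enrichment.

#' Lattice neighbors of every spot
#'
#' Square lattices use the 4-neighborhood; hex lattices use the Visium
#' odd-row-shifted 6-neighborhood (odd array rows offset half a column).
#' Boundary spots simply have fewer neighbors.
#'
#' @param sp a `spatial_dataset`.
#' @return list of integer neighbor index vectors, one per spot.
#' @export
lattice_neighbors <- function(sp) {
  key <- paste(sp$array_row, sp$array_col)
  pos <- setNames(seq_along(key), key)
  offs_square <- cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  offs_hex_even <- cbind(c(0L, 0L, -1L, -1L, 1L, 1L), c(-1L, 1L, -1L, 0L, -1L, 0L))
  offs_hex_odd <- cbind(c(0L, 0L, -1L, -1L, 1L, 1L), c(-1L, 1L, 0L, 1L, 0L, 1L))
  lapply(seq_along(key), function(i) {
    offs <- if (sp$lattice == "square") offs_square
            else if (sp$array_row[i] %% 2L == 0L) offs_hex_even else offs_hex_odd
    cand <- paste(sp$array_row[i] + offs[, 1L], sp$array_col[i] + offs[, 2L])
    unname(pos[cand[cand %in% names(pos)]])
  })
}

#' Cluster spots into transcriptional regions
#'
#' Delegates to the shared preprocessing chain (normalize, HVG, PCA, KNN,
#' Leiden) and writes the labels back onto the dataset as regions.
#'
#' @param sp a `spatial_dataset`.
#' @param n_hvg,d,k,resolution,target_sum,seed preprocessing knobs.
#' @return `sp` with `$region` set (`"c1"`, `"c2"`, ...).
#' @export
cluster_spots <- function(sp, n_hvg = 100L, d = 10L, k = 15L, resolution = 1,
                          target_sum = 1e4, seed = 1L) {
  norm <- normalize_log(sp$counts, target_sum = target_sum)
  if (length(attr(norm, "excluded_units")) > 0L)
    abort_format("spot(s) with zero counts: %s",
                 paste(head(attr(norm, "excluded_units"), 5L), collapse = ", "))
  hvg <- select_hvg(norm, min(n_hvg, nrow(norm)))
  z <- scale_genes(norm[hvg, , drop = FALSE])
  emb <- pca_embed(z, d)
  knn <- build_knn(emb, k)
  labels <- cluster_graph(knn, resolution = resolution, seed = seed)
  sp$region <- unname(labels[sp$spots])
  sp
}

#' Per-sample region proportions
#'
#' @param sp a `spatial_dataset` with regions assigned.
#' @return data.frame (`sample_id`, `region`, `n_spots`, `fraction`);
#'   fractions sum to 1 per sample.
#' @export
region_proportions <- function(sp) {
  if (is.null(sp$region)) abort_format("regions not assigned")
  tab <- as.data.frame(table(sample_id = sp$sample_id, region = sp$region),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "n_spots"
  tot <- tapply(tab$n_spots, tab$sample_id, sum)
  tab$fraction <- tab$n_spots / as.numeric(tot[tab$sample_id])
  tab[order(tab$sample_id, tab$region), ]
}

#' Region adjacency network from neighbor-pair fractions
#'
#' `P[r, s]` is the fraction of ordered neighbor pairs `(i in r, j in s)`
#' among all ordered neighbor pairs whose first spot is in `r`; rows sum
#' to 1 (self-adjacency included in the matrix). The edge list drops the
#' self-pairs for plotting. A region whose spots have no neighbors at all
#' yields an `NA` row.
#'
#' @param sp a `spatial_dataset` with regions assigned.
#' @return list of class `region_adjacency`: `P` (row-stochastic matrix)
#'   and `edges` (data.frame `source`, `target`, `weight`, self-pairs
#'   excluded).
#' @export
region_adjacency <- function(sp) {
  if (is.null(sp$region)) abort_format("regions not assigned")
  nb <- lattice_neighbors(sp)
  regions <- sort(unique(sp$region))
  k <- length(regions)
  P <- matrix(0, k, k, dimnames = list(regions, regions))
  ri <- match(sp$region, regions)
  for (i in seq_along(nb)) for (j in nb[[i]])
    P[ri[i], ri[j]] <- P[ri[i], ri[j]] + 1
  deg <- rowSums(P)
  for (r in seq_len(k)) {
    if (deg[r] == 0) P[r, ] <- NA_real_ else P[r, ] <- P[r, ] / deg[r]
  }
  ed <- which(!is.na(P) & P > 0 & row(P) != col(P), arr.ind = TRUE)
  edges <- data.frame(source = regions[ed[, 1L]], target = regions[ed[, 2L]],
                      weight = P[ed], stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(P = P, edges = edges), class = "region_adjacency")
}

#' Build a cell-type signature matrix from annotated single cells
#'
#' `S[g, t]` = mean linear-normalized expression of gene `g` in cells of
#' type `t` (clusters of the annotation), optionally restricted to a gene
#' subset (HVGs and/or markers). Types with fewer than `min_cells` cells
#' are kept but flagged with a warning.
#'
#' @param counts genes x cells count matrix.
#' @param annotation paired annotation with clusters assigned.
#' @param genes optional gene subset.
#' @param target_sum normalization total.
#' @param min_cells warning threshold.
#' @return genes x types non-negative matrix.
#' @export
build_signatures <- function(counts, annotation, genes = NULL,
                             target_sum = 1e4, min_cells = 10L) {
  ann <- as.data.frame(annotation)
  norm <- normalize_log(counts, target_sum = target_sum, log = FALSE)
  keep <- intersect(colnames(norm), ann$unit_id)
  norm <- norm[, keep, drop = FALSE]
  cl <- ann$cluster[match(keep, ann$unit_id)]
  if (all(is.na(cl))) abort_format("annotation has no cluster labels")
  sizes <- table(cl)
  small <- names(sizes)[sizes < min_cells]
  if (length(small) > 0L)
    warning(sprintf("type(s) with < %d cells: %s", min_cells,
                    paste(small, collapse = ", ")), call. = FALSE)
  types <- sort(unique(cl))
  S <- vapply(types, function(t)
    Matrix::rowMeans(norm[, cl == t, drop = FALSE]), numeric(nrow(norm)))
  rownames(S) <- rownames(norm)
  if (!is.null(genes)) S <- S[intersect(genes, rownames(S)), , drop = FALSE]
  S
}

# Lawson-Hanson active-set non-negative least squares: minimize
# ||A x - b||^2 subject to x >= 0. Small dense problems only (deconvolution
# has a handful of cell types).
nnls_solve <- function(A, b, tol = 1e-10, max_iter = 200L) {
  p <- ncol(A)
  x <- numeric(p)
  passive <- rep(FALSE, p)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(p)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- as.numeric(solve(crossprod(Ap) + diag(1e-12, ncol(Ap)),
                                     crossprod(Ap, b)))
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Deconvolve spot profiles against a signature matrix
#'
#' Per spot, non-negative least squares of the linear-normalized spot
#' vector on the signature matrix (columns renormalized to the same
#' total), then renormalization of the weights to the simplex.
#'
#' @param sp a `spatial_dataset`.
#' @param S genes x types signature matrix (from [build_signatures()] or
#'   a simulator).
#' @param target_sum normalization total for spots and signature columns.
#' @return list of class `deconvolution_result`: `weights` (spots x types
#'   simplex matrix), `residual` (per-spot residual norm), `S` (the
#'   matrix used, restricted to shared genes), and `region_means` (region
#'   x types mean composition) when regions are assigned.
#' @export
deconvolve <- function(sp, S, target_sum = 1e4) {
  shared <- intersect(rownames(S), rownames(sp$counts))
  if (length(shared) == 0L) abort_format("no shared genes between signatures and spots")
  if (ncol(S) > length(shared))
    abort_format("more types (%d) than shared genes (%d)", ncol(S), length(shared))
  Suse <- S[shared, , drop = FALSE]
  Suse <- sweep(Suse, 2L, colSums(Suse), "/") * target_sum
  norm <- normalize_log(sp$counts, target_sum = target_sum, log = FALSE)
  norm <- as.matrix(norm[shared, , drop = FALSE])
  W <- matrix(0, ncol(norm), ncol(Suse),
              dimnames = list(colnames(norm), colnames(Suse)))
  resid <- numeric(ncol(norm))
  for (i in seq_len(ncol(norm))) {
    b <- norm[, i]
    w <- nnls_solve(Suse, b)
    resid[i] <- sqrt(sum((Suse %*% w - b)^2))
    W[i, ] <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
  }
  out <- list(weights = W, residual = setNames(resid, colnames(norm)), S = Suse)
  if (!is.null(sp$region)) {
    reg <- sp$region[match(rownames(W), sp$spots)]
    out$region_means <- do.call(rbind, lapply(sort(unique(reg)), function(r)
      colMeans(W[reg == r, , drop = FALSE])))
    rownames(out$region_means) <- sort(unique(reg))
  }
  class(out) <- "deconvolution_result"
  out
}

#' Cell-type colocalization network across spots
#'
#' Pairwise Spearman correlation of deconvolved type proportions across
#' spots; edges above the threshold (diagonal excluded). Constant
#' proportion vectors yield `NA` correlations.
#'
#' @param deconv a `deconvolution_result`.
#' @param threshold minimum correlation for an edge (default 0.3).
#' @return list of class `colocalization_network`: `cor` (symmetric type
#'   x type matrix, unit diagonal) and `edges` (data.frame `source`,
#'   `target`, `weight`).
#' @export
colocalization <- function(deconv, threshold = 0.3) {
  W <- deconv$weights
  if (nrow(W) < 10L) abort_format("need >= 10 spots")
  const <- apply(W, 2L, function(x) sd(x) == 0)
  C <- suppressWarnings(cor(W, method = "spearman"))
  C[const, ] <- NA_real_; C[, const] <- NA_real_
  diag(C) <- 1
  ut <- which(upper.tri(C) & !is.na(C) & C >= threshold, arr.ind = TRUE)
  edges <- data.frame(source = colnames(W)[ut[, 1L]],
                      target = colnames(W)[ut[, 2L]],
                      weight = C[ut], stringsAsFactors = FALSE)
  structure(list(cor = C, edges = edges), class = "colocalization_network")
}

#' Marker genes of a region (rank-sum region vs rest)
#'
#' Per gene, two-sided Wilcoxon rank-sum test of log-normalized expression
#' in the region versus all other spots, log2 fold change of linear means
#' (with pseudocount), BH across genes.
#'
#' @param sp a `spatial_dataset` with regions assigned.
#' @param region region label to profile.
#' @param min_spots minimum region size (error below; default 20).
#' @param target_sum normalization total.
#' @param pseudocount added to both means in the fold change.
#' @return data.frame per gene (`gene`, `lfc`, `p`, `q`), ordered by `q`
#'   then `p`.
#' @export
region_markers <- function(sp, region, min_spots = 20L, target_sum = 1e4,
                           pseudocount = 0.1) {
  if (is.null(sp$region)) abort_format("regions not assigned")
  inr <- sp$region == region
  if (sum(inr) < min_spots)
    abort_format("region %s has %d spots (< %d)", region, sum(inr), min_spots)
  lin <- as.matrix(normalize_log(sp$counts, target_sum, log = FALSE))
  lg <- log1p(lin)
  res <- do.call(rbind, lapply(rownames(lg), function(g) {
    x <- lg[g, inr]; y <- lg[g, !inr]
    p <- if (sd(c(x, y)) == 0) 1
         else suppressWarnings(wilcox.test(x, y)$p.value)
    lfc <- log2((mean(lin[g, inr]) + pseudocount) /
                  (mean(lin[g, !inr]) + pseudocount))
    data.frame(gene = g, lfc = lfc, p = p, stringsAsFactors = FALSE)
  }))
  res$q <- bh(res$p)
  res <- res[order(res$q, res$p, res$gene), ]
  rownames(res) <- NULL
  res
}

# Shared permutation machinery: mean scaled expression of a gene set per
# group of units, against n_perm expression-matched random sets.
set_score_perm <- function(scaled, groups, set, n_perm = 999L, seed = 1L,
                           n_bins = 10L) {
  genes <- intersect(set$genes, rownames(scaled))
  if (length(genes) == 0L)
    abort_format("no gene of set '%s' present", set$name)
  means <- attr(scaled, "gene_means") %||% rowMeans(scaled)
  bins <- expression_bins(means, n_bins)
  names(bins) <- rownames(scaled)
  glev <- sort(unique(groups))
  gm <- vapply(glev, function(g)
    rowMeans(scaled[, groups == g, drop = FALSE]), numeric(nrow(scaled)))
  obs <- colMeans(gm[genes, , drop = FALSE])
  set.seed(seed)
  by_bin <- split(rownames(scaled), bins)
  need <- table(bins[genes])
  null <- matrix(NA_real_, n_perm, length(glev), dimnames = list(NULL, glev))
  for (p in seq_len(n_perm)) {
    rnd <- unlist(lapply(names(need), function(b) {
      pool <- by_bin[[b]]
      pool[sample.int(length(pool), min(need[[b]], length(pool)))]
    }))
    null[p, ] <- colMeans(gm[rnd, , drop = FALSE])
  }
  z <- (obs - colMeans(null)) / apply(null, 2L, sd)
  pval <- (1 + colSums(sweep(null, 2L, obs, `>=`))) / (1 + n_perm)
  data.frame(group = glev, score = unname(obs), z = unname(z),
             p = unname(pval), q = bh(unname(pval)),
             stringsAsFactors = FALSE)
}

#' Gene-set enrichment per spatial region (permutation null)
#'
#' Observed score = mean scaled expression of the set genes over the
#' region's spots. The null re-draws `n_perm` random gene sets of equal
#' size from expression-matched bins; empirical
#' `p = (1 + #null >= obs) / (1 + n_perm)` per region, BH across regions.
#'
#' @param sp a `spatial_dataset` with regions assigned.
#' @param set a [gene_set()] (e.g. GWAS susceptibility candidates).
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @param target_sum normalization total.
#' @return data.frame per region: `score`, `z`, `p`, `q`.
#' @export
region_set_enrichment <- function(sp, set, n_perm = 999L, seed = 1L,
                                  target_sum = 1e4) {
  if (is.null(sp$region)) abort_format("regions not assigned")
  z <- scale_genes(normalize_log(sp$counts, target_sum))
  out <- set_score_perm(z, sp$region, set, n_perm = n_perm, seed = seed)
  names(out)[1L] <- "region"
  out
}
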