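# Normalization, feature selection, embedding, KNN graph, community
# detection and gene-signature scoring. Shared by cells and spots.

#' Library-size normalization with optional log transform
#'
#' Each unit (cell/spot) is scaled so its total equals `target_sum`, then
#' `log(1 + x)` is applied (unless `log = FALSE`, used e.g. by the
#' deconvolution which needs linear scale). Units with zero total counts
#' are excluded with a warning; their ids are attached as attribute
#' `excluded_units`.
#'
#' @param counts genes x units count matrix.
#' @param target_sum per-unit total after scaling (default 1e4).
#' @param log apply `log1p` after scaling.
#' @return sparse normalized matrix; attribute `excluded_units` lists any
#'   dropped unit ids.
#' @export
normalize_log <- function(counts, target_sum = 1e4, log = TRUE) {
  stopifnot(target_sum > 0)
  validate_counts(counts)
  tot <- Matrix::colSums(counts)
  zero <- tot == 0
  excluded <- colnames(counts)[zero]
  if (any(zero)) {
    warning(sprintf("excluding %d unit(s) with zero total counts", sum(zero)),
            call. = FALSE)
    counts <- counts[, !zero, drop = FALSE]
    tot <- tot[!zero]
  }
  norm <- counts %*% Matrix::Diagonal(x = target_sum / tot)
  colnames(norm) <- colnames(counts)
  if (log) norm@x <- log1p(norm@x)
  norm <- as(norm, "CsparseMatrix")
  attr(norm, "excluded_units") <- excluded
  norm
}

#' Z-score genes across units
#'
#' Per-gene mean 0 / sd 1; constant genes are set to 0; values are clipped
#' at +-10. The per-gene means of the input are kept as attribute
#' `gene_means` for expression-matched background sampling downstream.
#'
#' @param normalized genes x units normalized matrix.
#' @param clip absolute z-value cap (default 10).
#' @return dense genes x units matrix of clipped z-scores.
#' @export
scale_genes <- function(normalized, clip = 10) {
  x <- as.matrix(normalized)
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, sd)
  z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  attr(z, "gene_means") <- mu
  z
}

#' Select highly variable genes
#'
#' Genes ranked by variance of normalized (log) expression; ties broken
#' deterministically by gene id.
#'
#' @param normalized genes x units normalized matrix.
#' @param n_top number of genes to keep (`<= n_genes`).
#' @return character vector of selected gene ids, most variable first.
#' @export
select_hvg <- function(normalized, n_top) {
  stopifnot(n_top <= nrow(normalized), n_top >= 1L)
  x <- as.matrix(normalized)
  v <- apply(x, 1L, var)
  ord <- order(-v, rownames(normalized))
  rownames(normalized)[ord][seq_len(n_top)]
}

#' PCA embedding
#'
#' @param scaled genes x units z-scored matrix (from [scale_genes()]).
#' @param d number of components.
#' @return units x d matrix of scores with attribute `method = "pca"`.
#' @export
pca_embed <- function(scaled, d = 10L) {
  x <- t(as.matrix(scaled))           # units x genes
  d <- min(d, ncol(x), nrow(x) - 1L)
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = d)
  emb <- pc$x[, seq_len(d), drop = FALSE]
  rownames(emb) <- colnames(scaled)
  attr(emb, "method") <- "pca"
  emb
}

#' Build a K-nearest-neighbor graph on an embedding
#'
#' Euclidean KNN, no self-loops, ties by unit order; optionally symmetrized
#' by union (the default, required by the clustering and neighborhood
#' machinery).
#'
#' @param embedding units x d matrix.
#' @param k neighbors per unit; must be `< n_units`.
#' @param symmetrize union-symmetrize the adjacency.
#' @return object of class `knn_graph`: list with `idx` (per-unit integer
#'   neighbor vectors), `unit_ids`, `k`, `symmetrized`.
#' @export
build_knn <- function(embedding, k = 15L, symmetrize = TRUE) {
  n <- nrow(embedding)
  if (k >= n) abort_format("k = %d must be smaller than the number of units (%d)", k, n)
  d2 <- as.matrix(dist(embedding))
  diag(d2) <- Inf
  idx <- lapply(seq_len(n), function(i) {
    o <- order(d2[i, ], seq_len(n))[seq_len(k)]
    as.integer(o)
  })
  if (symmetrize) {
    rev_idx <- vector("list", n)
    for (i in seq_len(n)) for (j in idx[[i]])
      rev_idx[[j]] <- c(rev_idx[[j]], i)
    idx <- lapply(seq_len(n), function(i) sort(unique(c(idx[[i]], rev_idx[[i]]))))
  }
  structure(list(idx = idx, unit_ids = rownames(embedding), k = as.integer(k),
                 symmetrized = symmetrize),
            class = "knn_graph")
}

# knn_graph -> igraph (undirected, simple).
knn_to_igraph <- function(knn) {
  edges <- do.call(rbind, lapply(seq_along(knn$idx), function(i)
    cbind(i, knn$idx[[i]])))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Graph community detection (Leiden, modularity objective)
#'
#' @param knn a `knn_graph`.
#' @param resolution modularity resolution parameter.
#' @param seed RNG seed (labels are deterministic given the seed).
#' @return character cluster labels (`"c1"`, `"c2"`, ...) named by unit id,
#'   numbered in order of first appearance.
#' @export
cluster_graph <- function(knn, resolution = 1, seed = 1L) {
  g <- knn_to_igraph(knn)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5L)
  mem <- igraph::membership(cl)
  relabel <- match(mem, unique(mem))     # stable numbering by node order
  setNames(paste0("c", relabel), knn$unit_ids)
}

#' Score a gene signature against an expression-matched background
#'
#' Score = mean scaled expression of the signature genes minus the mean of
#' a background set matched on expression decile (50 background genes per
#' signature gene by default), per unit.
#'
#' @param scaled genes x units z-score matrix from [scale_genes()] (its
#'   `gene_means` attribute supplies the matching bins).
#' @param set a [gene_set()].
#' @param background_size background genes sampled per signature gene.
#' @param n_bins number of expression bins for matching.
#' @param seed RNG seed for background sampling.
#' @return numeric per-unit score named by unit id; attribute `gene_set`
#'   carries the set name, `n_used` the number of signature genes found.
#' @export
score_signature <- function(scaled, set, background_size = 50L, n_bins = 10L,
                            seed = 1L) {
  stopifnot(inherits(set, "gene_set"))
  genes <- intersect(set$genes, rownames(scaled))
  if (length(genes) == 0L)
    abort_format("no gene of set '%s' present in the matrix", set$name)
  means <- attr(scaled, "gene_means") %||% rowMeans(scaled)
  bins <- expression_bins(means, n_bins)
  names(bins) <- rownames(scaled)
  set.seed(seed)
  bg <- unlist(lapply(genes, function(g) {
    cand <- setdiff(rownames(scaled)[bins == bins[g]], genes)
    if (length(cand) == 0L) return(character(0L))
    sample(cand, min(background_size, length(cand)))
  }))
  sig_score <- colMeans(scaled[genes, , drop = FALSE])
  bg_score <- if (length(bg) > 0L) colMeans(scaled[unique(bg), , drop = FALSE]) else 0
  out <- sig_score - bg_score
  attr(out, "gene_set") <- set$name
  attr(out, "n_used") <- length(genes)
  out
}
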