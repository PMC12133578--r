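# Centroid-tree pseudotime: minimum spanning tree over cluster centroids,
# units projected onto the nearest backbone edge, pseudotime = tree
# distance from the root to the projection. Fully specifiable stand-in for
# black-box trajectory tools: same readouts (ordering, branches,
# per-condition densities).

#' Fit pseudotime over a cluster backbone
#'
#' The backbone is the Euclidean minimum spanning tree over cluster
#' centroids. The root cluster is the one with the highest mean
#' `root_scores` (a per-unit signature score, see [score_signature()]),
#' or can be given directly. Each unit is projected to the nearest
#' backbone edge (ties toward the edge closer to the root) and its
#' pseudotime is the distance along the tree from the root centroid to
#' the projection.
#'
#' @param embedding units x d matrix.
#' @param clusters character cluster label per unit.
#' @param root_scores optional per-unit numeric score identifying the root
#'   state (highest cluster mean wins).
#' @param root_cluster optional explicit root cluster label (overrides
#'   `root_scores`).
#' @return object of class `pseudotime_result`: list with `tau` (named
#'   per-unit pseudotime, `NA` off the root component), `edge` (projection
#'   edge per unit, as centroid index pair), `offset` (distance from the
#'   root-side endpoint), `centroids`, `mst` (igraph), `root`,
#'   `d_root` (per-centroid tree distance), `clusters`, `branch` (filled
#'   by [assign_branches()]).
#' @export
fit_pseudotime <- function(embedding, clusters, root_scores = NULL,
                           root_cluster = NULL) {
  cl_levels <- sort(unique(clusters))
  if (length(cl_levels) < 2L) abort_format("need >= 2 clusters for a backbone")
  cent <- do.call(rbind, lapply(cl_levels, function(cl)
    colMeans(embedding[clusters == cl, , drop = FALSE])))
  rownames(cent) <- cl_levels
  if (is.null(root_cluster)) {
    if (is.null(root_scores))
      abort_format("supply root_scores or root_cluster")
    ms <- tapply(root_scores, clusters, mean)
    root_cluster <- names(ms)[which.max(ms)]
  }
  if (!root_cluster %in% cl_levels)
    abort_format("root cluster '%s' not among cluster labels", root_cluster)

  D <- as.matrix(dist(cent))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  root_i <- match(root_cluster, cl_levels)
  d_root <- as.numeric(igraph::distances(mst, v = root_i,
                                         weights = igraph::E(mst)$weight))
  el <- igraph::as_edgelist(mst, names = FALSE)
  # orient every edge root-side first
  flip <- d_root[el[, 2L]] < d_root[el[, 1L]]
  el[flip, ] <- el[flip, c(2L, 1L)]
  elen <- sqrt(rowSums((cent[el[, 2L], , drop = FALSE] -
                          cent[el[, 1L], , drop = FALSE])^2))

  n <- nrow(embedding)
  deg <- igraph::degree(mst)
  best_d <- rep(Inf, n); best_e <- integer(n); best_t <- numeric(n)
  for (e in seq_len(nrow(el))) {
    a <- cent[el[e, 1L], ]; b <- cent[el[e, 2L], ]
    ab <- b - a; L2 <- sum(ab^2)
    t <- if (L2 == 0) rep(0, n)
         else (sweep(embedding, 2L, a) %*% ab)[, 1L] / L2
    # terminal edges act as rays: beyond a leaf endpoint (and before a
    # leaf root) the projection extends instead of clamping, so ordering
    # is preserved past the last centroid
    lo <- if (el[e, 1L] == root_i && deg[root_i] == 1L) -Inf else 0
    hi <- if (deg[el[e, 2L]] == 1L) Inf else 1
    t <- pmin(hi, pmax(lo, t))
    proj <- outer(t, ab) + rep(a, each = n)
    d <- sqrt(rowSums((embedding - proj)^2))
    # ties go to the edge closer to the root
    upd <- d < best_d - 1e-12 |
      (abs(d - best_d) <= 1e-12 & d_root[el[e, 1L]] < d_root[el[best_e, 1L]] - 1e-12)
    upd[best_e == 0L & d <= best_d] <- TRUE
    best_d[upd] <- d[upd]; best_e[upd] <- e; best_t[upd] <- t[upd]
  }
  tau <- d_root[el[best_e, 1L]] + best_t * elen[best_e]
  comp <- igraph::components(mst)$membership
  tau[comp[el[best_e, 1L]] != comp[root_i]] <- NA_real_
  # pre-root extensions are negative: shift so the earliest unit sits at 0
  shift <- min(0, min(tau, na.rm = TRUE))
  tau <- tau - shift
  names(tau) <- rownames(embedding)
  structure(list(tau = tau, edge = el[best_e, , drop = FALSE],
                 offset = best_t * elen[best_e], centroids = cent,
                 edge_list = el, edge_len = elen, mst = mst,
                 root = root_cluster, d_root = d_root,
                 clusters = clusters, branch = NULL),
            class = "pseudotime_result")
}

#' Assign trunk/branch labels from a fitted backbone
#'
#' The branch point is the tree node of degree >= 3 nearest the root (by
#' tree distance). Units whose projection lies beyond it are labeled by
#' the subtree their projection falls in (`"1"`, `"2"`, ... ordered by
#' subtree cluster label); units at or before it are `"trunk"`. With no
#' degree-3 node, every unit is branch `"1"`.
#'
#' @param result a `pseudotime_result`.
#' @return the result with `$branch` filled (character per unit, named) and
#'   `$branch_point` set (cluster label or `NA`).
#' @export
assign_branches <- function(result) {
  mst <- result$mst
  deg <- igraph::degree(mst)
  cand <- which(deg >= 3L)
  n <- length(result$tau)
  cl_levels <- rownames(result$centroids)
  if (length(cand) == 0L) {
    result$branch <- setNames(rep("1", n), names(result$tau))
    result$branch_point <- NA_character_
    return(result)
  }
  bp <- cand[which.min(result$d_root[cand])]
  # subtrees hanging off the branch point, excluding the root side
  g2 <- igraph::delete_vertices(mst, bp)
  memb <- rep(NA_integer_, length(cl_levels))
  memb[-bp] <- igraph::components(g2)$membership
  root_i <- match(result$root, cl_levels)
  root_comp <- memb[root_i]
  branch_comps <- sort(setdiff(unique(memb[!is.na(memb)]), root_comp))
  comp_to_branch <- setNames(as.character(seq_along(branch_comps)), branch_comps)

  # a unit is beyond the branch point when its projection edge's root-side
  # endpoint is the branch point (with positive offset) or deeper
  el <- result$edge
  branch <- rep("trunk", n)
  for (i in seq_len(n)) {
    a <- el[i, 1L]; b <- el[i, 2L]
    if (is.na(result$tau[i])) { branch[i] <- NA_character_; next }
    if (a == bp) {
      if (result$offset[i] > 0 && !is.na(memb[b]) && memb[b] != root_comp)
        branch[i] <- comp_to_branch[as.character(memb[b])]
    } else if (!is.na(memb[a]) && memb[a] != root_comp) {
      branch[i] <- comp_to_branch[as.character(memb[a])]
    }
  }
  result$branch <- setNames(branch, names(result$tau))
  result$branch_point <- cl_levels[bp]
  result
}

#' Per-condition density of cells along pseudotime
#'
#' Gaussian kernel density per condition on a shared grid; bandwidth by
#' Silverman's rule on the pooled pseudotime unless given. Each curve is
#' renormalized to integrate to 1 on the grid.
#'
#' @param result a `pseudotime_result`.
#' @param annotation paired annotation.
#' @param bandwidth kernel bandwidth (default: Silverman on pooled tau).
#' @param n_grid grid points.
#' @return long data.frame (`condition`, `tau`, `density`).
#' @export
condition_density <- function(result, annotation, bandwidth = NULL,
                              n_grid = 512L) {
  ann <- as.data.frame(annotation)
  tau <- result$tau[ann$unit_id]
  ok <- !is.na(tau)
  tau <- tau[ok]; cond <- ann$condition[ok]
  if (is.null(bandwidth)) bandwidth <- bw.nrd0(tau)
  lo <- min(tau) - 3 * bandwidth; hi <- max(tau) + 3 * bandwidth
  out <- lapply(unique(cond), function(cc) {
    x <- tau[cond == cc]
    if (length(x) < 10L)
      warning(sprintf("condition %s has only %d unit(s) with pseudotime", cc,
                      length(x)), call. = FALSE)
    de <- density(x, bw = bandwidth, from = lo, to = hi, n = n_grid)
    y <- de$y / trapz(de$x, de$y)
    data.frame(condition = cc, tau = de$x, density = y,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-condition branch proportions
#'
#' Among post-branch-point units (trunk excluded from the denominator),
#' the fraction of each condition's cells in each branch.
#'
#' @param result a `pseudotime_result` with branches assigned.
#' @param annotation paired annotation.
#' @return data.frame (`condition`, `branch`, `n`, `fraction`); fractions
#'   sum to 1 within each condition.
#' @export
branch_proportions <- function(result, annotation) {
  if (is.null(result$branch)) abort_format("run assign_branches() first")
  ann <- as.data.frame(annotation)
  br <- result$branch[ann$unit_id]
  keep <- !is.na(br) & br != "trunk"
  br <- br[keep]; cond <- ann$condition[keep]
  branches <- sort(unique(br))
  out <- do.call(rbind, lapply(unique(cond), function(cc) {
    x <- br[cond == cc]
    n <- vapply(branches, function(b) sum(x == b), integer(1L))
    data.frame(condition = cc, branch = branches, n = n,
               fraction = if (sum(n) > 0) n / sum(n) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
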