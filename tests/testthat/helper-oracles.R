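# Independent oracles and fixture builders shared by the suite. Oracles
# deliberately avoid the code paths they check: enumeration and choose()
# arithmetic instead of dhyper/phyper/wilcox.test.

# Adjusted Rand index (Hubert-Arabie) from the contingency table.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sc <- function(x) sum(choose(x, 2))
  e <- sc(rowSums(tab)) * sc(colSums(tab)) / choose(n, 2)
  (sc(tab) - e) / ((sc(rowSums(tab)) + sc(colSums(tab))) / 2 - e)
}

# Exact two-sided Mann-Whitney p by enumeration of all rank assignments:
# all choose(nx+ny, nx) placements of the x-group among the pooled ranks.
mw_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- rank(c(x, y))
  u_obs <- sum(pooled[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- combn(nx + ny, nx)
  ranks <- seq_len(nx + ny)
  u_all <- apply(combos, 2L, function(ix) sum(ranks[ix]) - nx * (nx + 1) / 2)
  # two-sided: double the smaller tail, capped at 1
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Brute-force two-sided Fisher p: hypergeometric probabilities from
# choose() ratios, explicit comparison over the whole support.
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  supp <- lo:hi
  pr <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
  obs <- pr[supp == a]
  tot <- 0
  for (j in seq_along(supp)) if (pr[j] <= obs * (1 + 1e-7)) tot <- tot + pr[j]
  tot
}

# Exact two-sided hypergeometric doubling-rule p via choose() sums,
# independent of phyper.
hyper_doubling_oracle <- function(a, A, B, draw) {
  supp <- max(0L, draw - B):min(draw, A)
  pr <- choose(A, supp) * choose(B, draw - supp) / choose(A + B, draw)
  lo <- sum(pr[supp <= a]); hi <- sum(pr[supp >= a])
  min(1, 2 * min(lo, hi))
}

# Gini coefficient of a non-negative vector.
gini <- function(x) {
  x <- sort(x)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

# Tiny fixed clonotype table used across repertoire tests (junctions are
# translation-consistent with the amino-acid strings).
tiny_clonotypes <- function() {
  clonotype_table(data.frame(
    sample_id = c("HC_r1", "HC_r1", "HC_r1", "HC_r1", "HC_r1"),
    condition = "HC",
    v_call = c("TRBV28", "TRBV9", "TRBV28", "TRBV9", "TRBV19"),
    j_call = "TRBJ1-1",
    cdr3_nt = c("TGTGCCAGCAGCCTGTTT", "TGTGCCAGCAGCGGCTTT",
                "TGTGCCAGCCGTCTGTTT", "TGTGCCAGCACCACCTTT",
                "TGTGCCAGCCAGCAGTTT"),
    cdr3_aa = c("CASSLF", "CASSGF", "CASRLF", "CASTTF", "CASQQF"),
    count = c(3L, 1L, 1L, 2L, 1L), stringsAsFactors = FALSE))
}

# Y-shaped trajectory fixture: trunk along x, two branches diverging at
# x = 2; returns embedding, cluster labels, true latent time and true
# branch. Centroid geometry guarantees the MST is a genuine Y (branch
# point at the trunk tip).
y_fixture <- function(n = 900, noise = 0.15, seed = 1) {
  set.seed(seed)
  seg <- sample(c("trunk", "b1", "b2"), n, replace = TRUE,
                prob = c(0.4, 0.3, 0.3))
  t0 <- runif(n)
  pos <- matrix(0, n, 2)
  pos[seg == "trunk", 1] <- 2 * t0[seg == "trunk"]
  pos[seg == "b1", ] <- cbind(2 + 1.5 * t0[seg == "b1"], 1.8 * t0[seg == "b1"])
  pos[seg == "b2", ] <- cbind(2 + 1.5 * t0[seg == "b2"], -1.8 * t0[seg == "b2"])
  tau_true <- ifelse(seg == "trunk", 2 * t0,
                     2 + sqrt(1.5^2 + 1.8^2) * t0)
  pos <- pos + matrix(rnorm(2 * n, 0, noise), n, 2)
  rownames(pos) <- sprintf("u%04d", seq_len(n))
  cl <- ifelse(seg == "trunk", ifelse(t0 < 0.5, "root", "mid"),
               ifelse(seg == "b1", "b1", "b2"))
  list(embedding = pos, clusters = cl, tau = tau_true, branch = seg,
       t0 = t0)
}

# Spatial world with an "injected" signal: the B-cell signature occurs in
# the lymphoid-aggregate region only, so its marker set is a clean
# region-specific injection for enrichment tests.
injected_spatial_config <- function(seed = 109L, ...) {
  types <- c("enterocyte", "stem", "TRM", "Tfh", "Bcell", "plasma")
  comp <- list(
    villus_tip = c(0.84, 0.02, 0.10, 0.02, 0, 0.02),
    mid_villus = c(0.64, 0.10, 0.12, 0.04, 0, 0.10),
    crypt = c(0.32, 0.42, 0.10, 0.05, 0, 0.11),
    stem_niche = c(0.12, 0.62, 0.08, 0.05, 0, 0.13),
    lymphoid_aggregate = c(0.05, 0.05, 0.15, 0.20, 0.40, 0.15))
  comp <- lapply(comp, function(p) setNames(p, types))
  spatial_sim_config(composition = comp, seed = seed, ...)
}

# The B-cell marker block of the default signature matrix.
bcell_marker_set <- function() gene_set("bcell_markers", sprintf("sgene%03d", 81:95))

# Two-type dataset where the ligand is expressed only in senders (A) and
# the receptor only in receivers (B): a clean injected interaction.
ligrec_fixture_acc <- function(n_per_type = 60L, seed = 11L) {
  set.seed(seed)
  n <- 2L * n_per_type
  genes <- c("LIG1", "REC1", paste0("bg", 1:18))
  cl <- rep(c("A", "B"), each = n_per_type)
  m <- matrix(rpois(length(genes) * n, 3), length(genes),
              dimnames = list(genes, sprintf("c%03d", 1:n)))
  m["LIG1", ] <- ifelse(cl == "A", rpois(n, 20), 0L)
  m["REC1", ] <- ifelse(cl == "B", rpois(n, 20), 0L)
  ann <- annotation_table(colnames(m), rep(c("s1", "s2"), n / 2),
                          rep("ACD", n), cluster = cl)
  list(counts = count_matrix(m), ann = ann,
       pairs = rl_pairs("LIG1", "REC1", "LIG1_REC1"))
}

# Hand-built knn_graph from an explicit neighbor index list.
make_knn <- function(idx, unit_ids = NULL, k = max(lengths(idx))) {
  structure(list(idx = lapply(idx, as.integer),
                 unit_ids = unit_ids %||% paste0("u", seq_along(idx)),
                 k = as.integer(k), symmetrized = TRUE),
            class = "knn_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
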