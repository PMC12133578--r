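make_square <- function(nr, nc, region = NULL, ngene = 3L) {
  grid <- expand.grid(col = seq_len(nc) - 1L, row = seq_len(nr) - 1L)
  n <- nrow(grid)
  m <- count_matrix(matrix(rpois(ngene * n, 5), ngene,
                           dimnames = list(paste0("g", seq_len(ngene)),
                                           sprintf("s%03d", seq_len(n)))))
  spatial_dataset(m, grid$row, grid$col, lattice = "square", region = region)
}

test_that("lattice neighborhoods have the expected sizes", {
  sp <- make_square(4, 4)
  nb <- lattice_neighbors(sp)
  sizes <- lengths(nb)
  corner <- which(sp$array_row == 0 & sp$array_col == 0)
  interior <- which(sp$array_row == 1 & sp$array_col == 2)
  expect_identical(sizes[corner], 2L)
  expect_identical(sizes[interior], 4L)
  # neighbor relation is symmetric
  expect_true(all(vapply(seq_along(nb), function(i)
    all(vapply(nb[[i]], function(j) i %in% nb[[j]], logical(1))), logical(1))))
})

test_that("region adjacency reproduces the enumerated half-split example", {
  # single region: P = [[1.0]]
  sp1 <- make_square(3, 3, region = rep("only", 9))
  expect_equal(unname(region_adjacency(sp1)$P), matrix(1))

  # 4x4 split into left/right column halves: P[left, right] = 4/24 = 1/6
  sp <- make_square(4, 4)
  sp$region <- ifelse(sp$array_col < 2, "left", "right")
  adj <- region_adjacency(sp)
  expect_equal(adj$P["left", "right"], 1 / 6)
  expect_equal(adj$P["left", "left"], 5 / 6)
  expect_true(all(abs(rowSums(adj$P) - 1) < 1e-9))
  # plotted edges exclude self-pairs
  expect_false(any(adj$edges$source == adj$edges$target))

  # relabeling permutes the matrix accordingly
  sp2 <- sp
  sp2$region <- ifelse(sp$region == "left", "zright", "aleft")
  adj2 <- region_adjacency(sp2)
  expect_equal(adj2$P["zright", "aleft"], adj$P["left", "right"])
})

test_that("spot clustering recovers a two-region layout deterministically", {
  cfg <- spatial_sim_config(
    n_rows = 14L, n_cols = 14L,
    bands = data.frame(row_from = c(0L, 7L), row_to = c(6L, 13L),
                       region = c("villus_tip", "lymphoid_aggregate")),
    circles = NULL, seed = 97L)
  sim <- simulate_spatial(cfg)
  sp <- cluster_spots(sim$spatial, resolution = 0.3, seed = 1L)
  expect_gte(ari(sp$region, sim$truth$region), 0.9)
  sp2 <- cluster_spots(sim$spatial, resolution = 0.3, seed = 1L)
  expect_identical(sp2$region, sp$region)
})

test_that("region proportions sum to one and track aggregate radius", {
  sp <- make_square(3, 3, region = rep("only", 9))
  pr <- region_proportions(sp)
  expect_equal(pr$fraction, 1)
  frac_la <- vapply(c(2, 4), function(r) {
    cfg <- spatial_sim_config(circles = data.frame(row = 15L, col = 15L,
                                                   radius = r,
                                                   region = "lymphoid_aggregate"),
                              seed = 5L)
    sim <- simulate_spatial(cfg)
    mean(sim$truth$region == "lymphoid_aggregate")
  }, numeric(1))
  expect_gt(frac_la[2], frac_la[1])
})

test_that("signature building reproduces simulator type means", {
  sim <- simulate_cells(cell_sim_config(cells_per_sample = 250L, seed = 101L))
  ann <- sim$annotation
  ann$cluster <- sim$truth$true_type
  S <- build_signatures(sim$counts, ann)
  expect_true(all(S >= 0))
  # expected linear-normalized mean for a marker gene of type t:
  # target_sum * mu_marker / sum(mu) with 10 markers at 8x base elevation
  n_genes <- nrow(sim$counts)
  mu_sum <- (n_genes - 10) * 0.5 + 10 * 0.5 * 8
  expected_marker <- 1e4 * (0.5 * 8) / mu_sum
  mk <- attr(sim$truth, "marker_genes")$type3
  obs <- mean(S[mk, "type3"])
  expect_lt(abs(obs - expected_marker) / expected_marker, 0.1)
})

test_that("deconvolution is exact on noiseless mixtures", {
  # integer signature matrix with equal column sums: a pure column and the
  # sum of two columns are exact noiseless 100% and 50/50 mixtures
  S <- spatial_sim_config(seed = 1L)$signatures   # markers 8, background 0.5
  S <- S * 10                                     # integer-valued, equal sums
  pure <- S[, "stem"]
  mix <- S[, "TRM"] + S[, "Bcell"]
  cnt <- count_matrix(cbind(pure = pure, mix = mix))
  sp <- spatial_dataset(cnt, c(0L, 0L), c(0L, 1L), lattice = "square")
  dec <- deconvolve(sp, S)
  expect_lt(max(abs(dec$weights["pure", ] - (colnames(S) == "stem"))), 1e-6)
  target <- ifelse(colnames(S) %in% c("TRM", "Bcell"), 0.5, 0)
  expect_lt(max(abs(dec$weights["mix", ] - target)), 1e-6)
  expect_error(deconvolve(sp, matrix(1, 2, 1, dimnames = list(c("zz1", "zz2"), "t"))),
               "no shared genes")
})

test_that("deconvolution recovers simulated compositions", {
  sim <- simulate_spatial(spatial_sim_config(seed = 103L))
  sp <- sim$spatial; sp$region <- sim$truth$region
  dec <- deconvolve(sp, sim$config$signatures)
  truth <- attr(sim$truth, "composition")[rownames(dec$weights),
                                          colnames(dec$weights)]
  expect_lt(mean(abs(dec$weights - truth)), 0.05)
  expect_true(all(abs(rowSums(dec$weights) - 1) < 1e-6))
  expect_true(!is.null(dec$region_means))
})

test_that("colocalization reflects shared and disjoint occupancy", {
  set.seed(6)
  w1 <- runif(60)
  W <- cbind(a = w1, b = w1 * 0.8,                 # tied types
             c = 1.8 - w1 - w1 * 0.8, d = 0.0)     # complementary + constant
  W <- W / rowSums(W)
  W[, "d"] <- 0; rownames(W) <- paste0("s", 1:60)
  net <- colocalization(list(weights = W), threshold = 0.3)
  expect_gt(net$cor["a", "b"], 0.99)
  expect_lt(net$cor["a", "c"], 0)
  expect_true(is.na(net$cor["a", "d"]))
  expect_equal(net$cor, t(net$cor))
  expect_true(all(net$edges$weight >= 0.3))
  expect_error(colocalization(list(weights = W[1:5, ])), ">= 10 spots")
})

test_that("region markers surface simulator-elevated genes", {
  sim <- simulate_spatial(spatial_sim_config(seed = 107L))
  sp <- sim$spatial; sp$region <- sim$truth$region
  mks <- region_markers(sp, "lymphoid_aggregate")
  # Bcell markers (sgene081..sgene095) dominate the LA region (0.35 weight)
  expect_true(any(grepl("^sgene08[1-9]|^sgene09[0-5]", head(mks$gene, 10))))
  expect_true(all(diff(mks$q[order(mks$p)]) >= -1e-12))
  expect_error(region_markers(sp, "lymphoid_aggregate", min_spots = 1000L),
               "spots")
})

test_that("region set enrichment honors the permutation estimator bounds", {
  sim <- simulate_spatial(injected_spatial_config(seed = 109L))
  sp <- sim$spatial; sp$region <- sim$truth$region
  res <- region_set_enrichment(sp, bcell_marker_set(), n_perm = 199L, seed = 3L)
  expect_true(all(res$p >= 1 / 200))
  expect_identical(res$region[which.max(res$z)], "lymphoid_aggregate")
  expect_lte(res$p[res$region == "lymphoid_aggregate"], 2 / 200)
  expect_error(region_set_enrichment(sp, gene_set("none", "absent_gene")),
               "no gene")
})
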