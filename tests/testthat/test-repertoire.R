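test_that("aggregation merges duplicate keys and conserves totals", {
  tab <- clonotype_table(data.frame(
    sample_id = "s", condition = "HC",
    v_call = c("TRBV1", "TRBV1", "TRBV2"), j_call = "TRBJ1-1",
    cdr3_nt = c("TGTCTG", "TGCCTG", "TGTCTG"),   # first two are aa synonyms
    cdr3_aa = c("CL", "CL", "CL"),
    count = c(2L, 3L, 4L)))
  v_nt <- aggregate_clonotypes(tab, "v_nt")$s
  expect_length(v_nt, 3L)
  v_aa <- aggregate_clonotypes(tab, "v_aa")$s
  expect_length(v_aa, 2L)          # nt synonyms merged under the aa key
  expect_equal(unname(v_aa["TRBV1|CL"]), 5)
  expect_equal(sum(v_aa), sum(tab$count))
  expect_error(aggregate_clonotypes(tab[0, ], "v_nt"), "empty")
})

test_that("Morisita-Horn matches hand-derived values and is a proper overlap", {
  A <- c(c1 = 2, c2 = 1); B <- c(c1 = 1, c2 = 1)
  expect_equal(morisita_horn(A, B), 18 / 19, tolerance = 1e-12)
  expect_equal(morisita_horn(A, A), 1.0)
  expect_equal(morisita_horn(A, c(c9 = 5, c8 = 2)), 0.0)
  # symmetry, scale invariance, boundedness over random vectors
  set.seed(5)
  for (i in 1:50) {
    x <- setNames(rpois(8, 5) + 1, paste0("k", 1:8))
    y <- setNames(rpois(8, 5) + 1, paste0("k", sample(1:12, 8)))
    expect_equal(morisita_horn(x, y), morisita_horn(y, x))
    expect_equal(morisita_horn(x * 7, y), morisita_horn(x, y))
    expect_true(morisita_horn(x, y) >= 0 && morisita_horn(x, y) <= 1 + 1e-12)
  }
  m <- morisita_horn_matrix(list(a = A, b = B))
  expect_equal(m["a", "b"], m["b", "a"])
  expect_equal(diag(m), c(a = 1, b = 1))
  expect_error(morisita_horn(numeric(0), A), "empty")
})

test_that("v_usage_test returns null results on identical group counts", {
  rows <- expand.grid(sample_id = c("a1", "a2", "b1", "b2"),
                      v_call = c("TRBV1", "TRBV2"), idx = 1:10,
                      stringsAsFactors = FALSE)
  tab <- clonotype_table(data.frame(
    sample_id = rows$sample_id,
    condition = ifelse(grepl("^a", rows$sample_id), "ACD", "HC"),
    v_call = rows$v_call, j_call = "TRBJ1-1",
    cdr3_aa = sprintf("CASS%s%02dF", rows$v_call, rows$idx), count = 1L))
  res <- v_usage_test(tab)
  expect_true(all(abs(res$lfc) < 1e-8))
  expect_true(all(res$p > 0.99))
  expect_error(v_usage_test(tab[tab$sample_id != "a2", ]), ">= 2 samples")
})

test_that("segment fractions: unique, top-n and simulated recovery", {
  tab <- tiny_clonotypes()
  expect_equal(unname(unique_v_fraction(tab, "TRBV28")), 0.4)
  # n larger than repertoire: uses all, flagged
  tf <- top_expanded_v_fraction(tab, "TRBV28", n = 100L)
  expect_true(attr(tf, "used_all")[["HC_r1"]])
  expect_equal(as.numeric(tf), 0.4)
  # top 2 by count are (CASSLF count 3, CASTTF count 2): one TRBV28
  expect_equal(as.numeric(top_expanded_v_fraction(tab, "TRBV28", n = 2L)), 0.5)

  sim <- simulate_repertoire(repertoire_sim_config(
    n_clones = 5000L, samples_per_condition = c(HC = 0L, ACD = 3L, TCD = 0L),
    public_pool_fraction = 0, seed = 79L))
  fr <- unique_v_fraction(sim$table, "TRBV28")
  expect_true(all(abs(fr - 0.10) < 4 * sqrt(0.1 * 0.9 / 5000)))
})

test_that("quintile enrichment Fisher p equals the enumeration oracle", {
  expect_equal(fisher_two_sided(8, 2, 12, 18), fisher_enum_oracle(8, 2, 12, 18))
  expect_equal(fisher_enum_oracle(8, 2, 12, 18),
               fisher.test(matrix(c(8, 2, 12, 18), 2, byrow = TRUE))$p.value)
  # uniform segment spread: odds ratio near 1
  tab <- clonotype_table(data.frame(
    sample_id = "s", condition = "HC",
    v_call = rep(c("TRBV28", "TRBV9"), 25),
    j_call = "TRBJ1-1", cdr3_aa = sprintf("CASS%03dF", 1:50),
    count = rep(50:1)))
  qe <- quintile_enrichment(tab, "TRBV28", key_mode = "v_aa")
  expect_lt(abs(log(qe$or)), 0.5)
  expect_identical(sum(qe$table), 50L)
  # constant segment membership: OR undefined, noted
  tab2 <- tab; tab2$v_call <- "TRBV28"
  tab2 <- clonotype_table(as.data.frame(tab2)[1:8])
  qe2 <- quintile_enrichment(tab2, "TRBV28", key_mode = "v_aa")
  expect_true(is.na(qe2$or))
  expect_match(qe2$note, "undefined")
  # the worked example: OR = 6
  expect_equal((8 * 18) / (2 * 12), 6)
})

test_that("CDR3 amino-acid usage counts germline and core positions correctly", {
  tab <- clonotype_table(data.frame(
    sample_id = c("a1", "b1"), condition = c("ACD", "HC"),
    v_call = "TRBV1", j_call = "TRBJ1-1",
    cdr3_aa = c("CASSLG", "CASSFG"), count = 1L))
  res <- cdr3_aa_usage(tab, germline_prefix = 3L, germline_suffix = 1L)
  # global L frequency over both groups' 12 residues: 1 of 12
  gl <- res$global
  expect_equal(sum(gl["L", ] * 6) / 12, 1 / 12)
  # core of CASSLG under prefix 3 / suffix 1 is positions 4-5 = "SL"
  expect_equal(res$nongermline["L", "ACD"], 0.5)
  expect_equal(res$nongermline["S", "ACD"], 0.5)
  expect_equal(res$nongermline["F", "HC"], 0.5)
  expect_true(all(res$tests$q >= res$tests$p - 1e-12))
  tab_bad <- tab; tab_bad$cdr3_aa[1] <- "CASXZ9"
  expect_error(cdr3_aa_usage(clonotype_table(as.data.frame(tab_bad)[1:8])),
               "non-amino-acid")
})

test_that("core leucine bias injected by construction is detected", {
  set.seed(83)
  mk <- function(cond, n, p_l) {
    core <- replicate(n, paste(sample(c("L", "G", "S", "T"), 6, replace = TRUE,
                                      prob = c(p_l, rep((1 - p_l) / 3, 3))),
                               collapse = ""))
    data.frame(sample_id = paste0(cond, "_1"), condition = cond,
               v_call = "TRBV1", j_call = "TRBJ1-1",
               cdr3_aa = paste0("CAS", core, "F"), count = 1L)
  }
  tab <- clonotype_table(rbind(mk("ACD", 400, 0.5), mk("HC", 400, 0.2)))
  res <- cdr3_aa_usage(tab)
  lrow <- res$tests[res$tests$residue == "L", ]
  expect_lt(lrow$q, 0.01)
  expect_gt(res$nongermline["L", "ACD"], res$nongermline["L", "HC"])
})

test_that("motif frequencies are exact on constructed repertoires", {
  tab <- clonotype_table(data.frame(
    sample_id = "s", condition = "HC", v_call = "TRBV1", j_call = "TRBJ1-1",
    cdr3_aa = c("CASSLG", "CASSFG"), count = 1L))
  expect_equal(unname(motif_frequency(tab, "L")), 0.5)
  expect_equal(unname(motif_frequency(tab, "^CASS")), 1.0)
  expect_error(motif_frequency(tab, "(("), "invalid")
  # rate-r motif by construction
  tab2 <- clonotype_table(data.frame(
    sample_id = "s", condition = "HC", v_call = "TRBV1", j_call = "TRBJ1-1",
    cdr3_aa = c("CASSWDTAF", "CASSWDTCF", "CASSWDTDF",
                sprintf("CASS%03dF", 1:7)), count = 1L))
  expect_equal(unname(motif_frequency(tab2, "WDT")), 0.3)
})

test_that("sharing statistics separate public pools by condition", {
  tab <- tiny_clonotypes()
  both <- clonotype_table(rbind(
    cbind(as.data.frame(tab)[1:8]),
    transform(as.data.frame(tab)[1:8], sample_id = "HC_r2")))
  sh <- clonotype_sharing(both, key_mode = "v_aa")
  expect_equal(sh$jaccard, 1)
  expect_equal(sh$pair_class, "within-HC")

  sim <- simulate_repertoire(repertoire_sim_config(
    n_clones = 1500L,
    samples_per_condition = c(HC = 4L, ACD = 4L, TCD = 0L),
    public_pool_fraction = c(HC = 0, ACD = 0.10, TCD = 0), seed = 89L))
  sh2 <- clonotype_sharing(sim$table)
  within_acd <- sh2$shared[sh2$pair_class == "within-ACD"]
  between <- sh2$shared[sh2$pair_class == "between"]
  p_share <- suppressWarnings(
    wilcox.test(within_acd, between, alternative = "greater")$p.value)
  expect_lt(p_share, 0.05)
})

test_that("segment usage summaries are locus-restricted simplex columns", {
  tab <- clonotype_table(data.frame(
    sample_id = rep(c("a1", "b1"), each = 6), condition = rep(c("ACD", "HC"), each = 6),
    v_call = c(rep("TRGV3", 4), "TRGV4", "TRGV9",
               rep("TRGV3", 1), rep("TRGV4", 4), "TRGV9"),
    j_call = "TRGJ1", cdr3_aa = sprintf("CAS%02dF", 1:12), count = 1L))
  m <- segment_usage_summary(tab, locus = "TRGV", key_mode = "v_aa")
  expect_true(all(abs(colSums(m) - 1) < 1e-9))
  # injected TRGV3 excess in ACD recovered
  expect_gt(m["TRGV3", "a1"], m["TRGV3", "b1"])
  expect_gt(m["TRGV4", "b1"], m["TRGV4", "a1"])
  expect_error(segment_usage_summary(tab, locus = "TRDV", key_mode = "v_aa"),
               "no clonotypes")
})
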