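test_that("count matrix round-trips through MatrixMarket and validates invariants", {
  m <- count_matrix(matrix(c(0L, 2L, 1L, 0L, 5L, 0L), nrow = 3,
                           dimnames = list(c("g1", "g2", "g3"), c("u1", "u2"))))
  d <- withr::local_tempdir()
  write_counts(m, file.path(d, "m.mtx"), file.path(d, "g.tsv"), file.path(d, "u.tsv"))
  m2 <- read_counts(file.path(d, "m.mtx"), file.path(d, "g.tsv"), file.path(d, "u.tsv"))
  expect_identical(as.matrix(m2), as.matrix(m))
  expect_identical(rownames(m2), c("g1", "g2", "g3"))  # file order preserved

  expect_error(count_matrix(matrix(1L, 2, 1, dimnames = list(c("gA", "gA"), "u1"))),
               "gA")
  expect_error(count_matrix(matrix(-1, 1, 1, dimnames = list("g1", "u1"))),
               "negative")
  expect_error(count_matrix(matrix(1.5, 1, 1, dimnames = list("g1", "u1"))),
               "non-integer")
  # name-file / triplet dimension mismatch
  writeLines(c("g1", "g2"), file.path(d, "short.tsv"))
  expect_error(read_counts(file.path(d, "m.mtx"), file.path(d, "short.tsv"),
                           file.path(d, "u.tsv")), "name files")
})

test_that("generator counts survive a write/read cycle with totals intact", {
  sim <- simulate_cells(cell_sim_config(n_genes = 50L, cells_per_sample = 10L,
                                        samples_per_condition = c(HC = 5L, ACD = 5L, TCD = 0L),
                                        seed = 42L))
  expect_equal(dim(sim$counts), c(50L, 100L))
  d <- withr::local_tempdir()
  write_counts(sim$counts, file.path(d, "m.mtx"), file.path(d, "g.tsv"),
               file.path(d, "u.tsv"))
  m2 <- read_counts(file.path(d, "m.mtx"), file.path(d, "g.tsv"), file.path(d, "u.tsv"))
  expect_identical(sum(m2), sum(sim$counts))
  expect_identical(as.matrix(m2), as.matrix(sim$counts))
})

test_that("dense TSV counts are accepted for small fixtures", {
  d <- withr::local_tempdir()
  df <- data.frame(gene = c("g1", "g2"), u1 = c(1L, 0L), u2 = c(2L, 3L))
  write.table(df, file.path(d, "dense.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  m <- read_counts(file.path(d, "dense.tsv"))
  expect_equal(as.numeric(m["g2", "u2"]), 3)
})

test_that("clonotype IO: AIRR dialect, count defaulting, vocabulary flags", {
  tab <- tiny_clonotypes()
  expect_identical(sum(tab$count), 8L)  # counts (3,1,1,2,1)
  d <- withr::local_tempdir()
  write_clonotypes(tab, file.path(d, "airr.tsv"))
  tab2 <- read_clonotypes(file.path(d, "airr.tsv"))
  expect_identical(tab2$v_call, tab$v_call)
  expect_identical(tab2$count, tab$count)
  expect_identical(tab2$cdr3_aa, tab$cdr3_aa)

  # out-of-vocabulary v_call: warned, retained, flagged
  expect_warning(
    t3 <- read_clonotypes(file.path(d, "airr.tsv"),
                          v_vocabulary = c("TRBV28", "TRBV9")),
    "TRBV19")
  expect_true("TRBV19" %in% t3$v_call)
  expect_false(t3$v_flag[t3$v_call == "TRBV19"][1])

  # missing mandatory column named in the error
  df <- read.delim(file.path(d, "airr.tsv"))
  df$v_call <- NULL
  write.table(df, file.path(d, "broken.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_clonotypes(file.path(d, "broken.tsv")), "v_call")

  # missing duplicate_count defaults to 1
  df2 <- read.delim(file.path(d, "airr.tsv"))
  df2$duplicate_count <- NULL
  write.table(df2, file.path(d, "nocount.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_identical(read_clonotypes(file.path(d, "nocount.tsv"))$count,
                   rep(1L, nrow(tab)))
})

test_that("cdr3_aa must match the translated junction when both present", {
  expect_error(clonotype_table(data.frame(
    sample_id = "s1", condition = "HC", v_call = "TRBV9", j_call = "TRBJ1-1",
    cdr3_nt = "TGTGCCAGC", cdr3_aa = "CAT", count = 1L)), "inconsistent")
  expect_silent(t <- clonotype_table(data.frame(
    sample_id = "s1", condition = "HC", v_call = "TRBV9", j_call = "TRBJ1-1",
    cdr3_nt = "TGTGCCAGC", cdr3_aa = "CAS", count = 1L)))
})

test_that("spatial IO round-trips and rejects inconsistent inputs", {
  m <- count_matrix(matrix(rpois(16 * 5, 4), nrow = 5,
                           dimnames = list(paste0("g", 1:5), paste0("s", 1:16))))
  grid <- expand.grid(col = 0:3, row = 0:3)
  sp <- spatial_dataset(m, grid$row, grid$col, lattice = "square",
                        region = rep(c("a", "b"), each = 8))
  d <- withr::local_tempdir()
  write_spatial(sp, file.path(d, "m.mtx"), file.path(d, "g.tsv"),
                file.path(d, "u.tsv"), file.path(d, "coords.tsv"))
  sp2 <- read_spatial(file.path(d, "m.mtx"), file.path(d, "g.tsv"),
                      file.path(d, "u.tsv"), file.path(d, "coords.tsv"),
                      lattice = "square")
  expect_identical(sp2$spots, sp$spots)
  expect_identical(sp2$array_row, sp$array_row)
  expect_identical(sp2$region, sp$region)
  expect_identical(as.matrix(sp2$counts), as.matrix(sp$counts))

  # coordinate row for a spot absent from counts names the spot
  co <- read.delim(file.path(d, "coords.tsv"))
  co$spot_id[1] <- "ghost"
  write.table(co, file.path(d, "bad.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_spatial(file.path(d, "m.mtx"), file.path(d, "g.tsv"),
                            file.path(d, "u.tsv"), file.path(d, "bad.tsv"),
                            lattice = "square"), "ghost")

  # duplicated lattice coordinate
  expect_error(spatial_dataset(m, rep(0L, 16), c(0:14, 14L), lattice = "square"),
               "duplicate")
})

test_that("interior hex spot has six lattice neighbors", {
  m <- count_matrix(matrix(1L, 1, 25, dimnames = list("g1", paste0("s", 1:25))))
  grid <- expand.grid(col = 0:4, row = 0:4)
  sp <- spatial_dataset(m, grid$row, grid$col, lattice = "hex")
  nb <- lattice_neighbors(sp)
  interior <- which(grid$row == 2 & grid$col == 2)
  expect_length(nb[[interior]], 6L)
})

test_that("GMT and receptor-ligand readers parse and validate", {
  d <- withr::local_tempdir()
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg9"),
             file.path(d, "sets.gmt"))
  sets <- read_gmt(file.path(d, "sets.gmt"))
  expect_named(sets, c("setA", "setB"))
  expect_identical(sets$setA$genes, c("g1", "g2", "g3"))
  expect_error(gene_set("empty", character(0)), "empty")

  write.table(data.frame(ligand = c("CXCL13", "CCL19"),
                         receptor = c("CXCR5", "CCR7"),
                         pair_name = c("CXCL13_CXCR5", "CCL19_CCR7")),
              file.path(d, "pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pr <- read_rl_pairs(file.path(d, "pairs.tsv"))
  expect_identical(pr$pair_name, c("CXCL13_CXCR5", "CCL19_CCR7"))
  expect_error(rl_pairs(c("a", "a"), c("b", "b"), c("p", "p")), "duplicated")
})

test_that("annotation validates conditions and unit pairing", {
  expect_error(annotation_table("u1", "s1", "SICK"), "SICK")
  m <- count_matrix(matrix(1L, 1, 1, dimnames = list("g1", "u1")))
  expect_error(annotation_table("u2", "s1", "HC", counts = m), "u2")
  ann <- annotation_table(c("u1", "u2"), "s1", "ACD")
  expect_s3_class(ann, "celiac_annotation")
})
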