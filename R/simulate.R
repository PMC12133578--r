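# Synthetic generators with ground truth. All three are pure functions of
# (config, seed): same config object twice gives byte-identical output.
# Defaults mirror the study design they emulate at desk scale: 3 HC / 5 ACD
# / 4 TCD donors for single cells, 8 / 7 / 5 for bulk repertoires, and a
# 30 x 30 Visium-like hex slide with crypt-villus bands plus one focal
# lymphoid-aggregate circle.

#' Configuration for the single-cell count generator
#'
#' Cells belong to one of `n_types` discrete states; each state owns a
#' disjoint block of marker genes elevated by `2^marker_logfc` over the
#' baseline mean. Per-condition abundance shifts multiply a state's
#' baseline frequency before renormalization, emulating disease-driven
#' expansion (the default triples `type1` in ACD and doubles it in TCD,
#' the persistent-expansion pattern of disease-associated resident CD8
#' states).
#'
#' @param n_types number of cell states.
#' @param n_genes genes simulated (marker blocks must fit).
#' @param cells_per_sample cells per donor sample.
#' @param samples_per_condition named integer vector over HC/ACD/TCD.
#' @param base_mean expected counts per non-marker gene before depth.
#' @param marker_logfc log2 elevation of marker blocks.
#' @param markers_per_type genes per marker block.
#' @param abundance_shift data.frame (`type`, `condition`, `factor`) of
#'   multiplicative frequency shifts; factors must be positive.
#' @param dispersion negative-binomial size parameter (shared by genes).
#' @param depth_variation log-normal sigma of the per-cell depth factor.
#' @param seed integer RNG seed.
#' @return a `cell_sim_config` list.
#' @export
cell_sim_config <- function(n_types = 5L, n_genes = 200L, cells_per_sample = 400L,
                            samples_per_condition = c(HC = 3L, ACD = 5L, TCD = 4L),
                            base_mean = 0.5, marker_logfc = 3, markers_per_type = 10L,
                            abundance_shift = data.frame(
                              type = c("type1", "type1"),
                              condition = c("ACD", "TCD"),
                              factor = c(3, 2)),
                            dispersion = 2, depth_variation = 0.3, seed = 1L) {
  stopifnot(n_types >= 2L, n_genes >= 1L, cells_per_sample >= 1L,
            base_mean > 0, markers_per_type >= 1L, dispersion > 0,
            depth_variation > 0)
  check_conditions(names(samples_per_condition))
  if (n_types * markers_per_type > n_genes)
    abort_format("marker blocks (%d x %d) exceed n_genes = %d",
                 n_types, markers_per_type, n_genes)
  if (nrow(abundance_shift) > 0L) {
    check_conditions(abundance_shift$condition)
    if (any(abundance_shift$factor <= 0))
      abort_format("abundance_shift factors must be > 0")
  }
  structure(list(n_types = as.integer(n_types), n_genes = as.integer(n_genes),
                 cells_per_sample = as.integer(cells_per_sample),
                 samples_per_condition = samples_per_condition,
                 base_mean = base_mean, marker_logfc = marker_logfc,
                 markers_per_type = as.integer(markers_per_type),
                 abundance_shift = abundance_shift, dispersion = dispersion,
                 depth_variation = depth_variation, seed = as.integer(seed)),
            class = "cell_sim_config")
}

#' Simulate a multi-sample single-cell count dataset with ground truth
#'
#' Counts are negative binomial per gene with type- and condition-specific
#' means and a log-normal per-cell depth multiplier. The annotation's
#' `cluster` field is left `NA` (to be filled by clustering); true types
#' live in the ground truth.
#'
#' @param config a [cell_sim_config()].
#' @return list with `counts` (sparse genes x cells), `annotation`
#'   (`celiac_annotation`), `truth` (data.frame: `unit_id`, `sample_id`,
#'   `condition`, `true_type`, `marker_genes` attribute), `config`.
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "cell_sim_config"))
  set.seed(config$seed)
  types <- paste0("type", seq_len(config$n_types))
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  marker_idx <- split(seq_len(config$n_types * config$markers_per_type),
                      rep(seq_len(config$n_types), each = config$markers_per_type))
  names(marker_idx) <- types

  # per-condition type frequencies: uniform baseline times shift factors
  type_probs <- sapply(CONDITIONS, function(cond) {
    p <- rep(1, config$n_types)
    sh <- config$abundance_shift
    if (nrow(sh) > 0L) {
      rows <- which(sh$condition == cond)
      for (r in rows) p[match(sh$type[r], types)] <- p[match(sh$type[r], types)] * sh$factor[r]
    }
    p / sum(p)
  })

  # type-specific mean profiles (genes x types)
  mu_type <- matrix(config$base_mean, config$n_genes, config$n_types,
                    dimnames = list(genes, types))
  for (t in seq_len(config$n_types))
    mu_type[marker_idx[[t]], t] <- config$base_mean * 2^config$marker_logfc

  samples <- unlist(lapply(CONDITIONS, function(cond) {
    k <- config$samples_per_condition[cond]
    if (is.na(k) || k == 0L) character(0L) else paste0(cond, "_s", seq_len(k))
  }))
  cond_of_sample <- sub("_s[0-9]+$", "", samples)

  n_cells <- length(samples) * config$cells_per_sample
  cell_sample <- rep(samples, each = config$cells_per_sample)
  cell_cond <- rep(cond_of_sample, each = config$cells_per_sample)
  cell_type <- unlist(lapply(seq_along(samples), function(i) {
    sample(types, config$cells_per_sample, replace = TRUE,
           prob = type_probs[, cond_of_sample[i]])
  }))
  depth <- rlnorm(n_cells, meanlog = 0, sdlog = config$depth_variation)

  mu <- mu_type[, cell_type, drop = FALSE] *
    rep(depth, each = config$n_genes)
  vals <- rnbinom(length(mu), size = config$dispersion, mu = as.numeric(mu))
  counts <- count_matrix(matrix(vals, nrow = config$n_genes,
                                dimnames = list(genes, sprintf("cell%05d", seq_len(n_cells)))))
  ann <- annotation_table(colnames(counts), cell_sample, cell_cond)
  truth <- data.frame(unit_id = colnames(counts), sample_id = cell_sample,
                      condition = cell_cond, true_type = cell_type,
                      depth_factor = depth, stringsAsFactors = FALSE)
  attr(truth, "marker_genes") <- lapply(marker_idx, function(i) genes[i])
  attr(truth, "type_probs") <- type_probs
  list(counts = counts, annotation = ann, truth = truth, config = config)
}

#' Configuration for the TCR repertoire generator
#'
#' Per sample, `n_clones` unique clonotypes are drawn: the V segment from
#' the condition's usage vector, J uniformly, and the CDR3 as germline
#' prefix `CAS` + random amino-acid core + suffix `F`, with a
#' translation-consistent nucleotide junction (random synonymous codons).
#' Clone sizes follow a truncated zeta law. A `public_pool_fraction` of
#' clonotypes is drawn (without replacement) from a condition-shared pool,
#' creating inter-sample sharing. The default usage vectors encode the
#' disease effect the analysis must detect: the first vocabulary segment
#' (`TRBV28`) at 2% of unique clonotypes in HC versus 10% in ACD/TCD.
#'
#' @param v_vocabulary,j_vocabulary segment name vectors.
#' @param v_probs named list (per condition) of probability vectors over
#'   `v_vocabulary`, each summing to 1 within 1e-9.
#' @param n_clones unique clonotypes per sample.
#' @param expansion_shape zeta exponent for clone sizes (smaller = more
#'   expanded); sizes truncated at 1e4.
#' @param cdr3_core_length integer range `c(min, max)` of core lengths.
#' @param samples_per_condition named integer vector.
#' @param public_pool_fraction scalar or per-condition named vector in
#'   `[0, 1)`.
#' @param seed integer RNG seed.
#' @return a `repertoire_sim_config` list.
#' @export
repertoire_sim_config <- function(
    v_vocabulary = c("TRBV28", "TRBV2", "TRBV4-1", "TRBV5-1", "TRBV6-5",
                     "TRBV7-2", "TRBV9", "TRBV12-3", "TRBV15", "TRBV19",
                     "TRBV20-1", "TRBV30"),
    j_vocabulary = c("TRBJ1-1", "TRBJ1-2", "TRBJ2-1", "TRBJ2-3", "TRBJ2-7"),
    v_probs = NULL,
    n_clones = 5000L, expansion_shape = 2.5,
    cdr3_core_length = c(6L, 12L),
    samples_per_condition = c(HC = 8L, ACD = 7L, TCD = 5L),
    public_pool_fraction = 0.02, seed = 1L) {
  if (is.null(v_probs)) {
    nv <- length(v_vocabulary)
    rest <- function(p1) c(p1, rep((1 - p1) / (nv - 1L), nv - 1L))
    v_probs <- list(HC = rest(0.02), ACD = rest(0.10), TCD = rest(0.10))
  }
  check_conditions(names(samples_per_condition))
  for (cond in names(v_probs)) {
    p <- v_probs[[cond]]
    if (length(p) != length(v_vocabulary))
      abort_format("v_probs[%s] has length %d but vocabulary has %d segments",
                   cond, length(p), length(v_vocabulary))
    if (abs(sum(p) - 1) > 1e-9)
      abort_format("v_probs[%s] sums to %.12f, not 1", cond, sum(p))
  }
  stopifnot(n_clones >= 1L, expansion_shape > 0,
            length(cdr3_core_length) == 2L,
            cdr3_core_length[1L] >= 1L,
            cdr3_core_length[2L] >= cdr3_core_length[1L])
  if (length(public_pool_fraction) == 1L && is.null(names(public_pool_fraction)))
    public_pool_fraction <- setNames(rep(public_pool_fraction, 3L), CONDITIONS)
  stopifnot(all(public_pool_fraction >= 0), all(public_pool_fraction < 1))
  structure(list(v_vocabulary = v_vocabulary, j_vocabulary = j_vocabulary,
                 v_probs = v_probs, n_clones = as.integer(n_clones),
                 expansion_shape = expansion_shape,
                 cdr3_core_length = as.integer(cdr3_core_length),
                 samples_per_condition = samples_per_condition,
                 public_pool_fraction = public_pool_fraction,
                 seed = as.integer(seed)),
            class = "repertoire_sim_config")
}

# Vectorized CDR3 generation: n junctions with core lengths uniform in
# `len_range`, amino acids from the 20-letter alphabet, germline prefix
# "CAS" / suffix "F", nucleotides codon-wise with random synonymous codons.
# Works per length group so paste0 stays column-vectorized.
gen_cdr3 <- function(n, len_range) {
  lens <- if (len_range[1L] == len_range[2L]) rep(len_range[1L], n)
          else sample(seq(len_range[1L], len_range[2L]), n, replace = TRUE)
  aa <- character(n); nt <- character(n)
  cod_names <- names(CODONS_BY_AA)
  cod_n <- lengths(CODONS_BY_AA)
  cod_mat <- matrix(NA_character_, length(cod_names), max(cod_n),
                    dimnames = list(cod_names, NULL))
  for (a in cod_names) cod_mat[a, seq_len(cod_n[a])] <- CODONS_BY_AA[[a]]
  for (L in unique(lens)) {
    idx <- which(lens == L)
    full_len <- L + 4L  # CAS...F
    chars <- matrix(NA_character_, length(idx), full_len)
    chars[, 1L] <- "C"; chars[, 2L] <- "A"; chars[, 3L] <- "S"
    chars[, full_len] <- "F"
    chars[, 3L + seq_len(L)] <- sample(AA_ALPHABET, length(idx) * L, replace = TRUE)
    ci <- match(chars, cod_names)
    pick <- 1L + as.integer(floor(runif(length(ci)) * cod_n[ci]))
    codons <- matrix(cod_mat[cbind(ci, pick)], length(idx), full_len)
    aa[idx] <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
    nt[idx] <- do.call(paste0, as.data.frame(codons, stringsAsFactors = FALSE))
  }
  list(aa = aa, nt = nt)
}

# Truncated zeta clone-size sampler: P(k) proportional to k^-shape, k in
# 1..1e4.
rzeta_trunc <- function(n, shape, kmax = 1e4L) {
  k <- seq_len(kmax)
  sample(k, n, replace = TRUE, prob = k^(-shape))
}

#' Simulate per-sample TCR repertoires with ground truth
#'
#' @param config a [repertoire_sim_config()].
#' @return list with `table` (a `clonotype_table`, one row per unique
#'   clonotype per sample), `truth` (data.frame with `sample_id`,
#'   `clone_id`, `true_v`, `public`), `config`.
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "repertoire_sim_config"))
  set.seed(config$seed)
  vvoc <- config$v_vocabulary; jvoc <- config$j_vocabulary
  n <- config$n_clones

  # condition-shared public pools (size n per condition)
  pools <- lapply(CONDITIONS, function(cond) {
    p <- config$v_probs[[cond]] %||% rep(1 / length(vvoc), length(vvoc))
    v <- sample(vvoc, n, replace = TRUE, prob = p)
    j <- sample(jvoc, n, replace = TRUE)
    cd <- gen_cdr3(n, config$cdr3_core_length)
    data.frame(v_call = v, j_call = j, cdr3_nt = cd$nt, cdr3_aa = cd$aa,
               stringsAsFactors = FALSE)
  })
  names(pools) <- CONDITIONS

  rows <- list(); truths <- list()
  for (cond in CONDITIONS) {
    k <- config$samples_per_condition[cond]
    if (is.na(k) || k == 0L) next
    f <- config$public_pool_fraction[cond]
    for (s in seq_len(k)) {
      sid <- paste0(cond, "_r", s)
      n_pub <- rbinom(1L, n, f)
      pub_idx <- if (n_pub > 0L) sort(sample.int(n, n_pub)) else integer(0L)
      n_priv <- n - n_pub
      v <- sample(vvoc, n_priv, replace = TRUE, prob = config$v_probs[[cond]])
      j <- sample(jvoc, n_priv, replace = TRUE)
      cd <- gen_cdr3(n_priv, config$cdr3_core_length)
      df <- rbind(pools[[cond]][pub_idx, , drop = FALSE],
                  data.frame(v_call = v, j_call = j, cdr3_nt = cd$nt,
                             cdr3_aa = cd$aa, stringsAsFactors = FALSE))
      # drop intra-sample duplicate keys (rare hash-collision-like events)
      key <- paste(df$v_call, df$cdr3_nt)
      keep <- !duplicated(key)
      df <- df[keep, , drop = FALSE]
      m <- nrow(df)
      df$sample_id <- sid
      df$condition <- cond
      df$count <- rzeta_trunc(m, config$expansion_shape)
      rows[[sid]] <- df
      truths[[sid]] <- data.frame(sample_id = sid,
                                  clone_id = paste0(sid, "_c", seq_len(m)),
                                  true_v = df$v_call,
                                  public = seq_len(m) <= length(pub_idx),
                                  stringsAsFactors = FALSE)
    }
  }
  all <- do.call(rbind, rows)
  rownames(all) <- NULL
  tab <- clonotype_table(all, v_vocabulary = vvoc, j_vocabulary = jvoc)
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  list(table = tab, truth = truth, config = config)
}

#' Configuration for the spatial spot-lattice generator
#'
#' The slide is a `n_rows x n_cols` lattice (hex, odd-row-shifted, or
#' square). Regions come from horizontal bands emulating the crypt-villus
#' axis, overridden by circular "lymphoid aggregate" foci. Each region has
#' a cell-type composition vector; each spot's expected expression is the
#' signature matrix times its region's composition, scaled to a target
#' depth, with negative-binomial noise.
#'
#' @param lattice `"hex"` or `"square"`.
#' @param n_rows,n_cols lattice size.
#' @param bands data.frame (`row_from`, `row_to`, `region`), 0-based
#'   inclusive row ranges; must cover every row.
#' @param circles data.frame (`row`, `col`, `radius`, `region`) of focal
#'   regions overriding the bands.
#' @param composition named list region -> probability vector over cell
#'   types (each sums to 1).
#' @param signatures genes x types non-negative mean matrix; defaults to
#'   120 genes with 15 markers per type at 16x background.
#' @param depth expected total counts per spot.
#' @param noise_dispersion NB size parameter; `Inf` means Poisson.
#' @param seed integer RNG seed.
#' @return a `spatial_sim_config` list.
#' @export
spatial_sim_config <- function(
    lattice = "hex", n_rows = 30L, n_cols = 30L,
    bands = data.frame(row_from = c(0L, 8L, 15L, 22L),
                       row_to = c(7L, 14L, 21L, 29L),
                       region = c("villus_tip", "mid_villus", "crypt",
                                  "stem_niche")),
    circles = data.frame(row = 24L, col = 8L, radius = 3.2,
                         region = "lymphoid_aggregate"),
    composition = NULL, signatures = NULL,
    depth = 10000, noise_dispersion = 10, seed = 1L) {
  types <- c("enterocyte", "stem", "TRM", "Tfh", "Bcell", "plasma")
  if (is.null(composition)) {
    composition <- list(
      villus_tip = c(0.80, 0.02, 0.10, 0.02, 0.03, 0.03),
      mid_villus = c(0.60, 0.10, 0.12, 0.04, 0.06, 0.08),
      crypt = c(0.30, 0.40, 0.10, 0.05, 0.05, 0.10),
      stem_niche = c(0.10, 0.60, 0.08, 0.05, 0.07, 0.10),
      lymphoid_aggregate = c(0.05, 0.05, 0.15, 0.25, 0.35, 0.15))
    composition <- lapply(composition, function(p) setNames(p, types))
  }
  if (is.null(signatures)) {
    tt <- names(composition[[1L]])
    n_genes <- 20L * length(tt)
    sig <- matrix(0.5, n_genes, length(tt),
                  dimnames = list(sprintf("sgene%03d", seq_len(n_genes)), tt))
    for (t in seq_along(tt))
      sig[(t - 1L) * 20L + seq_len(15L), t] <- 8
    signatures <- sig
  }
  for (r in names(composition)) {
    p <- composition[[r]]
    if (abs(sum(p) - 1) > 1e-9)
      abort_format("composition[%s] sums to %.12f, not 1", r, sum(p))
    if (length(p) != ncol(signatures))
      abort_format("composition[%s] length != number of signature types", r)
  }
  stopifnot(lattice %in% c("hex", "square"), n_rows >= 1L, n_cols >= 1L,
            depth > 0, noise_dispersion > 0, all(signatures >= 0))
  structure(list(lattice = lattice, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), bands = bands,
                 circles = circles, composition = composition,
                 signatures = signatures, depth = depth,
                 noise_dispersion = noise_dispersion, seed = as.integer(seed)),
            class = "spatial_sim_config")
}

# Geometric x/y of lattice coordinates; hex rows are offset half a column
# on odd rows and packed at sqrt(3)/2 vertical pitch.
lattice_xy <- function(array_row, array_col, lattice) {
  if (lattice == "hex")
    cbind(x = array_col + 0.5 * (array_row %% 2L), y = array_row * sqrt(3) / 2)
  else cbind(x = as.numeric(array_col), y = as.numeric(array_row))
}

#' Simulate a spatial transcriptomics slide with ground truth
#'
#' @param config a [spatial_sim_config()].
#' @return list with `spatial` (a `spatial_dataset`, `region` unset),
#'   `truth` (data.frame `spot_id`, `region` plus a spots x types
#'   `composition` matrix attribute), `config`.
#' @export
simulate_spatial <- function(config) {
  stopifnot(inherits(config, "spatial_sim_config"))
  set.seed(config$seed)
  grid <- expand.grid(array_col = seq_len(config$n_cols) - 1L,
                      array_row = seq_len(config$n_rows) - 1L)
  grid <- grid[, c("array_row", "array_col")]
  region <- rep(NA_character_, nrow(grid))
  for (b in seq_len(nrow(config$bands))) {
    hit <- grid$array_row >= config$bands$row_from[b] &
           grid$array_row <= config$bands$row_to[b]
    region[hit] <- config$bands$region[b]
  }
  xy <- lattice_xy(grid$array_row, grid$array_col, config$lattice)
  if (!is.null(config$circles) && nrow(config$circles) > 0L) {
    for (ci in seq_len(nrow(config$circles))) {
      cxy <- lattice_xy(config$circles$row[ci], config$circles$col[ci],
                        config$lattice)
      d <- sqrt((xy[, 1L] - cxy[1L])^2 + (xy[, 2L] - cxy[2L])^2)
      region[d <= config$circles$radius[ci]] <- config$circles$region[ci]
    }
  }
  if (anyNA(region))
    abort_format("region layout leaves %d lattice position(s) uncovered",
                 sum(is.na(region)))
  S <- config$signatures
  types <- colnames(S)
  comp <- t(vapply(region, function(r) {
    p <- config$composition[[r]]
    if (is.null(p)) abort_format("no composition declared for region '%s'", r)
    as.numeric(p)
  }, numeric(ncol(S))))
  colnames(comp) <- types
  profile <- S %*% t(comp)                       # genes x spots
  profile <- sweep(profile, 2L, colSums(profile), "/")
  mu <- profile * config$depth
  vals <- if (is.infinite(config$noise_dispersion)) rpois(length(mu), as.numeric(mu))
          else rnbinom(length(mu), size = config$noise_dispersion, mu = as.numeric(mu))
  spot_ids <- sprintf("spot%04d", seq_len(nrow(grid)))
  counts <- count_matrix(matrix(vals, nrow = nrow(S),
                                dimnames = list(rownames(S), spot_ids)))
  sp <- spatial_dataset(counts, grid$array_row, grid$array_col,
                        lattice = config$lattice)
  truth <- data.frame(spot_id = spot_ids, region = region,
                      stringsAsFactors = FALSE)
  rownames(comp) <- spot_ids
  attr(truth, "composition") <- comp
  list(spatial = sp, truth = truth, config = config)
}
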