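# Core data containers and their validators. Counts are kept as sparse
# Matrix::dgCMatrix objects (genes x units) with dimnames; annotation and
# clonotype tables are plain data.frames so they compose with base tooling.

#' Construct a validated sparse count matrix
#'
#' Genes are rows, units (cell barcodes or spot ids) are columns. Entries
#' must be non-negative integers; ids must be unique. Zero entries are not
#' materialized.
#'
#' @param values matrix-like of counts (dense or sparse), genes x units.
#' @param gene_ids,unit_ids character vectors naming rows/columns; taken
#'   from `dimnames(values)` when omitted.
#' @return a `dgCMatrix` with dimnames set.
#' @export
count_matrix <- function(values, gene_ids = NULL, unit_ids = NULL) {
  m <- as(as(as(values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (!is.null(gene_ids)) rownames(m) <- gene_ids
  if (!is.null(unit_ids)) colnames(m) <- unit_ids
  validate_counts(m)
  m
}

#' Validate count-matrix invariants
#'
#' @param m a genes x units matrix with dimnames.
#' @return `m` invisibly; errors name the violated invariant and offending id.
#' @export
validate_counts <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    abort_format("count matrix must carry gene and unit names")
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup) > 0L)
    abort_format("duplicated gene id(s): %s", paste(unique(dup), collapse = ", "))
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup) > 0L)
    abort_format("duplicated unit id(s): %s", paste(unique(dup), collapse = ", "))
  x <- if (is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(x) > 0L) {
    if (any(x < 0)) abort_format("count matrix has negative entries")
    if (any(x != floor(x))) abort_format("count matrix has non-integer entries")
  }
  invisible(m)
}

#' Construct a validated annotation table
#'
#' One row per unit, pairing each cell/spot with its sample, disease
#' condition and (optionally, post-clustering) cluster label.
#'
#' @param unit_id,sample_id character vectors.
#' @param condition character vector over `HC`, `ACD`, `TCD`.
#' @param cluster optional character vector; `NA` before clustering.
#' @param counts optional paired count matrix; when given, every `unit_id`
#'   must be one of its columns.
#' @return a `data.frame` of class `celiac_annotation`.
#' @export
annotation_table <- function(unit_id, sample_id, condition, cluster = NA_character_,
                             counts = NULL) {
  if (anyDuplicated(unit_id))
    abort_format("duplicated unit_id(s): %s",
                 paste(unique(unit_id[duplicated(unit_id)]), collapse = ", "))
  check_conditions(condition)
  ann <- data.frame(unit_id = as.character(unit_id),
                    sample_id = as.character(sample_id),
                    condition = as.character(condition),
                    cluster = rep_len(as.character(cluster), length(unit_id)),
                    stringsAsFactors = FALSE)
  if (!is.null(counts)) {
    missing <- setdiff(ann$unit_id, colnames(counts))
    if (length(missing) > 0L)
      abort_format("unit_id(s) absent from count matrix: %s",
                   paste(head(missing, 5L), collapse = ", "))
  }
  class(ann) <- c("celiac_annotation", "data.frame")
  ann
}

#' Construct a validated clonotype table
#'
#' One row per (sample, clonotype) with IMGT-style V/J segment calls, the
#' CDR3 junction in nucleotide and/or amino-acid space, and a template
#' count. Segment calls outside the supplied vocabulary are retained and
#' flagged in the `v_flag` column, never dropped.
#'
#' @param df data.frame with columns `sample_id`, `condition`, `v_call`,
#'   `j_call`, `cdr3_nt`, `cdr3_aa`, `count`; `cluster` optional.
#' @param v_vocabulary,j_vocabulary optional character vectors of known
#'   segment names used to set the flag columns.
#' @return a `data.frame` of class `clonotype_table`.
#' @export
clonotype_table <- function(df, v_vocabulary = NULL, j_vocabulary = NULL) {
  need <- c("sample_id", "condition", "v_call", "j_call", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    abort_format("clonotype table missing column(s): %s", paste(miss, collapse = ", "))
  if (is.null(df$cdr3_nt)) df$cdr3_nt <- NA_character_
  if (is.null(df$cdr3_aa)) df$cdr3_aa <- NA_character_
  if (is.null(df$cluster)) df$cluster <- NA_character_
  check_conditions(df$condition)
  df$count <- as.integer(df$count)
  if (any(is.na(df$count)) || any(df$count < 1L))
    abort_format("clonotype counts must be integers >= 1")
  both <- !is.na(df$cdr3_nt) & !is.na(df$cdr3_aa)
  if (any(both)) {
    tr <- translate_nt(df$cdr3_nt[both])
    bad <- which(!is.na(tr) & tr != df$cdr3_aa[both])
    if (length(bad) > 0L)
      abort_format("cdr3_aa inconsistent with translation of cdr3_nt in %d row(s), e.g. %s",
                   length(bad), df$cdr3_nt[both][bad[1L]])
  }
  df$v_flag <- if (is.null(v_vocabulary)) TRUE else df$v_call %in% v_vocabulary
  df$j_flag <- if (is.null(j_vocabulary)) TRUE else df$j_call %in% j_vocabulary
  if (!all(df$v_flag))
    warning(sprintf("%d row(s) carry v_call outside the vocabulary (retained, flagged): %s",
                    sum(!df$v_flag),
                    paste(head(unique(df$v_call[!df$v_flag]), 3L), collapse = ", ")),
            call. = FALSE)
  out <- df[, c("sample_id", "condition", "cluster", "v_call", "j_call",
                "cdr3_nt", "cdr3_aa", "count", "v_flag", "j_flag")]
  class(out) <- c("clonotype_table", "data.frame")
  out
}

#' Construct a validated spatial dataset
#'
#' A spot lattice (Visium-style hex with odd-row shift, or square grid)
#' with 0-based integer array coordinates, a spots count matrix and an
#' optional per-spot region label.
#'
#' @param counts genes x spots count matrix; column names are the spot ids.
#' @param array_row,array_col integer lattice coordinates per spot, in spot
#'   (column) order.
#' @param lattice `"hex"` or `"square"`.
#' @param region optional character region label per spot.
#' @param sample_id optional sample label per spot (single slide by default).
#' @return an object of class `spatial_dataset`: list with elements
#'   `spots`, `lattice`, `array_row`, `array_col`, `counts`, `region`,
#'   `sample_id`.
#' @export
spatial_dataset <- function(counts, array_row, array_col,
                            lattice = c("hex", "square"),
                            region = NULL, sample_id = NULL) {
  lattice <- match.arg(lattice)
  validate_counts(counts)
  spots <- colnames(counts)
  n <- length(spots)
  if (length(array_row) != n || length(array_col) != n)
    abort_format("coordinate length does not match number of spots")
  array_row <- as.integer(array_row); array_col <- as.integer(array_col)
  key <- paste(array_row, array_col)
  if (anyDuplicated(key))
    abort_format("duplicate lattice coordinate(s): %s",
                 paste(head(unique(key[duplicated(key)]), 3L), collapse = "; "))
  if (!is.null(region)) {
    region <- as.character(region)
    if (length(region) != n) abort_format("region length does not match spots")
  }
  if (is.null(sample_id)) sample_id <- rep("slide1", n)
  structure(list(spots = spots, lattice = lattice,
                 array_row = array_row, array_col = array_col,
                 counts = counts, region = region,
                 sample_id = as.character(sample_id)),
            class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d spots (%s lattice), %d genes, %s\n",
              length(x$spots), x$lattice, nrow(x$counts),
              if (is.null(x$region)) "no regions"
              else sprintf("%d regions", length(unique(x$region)))))
  invisible(x)
}

#' Construct a gene set
#'
#' @param name set label.
#' @param genes character vector of gene ids; must be non-empty, duplicates
#'   removed.
#' @return list of class `gene_set` with `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) abort_format("gene set '%s' is empty", name)
  structure(list(name = as.character(name), genes = genes), class = "gene_set")
}

#' Construct a receptor-ligand pair list
#'
#' @param ligand,receptor gene ids.
#' @param pair_name unique pair labels; default `"ligand_receptor"`.
#' @return data.frame of class `rl_pairs`.
#' @export
rl_pairs <- function(ligand, receptor, pair_name = NULL) {
  if (is.null(pair_name)) pair_name <- paste(ligand, receptor, sep = "_")
  if (anyDuplicated(pair_name))
    abort_format("duplicated pair_name(s): %s",
                 paste(unique(pair_name[duplicated(pair_name)]), collapse = ", "))
  out <- data.frame(pair_name = as.character(pair_name),
                    ligand = as.character(ligand),
                    receptor = as.character(receptor),
                    stringsAsFactors = FALSE)
  class(out) <- c("rl_pairs", "data.frame")
  out
}

# Standard-code translation of in-frame nucleotide strings; NA when the
# length is not a multiple of 3 or a codon is unknown. Vectorized by
# length group (repertoires hold millions of junctions).
translate_nt <- function(nt) {
  out <- rep(NA_character_, length(nt))
  len <- nchar(nt)
  ok <- !is.na(nt) & len %% 3L == 0L & len > 0L
  for (L in unique(len[ok])) {
    idx <- which(ok & len == L)
    k <- L %/% 3L
    aa <- matrix(NA_character_, length(idx), k)
    for (j in seq_len(k))
      aa[, j] <- GENETIC_CODE_MAP[toupper(substr(nt[idx], 3L * j - 2L, 3L * j))]
    res <- do.call(paste0, as.data.frame(aa, stringsAsFactors = FALSE))
    res[rowSums(is.na(aa)) > 0L] <- NA_character_
    out[idx] <- res
  }
  out
}

# Codon table for the standard genetic code, built once at load.
GENETIC_CODE_MAP <- local({
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), times = 4L),
                   rep(bases, times = 16L))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1L]]
  setNames(aa, codons)
})

# Codons per amino acid (stop codons excluded), used by the repertoire
# simulator to emit translation-consistent nucleotide junctions.
CODONS_BY_AA <- local({
  keep <- GENETIC_CODE_MAP != "*"
  split(names(GENETIC_CODE_MAP)[keep], GENETIC_CODE_MAP[keep])
})
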