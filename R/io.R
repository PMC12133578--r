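# Readers and writers for the on-disk interchange formats: MatrixMarket
# count triplets with side-car name files, dense TSV (small fixtures),
# annotation TSV, AIRR-C rearrangement TSV, spot coordinate TSV, GMT gene
# sets, receptor-ligand pair TSV and edge-list TSV. Readers preserve file
# order and never silently reorder.

#' Read a count matrix
#'
#' Either a MatrixMarket coordinate file with matching row (gene) and
#' column (unit) name files, or a dense TSV with a header row of unit ids
#' and gene ids in the first column (fixtures up to 1000 x 1000).
#'
#' @param matrix_path path to `.mtx` or dense `.tsv`.
#' @param genes_path,units_path name files (one id per line) for the MTX
#'   route; ignored for dense TSV.
#' @return a validated sparse count matrix (genes x units).
#' @export
read_counts <- function(matrix_path, genes_path = NULL, units_path = NULL) {
  if (grepl("\\.mtx$", matrix_path)) {
    m <- as(Matrix::readMM(matrix_path), "CsparseMatrix")
    genes <- readLines(genes_path)
    units <- readLines(units_path)
    if (nrow(m) != length(genes) || ncol(m) != length(units))
      abort_format("matrix is %d x %d but name files have %d genes / %d units",
                   nrow(m), ncol(m), length(genes), length(units))
    count_matrix(m, gene_ids = genes, unit_ids = units)
  } else {
    df <- read_tsv(matrix_path)
    if (nrow(df) > 1000L || ncol(df) > 1001L)
      abort_format("dense TSV fixtures are limited to 1000 x 1000; use MatrixMarket")
    genes <- as.character(df[[1L]])
    vals <- as.matrix(df[, -1L, drop = FALSE])
    count_matrix(vals, gene_ids = genes, unit_ids = colnames(df)[-1L])
  }
}

#' Write a count matrix as MatrixMarket plus name files
#'
#' @param m count matrix.
#' @param matrix_path,genes_path,units_path output paths.
#' @return `matrix_path` invisibly.
#' @export
write_counts <- function(m, matrix_path, genes_path, units_path) {
  validate_counts(m)
  Matrix::writeMM(m, matrix_path)
  writeLines(rownames(m), genes_path)
  writeLines(colnames(m), units_path)
  invisible(matrix_path)
}

#' Read / write an annotation table
#'
#' @param path TSV with columns `unit_id`, `sample_id`, `condition` and
#'   optionally `cluster`.
#' @param counts optional paired count matrix for cross-validation.
#' @return `read_annotation`: a `celiac_annotation` data.frame.
#' @export
read_annotation <- function(path, counts = NULL) {
  df <- read_tsv(path)
  need <- c("unit_id", "sample_id", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    abort_format("annotation file missing column(s): %s", paste(miss, collapse = ", "))
  annotation_table(df$unit_id, df$sample_id, df$condition,
                   cluster = df$cluster %||% NA_character_, counts = counts)
}

#' @rdname read_annotation
#' @param ann annotation table to write.
#' @export
write_annotation <- function(ann, path) {
  write_tsv(as.data.frame(ann)[, c("unit_id", "sample_id", "condition", "cluster")],
            path)
}

# AIRR-C rearrangement column dialect accepted on input.
.airr_cols <- c(sample = "repertoire_id", v = "v_call", j = "j_call",
                nt = "junction", aa = "junction_aa", n = "duplicate_count")

#' Read a clonotype table from AIRR-C rearrangement TSV
#'
#' Accepts `repertoire_id` or `sample_id` for the sample column and
#' defaults `duplicate_count` to 1 when absent. Requires a `condition`
#' column (or a `sample -> condition` map via `conditions`).
#'
#' @param path rearrangement TSV.
#' @param v_vocabulary,j_vocabulary segment vocabularies; out-of-vocabulary
#'   calls are retained and flagged.
#' @param conditions optional named character vector mapping sample_id to
#'   condition when the file has no `condition` column.
#' @return a `clonotype_table`.
#' @export
read_clonotypes <- function(path, v_vocabulary = NULL, j_vocabulary = NULL,
                            conditions = NULL) {
  df <- read_tsv(path)
  sample_col <- intersect(c("repertoire_id", "sample_id"), names(df))[1L]
  if (is.na(sample_col)) abort_format("clonotype file missing column(s): repertoire_id/sample_id")
  miss <- setdiff(c("v_call", "j_call"), names(df))
  if (length(miss) > 0L)
    abort_format("clonotype file missing column(s): %s", paste(miss, collapse = ", "))
  if (!"junction_aa" %in% names(df) && !"junction" %in% names(df))
    abort_format("clonotype file missing column(s): junction or junction_aa")
  cond <- if ("condition" %in% names(df)) df$condition
          else if (!is.null(conditions)) unname(conditions[as.character(df[[sample_col]])])
          else abort_format("no condition column and no sample->condition map supplied")
  count <- if ("duplicate_count" %in% names(df)) {
    x <- df$duplicate_count
    x[is.na(x)] <- 1L
    x
  } else rep(1L, nrow(df))
  clonotype_table(
    data.frame(sample_id = as.character(df[[sample_col]]), condition = cond,
               cluster = df$cluster %||% NA_character_,
               v_call = df$v_call, j_call = df$j_call,
               cdr3_nt = df$junction %||% NA_character_,
               cdr3_aa = df$junction_aa %||% NA_character_,
               count = count, stringsAsFactors = FALSE),
    v_vocabulary = v_vocabulary, j_vocabulary = j_vocabulary)
}

#' Write a clonotype table as AIRR-C rearrangement TSV
#'
#' @param tab clonotype table.
#' @param path output TSV.
#' @export
write_clonotypes <- function(tab, path) {
  write_tsv(data.frame(repertoire_id = tab$sample_id, condition = tab$condition,
                       cluster = tab$cluster, v_call = tab$v_call,
                       j_call = tab$j_call, junction = tab$cdr3_nt,
                       junction_aa = tab$cdr3_aa, duplicate_count = tab$count,
                       stringsAsFactors = FALSE), path)
}

#' Read / write a spatial dataset
#'
#' Counts come from the MatrixMarket trio; coordinates from a TSV with
#' `spot_id`, `array_row`, `array_col` and optional `region`/`sample_id`.
#' Spots listed in the coordinate file but absent from the counts are an
#' error; count columns are reordered to coordinate-file order.
#'
#' @param matrix_path,genes_path,units_path count matrix files.
#' @param coords_path coordinate TSV.
#' @param lattice `"hex"` or `"square"`.
#' @return a `spatial_dataset`.
#' @export
read_spatial <- function(matrix_path, genes_path, units_path, coords_path,
                         lattice = c("hex", "square")) {
  lattice <- match.arg(lattice)
  counts <- read_counts(matrix_path, genes_path, units_path)
  co <- read_tsv(coords_path)
  miss <- setdiff(c("spot_id", "array_row", "array_col"), names(co))
  if (length(miss) > 0L)
    abort_format("coordinate file missing column(s): %s", paste(miss, collapse = ", "))
  absent <- setdiff(co$spot_id, colnames(counts))
  if (length(absent) > 0L)
    abort_format("spot(s) missing from count matrix: %s",
                 paste(head(absent, 5L), collapse = ", "))
  counts <- counts[, as.character(co$spot_id), drop = FALSE]
  spatial_dataset(counts, co$array_row, co$array_col, lattice = lattice,
                  region = co$region, sample_id = co$sample_id)
}

#' @rdname read_spatial
#' @param sp spatial dataset to write.
#' @export
write_spatial <- function(sp, matrix_path, genes_path, units_path, coords_path) {
  write_counts(sp$counts, matrix_path, genes_path, units_path)
  co <- data.frame(spot_id = sp$spots, array_row = sp$array_row,
                   array_col = sp$array_col, sample_id = sp$sample_id,
                   stringsAsFactors = FALSE)
  if (!is.null(sp$region)) co$region <- sp$region
  write_tsv(co, coords_path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: per line, name, description, then gene ids,
#'   tab-separated.
#' @return named list of `gene_set` objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) abort_format("malformed GMT line: %s", substr(l, 1, 40))
    gene_set(f[1L], f[-(1:2)])
  })
  setNames(sets, vapply(sets, `[[`, character(1L), "name"))
}

#' Read a receptor-ligand pair list from TSV
#'
#' @param path TSV with columns `ligand`, `receptor` and optional
#'   `pair_name`.
#' @return an `rl_pairs` data.frame.
#' @export
read_rl_pairs <- function(path) {
  df <- read_tsv(path)
  miss <- setdiff(c("ligand", "receptor"), names(df))
  if (length(miss) > 0L)
    abort_format("pair file missing column(s): %s", paste(miss, collapse = ", "))
  rl_pairs(df$ligand, df$receptor, df$pair_name)
}

#' Write a weighted edge list as TSV
#'
#' @param edges data.frame with columns `source`, `target`, `weight`.
#' @param path output TSV.
#' @export
write_edge_list <- function(edges, path) {
  write_tsv(edges[, c("source", "target", "weight")], path)
}
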