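# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_format <- function(...) stop(sprintf(...), call. = FALSE)

#' Validate a condition label vector
#'
#' @param x character vector of condition labels.
#' @return `x`, invisibly, after checking membership in `HC`/`ACD`/`TCD`.
#' @keywords internal
check_conditions <- function(x) {
  bad <- setdiff(unique(as.character(x)), CONDITIONS)
  if (length(bad) > 0L)
    abort_format("unknown condition label(s): %s (allowed: %s)",
                 paste(bad, collapse = ", "), paste(CONDITIONS, collapse = ", "))
  invisible(x)
}

# Deterministic TSV writer used by every CLI stage so reruns are
# byte-identical: fixed quoting, NA representation and no row names.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

# Benjamini-Hochberg wrapper that tolerates NAs.
bh <- function(p) p.adjust(p, method = "BH")

# Draw a reproducible child seed below 2^31 from a parent seed and stream id.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1000L + as.integer(stream)) %% 2147483587L
}

# Trapezoid integration on a regular-or-not grid.
trapz <- function(x, y) sum(diff(x) * (head(y, -1L) + y[-1L]) / 2)

# Mean expression decile bins used by expression-matched background sampling.
# Returns an integer bin id per gene (1..n_bins), computed on `means`.
expression_bins <- function(means, n_bins = 10L) {
  br <- unique(quantile(means, probs = seq(0, 1, length.out = n_bins + 1L),
                        names = FALSE))
  if (length(br) < 2L) return(rep(1L, length(means)))
  findInterval(means, br, rightmost.closed = TRUE, all.inside = TRUE)
}
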