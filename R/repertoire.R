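# TCR repertoire statistics: clonotype aggregation, Morisita-Horn overlap,
# negative-binomial V-segment usage tests, expansion structure (top-n and
# quintile enrichment), CDR3 amino-acid composition, motif frequencies and
# inter-sample sharing.

clonotype_key <- function(tab, key_mode) {
  switch(key_mode,
         nt = tab$cdr3_nt,
         aa = tab$cdr3_aa,
         v_nt = paste(tab$v_call, tab$cdr3_nt, sep = "|"),
         v_aa = paste(tab$v_call, tab$cdr3_aa, sep = "|"),
         abort_format("unknown key_mode '%s'", key_mode))
}

#' Aggregate a clonotype table into per-group count vectors
#'
#' Counts are summed over duplicate keys within each group (sample or
#' cluster). The default key is (V segment, CDR3 nucleotide); amino-acid
#' modes merge nucleotide synonyms.
#'
#' @param tab a `clonotype_table`.
#' @param key_mode one of `"v_nt"` (default), `"v_aa"`, `"nt"`, `"aa"`.
#' @param by grouping column, `"sample_id"` (default) or `"cluster"`.
#' @return named list of clonotype vectors (named numeric count vectors),
#'   one per group; attributes `key_mode`, `unique_clonotypes` and
#'   `total_templates` summarize each group.
#' @export
aggregate_clonotypes <- function(tab, key_mode = "v_nt", by = "sample_id") {
  if (nrow(tab) == 0L) abort_format("empty clonotype table")
  key <- clonotype_key(tab, key_mode)
  groups <- as.character(tab[[by]])
  if (by == "cluster" && all(is.na(groups)))
    abort_format("no cluster labels in the clonotype table")
  vecs <- lapply(split(seq_len(nrow(tab)), groups), function(i) {
    v <- tapply(tab$count[i], key[i], sum)
    # preserve first-appearance order, not alphabetical
    v[unique(key[i])]
  })
  structure(vecs, key_mode = key_mode,
            unique_clonotypes = vapply(vecs, length, integer(1L)),
            total_templates = vapply(vecs, sum, numeric(1L)))
}

#' Morisita-Horn overlap of two clonotype count vectors
#'
#' `MH = 2 sum(x_i y_i) / ((sum(x_i^2)/X^2 + sum(y_i^2)/Y^2) * X * Y)`
#' over the union of keys, with `X = sum(x)`, `Y = sum(y)`. Ranges from 0
#' (disjoint) to 1 (identical composition); abundance-weighted and
#' scale-invariant.
#'
#' @param A,B named numeric count vectors (keys as names).
#' @return scalar in `[0, 1]`.
#' @export
morisita_horn <- function(A, B) {
  if (length(A) == 0L || length(B) == 0L) abort_format("empty clonotype vector")
  X <- sum(A); Y <- sum(B)
  if (X <= 0 || Y <= 0) abort_format("clonotype vector with non-positive total")
  keys <- union(names(A), names(B))
  x <- unname(A[keys]); x[is.na(x)] <- 0
  y <- unname(B[keys]); y[is.na(y)] <- 0
  2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
}

#' Morisita-Horn overlap matrix between groups
#'
#' @param vecs list of clonotype vectors from [aggregate_clonotypes()].
#' @return symmetric matrix of pairwise overlaps with unit diagonal.
#' @export
morisita_horn_matrix <- function(vecs) {
  n <- length(vecs)
  M <- diag(1, n)
  dimnames(M) <- list(names(vecs), names(vecs))
  if (n < 2L) return(M)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    M[i, j] <- M[j, i] <- morisita_horn(vecs[[i]], vecs[[j]])
  M
}

# Per-sample segment x sample count matrix of unique clonotypes (or
# template sums), given a clonotype table.
segment_counts <- function(tab, count_type = c("unique", "templates")) {
  count_type <- match.arg(count_type)
  w <- if (count_type == "unique") rep(1, nrow(tab)) else tab$count
  xt <- stats::xtabs(w ~ v_call + sample_id, data = cbind(tab, w = w))
  m <- matrix(as.numeric(xt), nrow(xt), ncol(xt), dimnames = dimnames(xt))
  m
}

#' Negative-binomial V-segment usage test between condition groups
#'
#' Per segment, NB regression of per-sample segment counts on group with
#' log-offset = log(per-sample total); the dispersion is estimated by
#' pooled method-of-moments on Poisson residuals (floored at 1e-8) and the
#' group effect is tested two-sided by Wald. BH across segments. Each
#' segment is classed `high` when it carries more than `high_freq_cut` of
#' pooled clones, else `low`.
#'
#' @param tab a `clonotype_table`.
#' @param groups length-2 character vector of condition labels (first vs
#'   second; positive lfc = higher usage in the first).
#' @param count_type count unique clonotypes (default, the repertoire
#'   reading) or sum templates.
#' @param high_freq_cut pooled-frequency cut for the frequency class.
#' @return data.frame of class `v_usage_result`: per segment `lfc` (log2),
#'   `p`, `q`, `freq_class`, group mean rates and the dispersion used.
#'   Segments absent everywhere are dropped and reported via attribute
#'   `dropped`.
#' @export
v_usage_test <- function(tab, groups = c("ACD", "HC"),
                         count_type = c("unique", "templates"),
                         high_freq_cut = 0.01) {
  count_type <- match.arg(count_type)
  tab <- tab[tab$condition %in% groups, , drop = FALSE]
  cnt <- segment_counts(tab, count_type)
  sample_cond <- tapply(tab$condition, tab$sample_id, `[`, 1L)
  sample_cond <- sample_cond[colnames(cnt)]
  if (any(table(factor(sample_cond, levels = groups)) < 2L))
    abort_format("both groups need >= 2 samples")
  totals <- colSums(cnt)
  pooled_frac <- rowSums(cnt) / sum(cnt)
  dropped <- rownames(cnt)[rowSums(cnt) == 0]
  cnt <- cnt[rowSums(cnt) > 0, , drop = FALSE]
  grp <- factor(sample_cond, levels = rev(groups))  # 2nd level = first group
  res <- do.call(rbind, lapply(rownames(cnt), function(seg) {
    y <- cnt[seg, ]
    fit0 <- glm(y ~ grp + offset(log(totals)), family = poisson())
    mu <- fit0$fitted.values
    alpha <- max(1e-8, sum((y - mu)^2 - mu) / sum(mu^2))
    theta <- 1 / alpha
    fit <- tryCatch(
      glm(y ~ grp + offset(log(totals)),
          family = MASS::negative.binomial(theta = theta)),
      error = function(e) fit0, warning = function(w) suppressWarnings(
        glm(y ~ grp + offset(log(totals)),
            family = MASS::negative.binomial(theta = theta))))
    co <- summary(fit)$coefficients
    if (nrow(co) < 2L || is.na(co[2L, 2L]) || co[2L, 2L] == 0) {
      est <- 0; p <- 1
    } else {
      est <- co[2L, 1L]
      # Wald statistic against a t reference with residual df: the normal
      # reference is anti-conservative at 5-10 samples per group
      p <- 2 * stats::pt(-abs(co[2L, 1L] / co[2L, 2L]), df = fit$df.residual)
    }
    rate <- tapply(y / totals, grp, mean)
    data.frame(segment = seg, lfc = est / log(2), p = p,
               rate_groupA = unname(rate[groups[1L]]),
               rate_groupB = unname(rate[groups[2L]]),
               dispersion_alpha = alpha,
               freq_class = if (pooled_frac[seg] > high_freq_cut) "high" else "low",
               stringsAsFactors = FALSE)
  }))
  res$q <- bh(res$p)
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  attr(res, "groups") <- groups
  class(res) <- c("v_usage_result", "data.frame")
  res
}

#' Per-sample fraction of unique clonotypes using a segment
#'
#' @param tab a `clonotype_table`.
#' @param segment V segment name (e.g. `"TRBV28"`).
#' @param key_mode clonotype key for uniqueness.
#' @return named numeric vector, one fraction per sample.
#' @export
unique_v_fraction <- function(tab, segment, key_mode = "v_nt") {
  if (nrow(tab) == 0L) abort_format("empty clonotype table")
  vapply(split(seq_len(nrow(tab)), tab$sample_id), function(i) {
    sub <- tab[i, , drop = FALSE]
    key <- clonotype_key(sub, key_mode)
    v <- sub$v_call[match(unique(key), key)]
    mean(v == segment)
  }, numeric(1L))
}

#' Per-sample segment fraction among the top expanded clonotypes
#'
#' Unique clonotypes are ranked by count (descending, ties by first
#' appearance); the fraction of the top `n` carrying `segment` is
#' returned. Samples with fewer than `n` clonotypes use all of them and
#' are flagged via the `used_all` attribute.
#'
#' @inheritParams unique_v_fraction
#' @param n number of top clonotypes (default 100).
#' @return named numeric vector per sample; attribute `used_all` marks
#'   samples smaller than `n`.
#' @export
top_expanded_v_fraction <- function(tab, segment, n = 100L, key_mode = "v_nt") {
  used_all <- logical(0L)
  out <- vapply(split(seq_len(nrow(tab)), tab$sample_id), function(i) {
    sub <- tab[i, , drop = FALSE]
    key <- clonotype_key(sub, key_mode)
    cnt <- tapply(sub$count, key, sum)[unique(key)]
    vseg <- sub$v_call[match(names(cnt), key)]
    ord <- order(-cnt, seq_along(cnt))
    k <- min(n, length(cnt))
    used_all <<- c(used_all, setNames(k < n, sub$sample_id[1L]))
    mean(vseg[ord[seq_len(k)]] == segment)
  }, numeric(1L))
  attr(out, "used_all") <- used_all
  out
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Sum of hypergeometric probabilities no larger than the observed one
#' (the "minimum-likelihood" two-sided rule, with the standard 1e-7
#' relative tie tolerance).
#'
#' @param a,b,c,d cell counts of the table `rbind(c(a, b), c(c, d))`.
#' @return p-value in `(0, 1]`.
#' @export
fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  supp <- lo:hi
  pr <- dhyper(supp, m, n, k)
  obs <- pr[match(a, supp)]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

#' Quintile enrichment of a segment among expanded clonotypes
#'
#' Unique clonotypes (pooled or per sample) are ranked by count
#' (descending, ties by first appearance) and split into rank quintiles.
#' A 2x2 Fisher exact test asks whether `segment` membership is enriched
#' in the top quintile.
#'
#' @param tab a `clonotype_table` (typically one sample; rows are pooled).
#' @param segment V segment name.
#' @param key_mode clonotype key for uniqueness.
#' @return list with the 2x2 `table`, sample odds ratio `or` (`NA` with a
#'   `note` when a margin is empty) and Fisher `p`.
#' @export
quintile_enrichment <- function(tab, segment, key_mode = "v_nt") {
  key <- clonotype_key(tab, key_mode)
  cnt <- tapply(tab$count, key, sum)[unique(key)]
  if (length(cnt) < 5L) abort_format("need >= 5 unique clonotypes")
  vseg <- tab$v_call[match(names(cnt), key)] == segment
  ord <- order(-cnt, seq_along(cnt))
  top <- seq_along(cnt) %in% ord[seq_len(ceiling(length(cnt) / 5))]
  a <- sum(top & vseg); b <- sum(top & !vseg)
  c2 <- sum(!top & vseg); d <- sum(!top & !vseg)
  or <- if (b == 0L || c2 == 0L) {
    if (a * d == 0L) NA_real_ else Inf
  } else (a * d) / (b * c2)
  note <- NULL
  if (all(vseg) || !any(vseg)) {
    or <- NA_real_
    note <- "segment membership constant; odds ratio undefined"
  }
  list(table = matrix(c(a, b, c2, d), 2L, byrow = TRUE,
                      dimnames = list(c("top_quintile", "rest"),
                                      c(segment, "other"))),
       or = or, p = fisher_two_sided(a, b, c2, d), note = note)
}

#' CDR3 amino-acid usage by group, with per-residue tests
#'
#' Computes global and positional amino-acid frequencies over unique
#' clonotype CDR3s per group, distinguishing germline-templated positions
#' (the first `germline_prefix` and last `germline_suffix` residues) from
#' the non-germline core. Per residue, a two-proportion chi-square test
#' compares non-germline usage between the two groups, BH-adjusted.
#'
#' @param tab a `clonotype_table` with `cdr3_aa`.
#' @param groups length-2 condition labels.
#' @param germline_prefix,germline_suffix residue counts treated as
#'   V-/J-templated (defaults 3 = `CAS`, 1 = `F`).
#' @return list with `global` (residue x group frequency matrix over all
#'   positions), `nongermline` (same, core positions only), `tests`
#'   (per-residue counts, `p`, `q`).
#' @export
cdr3_aa_usage <- function(tab, groups = c("ACD", "HC"), germline_prefix = 3L,
                          germline_suffix = 1L) {
  tab <- tab[tab$condition %in% groups & !is.na(tab$cdr3_aa), , drop = FALSE]
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), tab$cdr3_aa)
  if (any(bad))
    abort_format("non-amino-acid character in cdr3_aa, e.g. %s", tab$cdr3_aa[bad][1L])
  count_res <- function(seqs, core_only) {
    ch <- strsplit(seqs, "", fixed = TRUE)
    if (core_only)
      ch <- lapply(ch, function(x) {
        n <- length(x)
        if (n <= germline_prefix + germline_suffix) character(0L)
        else x[(germline_prefix + 1L):(n - germline_suffix)]
      })
    tabulate(factor(unlist(ch), levels = AA_ALPHABET), nbins = 20L)
  }
  res <- list()
  for (what in c("global", "nongermline")) {
    m <- vapply(groups, function(g) {
      cnts <- count_res(unique(tab$cdr3_aa[tab$condition == g]),
                        core_only = what == "nongermline")
      cnts / max(1L, sum(cnts))
    }, numeric(20L))
    rownames(m) <- AA_ALPHABET
    res[[what]] <- m
  }
  cg <- vapply(groups, function(g)
    count_res(unique(tab$cdr3_aa[tab$condition == g]), TRUE), numeric(20L))
  tot <- colSums(cg)
  tests <- do.call(rbind, lapply(seq_len(20L), function(i) {
    p <- if (cg[i, 1L] + cg[i, 2L] == 0) 1
         else suppressWarnings(stats::prop.test(cg[i, ], tot)$p.value)
    data.frame(residue = AA_ALPHABET[i], countA = cg[i, 1L], countB = cg[i, 2L],
               p = p, stringsAsFactors = FALSE)
  }))
  tests$q <- bh(tests$p)
  list(global = res$global, nongermline = res$nongermline, tests = tests)
}

#' Per-sample fraction of unique clonotypes matching a CDR3 motif
#'
#' @param tab a `clonotype_table` with `cdr3_aa`.
#' @param pattern regular expression over the amino-acid alphabet (e.g.
#'   `"L"` or `"^CASS[LV]"`).
#' @param key_mode clonotype key for uniqueness.
#' @return named numeric vector of fractions per sample.
#' @export
motif_frequency <- function(tab, pattern, key_mode = "v_aa") {
  ok <- tryCatch({ grepl(pattern, "CASSF"); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_format("invalid motif pattern: %s", pattern)
  vapply(split(seq_len(nrow(tab)), tab$sample_id), function(i) {
    sub <- tab[i, , drop = FALSE]
    key <- clonotype_key(sub, key_mode)
    aa <- sub$cdr3_aa[match(unique(key), key)]
    mean(grepl(pattern, aa))
  }, numeric(1L))
}

#' Pairwise clonotype sharing between samples
#'
#' For every sample pair: number of shared unique keys, Jaccard index and
#' mean amino-acid length of the shared CDR3s; each pair is classed
#' `within-<condition>` or `between`.
#'
#' @param tab a `clonotype_table`.
#' @param key_mode clonotype key (default `"v_nt"`).
#' @return data.frame (`sampleA`, `sampleB`, `shared`, `jaccard`,
#'   `mean_shared_len`, `pair_class`).
#' @export
clonotype_sharing <- function(tab, key_mode = "v_nt") {
  samples <- unique(tab$sample_id)
  if (length(samples) < 2L) abort_format("need >= 2 samples")
  cond <- tapply(tab$condition, tab$sample_id, `[`, 1L)
  keysets <- lapply(split(seq_len(nrow(tab)), tab$sample_id), function(i) {
    sub <- tab[i, , drop = FALSE]
    key <- clonotype_key(sub, key_mode)
    aa <- sub$cdr3_aa[match(unique(key), key)]
    setNames(nchar(aa), unique(key))
  })
  pairs <- combn(samples, 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    sa <- pairs[1L, i]; sb <- pairs[2L, i]
    ka <- keysets[[sa]]; kb <- keysets[[sb]]
    sh <- intersect(names(ka), names(kb))
    un <- length(union(names(ka), names(kb)))
    data.frame(sampleA = sa, sampleB = sb, shared = length(sh),
               jaccard = if (un > 0) length(sh) / un else NA_real_,
               mean_shared_len = if (length(sh) > 0) mean(ka[sh]) else NA_real_,
               pair_class = if (cond[sa] == cond[sb])
                 paste0("within-", cond[sa]) else "between",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-segment per-sample usage fractions for a locus
#'
#' Fractions of unique clonotypes per V segment, restricted to segments of
#' the given locus prefix (e.g. `"TRGV"` for the gamma locus); per-sample
#' fractions sum to 1 over the locus.
#'
#' @param tab a `clonotype_table`.
#' @param locus segment-name prefix (`"TRBV"`, `"TRGV"`, `"TRDV"`, ...).
#' @param key_mode clonotype key for uniqueness.
#' @return segments x samples matrix of fractions.
#' @export
segment_usage_summary <- function(tab, locus = "TRBV", key_mode = "v_nt") {
  sub <- tab[startsWith(tab$v_call, locus), , drop = FALSE]
  if (nrow(sub) == 0L) abort_format("no clonotypes for locus %s", locus)
  key <- clonotype_key(sub, key_mode)
  first <- !duplicated(paste(sub$sample_id, key))
  u <- sub[first, , drop = FALSE]
  xt <- table(u$v_call, u$sample_id)
  m <- matrix(as.numeric(xt), nrow(xt), ncol(xt), dimnames = dimnames(xt))
  sweep(m, 2L, colSums(m), "/")
}
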