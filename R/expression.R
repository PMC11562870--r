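# Transcriptome-side statistics: transcribed/untranscribed partition, the
# documented stand-in differential-expression test, BH adjustment,
# hypergeometric over-representation, preranked GSEA and cross-dataset
# gene-set correlation.

tissue_columns <- function(expr, tissue) {
  stopifnot(inherits(expr, "expression_table"))
  idx <- which(expr$samples$tissue == tissue)
  if (!length(idx)) stop("unknown tissue: ", tissue)
  idx
}

#' Partition genes by transcriptional status
#'
#' A gene is transcribed in a tissue when its mean TPM across that tissue's
#' replicates is at least `tpm_threshold` (default 1 TPM). The partition is
#' exhaustive and disjoint.
#'
#' @param expr An `expression_table`.
#' @param tissue Tissue label present in the sample metadata.
#' @param tpm_threshold Mean-TPM cutoff (default 1).
#' @return List with character vectors `transcribed` and `untranscribed`.
#' @export
partition_by_expression <- function(expr, tissue, tpm_threshold = 1) {
  idx <- tissue_columns(expr, tissue)
  mu <- rowMeans(expr$tpm[, idx, drop = FALSE])
  list(
    transcribed = rownames(expr$tpm)[mu >= tpm_threshold],
    untranscribed = rownames(expr$tpm)[mu < tpm_threshold]
  )
}

#' Simple differential expression between two tissues
#'
#' A deliberately simple stand-in for a count-model DE stage: per gene, the
#' log2 fold change is the difference of mean `log2(TPM + 1)` between the
#' tissues (`a - b`), the p-value comes from Welch's two-sample t-test on
#' `log2(TPM + 1)`, and BH adjustment is applied across genes. Genes with
#' zero variance in both groups get p = 1.
#'
#' @param expr An `expression_table` with >= 2 replicates per tissue.
#' @param tissue_a,tissue_b Tissue labels (`a` is the focal tissue).
#' @return DE data frame (`gene_id`, `log2fc`, `pvalue`, `padj`) with a
#'   `contrast` attribute `"a_vs_b"`.
#' @export
simple_de <- function(expr, tissue_a, tissue_b) {
  ia <- tissue_columns(expr, tissue_a)
  ib <- tissue_columns(expr, tissue_b)
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("need >= 2 replicates per tissue for the Welch test")
  }
  xa <- log2(expr$tpm[, ia, drop = FALSE] + 1)
  xb <- log2(expr$tpm[, ib, drop = FALSE] + 1)
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var); vb <- apply(xb, 1, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[va == 0 & vb == 0] <- 1
  p[!is.finite(p)] <- 1
  out <- data.frame(
    gene_id = rownames(expr$tpm),
    log2fc = ma - mb,
    pvalue = p,
    padj = bh_adjust(p),
    stringsAsFactors = FALSE
  )
  validate_de_table(out)
  attr(out, "contrast") <- paste0(tissue_a, "_vs_", tissue_b)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment: sort ascending, multiply by
#' `n/i`, enforce monotonicity by a cumulative minimum from the largest
#' rank, cap at 1, return in input order (delegated to [stats::p.adjust()]
#' after input validation).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Tissue-specific differentially expressed genes across two contrasts
#'
#' A gene qualifies only when `log2fc > min_lfc` (strict) and
#' `padj < alpha` in *both* contrasts — the both-contrast filter for
#' tissue-specifically expressed genes.
#'
#' @param de_vs_stem,de_vs_leaf DE tables sharing a gene namespace.
#' @param min_lfc Log2 fold-change threshold (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Character vector of qualifying gene ids.
#' @export
filter_tissue_specific_de <- function(de_vs_stem, de_vs_leaf, min_lfc = 2,
                                      alpha = 0.05) {
  validate_de_table(de_vs_stem)
  validate_de_table(de_vs_leaf)
  pass <- function(de) de$gene_id[de$log2fc > min_lfc & de$padj < alpha]
  intersect(pass(de_vs_stem), pass(de_vs_leaf))
}

#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the query over-represents the term's genes
#' with the upper hypergeometric tail `P(X >= k)` (including the observed
#' overlap), followed by BH adjustment across terms. Terms are intersected
#' with the declared universe; empty intersections are dropped.
#'
#' @param query_genes Character vector, a subset of `universe`.
#' @param term_map Named list mapping term ids to gene-id vectors.
#' @param universe Character vector of all considered genes.
#' @return Data frame sorted by `padj` with columns `term_id`, `k`, `K`,
#'   `n`, `N`, `fold_enrichment`, `p`, `padj`.
#' @export
ora_hypergeometric <- function(query_genes, term_map, universe) {
  universe <- unique(universe)
  query_genes <- unique(query_genes)
  if (!length(universe)) stop("empty universe")
  if (!length(query_genes)) stop("empty query")
  if (!all(query_genes %in% universe)) {
    stop("query genes must be a subset of the universe")
  }
  terms <- lapply(term_map, function(g) intersect(unique(g), universe))
  terms <- terms[lengths(terms) > 0L]
  if (!length(terms)) stop("no term overlaps the universe")
  N <- length(universe)
  n <- length(query_genes)
  k <- vapply(terms, function(g) length(intersect(g, query_genes)), numeric(1))
  K <- lengths(terms)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(
    term_id = names(terms), k = as.integer(k), K = as.integer(K),
    n = n, N = N,
    fold_enrichment = (k / n) / (K / N),
    p = p, padj = bh_adjust(p),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$padj, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic on a ranked gene list:
#' walking down the ranking, hits increment by `|score|^weight` normalized
#' by the in-set total, misses decrement by `1/(N - N_hits)`; the enrichment
#' score (ES) is the maximum signed deviation. The null is built by
#' permuting gene labels `n_perm` times under a fixed seed; NES divides the
#' ES by the mean magnitude of same-sign null scores, and the permutation p
#' is the fraction of same-sign null scores at least as extreme, with +1
#' smoothing.
#'
#' @param scores Named numeric vector of ranking scores (names = gene ids);
#'   sorted in decreasing order internally.
#' @param gene_set Character vector; must intersect the ranked list.
#' @param weight Score weighting exponent (default 1).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed RNG seed for the permutation null.
#' @return Object of class `gsea_result`: `es`, `nes`, `p_value`,
#'   `n_perm`, `n_hits`, `running` (the running sum), `hit_index`.
#' @export
gsea_preranked <- function(scores, gene_set, weight = 1, n_perm = 1000L,
                           seed = 1L) {
  if (is.null(names(scores))) stop("scores must be a named vector")
  if (any(!is.finite(scores))) stop("ranking scores must be finite")
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  hits <- names(scores) %in% gene_set
  if (!any(hits)) stop("gene_set is disjoint from the ranked list")
  es_stat <- function(hits_idx) {
    h <- logical(length(scores))
    h[hits_idx] <- TRUE
    w <- abs(scores)^weight
    nr <- sum(w[h])
    inc <- ifelse(h, if (nr > 0) w / nr else 0, -1 / (length(scores) - sum(h)))
    run <- cumsum(inc)
    run[which.max(abs(run))]
  }
  run_inc <- {
    w <- abs(scores)^weight
    nr <- sum(w[hits])
    ifelse(hits, if (nr > 0) w / nr else 0, -1 / (length(scores) - sum(hits)))
  }
  running <- cumsum(run_inc)
  es <- running[which.max(abs(running))]
  nh <- sum(hits)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(b) {
    es_stat(sample.int(length(scores), nh))
  }, numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  structure(list(
    es = es, nes = nes, p_value = min(p, 1), n_perm = n_perm, n_hits = nh,
    running = running, hit_index = which(hits)
  ), class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA (preranked): ES = %.4f, NES = %.3f, p = %.4g (%d permutations, %d hits)\n",
              x$es, x$nes, x$p_value, x$n_perm, x$n_hits))
  invisible(x)
}

#' @method plot gsea_result
#' @export
plot.gsea_result <- function(x, ...) {
  plot(seq_along(x$running), x$running, type = "l",
       xlab = "rank", ylab = "running enrichment score", ...)
  abline(h = 0, lty = 2, col = "grey")
  points(x$hit_index, rep(min(x$running), length(x$hit_index)), pch = "|")
  invisible(x)
}

#' Cross-dataset gene-set expression correlation
#'
#' Restricts each expression table to a gene set (the intersection across
#' tables is used and its size reported) and computes the pairwise Spearman
#' correlation of the restricted TPM vectors across all samples — the
#' cross-validation view of a tissue-specific gene program across
#' independent transcriptome datasets.
#'
#' @param expression_tables A single `expression_table` or a list of them.
#' @param gene_set Character vector of gene ids.
#' @return List with the correlation `matrix` and `n_genes` used.
#' @export
geneset_expression_correlation <- function(expression_tables, gene_set) {
  if (inherits(expression_tables, "expression_table")) {
    expression_tables <- list(expression_tables)
  }
  common <- Reduce(intersect, lapply(expression_tables, function(e) rownames(e$tpm)))
  common <- intersect(common, gene_set)
  if (!length(common)) stop("gene_set intersection with the tables is empty")
  m <- do.call(cbind, lapply(expression_tables, function(e) e$tpm[common, , drop = FALSE]))
  if (ncol(m) < 2L) stop("need at least 2 samples")
  rho <- stats::cor(m, method = "spearman")
  diag(rho) <- 1
  list(matrix = rho, n_genes = length(common))
}
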