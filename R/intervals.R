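# Exact set operations, distance queries and co-localization statistics on
# interval collections. Everything operates on the plain data-frame interval
# representation (0-based half-open) and is validated against per-base
# bitmap / all-pairs oracles in the test suite.

# all overlapping index pairs between two interval sets on one chromosome;
# quadratic candidate generation, adequate at the desk scales this package
# targets (<= 10^4 intervals per set).
overlap_pairs_chrom <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(i = integer(), j = integer(), overlap = numeric()))
  }
  ord <- order(b$start)
  bs <- b$start[ord]
  be <- b$end[ord]
  res_i <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    # candidates: b with start < a_end; filter by end > a_start
    hi <- findInterval(a$end[i] - 0.5, bs)
    if (hi == 0L) next
    j <- seq_len(hi)
    keep <- be[j] > a$start[i]
    if (any(keep)) res_i[[i]] <- j[keep]
  }
  n_per <- lengths(res_i)
  i <- rep(seq_len(nrow(a)), n_per)
  j <- ord[unlist(res_i, use.names = FALSE)]
  if (!length(i)) {
    return(data.frame(i = integer(), j = integer(), overlap = numeric()))
  }
  overlap <- pmin(a$end[i], b$end[j]) - pmax(a$start[i], b$start[j])
  data.frame(i = i, j = j, overlap = overlap)
}

# all overlapping index pairs between interval sets a and b (global indices)
overlap_pairs <- function(a, b) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  out <- lapply(chroms, function(ch) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    p <- overlap_pairs_chrom(a[ia, , drop = FALSE], b[ib, , drop = FALSE])
    p$i <- ia[p$i]
    p$j <- ib[p$j]
    p
  })
  if (!length(out)) {
    return(data.frame(i = integer(), j = integer(), overlap = numeric()))
  }
  do.call(rbind, out)
}

#' Merge overlapping intervals
#'
#' Computes the union of an interval collection: output intervals are
#' sorted by `(chrom, start)`, non-overlapping, and book-ended intervals
#' (`end == start`) are merged.
#'
#' @param x Interval data frame.
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @examples
#' merge_intervals(genomic_intervals("chr1", c(0, 5), c(10, 15)))
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  new_run <- c(TRUE, x$chrom[-1L] != x$chrom[-nrow(x)] |
                 x$start[-1L] > cummax_by(x$end, x$chrom)[-nrow(x)])
  grp <- cumsum(new_run)
  data.frame(
    chrom = x$chrom[new_run],
    start = x$start[new_run],
    end = as.numeric(tapply(x$end, grp, max)),
    stringsAsFactors = FALSE
  )
}

# running maximum restarted at each chromosome change (input sorted by chrom)
cummax_by <- function(v, chrom) {
  grp <- cumsum(c(TRUE, chrom[-1L] != chrom[-length(chrom)]))
  unlist(lapply(split(v, grp), cummax), use.names = FALSE)
}

#' Intersect two interval sets
#'
#' With `mode = "whole_a"` returns each interval of `A` that has at least one
#' qualifying overlap in `B`, once (bedtools `-wa -u` semantics); with
#' `mode = "fragment"` returns the per-pair overlap segments. An overlap
#' qualifies when `overlap_len >= min_frac_a * len(a)`; with
#' `reciprocal = TRUE` it must also cover `min_frac_b` (at least
#' `min_frac_a` when `min_frac_b` is smaller) of the `B` interval.
#'
#' @param a,b Interval data frames.
#' @param min_frac_a,min_frac_b Minimum overlap fractions in `[0, 1]`.
#' @param reciprocal Require the fraction on both intervals.
#' @param mode `"whole_a"` or `"fragment"`.
#' @return Interval data frame; for `"whole_a"` the qualifying rows of `a`
#'   (original columns preserved), for `"fragment"` columns `chrom`,
#'   `start`, `end` of each overlap segment.
#' @export
intersect_intervals <- function(a, b, min_frac_a = 0, min_frac_b = 0,
                                reciprocal = FALSE,
                                mode = c("whole_a", "fragment")) {
  mode <- match.arg(mode)
  validate_intervals(a)
  validate_intervals(b)
  if (min_frac_a < 0 || min_frac_a > 1 || min_frac_b < 0 || min_frac_b > 1) {
    stop("overlap fractions must lie in [0, 1]")
  }
  if (reciprocal) min_frac_b <- max(min_frac_b, min_frac_a)
  p <- overlap_pairs(a, b)
  if (nrow(p)) {
    ok <- p$overlap >= min_frac_a * (a$end[p$i] - a$start[p$i]) &
      p$overlap >= min_frac_b * (b$end[p$j] - b$start[p$j])
    p <- p[ok, , drop = FALSE]
  }
  if (mode == "whole_a") {
    out <- a[sort(unique(p$i)), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  frag <- data.frame(
    chrom = a$chrom[p$i],
    start = pmax(a$start[p$i], b$start[p$j]),
    end = pmin(a$end[p$i], b$end[p$j]),
    stringsAsFactors = FALSE
  )
  frag <- frag[order(frag$chrom, frag$start, frag$end), , drop = FALSE]
  rownames(frag) <- NULL
  frag
}

#' Subtract intervals with whole-interval semantics
#'
#' Returns the intervals of `A` that have zero overlap with any interval of
#' `B` (bedtools `intersect -v`): any overlap, however small, disqualifies
#' the whole `A` interval.
#'
#' @param a,b Interval data frames.
#' @return The non-overlapping rows of `a`.
#' @export
subtract_exclusive <- function(a, b) {
  validate_intervals(a)
  validate_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    rownames(a) <- NULL
    return(a)
  }
  p <- overlap_pairs(a, b)
  out <- a[setdiff(seq_len(nrow(a)), unique(p$i)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tissue-specific peaks by sequential exclusive subtraction
#'
#' Applies [subtract_exclusive()] against each other-tissue peak set in
#' turn, so the result overlaps no peak of any other tissue.
#'
#' @param target_peaks Peak/interval data frame for the focal tissue.
#' @param other_tissue_peaksets List of peak data frames (>= 1).
#' @return The rows of `target_peaks` specific to the focal tissue.
#' @export
tissue_specific <- function(target_peaks, other_tissue_peaksets) {
  if (!is.list(other_tissue_peaksets) || is.data.frame(other_tissue_peaksets)) {
    other_tissue_peaksets <- list(other_tissue_peaksets)
  }
  if (!length(other_tissue_peaksets)) stop("need at least one other tissue peak set")
  out <- target_peaks
  for (other in other_tissue_peaksets) out <- subtract_exclusive(out, other)
  out
}

#' Nearest transcription start site
#'
#' For each peak, finds the gene with the nearest TSS on the same
#' chromosome. Under the `midpoint` anchor the distance is
#' `|midpoint(peak) - tss|`; under the `edges` anchor it is 0 when the TSS
#' lies inside the peak and otherwise the distance from the nearest peak
#' edge. Ties break to the lexicographically smallest `gene_id`.
#'
#' @param peaks Peak/interval data frame.
#' @param genes Gene-model data frame.
#' @param anchor `"midpoint"` or `"edges"`.
#' @return Data frame with one row per peak: `gene_id`, `distance`.
#' @export
nearest_tss <- function(peaks, genes, anchor = c("midpoint", "edges")) {
  anchor <- match.arg(anchor)
  validate_intervals(peaks, "peak")
  validate_genes(genes)
  out <- data.frame(gene_id = character(nrow(peaks)), distance = numeric(nrow(peaks)),
                    stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L) return(out)
  mids <- midpoint(peaks)
  for (ch in unique(peaks$chrom)) {
    gi <- which(genes$chrom == ch)
    if (!length(gi)) stop("no gene on chromosome ", ch)
    pi <- which(peaks$chrom == ch)
    # order candidate genes so that which.min tie-breaks by gene_id
    gi <- gi[order(genes$gene_id[gi])]
    tss <- genes$tss[gi]
    for (k in pi) {
      d <- if (anchor == "midpoint") {
        abs(mids[k] - tss)
      } else {
        inside <- tss >= peaks$start[k] & tss < peaks$end[k]
        ifelse(inside, 0, pmin(abs(peaks$start[k] - tss), abs(peaks$end[k] - 1 - tss)))
      }
      best <- which.min(d)
      out$gene_id[k] <- genes$gene_id[gi[best]]
      out$distance[k] <- d[best]
    }
  }
  out
}

#' Filter peaks distal to every TSS
#'
#' Retains peaks whose midpoint lies strictly more than `min_distance` bp
#' from the nearest TSS. Peaks on chromosomes without any gene are retained
#' and flagged in the `no_gene_on_chrom` column.
#'
#' @param peaks Peak/interval data frame.
#' @param genes Gene-model data frame.
#' @param min_distance Distance threshold in bp (default 1500).
#' @return The distal rows of `peaks` with added columns `nearest_gene`,
#'   `tss_distance` and `no_gene_on_chrom`.
#' @export
distal_filter <- function(peaks, genes, min_distance = 1500) {
  if (min_distance < 0) stop("min_distance must be >= 0")
  validate_intervals(peaks, "peak")
  validate_genes(genes)
  peaks$no_gene_on_chrom <- !(peaks$chrom %in% genes$chrom)
  peaks$nearest_gene <- NA_character_
  peaks$tss_distance <- NA_real_
  has_gene <- which(!peaks$no_gene_on_chrom)
  if (length(has_gene)) {
    nn <- nearest_tss(peaks[has_gene, , drop = FALSE], genes, anchor = "midpoint")
    peaks$nearest_gene[has_gene] <- nn$gene_id
    peaks$tss_distance[has_gene] <- nn$distance
  }
  keep <- peaks$no_gene_on_chrom | peaks$tss_distance > min_distance
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify peaks by genomic feature
#'
#' Each peak is classified by its midpoint with priority
#' promoter > TTS flank > gene body > intergenic. Windows are strand-aware:
#' the promoter window is `promoter_window` bp around the TSS in the
#' direction of transcription (default TSS-1000..TSS+100), the TTS flank is
#' `tts_window` downstream of the TES.
#'
#' @param peaks Peak/interval data frame.
#' @param genes Gene-model data frame.
#' @param promoter_window Length-2 numeric, offsets relative to the TSS.
#' @param tts_window Length-2 numeric, offsets relative to the TES.
#' @return Object of class `feature_class_counts`: list with `counts` and
#'   `fractions` over promoter/gene_body/tts_flank/intergenic, and the
#'   per-peak `class` vector.
#' @export
feature_distribution <- function(peaks, genes, promoter_window = c(-1000, 100),
                                 tts_window = c(0, 100)) {
  validate_intervals(peaks, "peak")
  validate_genes(genes)
  mids <- midpoint(peaks)
  cls <- rep("intergenic", nrow(peaks))
  sgn <- ifelse(genes$strand == "+", 1, -1)
  for (k in seq_len(nrow(peaks))) {
    gi <- which(genes$chrom == peaks$chrom[k])
    if (!length(gi)) next
    rel_tss <- sgn[gi] * (mids[k] - genes$tss[gi])
    rel_tes <- sgn[gi] * (mids[k] - genes$tes[gi])
    if (any(rel_tss >= promoter_window[1] & rel_tss <= promoter_window[2])) {
      cls[k] <- "promoter"
    } else if (any(rel_tes >= tts_window[1] & rel_tes <= tts_window[2])) {
      cls[k] <- "tts_flank"
    } else if (any(mids[k] >= genes$start[gi] & mids[k] < genes$end[gi])) {
      cls[k] <- "gene_body"
    }
  }
  counts <- vapply(FEATURE_CLASSES, function(f) sum(cls == f), numeric(1))
  fractions <- if (nrow(peaks)) counts / nrow(peaks) else counts
  structure(list(counts = counts, fractions = fractions, class = cls),
            class = "feature_class_counts")
}

#' @export
print.feature_class_counts <- function(x, ...) {
  cat("peak feature distribution:\n")
  print(data.frame(class = names(x$counts), count = as.integer(x$counts),
                   fraction = round(x$fractions, 4)))
  invisible(x)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The p-value is the sum of hypergeometric probabilities of all tables with
#' the observed margins whose probability does not exceed that of the
#' observed table (computed by [stats::fisher.test()]); the odds ratio is
#' the sample odds ratio `(n11 * n22) / (n12 * n21)`, not the conditional
#' MLE, optionally with a 0.5 continuity correction.
#'
#' @param table 2x2 numeric matrix, or `c(n11, n12, n21, n22)` in row-major
#'   order (overlapping; A-only; B-only; neither).
#' @param continuity Add 0.5 to every cell before computing the odds ratio.
#' @return List with `p_value`, `odds_ratio` and the `table`.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table, continuity = FALSE) {
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2, 2, byrow = TRUE)
  if (any(table < 0) || any(table != round(table))) {
    stop("contingency table cells must be non-negative integers")
  }
  if (sum(table) == 0) stop("all-zero contingency table")
  p <- stats::fisher.test(table, alternative = "two.sided")$p.value
  tb <- if (continuity) table + 0.5 else table
  or <- (tb[1, 1] * tb[2, 2]) / (tb[1, 2] * tb[2, 1])
  list(p_value = min(p, 1), odds_ratio = or, table = table)
}

#' Co-localization Fisher test for two peak sets
#'
#' Both sets are merged; the contingency table counts merged `A` intervals
#' with/without a `B` overlap, `B` intervals without an `A` overlap, and a
#' "neither" cell estimated as the number of genome slots of mean interval
#' length not occupied by the other cells (the bedtools-fisher style
#' estimate). The table construction is approximate by nature; it is
#' validated by monotonicity of `p` in the planted overlap fraction, never
#' against a published p-value.
#'
#' @param a,b Interval data frames (non-empty).
#' @param genome_size Total genome length in bp; must be at least the number
#'   of bases covered by the merged sets.
#' @return List with the contingency `table` (n11, n12, n21, n22),
#'   `p_value` and `odds_ratio`.
#' @export
colocalization_fisher <- function(a, b, genome_size) {
  am <- merge_intervals(a)
  bm <- merge_intervals(b)
  if (nrow(am) == 0L || nrow(bm) == 0L) stop("both interval sets must be non-empty")
  covered <- sum(merge_intervals(rbind(am, bm[, c("chrom", "start", "end")]))$end -
                   merge_intervals(rbind(am, bm[, c("chrom", "start", "end")]))$start)
  if (genome_size < covered) {
    stop(sprintf("genome_size (%g) smaller than covered bases (%g)", genome_size, covered))
  }
  p <- overlap_pairs(am, bm)
  n11 <- length(unique(p$i))
  n12 <- nrow(am) - n11
  n21 <- nrow(bm) - length(unique(p$j))
  mean_len <- mean(c(am$end - am$start, bm$end - bm$start))
  n22 <- max(0, round(genome_size / mean_len) - n11 - n12 - n21)
  tab <- matrix(c(n11, n12, n21, n22), 2, 2, byrow = TRUE,
                dimnames = list(c("A", "not_A"), c("B", "not_B")))
  ft <- fisher_exact_2x2(tab)
  list(table = tab, p_value = ft$p_value, odds_ratio = ft$odds_ratio)
}
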