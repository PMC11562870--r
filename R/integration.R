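# The core joins: marks -> genes, transcribed x mark cross-tabulation,
# tissue-specific chromatin, bivalent loci, and distal enhancer -> target
# gene pairing.

gene_assignment_windows <- function(genes, promoter_extension) {
  data.frame(
    chrom = genes$chrom,
    start = pmax(0, ifelse(genes$strand == "+", genes$start - promoter_extension,
                           genes$start)),
    end = ifelse(genes$strand == "+", genes$end, genes$end + promoter_extension),
    gene_id = genes$gene_id,
    stringsAsFactors = FALSE
  )
}

#' Assign histone marks to genes
#'
#' A mark is present for a gene when any consolidated peak of that mark
#' overlaps the gene span extended by `promoter_extension` bp upstream
#' (strand-aware). The bivalent flag records joint presence of H3K4me3 and
#' H3K27me3.
#'
#' @param genes Gene-model data frame.
#' @param consolidated_peaks_by_mark Named list of peak data frames, one per
#'   mark.
#' @param transcribed Optional character vector of transcribed gene ids; the
#'   `transcribed` column is `NA` when omitted.
#' @param promoter_extension Upstream extension in bp (default 1000).
#' @return Data frame with one row per gene: `gene_id`, `transcribed`, one
#'   logical column per mark, and `bivalent`.
#' @export
assign_marks_to_genes <- function(genes, consolidated_peaks_by_mark,
                                  transcribed = NULL, promoter_extension = 1000) {
  validate_genes(genes)
  stopifnot(is.list(consolidated_peaks_by_mark),
            !is.null(names(consolidated_peaks_by_mark)))
  win <- gene_assignment_windows(genes, promoter_extension)
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  out$transcribed <- if (is.null(transcribed)) NA else genes$gene_id %in% transcribed
  for (mk in names(consolidated_peaks_by_mark)) {
    pk <- consolidated_peaks_by_mark[[mk]]
    hit <- logical(nrow(genes))
    if (!is.null(pk) && nrow(pk)) {
      p <- overlap_pairs(win, pk)
      hit[unique(p$i)] <- TRUE
    }
    out[[mk]] <- hit
  }
  out$bivalent <- if (all(c("H3K4me3", "H3K27me3") %in% names(out))) {
    out$H3K4me3 & out$H3K27me3
  } else FALSE
  out
}

#' Bivalent loci from activating and repressive peak sets
#'
#' Intersection fragments of H3K4me3 and H3K27me3 peaks within one tissue,
#' plus the count of H3K4me3 peaks having any H3K27me3 overlap.
#'
#' @param k4_peaks,k27_peaks Peak data frames from one tissue.
#' @return List with `fragments` (interval data frame) and
#'   `n_overlapping` (count of overlapping H3K4me3 peaks).
#' @export
bivalent_loci <- function(k4_peaks, k27_peaks) {
  fragments <- intersect_intervals(k4_peaks, k27_peaks, mode = "fragment")
  overlapping <- intersect_intervals(k4_peaks, k27_peaks, mode = "whole_a")
  list(fragments = fragments, n_overlapping = nrow(overlapping))
}

#' Tissue-specific chromatin for one mark
#'
#' Subtracts every other tissue's consolidated peaks from the target
#' tissue's set (sequential exclusive subtraction), annotating the result
#' with the target tissue and a `"consolidated"` replicate label.
#'
#' @param peaks_by_tissue Named list (>= 2 tissues) of consolidated peak
#'   data frames for one mark.
#' @param target_tissue Name of the focal tissue in `peaks_by_tissue`.
#' @return Peak data frame specific to the target tissue.
#' @export
tissue_specific_chromatin <- function(peaks_by_tissue, target_tissue) {
  stopifnot(is.list(peaks_by_tissue), !is.null(names(peaks_by_tissue)))
  if (!target_tissue %in% names(peaks_by_tissue)) {
    stop("target tissue missing from peak sets: ", target_tissue)
  }
  if (length(peaks_by_tissue) < 2L) stop("need >= 2 tissues")
  others <- peaks_by_tissue[setdiff(names(peaks_by_tissue), target_tissue)]
  out <- tissue_specific(as_peaks(peaks_by_tissue[[target_tissue]]), others)
  if (nrow(out)) {
    out$tissue <- target_tissue
    out$replicate <- "consolidated"
  }
  out
}

#' Distal enhancer to target gene pairing
#'
#' The enhancer-calling join: (1) tissue-specific H3K56ac loci are filtered
#' to those strictly more than `min_distance` bp (peak midpoint) from *any*
#' TSS, excluding gene-proximal promoters; (2) each surviving locus is
#' matched to its nearest gene among *all* annotated genes; (3) the pair is
#' retained only when that nearest gene passed the both-contrast
#' tissue-specific DE filter; (4) DE statistics from both contrasts and an
#' intragenic flag (locus overlaps another gene's body) are attached. Loci
#' whose nearest gene fails the filter are reported in a rejects table.
#'
#' @param h3k56ac_tissue_specific Tissue-specific H3K56ac peak data frame.
#' @param genes Gene-model data frame (all annotated genes).
#' @param de_filtered_gene_set Character vector from
#'   [filter_tissue_specific_de()].
#' @param de_tables Named list of DE tables (one per contrast) used to
#'   attach `log2fc`/`padj` evidence.
#' @param min_distance Distal threshold in bp (default 1500).
#' @return List with `pairs` (one row per enhancer-target pair) and
#'   `rejects` (loci dropped, with a `reason` column).
#' @export
enhancer_target_pairs <- function(h3k56ac_tissue_specific, genes,
                                  de_filtered_gene_set, de_tables,
                                  min_distance = 1500) {
  validate_genes(genes)
  peaks <- as_peaks(h3k56ac_tissue_specific)
  empty_pairs <- data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    gene_id = character(), distance = numeric(), intragenic = logical(),
    stringsAsFactors = FALSE
  )
  if (nrow(peaks) == 0L) {
    warning("empty H3K56ac peak set; no enhancer-target pairs")
    return(list(pairs = empty_pairs, rejects = empty_pairs))
  }
  ann <- distal_filter(peaks, genes, min_distance = min_distance)
  nn <- nearest_tss(peaks, genes, anchor = "midpoint")
  proximal <- peaks[!(paste(peaks$chrom, peaks$start) %in%
                        paste(ann$chrom, ann$start)), , drop = FALSE]
  rejects <- list()
  if (nrow(proximal)) {
    proximal$reason <- "within_distal_threshold"
    rejects[[1]] <- proximal[, c("chrom", "start", "end", "reason")]
  }
  keep <- ann$nearest_gene %in% de_filtered_gene_set
  dropped <- ann[!keep, , drop = FALSE]
  if (nrow(dropped)) {
    dropped$reason <- "nearest_gene_not_tissue_specific"
    rejects[[length(rejects) + 1L]] <-
      dropped[, c("chrom", "start", "end", "reason")]
  }
  hit <- ann[keep, , drop = FALSE]
  pairs <- data.frame(
    chrom = hit$chrom, start = hit$start, end = hit$end,
    gene_id = hit$nearest_gene, distance = hit$tss_distance,
    stringsAsFactors = FALSE
  )
  # intragenic: locus overlaps the body of some gene other than its target
  pairs$intragenic <- vapply(seq_len(nrow(pairs)), function(i) {
    gi <- genes$chrom == pairs$chrom[i] & genes$gene_id != pairs$gene_id[i]
    any(genes$start[gi] < pairs$end[i] & genes$end[gi] > pairs$start[i])
  }, logical(1))
  for (ct in names(de_tables)) {
    de <- de_tables[[ct]]
    m <- match(pairs$gene_id, de$gene_id)
    pairs[[paste0("log2fc_", ct)]] <- de$log2fc[m]
    pairs[[paste0("padj_", ct)]] <- de$padj[m]
  }
  rejects <- if (length(rejects)) do.call(rbind, rejects) else
    cbind(empty_pairs[, 1:3], reason = character())
  rownames(pairs) <- NULL
  rownames(rejects) <- NULL
  list(pairs = pairs, rejects = rejects)
}

#' Cross-tabulate transcription status against marks
#'
#' Counts genes in each (transcribed x mark) cell; a gene contributes to
#' every mark column it carries, so rows sum to at least the partition
#' sizes.
#'
#' @param states Output of [assign_marks_to_genes()] with a non-`NA`
#'   `transcribed` column.
#' @return 2 x n-mark integer matrix with rows `transcribed`,
#'   `untranscribed`.
#' @export
mark_state_crosstab <- function(states) {
  marks <- intersect(MARKS, names(states))
  if (!length(marks)) stop("no mark columns in states")
  if (any(is.na(states$transcribed))) stop("states lack transcription status")
  out <- rbind(
    transcribed = vapply(marks, function(m) sum(states[[m]] & states$transcribed), numeric(1)),
    untranscribed = vapply(marks, function(m) sum(states[[m]] & !states$transcribed), numeric(1))
  )
  storage.mode(out) <- "integer"
  out
}
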