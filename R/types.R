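#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dnorm pnorm qnorm phyper p.adjust pt t.test
#'   fisher.test rnorm rlnorm runif rexp setNames complete.cases
#' @importFrom utils read.delim write.table head tail
#' @importFrom graphics plot points abline legend lines
NULL

MARKS <- c("H3K4me3", "H3K56ac", "H3K27me3", "H2A.Z")
FEATURE_CLASSES <- c("promoter", "gene_body", "tts_flank", "intergenic")

#' Construct a genomic-interval data frame
#'
#' Intervals are the atoms of all interval algebra in this package. They are
#' stored as plain data frames in 0-based half-open coordinates (`start`
#' inclusive, `end` exclusive), the convention of the BED family of formats.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start,end Integer-like base positions with `0 <= start < end`.
#' @param strand Strand, one of `"+"`, `"-"`, `"."`.
#' @param name Optional labels.
#' @return A data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, validated against the interval invariants.
#' @examples
#' genomic_intervals("chr1", 0, 100)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = NA_character_) {
  x <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand),
    name = as.character(name),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  x
}

#' Validate interval invariants
#'
#' Checks `0 <= start < end`, non-empty chromosome names and legal strand
#' symbols; raises on violation rather than coercing.
#'
#' @param x Data frame with at least `chrom`, `start`, `end` columns.
#' @param what Label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(sprintf("%s table is missing column(s): %s", what, paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom) | !nzchar(x$chrom))) {
    stop(sprintf("%s with empty chromosome name", what))
  }
  if (any(x$start < 0)) {
    stop(sprintf("negative coordinate in %s (row %d)", what, which(x$start < 0)[1L]))
  }
  bad <- which(x$start >= x$end)
  if (length(bad)) {
    stop(sprintf("%s with start >= end (row %d: %s:%g-%g)", what,
                 bad[1L], x$chrom[bad[1L]], x$start[bad[1L]], x$end[bad[1L]]))
  }
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "."))) {
    stop(sprintf("unknown strand symbol in %s", what))
  }
  invisible(x)
}

#' Validate peak invariants
#'
#' Peaks extend intervals with a mark/tissue/replicate annotation, an
#' enrichment score (`signalValue`), -log10 p and q values and an optional
#' summit offset. Absent values are `NA`, never sentinel numbers.
#'
#' @param x Peak data frame.
#' @return `x`, invisibly.
#' @export
validate_peaks <- function(x) {
  validate_intervals(x, what = "peak")
  if (nrow(x) == 0L) return(invisible(x))
  for (col in c("score", "neglog10p", "neglog10q")) {
    if (col %in% names(x)) {
      v <- x[[col]]
      if (any(!is.na(v) & v < 0)) stop(sprintf("peak with negative %s", col))
    }
  }
  if ("summit" %in% names(x)) {
    s <- x$summit
    len <- x$end - x$start
    bad <- !is.na(s) & (s < 0 | s >= len)
    if (any(bad)) {
      stop(sprintf("peak summit outside [0, length) (row %d)", which(bad)[1L]))
    }
  }
  invisible(x)
}

empty_peaks <- function() {
  data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    name = character(), score = numeric(), strand = character(),
    neglog10p = numeric(), neglog10q = numeric(), summit = numeric(),
    mark = character(), tissue = character(), replicate = character(),
    stringsAsFactors = FALSE
  )
}

as_peaks <- function(x, mark = NA_character_, tissue = NA_character_,
                     replicate = NA_character_) {
  if (nrow(x) == 0L) return(empty_peaks())
  defaults <- list(
    name = NA_character_, score = NA_real_, strand = ".",
    neglog10p = NA_real_, neglog10q = NA_real_, summit = NA_real_
  )
  for (col in names(defaults)) if (!col %in% names(x)) x[[col]] <- defaults[[col]]
  if (!"mark" %in% names(x)) x$mark <- mark
  if (!"tissue" %in% names(x)) x$tissue <- tissue
  if (!"replicate" %in% names(x)) x$replicate <- replicate
  x <- x[, names(empty_peaks())]
  rownames(x) <- NULL
  validate_peaks(x)
  x
}

#' Validate gene models
#'
#' A gene model is a stranded interval with a strand-aware transcription
#' start site (TSS) and termination site (TES). The TSS of a minus-strand
#' gene is `end - 1`, the last covered base, so that the TSS always lies
#' inside the half-open interval.
#'
#' @param x Gene-model data frame with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `tss`, `tes`.
#' @return `x`, invisibly.
#' @export
validate_genes <- function(x) {
  validate_intervals(x, what = "gene")
  need <- c("gene_id", "strand", "tss", "tes")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("gene table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0L) return(invisible(x))
  if (anyDuplicated(x$gene_id)) {
    stop("duplicate gene_id: ", x$gene_id[duplicated(x$gene_id)][1L])
  }
  if (!all(x$strand %in% c("+", "-"))) stop("unknown strand symbol in gene models")
  if (any(x$tss < x$start | x$tss >= x$end | x$tes < x$start | x$tes >= x$end)) {
    stop("gene tss/tes outside [start, end)")
  }
  invisible(x)
}

#' Build gene models from spans
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom,start,end Gene span in 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @return Gene-model data frame with derived `tss` and `tes`.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand) {
  x <- data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    start = as.numeric(start), end = as.numeric(end),
    strand = as.character(strand), stringsAsFactors = FALSE
  )
  x$tss <- ifelse(x$strand == "+", x$start, x$end - 1)
  x$tes <- ifelse(x$strand == "+", x$end - 1, x$start)
  validate_genes(x)
  x
}

#' Construct an expression table
#'
#' @param tpm Numeric matrix of transcripts-per-million values, genes in
#'   rows (rownames = gene ids), samples in columns.
#' @param samples Data frame with columns `sample`, `tissue`, `replicate`
#'   describing the columns of `tpm`; derived from column names of the form
#'   `tissue_replicate` when omitted.
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(tpm, samples = NULL) {
  stopifnot(is.matrix(tpm), !is.null(rownames(tpm)), !is.null(colnames(tpm)))
  if (anyDuplicated(rownames(tpm))) stop("duplicate gene_id in expression table")
  if (any(!is.finite(tpm)) || any(tpm < 0)) stop("TPM values must be finite and >= 0")
  if (is.null(samples)) {
    nm <- colnames(tpm)
    tissue <- sub("_[^_]*$", "", nm)
    replicate <- sub("^.*_", "", nm)
    samples <- data.frame(sample = nm, tissue = tissue, replicate = replicate,
                          stringsAsFactors = FALSE)
  }
  stopifnot(nrow(samples) == ncol(tpm))
  structure(list(tpm = tpm, samples = samples), class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples (%s)\n",
              nrow(x$tpm), ncol(x$tpm),
              paste(unique(x$samples$tissue), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_table <- function(x) dim(x$tpm)

#' Validate a differential-expression table
#'
#' @param x Data frame with columns `gene_id`, `log2fc`, `pvalue`, `padj`.
#' @return `x`, invisibly.
#' @export
validate_de_table <- function(x) {
  need <- c("gene_id", "log2fc", "pvalue", "padj")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("DE table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0L) return(invisible(x))
  if (anyDuplicated(x$gene_id)) stop("duplicate gene_id in DE table")
  if (any(x$padj < 0 | x$padj > 1, na.rm = TRUE)) stop("padj outside [0, 1]")
  if (any(x$pvalue < 0 | x$pvalue > 1, na.rm = TRUE)) stop("pvalue outside [0, 1]")
  invisible(x)
}

#' Validate a binned signal track
#'
#' A track is a data frame of `(chrom, start, end, value)` bins, sorted by
#' `(chrom, start)`, non-overlapping, with finite values.
#'
#' @param x Track data frame.
#' @return `x`, invisibly.
#' @export
validate_track <- function(x) {
  validate_intervals(x, what = "track bin")
  if (!"value" %in% names(x)) stop("track is missing the value column")
  if (nrow(x) == 0L) return(invisible(x))
  if (any(!is.finite(x$value))) stop("non-finite value in track")
  o <- order(x$chrom, x$start)
  if (!identical(o, seq_len(nrow(x)))) stop("unsorted track")
  same <- x$chrom[-1L] == x$chrom[-nrow(x)]
  if (any(same & x$start[-1L] < x$end[-nrow(x)])) stop("overlapping bins in track")
  invisible(x)
}

#' Construct a position frequency matrix
#'
#' @param motif_id Motif identifier.
#' @param counts 4 x L non-negative count matrix over the DNA alphabet;
#'   rows are taken in A, C, G, T order (rownames optional).
#' @param family Optional transcription-factor family label.
#' @return An object of class `motif_pfm`.
#' @export
motif_pfm <- function(motif_id, counts, family = NA_character_) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PFM must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 2L) stop("PFM length must be >= 2")
  if (any(counts < 0)) stop("PFM counts must be non-negative")
  if (any(colSums(counts) <= 0)) stop("PFM column with non-positive total count")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, counts = counts, family = family),
            class = "motif_pfm")
}

#' @export
print.motif_pfm <- function(x, ...) {
  cons <- paste(rownames(x$counts)[apply(x$counts, 2, which.max)], collapse = "")
  cat(sprintf("motif_pfm %s (L = %d, consensus %s)\n", x$motif_id, ncol(x$counts), cons))
  invisible(x)
}

interval_length <- function(x) x$end - x$start

midpoint <- function(x) floor((x$start + x$end) / 2)
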