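# Readers/writers for the BED-family peak formats, bedGraph, TSV tables,
# FASTA and JASPAR motif text. All coordinates are converted to 0-based
# half-open at the boundary; GFF3/GTF (1-based inclusive) are the only
# formats that need conversion.

read_tab_lines <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

split_fields <- function(lines, min_fields, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  bad <- which(n < min_fields)
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: expected >= %d tab-separated fields, got %d",
                 bad[1L], path, min_fields, n[bad[1L]]))
  }
  fields
}

num_or_na <- function(x, absent = c(".", "-1", "")) {
  out <- suppressWarnings(as.numeric(x))
  out[x %in% absent] <- NA_real_
  bad <- which(is.na(out) & !x %in% absent)
  if (length(bad)) stop(sprintf("non-numeric field '%s' (line %d)", x[bad[1L]], bad[1L]))
  out
}

#' Read peak calls
#'
#' Reads ENCODE narrowPeak (BED6+4), broadPeak (BED6+3) or plain BED6 peak
#' files into the package's peak data frame. Coordinates are interpreted as
#' 0-based half-open. Missing score/p/q fields (`.` or `-1`) become `NA`;
#' a narrowPeak summit of `-1` means "absent". Input order is preserved.
#'
#' @param path Path to a tab-separated peak file.
#' @param dialect One of `"narrowPeak"`, `"broadPeak"`, `"bed6"`.
#' @param mark,tissue,replicate Optional annotations attached to every peak.
#' @return Peak data frame (see [validate_peaks()]).
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "broadPeak", "bed6"),
                       mark = NA_character_, tissue = NA_character_,
                       replicate = NA_character_) {
  dialect <- match.arg(dialect)
  min_fields <- switch(dialect, narrowPeak = 10L, broadPeak = 9L, bed6 = 6L)
  lines <- read_tab_lines(path)
  if (!length(lines)) return(empty_peaks())
  fields <- split_fields(lines, min_fields, path)
  col <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop(sprintf("malformed coordinates on line %d in %s", bad[1L], path))
  if (any(start < 0)) {
    stop(sprintf("negative coordinate on line %d in %s", which(start < 0)[1L], path))
  }
  swapped <- which(start >= end)
  if (length(swapped)) {
    stop(sprintf("start >= end on line %d in %s", swapped[1L], path))
  }
  x <- data.frame(
    chrom = col(1), start = start, end = end,
    name = ifelse(col(4) == ".", NA_character_, col(4)),
    strand = col(6), stringsAsFactors = FALSE
  )
  x$strand[!x$strand %in% c("+", "-", ".")] <- "."
  if (dialect == "bed6") {
    x$score <- num_or_na(col(5))
  } else {
    x$score <- num_or_na(col(7))
    x$neglog10p <- num_or_na(col(8))
    x$neglog10q <- num_or_na(col(9))
  }
  if (dialect == "narrowPeak") x$summit <- num_or_na(col(10))
  as_peaks(x, mark = mark, tissue = tissue, replicate = replicate)
}

#' Write peak calls
#'
#' Inverse of [read_peaks()]: emits tab-separated, newline-terminated
#' records. Absent values are written as the dialect's conventional
#' sentinels (`.` for name, `-1` for numeric fields and the summit).
#'
#' @param peaks Peak data frame.
#' @param path Output path.
#' @param dialect One of `"narrowPeak"`, `"broadPeak"`, `"bed6"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, dialect = c("narrowPeak", "broadPeak", "bed6")) {
  dialect <- match.arg(dialect)
  peaks <- as_peaks(peaks)
  if (nrow(peaks) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  fmt <- function(v) ifelse(is.na(v), "-1", format(v, scientific = FALSE, trim = TRUE, digits = 15))
  nm <- ifelse(is.na(peaks$name), ".", peaks$name)
  base <- cbind(peaks$chrom, fmt(peaks$start), fmt(peaks$end), nm, "0", peaks$strand)
  out <- switch(dialect,
    bed6 = cbind(base[, 1:4, drop = FALSE], fmt(peaks$score), peaks$strand),
    broadPeak = cbind(base, fmt(peaks$score), fmt(peaks$neglog10p), fmt(peaks$neglog10q)),
    narrowPeak = cbind(base, fmt(peaks$score), fmt(peaks$neglog10p), fmt(peaks$neglog10q),
                       fmt(peaks$summit))
  )
  writeLines(apply(out, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read gene models from GFF3 or GTF
#'
#' Only records of feature type `gene` are retained; 1-based inclusive file
#' coordinates are converted to internal 0-based half-open, and strand-aware
#' TSS/TES positions are derived. Parsing is delegated to
#' [rtracklayer::import()].
#'
#' @param path Path to a GFF3 or GTF file.
#' @param dialect `"gff3"` or `"gtf"`.
#' @return Gene-model data frame (see [validate_genes()]).
#' @export
read_gene_models <- function(path, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  gr <- rtracklayer::import(path, format = dialect)
  md <- S4Vectors::mcols(gr)
  gr <- gr[!is.na(md$type) & as.character(md$type) == "gene"]
  md <- S4Vectors::mcols(gr)
  ids <- if ("gene_id" %in% names(md) && !all(is.na(md$gene_id))) {
    as.character(md$gene_id)
  } else if ("ID" %in% names(md)) {
    as.character(md$ID)
  } else {
    stop("no gene_id/ID attribute found in ", path)
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) stop("unknown strand symbol in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in ", path, ": ", ids[duplicated(ids)][1L])
  }
  gene_models(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand
  )
}

#' Write gene models as GFF3
#'
#' @param genes Gene-model data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  validate_genes(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$gene_id <- genes$gene_id
  S4Vectors::mcols(gr)$source <- "epitrichome"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a TPM expression table
#'
#' Expects a tab-separated table with a `gene_id` column followed by one
#' numeric column per sample. Sample names of the form `tissue_replicate`
#' are parsed into sample metadata.
#'
#' @param path Path to the TSV file.
#' @return An [expression_table()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop("expression table must have a gene_id column")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric cell in expression table at row %d, column %d",
                 bad[1, 1], bad[1, 2] + 1L))
  }
  rownames(m) <- df$gene_id
  expression_table(m)
}

#' Write a TPM expression table
#' @param expr An `expression_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_table"))
  df <- data.frame(gene_id = rownames(expr$tpm), expr$tpm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' @param path TSV with columns `gene_id`, `log2fc`, `pvalue`, `padj`.
#' @param contrast Optional contrast label attached as an attribute.
#' @return Validated DE data frame.
#' @export
read_de_table <- function(path, contrast = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_de_table(df)
  if (!is.null(contrast)) attr(df, "contrast") <- contrast
  df
}

#' Write a differential-expression table
#' @param de Validated DE data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  validate_de_table(de)
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Bins must be sorted by `(chrom, start)` and non-overlapping; violations
#' raise an error rather than being silently reordered.
#'
#' @param path Path to a bedGraph file.
#' @param label Track label (defaults to the file name).
#' @return Track data frame with a `label` attribute.
#' @export
read_signal <- function(path, label = NULL) {
  lines <- read_tab_lines(path)
  lines <- lines[!startsWith(lines, "track")]
  if (!length(lines)) {
    x <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    value = numeric(), stringsAsFactors = FALSE)
  } else {
    fields <- split_fields(lines, 4L, path)
    x <- data.frame(
      chrom = vapply(fields, `[[`, character(1), 1),
      start = num_or_na(vapply(fields, `[[`, character(1), 2), absent = character()),
      end = num_or_na(vapply(fields, `[[`, character(1), 3), absent = character()),
      value = num_or_na(vapply(fields, `[[`, character(1), 4), absent = character()),
      stringsAsFactors = FALSE
    )
  }
  validate_track(x)
  attr(x, "label") <- if (is.null(label)) basename(path) else label
  x
}

#' Write a bedGraph signal track
#' @param track Track data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(track, path) {
  validate_track(track)
  out <- sprintf("%s\t%d\t%d\t%s", track$chrom, as.integer(track$start),
                 as.integer(track$end),
                 format(track$value, scientific = FALSE, trim = TRUE, digits = 10))
  writeLines(out, path)
  invisible(path)
}

#' Read FASTA sequences
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning an
#' upper-cased named character vector. Duplicate sequence ids are an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ", ids[duplicated(ids)][1L])
  }
  stats::setNames(toupper(as.character(ss)), ids)
}

#' Write FASTA sequences
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read motifs in JASPAR text format
#'
#' Accepts both the bracketed layout (`A [ 3 5 ... ]`) and the matrix-only
#' layout (four bare numeric rows per motif). Header lines start with `>`
#' and carry `motif_id` and an optional name/family token.
#'
#' @param path Path to a JASPAR-format text file.
#' @return List of [motif_pfm()] objects.
#' @export
read_jaspar <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) stop("no motif header ('>') found in ", path)
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    hdr <- trimws(sub("^>", "", lines[heads[i]]))
    toks <- strsplit(hdr, "\\s+")[[1]]
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) < 4L) stop("motif ", toks[1], " has fewer than 4 matrix rows")
    body <- body[1:4]
    rows <- lapply(seq_along(body), function(j) {
      ln <- gsub("^[ \t]*[ACGTacgt][ \t]*", "", body[j])
      ln <- gsub("[\\[\\]]", " ", ln, perl = TRUE)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (any(is.na(vals))) {
        stop(sprintf("non-numeric cell in motif %s, matrix row %d", toks[1], j))
      }
      vals
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop("ragged matrix rows in motif ", toks[1])
    }
    out[[i]] <- motif_pfm(
      motif_id = toks[1],
      counts = do.call(rbind, rows),
      family = if (length(toks) > 1L) toks[2] else NA_character_
    )
  }
  out
}

#' Write motifs in JASPAR text format (bracketed layout)
#' @param motifs List of `motif_pfm` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(motifs, path) {
  if (inherits(motifs, "motif_pfm")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    fam <- if (is.na(m$family)) "" else paste0(" ", m$family)
    writeLines(sprintf(">%s%s", m$motif_id, fam), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(m$counts[b, ], trim = TRUE), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a two-column term map (term_id, gene_id)
#'
#' @param path TSV with columns `term_id` and `gene_id` (header required).
#' @return Named list mapping term ids to character vectors of gene ids.
#' @export
read_term_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term_id", "gene_id") %in% names(df))) {
    stop("term map must have term_id and gene_id columns")
  }
  split(df$gene_id, df$term_id)
}

#' Write a term map as two-column TSV
#' @param term_map Named list of gene-id vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_term_map <- function(term_map, path) {
  df <- data.frame(
    term_id = rep(names(term_map), lengths(term_map)),
    gene_id = unlist(term_map, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
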