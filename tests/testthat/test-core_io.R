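# Readers/writers: field mapping, coordinate conventions, absent-value
# sentinels, error contracts, and record-level round-trip identity.

tmpfile <- function(ext) withr::local_tempfile(fileext = ext, .local_envir = parent.frame())

test_that("narrowPeak fields map directly and sentinels mean absent", {
  f <- tmpfile(".narrowPeak")
  writeLines(c("chr1\t100\t600\tp1\t0\t.\t8.5\t12.0\t9.1\t250",
               "chr2\t0\t50\t.\t0\t+\t-1\t-1\t-1\t-1"), f)
  p <- read_peaks(f, "narrowPeak")
  expect_equal(p$chrom, c("chr1", "chr2"))
  expect_equal(p$start, c(100, 0))
  expect_equal(p$end, c(600, 50))
  expect_equal(p$name[1], "p1")
  expect_equal(p$score, c(8.5, NA))
  expect_equal(p$neglog10p, c(12.0, NA))
  expect_equal(p$summit, c(250, NA))
  expect_equal(p$strand, c(".", "+"))
})

test_that("empty peak file reads as an empty peak set", {
  f <- tmpfile(".narrowPeak")
  file.create(f)
  expect_identical(nrow(read_peaks(f, "narrowPeak")), 0L)
})

test_that("malformed peak files raise errors naming the line", {
  f <- tmpfile(".narrowPeak")
  writeLines(c("chr1\t1\t10\tp\t0\t.\t1\t1\t1\t5", "chr1\t5"), f)
  expect_error(read_peaks(f, "narrowPeak"), "line 2")
  writeLines("chr1\t600\t100\tp\t0\t.\t1\t1\t1\t5", f)
  expect_error(read_peaks(f, "narrowPeak"), "start >= end")
  writeLines("chr1\t-5\t100\tp\t0\t.\t1\t1\t1\t5", f)
  expect_error(read_peaks(f, "narrowPeak"), "negative coordinate")
})

test_that("peak read/write round-trips 1000 random records in each dialect", {
  set.seed(42)
  n <- 1000
  iv <- rand_intervals(n)
  peaks <- data.frame(
    iv, name = sprintf("pk%04d", seq_len(n)),
    score = round(runif(n, 0, 50), 4), strand = sample(c("+", "-", "."), n, TRUE),
    neglog10p = round(runif(n, 0, 30), 4), neglog10q = round(runif(n, 0, 20), 4),
    summit = ifelse(runif(n) < 0.1, NA,
                    floor(runif(n, 0, iv$end - iv$start))),
    stringsAsFactors = FALSE
  )
  for (dialect in c("narrowPeak", "broadPeak", "bed6")) {
    f <- tmpfile(paste0(".", dialect))
    write_peaks(peaks, f, dialect)
    back <- read_peaks(f, dialect)
    cols <- switch(dialect,
      narrowPeak = c("chrom", "start", "end", "name", "score", "strand",
                     "neglog10p", "neglog10q", "summit"),
      broadPeak = c("chrom", "start", "end", "name", "score", "strand",
                    "neglog10p", "neglog10q"),
      bed6 = c("chrom", "start", "end", "name", "score", "strand")
    )
    expect_equal(back[, cols], peaks[, cols], ignore_attr = TRUE)
  }
})

test_that("gene models convert GFF3 coordinates and derive strand-aware TSS", {
  f <- tmpfile(".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gA",
    "chr1\tsrc\texon\t1001\t1500\t.\t+\t.\tID=gA.e1;Parent=gA",
    "chr1\tsrc\tgene\t5001\t6000\t.\t-\t.\tID=gB"
  ), f)
  g <- read_gene_models(f, "gff3")
  expect_equal(nrow(g), 2L)
  expect_equal(g$start[g$gene_id == "gA"], 1000)
  expect_equal(g$end[g$gene_id == "gA"], 2000)
  expect_equal(g$tss[g$gene_id == "gA"], 1000)
  expect_equal(g$tes[g$gene_id == "gA"], 1999)
  # minus strand: TSS is the last covered base
  expect_equal(g$tss[g$gene_id == "gB"], 5999)
  expect_equal(g$tes[g$gene_id == "gB"], 5000)
})

test_that("only gene records are retained from mixed-feature annotation", {
  f <- tmpfile(".gff3")
  genes <- sprintf("chr1\tsrc\tgene\t%d\t%d\t.\t+\t.\tID=g%d",
                   (1:5) * 10000, (1:5) * 10000 + 999, 1:5)
  exons <- sprintf("chr1\tsrc\texon\t%d\t%d\t.\t+\t.\tID=e%d;Parent=g1",
                   10000 + (1:50) * 10, 10000 + (1:50) * 10 + 5, 1:50)
  writeLines(c("##gff-version 3", genes, exons), f)
  # oracle: count gene lines directly
  n_gene_lines <- sum(grepl("\tgene\t", readLines(f)))
  g <- read_gene_models(f, "gff3")
  expect_equal(nrow(g), n_gene_lines)
  expect_equal(nrow(g), 5L)
})

test_that("duplicate gene ids and unknown strands are rejected", {
  f <- tmpfile(".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\tsrc\tgene\t500\t900\t.\t+\t.\tID=g1"), f)
  expect_error(read_gene_models(f, "gff3"), "duplicate gene_id")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t100\t.\t*\t.\tID=g1"), f)
  expect_error(read_gene_models(f, "gff3"), "strand")
})

test_that("gene model write/read round-trips", {
  g <- gene_models(c("g1", "g2"), "chr1", c(100, 9000), c(2100, 12000), c("+", "-"))
  f <- tmpfile(".gff3")
  write_gene_models(g, f)
  back <- read_gene_models(f, "gff3")
  expect_equal(back[order(back$gene_id), names(g)[1:7]],
               g[order(g$gene_id), 1:7], ignore_attr = TRUE)
})

test_that("expression tables read with matching dimensions and typed errors", {
  f <- tmpfile(".tsv")
  set.seed(7)
  m <- matrix(round(rexp(90, 0.1), 3), 10, 9)
  hdr <- as.vector(outer(c("trichome", "stem", "leaf"), 1:3,
                         function(t, r) paste0(t, "_", r)))
  df <- data.frame(gene_id = sprintf("g%02d", 1:10), m)
  names(df)[-1] <- hdr
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  # dimension oracle from raw line/field counts
  raw <- readLines(f)
  expect_equal(length(raw) - 1L, 10L)
  expect_equal(length(strsplit(raw[1], "\t")[[1]]) - 1L, 9L)
  e <- read_expression(f)
  expect_s3_class(e, "expression_table")
  expect_equal(dim(e), c(10L, 9L))
  expect_setequal(unique(e$samples$tissue), c("trichome", "stem", "leaf"))
  df[3, 4] <- "oops"
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(f), "row|column|non-numeric")
})

test_that("bedGraph reader enforces sortedness and round-trips", {
  f <- tmpfile(".bedGraph")
  writeLines(c("chr1\t100\t200\t1.5", "chr1\t0\t100\t2.0"), f)
  expect_error(read_signal(f), "unsorted track")
  tr <- uniform_track(50, 100, 1.25)
  tr$value <- round(runif(50, 0, 9), 4)
  write_signal(tr, f)
  expect_equal(read_signal(f), tr, ignore_attr = TRUE)
})

test_that("JASPAR reader handles bracketed and matrix-only layouts", {
  f <- tmpfile(".jaspar")
  writeLines(c(
    ">MA0001.1 FAM1",
    "A [ 3 5 2 0 1 9 8 1 ]",
    "C [ 1 1 6 0 0 0 0 2 ]",
    "G [ 4 2 1 9 8 0 1 3 ]",
    "T [ 2 2 1 1 1 1 1 4 ]",
    ">MA0002.1",
    "1 2 3",
    "4 5 6",
    "7 8 9",
    "1 1 1"
  ), f)
  ms <- read_jaspar(f)
  expect_length(ms, 2L)
  expect_equal(ncol(ms[[1]]$counts), 8L)
  expect_equal(ms[[1]]$family, "FAM1")
  expect_equal(unname(ms[[1]]$counts["A", 2]), 5)
  expect_equal(ncol(ms[[2]]$counts), 3L)
  # round trip
  f2 <- tmpfile(".jaspar")
  write_jaspar(ms, f2)
  back <- read_jaspar(f2)
  expect_equal(back[[1]]$counts, ms[[1]]$counts)
  expect_equal(back[[2]]$motif_id, "MA0002.1")
})

test_that("FASTA round-trips and rejects duplicate ids", {
  f <- tmpfile(".fa")
  seqs <- c(chrA = "ACGTACGTAACC", chrB = "GGGTTTAAACCC")
  write_fasta(seqs, f)
  expect_equal(read_fasta(f), seqs)
  writeLines(c(">x", "ACGT", ">x", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate sequence id")
})

test_that("parsed objects enforce their type invariants", {
  expect_error(genomic_intervals("chr1", 10, 10), "start >= end")
  expect_error(genomic_intervals("chr1", -1, 10), "negative")
  expect_error(gene_models("g1", "chr1", 0, 100, "*"), "strand")
  expect_error(motif_pfm("m", matrix(1, 4, 1)), "length")
  expect_error(motif_pfm("m", matrix(c(rep(1, 4), rep(0, 4)), 4, 2)),
               "non-positive")
  expect_error(expression_table(matrix(-1, 1, 1, dimnames = list("g", "s"))),
               ">= 0")
})
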