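# The synthetic study generator: determinism, placement guarantees, planted
# structure, file round-trips and the truth evaluator.

test_that("identical seeds give identical bundles", {
  b1 <- simulate_study(small_synth_config(seed = 5), tracks = FALSE)
  b2 <- simulate_study(small_synth_config(seed = 5), tracks = FALSE)
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$peaks, b2$peaks)
  expect_identical(b1$expression$tpm, b2$expression$tpm)
  expect_identical(b1$manifest, b2$manifest)
  b3 <- simulate_study(small_synth_config(seed = 6), tracks = FALSE)
  expect_false(identical(b1$genome, b3$genome))
})

test_that("manifest counts equal the configured counts", {
  cfg <- synthetic_config(seed = 2)
  b <- simulate_study(cfg, tracks = FALSE)
  expect_equal(nrow(b$manifest$enhancer_pair), 25L)
  expect_equal(nrow(b$manifest$de_gene), 40L)
  expect_equal(nrow(b$manifest$bivalent_gene), 15L)
  expect_equal(nrow(b$genes), 300L)
  # intergenic gaps respect the 1 kb minimum
  for (ch in unique(b$genes$chrom)) {
    g <- b$genes[b$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] - g$end[-nrow(g)] >= 1000))
  }
  # enhancer loci are distal and their paired gene is the nearest TSS
  nn <- nearest_tss(b$manifest$enhancer_pair, b$genes)
  expect_equal(nn$gene_id, b$manifest$enhancer_pair$gene_id)
  expect_true(all(nn$distance >= 2000 & nn$distance <= 50000))
})

test_that("with noise off every replicate-1 peak matches replicate 2 exactly", {
  cfg <- small_synth_config(seed = 3, jitter_sd = 0, spurious_rate = 0)
  b <- simulate_study(cfg, tracks = FALSE)
  for (ts in names(b$peaks)) {
    for (mk in names(b$peaks[[ts]])) {
      r1 <- b$peaks[[ts]][[mk]]$rep1
      r2 <- b$peaks[[ts]][[mk]]$rep2
      expect_equal(r1[, c("chrom", "start", "end")],
                   r2[, c("chrom", "start", "end")])
    }
  }
})

test_that("planted expression structure is recoverable from the tables", {
  b <- simulate_study(synthetic_config(seed = 4), tracks = FALSE)
  part <- partition_by_expression(b$expression, "trichome")
  # untranscribed fraction in the focal tissue reflects baseline minus induction
  expect_true(all(b$manifest$de_gene$gene_id %in% part$transcribed))
  part_stem <- partition_by_expression(b$expression, "stem")
  expect_true(all(b$manifest$de_gene$gene_id %in% part_stem$untranscribed))
  # measured log2FC tracks the planted effect
  de <- simple_de(b$expression, "trichome", "stem")
  m <- match(b$manifest$de_gene$gene_id, de$gene_id)
  expect_lt(median(abs(de$log2fc[m] - b$manifest$de_gene$true_log2fc)), 0.25)
})

test_that("true replicate score pairs carry the configured rank correlation", {
  s1 <- s2 <- numeric(0)
  for (seed in 8:9) {
    b <- simulate_study(synthetic_config(seed = seed), tracks = FALSE)
    for (ts in names(b$peaks)) {
      for (mk in names(b$peaks[[ts]])) {
        r1 <- b$peaks[[ts]][[mk]]$rep1
        r2 <- b$peaks[[ts]][[mk]]$rep2
        true1 <- r1[!grepl("_sp", r1$name), ]
        true2 <- r2[!grepl("_sp", r2$name), ]
        m <- match(sub("r1", "r2", true1$name), true2$name)
        s1 <- c(s1, true1$neglog10p)
        s2 <- c(s2, true2$neglog10p[m])
      }
    }
  }
  expect_gte(length(s1), 2000L)
  expect_lt(abs(cor(s1, s2, method = "spearman") - 0.8), 0.05)
})

test_that("bundles round-trip through their external formats", {
  dir <- withr::local_tempdir()
  cfg <- small_synth_config(seed = 9, bin_width = 1000)
  b <- simulate_study(cfg, tracks = TRUE)
  write_bundle(b, dir)
  genes <- read_gene_models(file.path(dir, "genes.gff3"), "gff3")
  expect_equal(genes$gene_id, b$genes$gene_id)
  expect_equal(genes$tss, b$genes$tss)
  genome <- read_fasta(file.path(dir, "genome.fa"))
  expect_identical(genome, b$genome)
  pk <- read_peaks(file.path(dir, "peaks", "trichome_H3K4me3_rep1.narrowPeak"),
                   "narrowPeak")
  expect_equal(pk[, c("chrom", "start", "end", "score")],
               b$peaks$trichome$H3K4me3$rep1[, c("chrom", "start", "end", "score")])
  expr <- read_expression(file.path(dir, "tpm.tsv"))
  expect_equal(expr$tpm, b$expression$tpm)
  motifs <- read_jaspar(file.path(dir, "motifs.jaspar"))
  expect_equal(motifs[[1]]$counts, b$motifs$planted$counts)
  tr <- read_signal(file.path(dir, "tracks", "trichome_H3K4me3_rep1.bedGraph"))
  expect_equal(tr$value, b$tracks$trichome_H3K4me3_rep1$value, tolerance = 1e-9)
  tm <- read_term_map(file.path(dir, "term_map.tsv"))
  expect_equal(sort(names(tm)), sort(names(b$term_map)))
})

test_that("planted motif instances sit in the genome at the recorded positions", {
  b <- simulate_study(synthetic_config(seed = 10), tracks = FALSE)
  cons <- paste(rownames(b$motifs$planted$counts)[
    apply(b$motifs$planted$counts, 2, which.max)], collapse = "")
  mi <- b$manifest$motif_instances
  expect_gt(nrow(mi), 0L)
  for (i in seq_len(nrow(mi))) {
    found <- unname(substr(b$genome[mi$chrom[i]], mi$pos[i] + 1, mi$pos[i] + 10))
    want <- if (mi$strand[i] == "+") cons else
      chartr("ACGT", "TGCA", paste(rev(strsplit(cons, "")[[1]]), collapse = ""))
    expect_identical(found, want)
  }
})

test_that("infeasible configurations fail before generating anything", {
  expect_error(synthetic_config(n_genes = 5000L), "infeasible placement")
  expect_error(synthetic_config(n_de_genes = 100L), "untranscribed pool")
  expect_error(synthetic_config(n_enhancers = 50L), "n_enhancers")
})

test_that("truth_eval applies the matching rule of each entity kind", {
  man <- list(
    de_gene = data.frame(gene_id = c("g1", "g2", "g3", "g4")),
    tissue_specific_peak = data.frame(
      mark = c("H3K4me3", "H3K4me3"), chrom = "chr1",
      start = c(1000, 5000), end = c(2000, 6000)),
    enhancer_pair = data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                               start = c(100, 900), end = c(300, 1200))
  )
  # half-correct gene prediction: precision 1, recall 0.5, F1 = 2/3
  ev <- truth_eval(c("g1", "g2"), man, "de_gene")
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 0.5)
  expect_equal(ev$f1, 2 / 3)
  # identity gives perfect scores
  evp <- truth_eval(man$tissue_specific_peak, man, "tissue_specific_peak")
  expect_equal(evp$f1, 1)
  # reciprocal 0.5 rule: a shifted peak covering < half fails
  shifted <- data.frame(mark = "H3K4me3", chrom = "chr1", start = 1800, end = 2800)
  expect_equal(truth_eval(shifted, man, "tissue_specific_peak")$precision, 0)
  half <- data.frame(mark = "H3K4me3", chrom = "chr1", start = 1400, end = 2400)
  expect_equal(truth_eval(half, man, "tissue_specific_peak")$precision, 1)
  # pair matching needs the same gene AND locus overlap
  good <- data.frame(gene_id = "g1", chrom = "chr1", start = 150, end = 250)
  wrong_gene <- data.frame(gene_id = "g9", chrom = "chr1", start = 150, end = 250)
  expect_equal(truth_eval(good, man, "enhancer_pair")$recall, 0.5)
  expect_equal(truth_eval(wrong_gene, man, "enhancer_pair")$recall, 0)
  # degenerate empty prediction
  ev0 <- truth_eval(character(), man, "de_gene")
  expect_true(ev0$degenerate)
  expect_equal(ev0$precision, 0)
  expect_equal(ev0$recall, 0)
  expect_error(truth_eval(good, man, "unknown_kind"), "arg")
})
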