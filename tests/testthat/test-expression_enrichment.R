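# Transcriptome statistics: partition, stand-in DE test, BH, ORA,
# preranked GSEA and gene-set correlation.

mk_expr <- function(tpm, tissues = c("trichome", "stem"), reps = 3) {
  colnames(tpm) <- as.vector(outer(seq_len(reps), tissues,
                                   function(r, t) paste0(t, "_", r)))
  expression_table(tpm)
}

test_that("transcription partition uses the mean TPM across replicates", {
  tpm <- rbind(gA = c(0.5, 1.5, 2.0, 0, 0, 0),
               gB = c(0, 0, 0, 5, 5, 5),
               gC = c(0.2, 0.3, 0.4, 0, 0, 0))
  e <- mk_expr(tpm)
  part <- partition_by_expression(e, "trichome")
  expect_equal(part$transcribed, "gA")   # mean 1.33 >= 1
  expect_setequal(part$untranscribed, c("gB", "gC"))
  expect_setequal(c(part$transcribed, part$untranscribed), rownames(tpm))
  expect_error(partition_by_expression(e, "root"), "unknown tissue")
  # definitional oracle on random data
  set.seed(31)
  tpm2 <- matrix(rexp(600, 0.5), 100)
  rownames(tpm2) <- sprintf("g%03d", 1:100)
  e2 <- mk_expr(tpm2)
  p2 <- partition_by_expression(e2, "stem")
  expect_setequal(p2$transcribed,
                  rownames(tpm2)[rowMeans(tpm2[, 4:6]) >= 1])
})

test_that("simple_de is antisymmetric and null-calibrated", {
  set.seed(32)
  tpm <- matrix(rep(exp(rnorm(100, 2, 1)), each = 6), ncol = 6, byrow = TRUE) *
    matrix(exp(rnorm(600, 0, 0.1)), ncol = 6)
  rownames(tpm) <- sprintf("g%03d", 1:100)
  e <- mk_expr(tpm)
  de_ab <- simple_de(e, "trichome", "stem")
  de_ba <- simple_de(e, "stem", "trichome")
  expect_equal(de_ab$log2fc, -de_ba$log2fc)
  expect_equal(de_ab$pvalue, de_ba$pvalue)
  expect_true(all(de_ab$padj >= de_ab$pvalue))
  # constant genes in identical groups: p = 1, lfc = 0
  tpmc <- matrix(4, 10, 6, dimnames = list(sprintf("c%d", 1:10), NULL))
  dec <- simple_de(mk_expr(tpmc), "trichome", "stem")
  expect_true(all(dec$pvalue == 1))
  expect_true(all(dec$log2fc == 0))
  # type-I error near nominal on null data (no planted effect)
  rej <- vapply(1:20, function(s) {
    set.seed(s)
    t0 <- matrix(rep(exp(rnorm(100, 2, 1)), each = 6), ncol = 6, byrow = TRUE) *
      matrix(exp(rnorm(600, 0, 0.3)), ncol = 6)
    rownames(t0) <- sprintf("g%03d", 1:100)
    mean(simple_de(mk_expr(t0), "trichome", "stem")$pvalue < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
  one_rep <- tpm[, c(1, 4, 5, 6), drop = FALSE]
  colnames(one_rep) <- c("trichome_1", "stem_1", "stem_2", "stem_3")
  expect_error(simple_de(expression_table(one_rep), "trichome", "stem"),
               "replicates")
})

test_that("a strongly induced gene is detected in nearly every simulation", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    base <- exp(rnorm(100, 2, 1))
    tpm <- matrix(rep(base, each = 6), ncol = 6, byrow = TRUE)
    tpm[1, 1:3] <- tpm[1, 1:3] * 2^6       # planted log2FC 6 in trichome
    tpm <- tpm * matrix(exp(rnorm(600, 0, 0.1)), ncol = 6)  # CV ~ 10%
    rownames(tpm) <- sprintf("g%03d", 1:100)
    de <- simple_de(mk_expr(tpm), "trichome", "stem")
    de$padj[1] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(33)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-15)
    # monotone in the input order statistics
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("both-contrast DE filter uses strict thresholds in both tables", {
  de1 <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(3, 3, 2.0, 4), pvalue = 0.001,
                    padj = c(0.01, 0.01, 0.01, 0.2))
  de2 <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(3, 1, 3, 3), pvalue = 0.001,
                    padj = c(0.01, 0.01, 0.01, 0.01))
  sel <- filter_tissue_specific_de(de1, de2)
  expect_equal(sel, "a")   # b fails contrast 2, c fails strict lfc, d fails padj
})

test_that("hypergeometric ORA matches tail summation", {
  universe <- sprintf("g%02d", 1:20)
  term_map <- list(T1 = universe[1:5], T2 = universe[6:17])
  query <- universe[c(1:4, 18)]           # k = 4 of K = 5, n = 5
  res <- ora_hypergeometric(query, term_map, universe)
  r1 <- res[res$term_id == "T1", ]
  expect_equal(r1$p, oracle_hyper_upper(4, 5, 5, 20), tolerance = 1e-12)
  expect_equal(r1$k, 4L)
  expect_true(all(res$padj >= res$p))
  # k = 0 gives p = 1; query == term gives the geometry's smallest p
  res0 <- ora_hypergeometric(universe[18:20], list(T = universe[1:5]), universe)
  expect_equal(res0$p, 1)
  resq <- ora_hypergeometric(universe[1:5], list(T = universe[1:5]), universe)
  expect_equal(resq$p, oracle_hyper_upper(5, 5, 5, 20), tolerance = 1e-12)
  expect_error(ora_hypergeometric(character(), term_map, universe), "empty query")
  expect_error(ora_hypergeometric("zz", term_map, universe), "subset")
})

test_that("GSEA running sum matches a hand computation on a 10-gene list", {
  scores <- setNames(rep(1, 10), letters[1:10])
  # with equal scores and hits at the top 3: increments 1/3 (hit), -1/7 (miss)
  res <- gsea_preranked(scores, letters[1:3], n_perm = 100, seed = 1)
  run <- cumsum(c(1/3, 1/3, 1/3, rep(-1/7, 7)))
  expect_equal(res$es, run[which.max(abs(run))], tolerance = 1e-12)
  expect_equal(res$es, 1)
  expect_gt(res$es, 0)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  # reversing the ranking negates the ES of the same set
  sc <- setNames(10:1, letters[1:10])
  up <- gsea_preranked(sc, c("a", "b", "c"), n_perm = 50, seed = 1)
  dn <- gsea_preranked(-sc, c("a", "b", "c"), n_perm = 50, seed = 1)
  expect_equal(up$es, -dn$es, tolerance = 1e-12)
  expect_lte(abs(up$es), 1)
  expect_error(gsea_preranked(sc, c("zz")), "disjoint")
})

test_that("an evenly spread gene set is not called enriched", {
  set.seed(34)
  scores <- setNames(sort(rnorm(300), decreasing = TRUE), sprintf("g%03d", 1:300))
  spread <- names(scores)[seq(8, 300, by = 15)]
  ps <- vapply(1:10, function(s) {
    gsea_preranked(scores, spread, n_perm = 500, seed = s)$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.1), 0.9)
})

test_that("gene-set expression correlation matches its definition", {
  set.seed(35)
  tpm <- matrix(rexp(300, 0.2), 50)
  rownames(tpm) <- sprintf("g%02d", 1:50)
  e <- mk_expr(tpm)
  gs <- rownames(tpm)[1:20]
  got <- geneset_expression_correlation(e, gs)
  expect_equal(got$n_genes, 20L)
  expect_equal(unname(got$matrix),
               unname(cor(tpm[gs, ], method = "spearman")), tolerance = 1e-12)
  # duplicated sample correlates at exactly 1
  e2 <- expression_table(cbind(tpm, dup_1 = tpm[, 1]))
  m2 <- geneset_expression_correlation(e2, gs)$matrix
  expect_equal(m2[1, 7], 1)
  expect_error(geneset_expression_correlation(e, "nope"), "empty")
})
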