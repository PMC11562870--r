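# Interval set operations against independent per-base bitmap and all-pairs
# oracles, plus the exact-test statistics.

test_that("merge_intervals unions, sorts and merges book-ended intervals", {
  x <- genomic_intervals("chr1", c(0, 5), c(10, 15))
  expect_equal(merge_intervals(x)[, c("start", "end")],
               data.frame(start = 0, end = 15))
  expect_equal(nrow(merge_intervals(x[0, ])), 0L)
  # book-ended intervals merge
  y <- genomic_intervals("chr1", c(0, 10), c(10, 20))
  expect_equal(nrow(merge_intervals(y)), 1L)
})

test_that("merged covered bases equal the per-base bitmap union", {
  set.seed(101)
  x <- rand_intervals(1000)
  m <- merge_intervals(x)
  bm <- oracle_bitmap(x, 1e6)
  for (ch in names(bm)) {
    mi <- m[m$chrom == ch, ]
    expect_equal(sum(mi$end - mi$start), sum(bm[[ch]]))
    # merged output must itself cover exactly the bitmap
    bm2 <- oracle_bitmap(mi, 1e6)[[ch]]
    expect_identical(bm2, bm[[ch]])
    # sorted, non-overlapping
    expect_true(all(diff(mi$start) > 0))
    expect_true(all(mi$start[-1] > mi$end[-nrow(mi)]))
  }
})

test_that("intersect respects overlap fractions and reciprocal condition", {
  a <- genomic_intervals("chr1", 0, 100)
  b <- genomic_intervals("chr1", 0, 10)
  # overlap covers only 10% of a: fails f=0.3 reciprocal
  expect_equal(nrow(intersect_intervals(a, b, 0.3, reciprocal = TRUE)), 0L)
  expect_equal(nrow(intersect_intervals(a, b)), 1L)
  frag <- intersect_intervals(genomic_intervals("chr1", 0, 10),
                              genomic_intervals("chr1", 5, 8),
                              mode = "fragment")
  expect_equal(frag[, c("start", "end")], data.frame(start = 5, end = 8))
  expect_error(intersect_intervals(a, b, min_frac_a = 1.2), "\\[0, 1\\]")
})

test_that("intersect and subtract match the all-pairs oracle on random sets", {
  set.seed(202)
  a <- rand_intervals(500)
  b <- rand_intervals(500)
  for (fr in list(c(0, 0), c(0.3, 0.3), c(0.5, 0))) {
    recip <- fr[1] == fr[2] && fr[1] > 0
    got <- intersect_intervals(a, b, fr[1], fr[2], reciprocal = recip)
    want <- oracle_intersect_whole_a(a, b, fr[1], fr[2])
    expect_equal(got[, c("chrom", "start", "end")],
                 a[want, c("chrom", "start", "end")], ignore_attr = TRUE)
  }
  got_sub <- subtract_exclusive(a, b)
  expect_equal(got_sub[, c("chrom", "start", "end")],
               a[oracle_subtract(a, b), c("chrom", "start", "end")],
               ignore_attr = TRUE)
  # fragment mode: total fragment bases equal per-pair oracle total
  frags <- intersect_intervals(a, b, mode = "fragment")
  want_total <- sum(vapply(seq_len(nrow(a)), function(i) {
    j <- oracle_qualifying(a[i, ], b)
    if (!length(j)) return(0)
    sum(pmin(a$end[i], b$end[j]) - pmax(a$start[i], b$start[j]))
  }, numeric(1)))
  expect_equal(sum(frags$end - frags$start), want_total)
})

test_that("subtract_exclusive has whole-interval semantics and partitions A", {
  a <- genomic_intervals("chr1", c(0, 20), c(10, 30))
  b <- genomic_intervals("chr1", 25, 26)
  expect_equal(subtract_exclusive(a, b)$start, 0)
  expect_equal(subtract_exclusive(a, a[0, ]), a, ignore_attr = TRUE)
  set.seed(303)
  ra <- rand_intervals(300)
  rb <- rand_intervals(300)
  kept <- subtract_exclusive(ra, rb)
  hit <- intersect_intervals(ra, rb, mode = "whole_a")
  expect_equal(nrow(kept) + nrow(hit), nrow(ra))
  expect_equal(nrow(intersect_intervals(kept, rb, mode = "whole_a")), 0L)
})

test_that("tissue_specific subtracts every other tissue in turn", {
  target <- genomic_intervals("chr1", c(0, 100), c(50, 150), name = c("p1", "p2"))
  stem <- genomic_intervals("chr1", 10, 20)
  leaf <- genomic_intervals("chr2", 0, 10)
  out <- tissue_specific(target, list(stem, leaf))
  expect_equal(out$name, "p2")
  expect_equal(tissue_specific(target, list(stem[0, ], leaf[0, ])), target,
               ignore_attr = TRUE)
  expect_error(tissue_specific(target, list()), "at least one")
})

test_that("nearest_tss distances, tie-break and errors behave as specified", {
  genes <- gene_models(c("gB", "gA"), "chr1", c(4000, 1400), c(5000, 2400), "+")
  pk <- genomic_intervals("chr1", 1000, 2000)   # midpoint 1500
  nn <- nearest_tss(pk, genes)
  expect_equal(nn$distance, 100)                # TSS 1400 vs midpoint 1500
  pk2 <- genomic_intervals("chr1", 4500, 5500)  # midpoint 5000
  g2 <- gene_models(c("g1", "g2"), "chr1", c(4000, 6001), c(5500, 7000), "+")
  nn2 <- nearest_tss(pk2, g2)
  expect_equal(nn2$gene_id, "g1")
  expect_equal(nn2$distance, 1000)
  # tie: equidistant TSSs resolve to lexicographically smallest gene id
  gt <- gene_models(c("gZ", "gA"), "chr1", c(900, 2900), c(1900, 3900), "+")
  pkt <- genomic_intervals("chr1", 1800, 2000)  # midpoint 1900, both at 1000
  expect_equal(nearest_tss(pkt, gt)$gene_id, "gA")
  expect_error(nearest_tss(genomic_intervals("chrX", 0, 10), genes),
               "chromosome chrX|no gene on chromosome")
  # edges anchor: TSS inside the peak gives distance 0
  ge <- gene_models("g", "chr1", 1500, 2500, "+")
  expect_equal(nearest_tss(genomic_intervals("chr1", 1000, 2000), ge,
                           anchor = "edges")$distance, 0)
})

test_that("nearest_tss matches the exhaustive oracle on random layouts", {
  set.seed(404)
  genes <- gene_models(sprintf("g%02d", 1:50), "chr1",
                       st <- sort(sample.int(9e5, 50)) , st + 1000,
                       sample(c("+", "-"), 50, TRUE))
  peaks <- rand_intervals(200, chroms = "chr1")
  got <- nearest_tss(peaks, genes)
  want <- oracle_nearest_tss(peaks, genes)
  expect_equal(got$gene_id, genes$gene_id[want[, "idx"]])
  expect_equal(got$distance, unname(want[, "distance"]))
})

test_that("distal_filter applies a strict threshold and flags gene-free chromosomes", {
  genes <- gene_models("g1", "chr1", 10000, 12000, "+")
  near <- genomic_intervals("chr1", 8500, 9500)    # midpoint 9000, distance 1000
  boundary <- genomic_intervals("chr1", 8000, 9000) # midpoint 8500, distance 1500
  past <- genomic_intervals("chr1", 7999, 8999)     # midpoint 8499, distance 1501
  expect_equal(nrow(distal_filter(near, genes)), 0L)
  expect_equal(nrow(distal_filter(boundary, genes)), 0L)
  kept <- distal_filter(past, genes)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$tss_distance, 1501)
  orphan <- genomic_intervals("chr9", 0, 100)
  expect_true(distal_filter(orphan, genes)$no_gene_on_chrom)
  expect_error(distal_filter(near, genes, min_distance = -1), ">= 0")
})

test_that("distal_filter equals brute force and partitions at threshold 0", {
  set.seed(505)
  genes <- gene_models(sprintf("g%02d", 1:30), "chr1",
                       st <- sort(sample.int(9e5, 30)), st + 2000,
                       sample(c("+", "-"), 30, TRUE))
  peaks <- rand_intervals(200, chroms = "chr1")
  got <- distal_filter(peaks, genes, 1500)
  want_d <- oracle_nearest_tss(peaks, genes)[, "distance"]
  expect_equal(nrow(got), sum(want_d > 1500))
  expect_setequal(got$start, peaks$start[want_d > 1500])
  at0 <- distal_filter(peaks, genes, 0)
  expect_equal(nrow(at0) + sum(want_d == 0), nrow(peaks))
})

test_that("feature classification follows midpoint priority and sums to 1", {
  genes <- gene_models(c("gP", "gM"), "chr1", c(10000, 30000),
                       c(14000, 34000), c("+", "-"))
  # 500 bp upstream of the plus-strand TSS
  up <- genomic_intervals("chr1", 9300, 9700)   # midpoint 9500, rel -500
  fd <- feature_distribution(up, genes)
  expect_equal(fd$class, "promoter")
  lonely <- genomic_intervals("chr5", 0, 1000)
  expect_equal(feature_distribution(lonely, genes)$class, "intergenic")
  body <- genomic_intervals("chr1", 12000, 12400)
  expect_equal(feature_distribution(body, genes)$class, "gene_body")
  set.seed(606)
  peaks <- rand_intervals(500, chroms = "chr1", len_range = c(100, 2000))
  fd2 <- feature_distribution(peaks, genes)
  expect_equal(sum(fd2$fractions), 1, tolerance = 1e-9)
  expect_equal(sum(fd2$counts), nrow(peaks))
  # per-peak oracle classification
  mids <- floor((peaks$start + peaks$end) / 2)
  oracle_class <- vapply(mids, function(m) {
    rel_tss <- ifelse(genes$strand == "+", m - genes$tss, genes$tss - m)
    rel_tes <- ifelse(genes$strand == "+", m - genes$tes, genes$tes - m)
    if (any(rel_tss >= -1000 & rel_tss <= 100)) "promoter"
    else if (any(rel_tes >= 0 & rel_tes <= 100)) "tts_flank"
    else if (any(m >= genes$start & m < genes$end)) "gene_body"
    else "intergenic"
  }, character(1))
  expect_equal(fd2$class, oracle_class)
})

test_that("Fisher 2x2 matches direct enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p_value,
               34 / 70, tolerance = 1e-12)
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "all-zero")
  or <- fisher_exact_2x2(c(6, 2, 3, 9))
  expect_equal(or$odds_ratio, (6 * 9) / (2 * 3))
  set.seed(707)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 6), 2, 2)
    if (sum(tab) == 0) tab[1, 1] <- 1
    got <- fisher_exact_2x2(tab)$p_value
    expect_equal(got, oracle_fisher_2x2(tab), tolerance = 1e-12)
    expect_gt(got, 0)
    expect_lte(got, 1)
  }
})

test_that("co-localization table behaves at the extremes and p is monotone", {
  a <- genomic_intervals("chr1", c(0, 1000, 5000), c(500, 1500, 5600))
  same <- colocalization_fisher(a, a, 1e6)
  expect_equal(same$table[1, 2], 0)
  expect_equal(same$table[2, 1], 0)
  expect_lt(same$p_value, 1e-3)
  b <- genomic_intervals("chr2", c(0, 1000), c(500, 1500))
  expect_equal(colocalization_fisher(a, b, 1e6)$table[1, 1], 0)
  expect_error(colocalization_fisher(a, a, 100), "genome_size")
  # planted overlap sweep: p non-increasing in the overlap fraction
  set.seed(808)
  base <- rand_intervals(200, chroms = "chr1", len_range = c(500, 1500))
  ps <- vapply(seq(0, 0.9, by = 0.3), function(fr) {
    n_ov <- round(fr * nrow(base))
    b_ov <- base[seq_len(n_ov), , drop = FALSE]
    n_free <- nrow(base) - n_ov
    b_free <- rand_intervals(max(n_free, 1), chroms = "chr1",
                             len_range = c(500, 1500))
    colocalization_fisher(base, rbind(b_ov, b_free), 1e6)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})
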