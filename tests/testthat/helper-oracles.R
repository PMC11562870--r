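# Independent oracles for the interval algebra and the exact tests. These
# are deliberately naive (per-base bitmaps, all-pairs loops, direct
# enumeration) and share no code with the implementation they check.

rand_intervals <- function(n, chroms = c("chr1", "chr2"), genome_len = 1e6,
                           len_range = c(50, 5000)) {
  len <- round(runif(n, len_range[1], len_range[2]))
  start <- floor(runif(n, 0, genome_len - len))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

# covered-base bitmap of an interval set, per chromosome
oracle_bitmap <- function(x, genome_len) {
  out <- list()
  for (ch in unique(x$chrom)) {
    v <- logical(genome_len)
    xi <- x[x$chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(xi))) v[(xi$start[r] + 1):xi$end[r]] <- TRUE
    out[[ch]] <- v
  }
  out
}

# all-pairs qualifying-overlap test between one a interval and a set b
oracle_qualifying <- function(a_row, b, fa = 0, fb = 0) {
  ov <- pmin(a_row$end, b$end) - pmax(a_row$start, b$start)
  ov[b$chrom != a_row$chrom] <- 0
  la <- a_row$end - a_row$start
  lb <- b$end - b$start
  which(ov >= 1 & ov >= fa * la & ov >= fb * lb)
}

oracle_intersect_whole_a <- function(a, b, fa = 0, fb = 0) {
  keep <- vapply(seq_len(nrow(a)), function(i) {
    length(oracle_qualifying(a[i, ], b, fa, fb)) > 0
  }, logical(1))
  which(keep)
}

oracle_subtract <- function(a, b) {
  keep <- vapply(seq_len(nrow(a)), function(i) {
    length(oracle_qualifying(a[i, ], b)) == 0
  }, logical(1))
  which(keep)
}

oracle_nearest_tss <- function(peaks, genes) {
  mid <- floor((peaks$start + peaks$end) / 2)
  t(vapply(seq_len(nrow(peaks)), function(i) {
    gi <- which(genes$chrom == peaks$chrom[i])
    d <- abs(mid[i] - genes$tss[gi])
    best <- gi[d == min(d)]
    best <- best[order(genes$gene_id[best])][1]
    c(idx = best, distance = min(d))
  }, c(idx = 0, distance = 0)))
}

# two-sided Fisher p by direct enumeration over the hypergeometric support
oracle_fisher_2x2 <- function(tab) {
  m <- tab[1, 1] + tab[1, 2]
  nn <- tab[2, 1] + tab[2, 2]
  k <- tab[1, 1] + tab[2, 1]
  support <- max(0, k - nn):min(k, m)
  probs <- dhyper(support, m, nn, k)
  p_obs <- dhyper(tab[1, 1], m, nn, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

oracle_hyper_upper <- function(k, K, n, N) {
  sum(dhyper(k:min(K, n), K, N - K, n))
}

# simulate matched score pairs from the IDR copula mixture, with labels
sim_idr_pairs <- function(n, pi1 = 0.7, mu = 2.5, sigma = 1.3, rho = 0.8) {
  lab <- runif(n) < pi1
  e1 <- rnorm(n)
  e2 <- rnorm(n)
  z1 <- ifelse(lab, mu + sigma * e1, e1)
  z2 <- ifelse(lab, mu + sigma * (rho * e1 + sqrt(1 - rho^2) * e2), e2)
  list(scores = cbind(z1, z2), reproducible = lab)
}

uniform_track <- function(nbins = 100, width = 100, value = 2, chrom = "chr1") {
  data.frame(chrom = chrom, start = (seq_len(nbins) - 1) * width,
             end = seq_len(nbins) * width, value = value,
             stringsAsFactors = FALSE)
}

small_synth_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, n_chrom = 2L, chrom_len = 5e5, n_genes = 80L,
                   n_de_genes = 12L, n_bivalent = 6L, n_enhancers = 8L, ...)
}
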