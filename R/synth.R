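# Seeded generator of a complete miniature multi-tissue histone-mark study:
# genome, annotation, per-tissue/per-replicate peak calls, signal tracks,
# expression tables, motifs -- with a ground-truth manifest so every
# pipeline stage has recoverable planted structure. The generator emits the
# downstream products a peak-calling pipeline would produce (peaks and
# tracks), never reads.

#' Configuration for the synthetic study generator
#'
#' Defaults define the reference study conditions: a 3 x 1 Mb genome with
#' 300 genes across three tissues (trichome, stem, leaf), 2 ChIP replicates
#' and 3 RNA replicates, 40 trichome-induced DE genes (planted log2FC
#' uniform on 2.5-8), 15 bivalent trichome genes, 25 trichome-only distal
#' H3K56ac enhancer loci each guaranteed nearest to its paired DE gene,
#' replicate boundary jitter of sd 50 bp, a spurious-peak rate of 0.2 of
#' the true count per replicate, and replicate score correlation 0.8.
#'
#' @param seed Master seed; one RNG stream per output kind is derived from
#'   it, so adding an output kind does not perturb the others.
#' @param n_chrom,chrom_len Number and length (bp) of chromosomes.
#' @param n_genes Total genes (log-normal lengths, median 3 kb, min 500 bp,
#'   min intergenic gap 1 kb).
#' @param n_de_genes Trichome-induced genes with planted log2FC ~ U(2.5, 8)
#'   versus both other tissues.
#' @param n_bivalent Trichome genes carrying both H3K4me3 and H3K27me3.
#' @param n_enhancers Trichome-only distal H3K56ac loci placed 2-50 kb from
#'   the TSS of a planted DE gene, with that gene guaranteed nearest.
#' @param n_chip_reps,n_rna_reps Replicates for ChIP peaks and RNA samples.
#' @param untranscribed_frac Fraction of genes with baseline TPM < 1.
#' @param tpm_median Median baseline TPM of transcribed genes (log-normal).
#' @param replicate_cv Coefficient of variation of replicate TPM noise.
#' @param lfc_range Range of the planted trichome log2 fold change.
#' @param narrow_width Width range (bp) of TSS-centred narrow peaks
#'   (H3K4me3/H3K56ac).
#' @param broad_flank Broad domains span the gene body +/- this many bp
#'   (H3K27me3/H2A.Z on untranscribed genes).
#' @param jitter_sd Replicate boundary jitter (bp, sd of a normal).
#' @param spurious_rate Per-replicate spurious peaks as a fraction of the
#'   true count.
#' @param rho_scores Replicate score correlation of true peaks (bivariate
#'   log-normal).
#' @param motif_plant_rate Fraction of enhancer loci carrying the planted
#'   motif.
#' @param gc GC content of the random genome.
#' @param enhancer_dist Allowed enhancer midpoint-to-TSS distance range (bp).
#' @param bin_width Signal-track bin width (bp).
#' @param tissues Tissue labels; the first is the focal tissue.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_chrom = 3L, chrom_len = 1e6,
                             n_genes = 300L, n_de_genes = 40L,
                             n_bivalent = 15L, n_enhancers = 25L,
                             n_chip_reps = 2L, n_rna_reps = 3L,
                             untranscribed_frac = 0.2, tpm_median = 8,
                             replicate_cv = 0.1, lfc_range = c(2.5, 8),
                             narrow_width = c(400, 1500), broad_flank = 1000,
                             jitter_sd = 50, spurious_rate = 0.2,
                             rho_scores = 0.8, motif_plant_rate = 0.6,
                             gc = 0.42, enhancer_dist = c(2000, 50000),
                             bin_width = 200,
                             tissues = c("trichome", "stem", "leaf")) {
  cfg <- as.list(environment())
  n_untr <- round(untranscribed_frac * n_genes)
  if (n_de_genes > n_untr) {
    stop("n_de_genes exceeds the untranscribed pool (", n_untr, ")")
  }
  if (n_bivalent > n_genes - n_untr) stop("n_bivalent exceeds the transcribed pool")
  if (n_enhancers > n_de_genes) stop("n_enhancers exceeds n_de_genes")
  if (n_genes * 3500 > n_chrom * chrom_len) {
    stop("infeasible placement: too many genes for the configured genome")
  }
  if (length(tissues) < 2L) stop("need >= 2 tissues")
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "synthetic_config: seed %d; %d x %.2g bp genome; %d genes (%d DE, %d bivalent); %d enhancers; jitter %g bp; spurious rate %g\n",
    x$seed, x$n_chrom, x$chrom_len, x$n_genes, x$n_de_genes, x$n_bivalent,
    x$n_enhancers, x$jitter_sd, x$spurious_rate))
  invisible(x)
}

# derive one sub-seed per output kind from the master seed
stream_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(2^31 - 2, 8),
                  c("genome", "genes", "expression", "peaks", "enhancers",
                    "motifs", "tracks", "terms"))
}

rlnorm_clamped <- function(n, median, sdlog, lo, hi) {
  pmin(pmax(stats::rlnorm(n, log(median), sdlog), lo), hi)
}

# correlated log-normal replicate score pairs
score_pairs <- function(n, rho, meanlog = log(8), sdlog = 0.7) {
  e1 <- rnorm(n)
  e2 <- rnorm(n)
  z1 <- meanlog + sdlog * e1
  z2 <- meanlog + sdlog * (rho * e1 + sqrt(1 - rho^2) * e2)
  cbind(exp(z1), exp(z2))
}

# --- gene placement -------------------------------------------------------

place_genes <- function(cfg) {
  n <- cfg$n_genes
  per <- diff(round(seq(0, n, length.out = cfg$n_chrom + 1)))
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chrom))

  lens <- round(rlnorm_clamped(n, 3000, 0.45, 500, 12000))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_untr <- round(cfg$untranscribed_frac * n)
  untr_pool <- sort(sample.int(n, n_untr))
  de_idx <- sort(sample(untr_pool, cfg$n_de_genes))
  biv_idx <- sort(sample(setdiff(seq_len(n), untr_pool), cfg$n_bivalent))
  carrier <- sort(union(untr_pool, biv_idx))

  chrom <- rep(chrom_names, per)
  # enhancer genes: distinct TSS-side gaps (gap index within chromosome)
  idx_within <- sequence(per)
  tss_gap <- ifelse(strand == "+", idx_within, idx_within + 1L)
  gap_key <- paste(chrom, tss_gap)
  k_of_gene <- per[match(chrom, chrom_names)]
  enh_genes <- integer(0)
  for (g in sample(de_idx)) {
    if (tss_gap[g] > k_of_gene[g]) next  # trailing gap: size not guaranteed
    if (!gap_key[g] %in% gap_key[enh_genes]) enh_genes <- c(enh_genes, g)
    if (length(enh_genes) == cfg$n_enhancers) break
  }
  if (length(enh_genes) < cfg$n_enhancers) {
    stop("infeasible placement: cannot assign distinct enhancer gaps")
  }
  enh_genes <- sort(enh_genes)

  start <- numeric(n)
  offset <- 0L
  for (c_i in seq_len(cfg$n_chrom)) {
    k <- per[c_i]
    gi <- offset + seq_len(k)
    ok <- FALSE
    for (try in 1:30) {
      req <- rep(1400, k)                 # gap preceding each gene
      is_car <- gi %in% carrier
      req[-1][is_car[-k] | is_car[-1]] <- 2400
      req[1] <- 1500
      gaps <- req + round(rexp(k, 1 / 2500))
      enh_here <- which(gi %in% enh_genes)
      for (e in enh_here) {
        gidx <- if (strand[gi[e]] == "+") e else e + 1L
        extra <- 4000 + round(rexp(1, 1 / 4000))
        if (gidx <= k) {
          gaps[gidx] <- max(gaps[gidx], req[gidx] + extra)
        }
        # a minus-strand last gene uses trailing space; nothing to enlarge
      }
      pos <- cumsum(gaps + c(0, lens[gi][-k]))
      if (pos[k] + lens[gi[k]] + 1500 <= cfg$chrom_len) {
        start[gi] <- pos
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("infeasible placement: genes do not fit on ", chrom_names[c_i])
    offset <- offset + k
  }

  genes <- gene_models(
    gene_id = sprintf("gene%03d", seq_len(n)),
    chrom = chrom, start = start, end = start + lens, strand = strand
  )
  genes$untranscribed_baseline <- seq_len(n) %in% untr_pool
  genes$de <- seq_len(n) %in% de_idx
  genes$bivalent <- seq_len(n) %in% biv_idx
  genes$enhancer_gene <- seq_len(n) %in% enh_genes
  genes
}

# --- enhancer placement ---------------------------------------------------

place_enhancers <- function(cfg, genes) {
  idx <- which(genes$enhancer_gene)
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    g <- idx[k]
    same <- which(genes$chrom == genes$chrom[g])
    pos_in <- match(g, same)
    tss <- genes$tss[g]
    if (genes$strand[g] == "+") {
      left <- if (pos_in > 1L) genes$end[same[pos_in - 1L]] else 0
      lo <- left + 1300
      hi <- genes$start[g] - 1250
    } else {
      right <- if (pos_in < length(same)) genes$start[same[pos_in + 1L]] else cfg$chrom_len
      lo <- genes$end[g] + 1250
      hi <- right - 1300
    }
    other_tss <- genes$tss[genes$chrom == genes$chrom[g]]
    other_tss <- other_tss[other_tss != tss]
    placed <- NULL
    for (try in 1:60) {
      w <- round(runif(1, cfg$narrow_width[1], cfg$narrow_width[2]))
      if (genes$strand[g] == "+") {
        m_lo <- max(lo + w / 2, tss - cfg$enhancer_dist[2])
        m_hi <- min(hi - w / 2, tss - cfg$enhancer_dist[1])
      } else {
        m_lo <- max(lo + w / 2, tss + cfg$enhancer_dist[1])
        m_hi <- min(hi - w / 2, tss + cfg$enhancer_dist[2])
      }
      m_lo <- max(m_lo, w / 2 + 1)
      m_hi <- min(m_hi, cfg$chrom_len - w / 2 - 1)
      if (m_lo >= m_hi) next
      m <- round(runif(1, m_lo, m_hi))
      d <- abs(m - tss)
      if (d < cfg$enhancer_dist[1] || d > cfg$enhancer_dist[2]) next
      if (length(other_tss) && min(abs(m - other_tss)) < d + 400) next
      placed <- c(start = m - floor(w / 2), end = m - floor(w / 2) + w, d = d)
      break
    }
    if (is.null(placed)) {
      stop("infeasible placement: no valid enhancer position for ",
           genes$gene_id[g], " after bounded retries")
    }
    out[[k]] <- data.frame(
      chrom = genes$chrom[g], start = placed["start"], end = placed["end"],
      gene_id = genes$gene_id[g], distance = placed["d"],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# --- peak templates and replicate realisations ----------------------------

narrow_template <- function(cfg, genes, idx) {
  # TSS-centred widths, capped by clearance to neighbouring genes so that a
  # zero-noise peak never bleeds into another gene's assignment window
  out <- lapply(idx, function(g) {
    same <- which(genes$chrom == genes$chrom[g])
    pos_in <- match(g, same)
    tss <- genes$tss[g]
    hmax <- cfg$narrow_width[2] / 2
    if (pos_in > 1L) {
      nb <- same[pos_in - 1L]
      hmax <- min(hmax, (tss - genes$tss[nb] - 300) / 2, tss - (genes$end[nb] + 1300))
    }
    if (pos_in < length(same)) {
      nb <- same[pos_in + 1L]
      hmax <- min(hmax, (genes$tss[nb] - tss - 300) / 2, (genes$start[nb] - 1300) - tss)
    }
    hmax <- max(hmax, 150)
    w <- round(runif(1, min(cfg$narrow_width[1], 2 * hmax), min(cfg$narrow_width[2], 2 * hmax)))
    c(start = max(0, tss - floor(w / 2)), end = max(0, tss - floor(w / 2)) + w)
  })
  m <- do.call(rbind, out)
  data.frame(chrom = genes$chrom[idx], start = m[, "start"], end = m[, "end"],
             gene_id = genes$gene_id[idx], stringsAsFactors = FALSE)
}

broad_template <- function(cfg, genes, idx) {
  data.frame(
    chrom = genes$chrom[idx],
    start = pmax(0, genes$start[idx] - cfg$broad_flank),
    end = pmin(cfg$chrom_len, genes$end[idx] + cfg$broad_flank),
    gene_id = genes$gene_id[idx],
    stringsAsFactors = FALSE
  )
}

jitter_interval <- function(cfg, start, end) {
  if (cfg$jitter_sd > 0) {
    start <- start + round(rnorm(length(start), 0, cfg$jitter_sd))
    end <- end + round(rnorm(length(end), 0, cfg$jitter_sd))
  }
  start <- pmax(0, start)
  end <- pmax(start + 100, end)
  pmin_end <- pmin(end, cfg$chrom_len)
  cbind(start = pmin(start, pmin_end - 100), end = pmin_end)
}

realize_peaks <- function(cfg, template, scores, mark, tissue, rep_i, broad = FALSE) {
  co <- jitter_interval(cfg, template$start, template$end)
  nlp <- scores
  data.frame(
    chrom = template$chrom, start = co[, "start"], end = co[, "end"],
    name = sprintf("%s_%s_r%d_%d", tissue, mark, rep_i, seq_len(nrow(template))),
    score = round(nlp * 0.8, 4), strand = ".",
    neglog10p = round(nlp, 4), neglog10q = round(pmax(nlp - 0.5, 0.01), 4),
    summit = if (broad) NA_real_ else floor((co[, "end"] - co[, "start"]) / 2),
    mark = mark, tissue = tissue, replicate = as.character(rep_i),
    stringsAsFactors = FALSE
  )
}

spurious_peaks <- function(cfg, n, width_range, mark, tissue, rep_i, broad = FALSE) {
  if (n <= 0) return(empty_peaks())
  chrom <- sprintf("chr%d", sample.int(cfg$n_chrom, n, replace = TRUE))
  w <- round(runif(n, width_range[1], width_range[2]))
  start <- floor(runif(n, 0, cfg$chrom_len - w - 1))
  nlp <- exp(rnorm(n, log(3), 0.6))
  data.frame(
    chrom = chrom, start = start, end = start + w,
    name = sprintf("%s_%s_r%d_sp%d", tissue, mark, rep_i, seq_len(n)),
    score = round(nlp * 0.8, 4), strand = ".",
    neglog10p = round(nlp, 4), neglog10q = round(pmax(nlp - 0.5, 0.01), 4),
    summit = if (broad) NA_real_ else floor(w / 2),
    mark = mark, tissue = tissue, replicate = as.character(rep_i),
    stringsAsFactors = FALSE
  )
}

# --- the generator --------------------------------------------------------

#' Generate a synthetic multi-tissue histone-mark study
#'
#' Emits a complete miniature study: genome FASTA-able sequences, gene
#' models, per tissue x mark x replicate peak calls (narrowPeak-style for
#' H3K4me3/H3K56ac, broadPeak-style for H3K27me3/H2A.Z), replicate TPM
#' tables, signal tracks consistent with peak placement, a planted and a
#' decoy motif, a synthetic GO-like term map, and a ground-truth manifest of
#' every planted entity. Identical seeds give identical bundles.
#'
#' Planted structure: the 40 DE genes are untranscribed in stem/leaf and
#' induced in trichome (so their TSS peaks are trichome-specific and they
#' carry repressive domains in the other tissues); 15 transcribed genes
#' additionally carry a trichome-only H3K27me3 domain (bivalent); 25
#' trichome-only H3K56ac enhancer loci sit 2-50 kb from their paired DE
#' gene's TSS with that gene guaranteed nearest; 60% of enhancer loci carry
#' the planted motif consensus in the genome sequence.
#'
#' @param config A [synthetic_config()].
#' @param tracks Generate signal tracks (set `FALSE` to skip the most
#'   expensive output when only peaks/expression are needed).
#' @return A bundle: list with `config`, `genome`, `genes`, `expression`,
#'   `peaks` (nested tissue/mark/replicate list), `tracks`, `motifs`,
#'   `term_map` and `manifest`.
#' @export
simulate_study <- function(config = synthetic_config(), tracks = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  seeds <- stream_seeds(cfg$seed)
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chrom))

  set.seed(seeds["genes"])
  genes <- place_genes(cfg)

  set.seed(seeds["enhancers"])
  enhancers <- place_enhancers(cfg, genes)

  set.seed(seeds["genome"])
  p_gc <- cfg$gc / 2
  genome <- stats::setNames(vapply(chrom_names, function(ch) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE,
                 prob = c(0.5 - p_gc, p_gc, p_gc, 0.5 - p_gc)), collapse = "")
  }, character(1)), chrom_names)

  # motifs: a strongly informative planted PFM and an unplanted decoy
  set.seed(seeds["motifs"])
  draw_consensus <- function() paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
  planted_cons <- draw_consensus()
  decoy_cons <- draw_consensus()
  while (sum(strsplit(planted_cons, "")[[1]] == strsplit(decoy_cons, "")[[1]]) > 5) {
    decoy_cons <- draw_consensus()
  }
  cons_pfm <- function(id, cons, family) {
    b <- strsplit(cons, "")[[1]]
    counts <- matrix(5, 4, length(b), dimnames = list(c("A", "C", "G", "T"), NULL))
    counts[cbind(match(b, rownames(counts)), seq_along(b))] <- 85
    motif_pfm(id, counts, family = family)
  }
  motifs <- list(planted = cons_pfm("SYN_PLANTED", planted_cons, "MYB"),
                 decoy = cons_pfm("SYN_DECOY", decoy_cons, "bZIP"))
  n_plant <- round(cfg$motif_plant_rate * nrow(enhancers))
  plant_rows <- sort(sample.int(nrow(enhancers), n_plant))
  motif_instances <- data.frame(chrom = character(), pos = numeric(),
                                strand = character(), locus = character(),
                                stringsAsFactors = FALSE)
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (r in plant_rows) {
    w <- enhancers$end[r] - enhancers$start[r]
    off <- round(runif(1, 30, w - 10 - 30))
    pos <- enhancers$start[r] + off
    strand <- sample(c("+", "-"), 1)
    ins <- if (strand == "+") planted_cons else rc(planted_cons)
    ch <- enhancers$chrom[r]
    substr(genome[ch], pos + 1, pos + 10) <- ins
    motif_instances <- rbind(motif_instances, data.frame(
      chrom = ch, pos = pos, strand = strand,
      locus = sprintf("%s:%d-%d", ch, as.integer(enhancers$start[r]),
                      as.integer(enhancers$end[r])),
      stringsAsFactors = FALSE
    ))
  }

  # expression: baselines, planted trichome induction, replicate noise
  set.seed(seeds["expression"])
  n <- cfg$n_genes
  base <- numeric(n)
  untr <- genes$untranscribed_baseline
  base[!untr] <- rlnorm_clamped(sum(!untr), cfg$tpm_median, 1, 1.2, 500)
  base[untr] <- rlnorm_clamped(sum(untr), 0.2, 0.7, 0.01, 0.85)
  true_lfc <- rep(NA_real_, n)
  de <- which(genes$de)
  true_lfc[de] <- runif(length(de), cfg$lfc_range[1], cfg$lfc_range[2])
  true_tpm <- sapply(cfg$tissues, function(ts) {
    v <- base
    if (ts == cfg$tissues[1]) v[de] <- (base[de] + 1) * 2^true_lfc[de] - 1
    v
  })
  sdlog <- sqrt(log(1 + cfg$replicate_cv^2))
  tpm <- do.call(cbind, lapply(cfg$tissues, function(ts) {
    sapply(seq_len(cfg$n_rna_reps), function(r) {
      true_tpm[, ts] * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    })
  }))
  colnames(tpm) <- as.vector(outer(seq_len(cfg$n_rna_reps), cfg$tissues,
                                   function(r, ts) paste0(ts, "_", r)))
  rownames(tpm) <- genes$gene_id
  expr <- expression_table(round(tpm, 4))

  # per-tissue transcription status drives peak placement
  focal <- cfg$tissues[1]
  transcribed_in <- lapply(cfg$tissues, function(ts) {
    if (ts == focal) !untr | genes$de else !untr
  })
  names(transcribed_in) <- cfg$tissues

  set.seed(seeds["peaks"])
  # one width template per gene per narrow mark, shared across tissues
  templ_k4 <- narrow_template(cfg, genes, seq_len(n))
  templ_k56 <- narrow_template(cfg, genes, seq_len(n))
  peaks <- list()
  for (ts in cfg$tissues) {
    tr_idx <- which(transcribed_in[[ts]])
    untr_idx <- which(!transcribed_in[[ts]])
    domain_idx <- if (ts == focal) sort(c(untr_idx, which(genes$bivalent))) else untr_idx
    sets <- list(
      H3K4me3 = list(templ = templ_k4[tr_idx, , drop = FALSE], broad = FALSE),
      H3K56ac = list(templ = {
        t56 <- templ_k56[tr_idx, , drop = FALSE]
        if (ts == focal) {
          enh_t <- enhancers[, c("chrom", "start", "end")]
          enh_t$gene_id <- paste0("enh_", enhancers$gene_id)
          t56 <- rbind(t56, enh_t)
        }
        t56
      }, broad = FALSE),
      H3K27me3 = list(templ = broad_template(cfg, genes, domain_idx), broad = TRUE),
      H2A.Z = list(templ = broad_template(cfg, genes, untr_idx), broad = TRUE)
    )
    peaks[[ts]] <- lapply(names(sets), function(mk) {
      s <- sets[[mk]]
      nt <- nrow(s$templ)
      sc <- score_pairs(nt, cfg$rho_scores)
      reps <- lapply(seq_len(cfg$n_chip_reps), function(r) {
        true_part <- realize_peaks(cfg, s$templ, sc[, min(r, 2)], mk, ts, r, s$broad)
        sp <- spurious_peaks(cfg, round(cfg$spurious_rate * nt),
                             if (s$broad) c(2000, 8000) else cfg$narrow_width,
                             mk, ts, r, s$broad)
        out <- as_peaks(rbind(true_part[, names(empty_peaks())],
                              sp[, names(empty_peaks())]))
        out <- out[order(out$chrom, out$start), , drop = FALSE]
        rownames(out) <- NULL
        out
      })
      names(reps) <- paste0("rep", seq_len(cfg$n_chip_reps))
      reps
    })
    names(peaks[[ts]]) <- names(sets)
  }

  # signal tracks consistent with peak placement
  track_list <- NULL
  if (tracks) {
    set.seed(seeds["tracks"])
    nb <- ceiling(cfg$chrom_len / cfg$bin_width)
    grid <- data.frame(
      chrom = rep(chrom_names, each = nb),
      start = rep((seq_len(nb) - 1) * cfg$bin_width, cfg$n_chrom),
      end = rep(pmin(seq_len(nb) * cfg$bin_width, cfg$chrom_len), cfg$n_chrom),
      stringsAsFactors = FALSE
    )
    track_list <- list()
    for (ts in cfg$tissues) {
      for (mk in MARKS) {
        for (r in seq_len(cfg$n_chip_reps)) {
          pk <- peaks[[ts]][[mk]][[r]]
          val <- abs(rnorm(nrow(grid), 0, 0.25))
          ci <- match(pk$chrom, chrom_names)
          b1 <- (ci - 1) * nb + floor(pk$start / cfg$bin_width) + 1
          b2 <- (ci - 1) * nb + ceiling(pk$end / cfg$bin_width)
          for (i in seq_len(nrow(pk))) {
            rng <- b1[i]:b2[i]
            val[rng] <- val[rng] + pk$score[i]
          }
          tr <- cbind(grid, value = round(val, 4))
          attr(tr, "label") <- sprintf("%s_%s_rep%d", ts, mk, r)
          track_list[[sprintf("%s_%s_rep%d", ts, mk, r)]] <- tr
        }
      }
    }
  }

  # synthetic GO-like term map: one trichome-program term + random terms
  set.seed(seeds["terms"])
  de_ids <- genes$gene_id[genes$de]
  other_ids <- genes$gene_id[!genes$de]
  term_map <- c(
    list(SYNT0001 = unique(c(sample(de_ids, min(30, length(de_ids))),
                             sample(other_ids, min(5, length(other_ids)))))),
    stats::setNames(lapply(2:20, function(i) {
      sample(genes$gene_id, min(round(runif(1, 10, 40)), cfg$n_genes))
    }), sprintf("SYNT%04d", 2:20))
  )

  # ground-truth manifest
  ts_peaks <- rbind(
    data.frame(mark = "H3K4me3", templ_k4[genes$de, c("chrom", "start", "end")],
               stringsAsFactors = FALSE),
    data.frame(mark = "H3K56ac", templ_k56[genes$de, c("chrom", "start", "end")],
               stringsAsFactors = FALSE),
    data.frame(mark = "H3K56ac", enhancers[, c("chrom", "start", "end")],
               stringsAsFactors = FALSE),
    data.frame(mark = "H3K27me3",
               broad_template(cfg, genes, which(genes$bivalent))[, c("chrom", "start", "end")],
               stringsAsFactors = FALSE)
  )
  rownames(ts_peaks) <- NULL
  manifest <- list(
    tissue_specific_peak = ts_peaks,
    bivalent_gene = data.frame(gene_id = genes$gene_id[genes$bivalent],
                               stringsAsFactors = FALSE),
    de_gene = data.frame(gene_id = genes$gene_id[de],
                         true_log2fc = true_lfc[de], stringsAsFactors = FALSE),
    enhancer_pair = enhancers,
    motif = data.frame(motif_id = "SYN_PLANTED", stringsAsFactors = FALSE),
    motif_instances = motif_instances
  )
  stopifnot(
    nrow(manifest$enhancer_pair) == cfg$n_enhancers,
    nrow(manifest$de_gene) == cfg$n_de_genes,
    nrow(manifest$bivalent_gene) == cfg$n_bivalent
  )

  list(config = cfg, genome = genome, genes = genes, expression = expr,
       peaks = peaks, tracks = track_list, motifs = motifs,
       term_map = term_map, manifest = manifest)
}

#' Write a synthetic bundle to disk
#'
#' Materializes every component of a [simulate_study()] bundle in its
#' external format: genome FASTA, GFF3 annotation, per tissue x mark x
#' replicate narrowPeak/broadPeak files, bedGraph tracks, a TPM TSV, JASPAR
#' motifs, the term map, the manifest TSVs and a resolved-parameters file.
#'
#' @param bundle Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "manifest"), showWarnings = FALSE)
  write_fasta(bundle$genome, file.path(dir, "genome.fa"))
  write_gene_models(bundle$genes, file.path(dir, "genes.gff3"))
  write_expression(bundle$expression, file.path(dir, "tpm.tsv"))
  write_jaspar(bundle$motifs, file.path(dir, "motifs.jaspar"))
  write_term_map(bundle$term_map, file.path(dir, "term_map.tsv"))
  for (ts in names(bundle$peaks)) {
    for (mk in names(bundle$peaks[[ts]])) {
      broad <- mk %in% c("H3K27me3", "H2A.Z")
      for (r in names(bundle$peaks[[ts]][[mk]])) {
        f <- file.path(dir, "peaks", sprintf("%s_%s_%s.%s", ts, gsub("\\.", "", mk), r,
                                             if (broad) "broadPeak" else "narrowPeak"))
        write_peaks(bundle$peaks[[ts]][[mk]][[r]], f,
                    dialect = if (broad) "broadPeak" else "narrowPeak")
      }
    }
  }
  if (!is.null(bundle$tracks)) {
    dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
    for (nm in names(bundle$tracks)) {
      write_signal(bundle$tracks[[nm]], file.path(dir, "tracks", paste0(nm, ".bedGraph")))
    }
  }
  for (nm in names(bundle$manifest)) {
    write.table(bundle$manifest[[nm]], file.path(dir, "manifest", paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- bundle$config
  params <- data.frame(
    key = names(cfg),
    value = vapply(cfg, function(v) paste(format(v, trim = TRUE), collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE
  )
  write.table(params, file.path(dir, "params.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Evaluate predictions against the ground-truth manifest
#'
#' Matching rules by entity kind: peaks match by >= 0.5 reciprocal overlap
#' within the same mark; enhancer pairs match by equal target gene plus any
#' locus overlap; genes and motifs match by id. An empty prediction yields
#' recall 0 and precision reported as 0 with a `degenerate` flag.
#'
#' @param predicted For peaks/pairs a data frame; for genes/motifs a
#'   character vector (or data frame with a `gene_id`/`motif_id` column).
#' @param manifest The bundle manifest (the matching entry is selected by
#'   `entity_kind`), or the entry itself.
#' @param entity_kind One of `"tissue_specific_peak"`, `"bivalent_gene"`,
#'   `"de_gene"`, `"enhancer_pair"`, `"motif"`.
#' @return List with `precision`, `recall`, `f1`, `n_predicted`, `n_truth`,
#'   `degenerate`.
#' @export
truth_eval <- function(predicted, manifest,
                       entity_kind = c("tissue_specific_peak", "bivalent_gene",
                                       "de_gene", "enhancer_pair", "motif")) {
  entity_kind <- match.arg(entity_kind)
  truth <- if (is.list(manifest) && !is.data.frame(manifest)) {
    if (!entity_kind %in% names(manifest)) stop("unknown entity kind in manifest")
    manifest[[entity_kind]]
  } else manifest

  metrics <- function(n_pred_matched, n_pred, n_truth_matched, n_truth) {
    degenerate <- n_pred == 0L
    precision <- if (n_pred > 0) n_pred_matched / n_pred else 0
    recall <- if (n_truth > 0) n_truth_matched / n_truth else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    list(precision = precision, recall = recall, f1 = f1,
         n_predicted = n_pred, n_truth = n_truth, degenerate = degenerate)
  }

  if (entity_kind %in% c("bivalent_gene", "de_gene", "motif")) {
    key <- if (entity_kind == "motif") "motif_id" else "gene_id"
    pred_ids <- if (is.data.frame(predicted)) predicted[[key]] else as.character(predicted)
    pred_ids <- unique(pred_ids)
    truth_ids <- unique(truth[[key]])
    return(metrics(sum(pred_ids %in% truth_ids), length(pred_ids),
                   sum(truth_ids %in% pred_ids), length(truth_ids)))
  }

  if (entity_kind == "tissue_specific_peak") {
    if (nrow(predicted) == 0L || nrow(truth) == 0L) {
      return(metrics(0L, nrow(predicted), 0L, nrow(truth)))
    }
    if (!"mark" %in% names(predicted)) predicted$mark <- NA_character_
    pred_matched <- logical(nrow(predicted))
    truth_matched <- logical(nrow(truth))
    for (mk in unique(c(predicted$mark, truth$mark))) {
      pi <- which(predicted$mark %in% mk)
      ti <- which(truth$mark %in% mk)
      if (!length(pi) || !length(ti)) next
      p <- overlap_pairs(predicted[pi, , drop = FALSE], truth[ti, , drop = FALSE])
      if (!nrow(p)) next
      lp <- predicted$end[pi][p$i] - predicted$start[pi][p$i]
      lt <- truth$end[ti][p$j] - truth$start[ti][p$j]
      ok <- p$overlap >= 0.5 * lp & p$overlap >= 0.5 * lt
      pred_matched[pi[unique(p$i[ok])]] <- TRUE
      truth_matched[ti[unique(p$j[ok])]] <- TRUE
    }
    return(metrics(sum(pred_matched), nrow(predicted),
                   sum(truth_matched), nrow(truth)))
  }

  # enhancer_pair
  if (nrow(predicted) == 0L || nrow(truth) == 0L) {
    return(metrics(0L, nrow(predicted), 0L, nrow(truth)))
  }
  pred_matched <- logical(nrow(predicted))
  truth_matched <- logical(nrow(truth))
  for (i in seq_len(nrow(predicted))) {
    j <- which(truth$gene_id == predicted$gene_id[i] &
                 truth$chrom == predicted$chrom[i] &
                 truth$start < predicted$end[i] & truth$end > predicted$start[i])
    if (length(j)) {
      pred_matched[i] <- TRUE
      truth_matched[j] <- TRUE
    }
  }
  metrics(sum(pred_matched), nrow(predicted), sum(truth_matched), nrow(truth))
}
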