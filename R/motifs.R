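# SEA-style known-motif enrichment: sequence extraction, PFM -> PWM
# transform, log-odds scanning on both strands, per-sequence Fisher
# enrichment against a control set, and the TF-family summary table.

#' Extract peak sequences from a genome
#'
#' One upper-cased sequence per peak, sliced 0-based half-open and labelled
#' `chrom:start-end`.
#'
#' @param peaks Peak/interval data frame.
#' @param genome Named character vector of chromosome sequences (as from
#'   [read_fasta()]) or a [Biostrings::DNAStringSet].
#' @return Named character vector of sequences (order of `peaks`).
#' @export
extract_peak_sequences <- function(peaks, genome) {
  validate_intervals(peaks, "peak")
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  if (nrow(peaks) == 0L) return(stats::setNames(character(), character()))
  miss <- setdiff(unique(peaks$chrom), names(genome))
  if (length(miss)) stop("chromosome not in genome: ", miss[1L])
  lens <- nchar(genome)[peaks$chrom]
  bad <- which(peaks$end > lens)
  if (length(bad)) {
    stop(sprintf("peak %s:%g-%g extends beyond chromosome end (%d)",
                 peaks$chrom[bad[1L]], peaks$start[bad[1L]], peaks$end[bad[1L]],
                 lens[bad[1L]]))
  }
  seqs <- toupper(substring(genome[peaks$chrom], peaks$start + 1, peaks$end))
  stats::setNames(seqs, sprintf("%s:%d-%d", peaks$chrom, as.integer(peaks$start),
                                as.integer(peaks$end)))
}

#' Convert a position frequency matrix to a log-odds PWM
#'
#' Per column: `freq = (count + pseudocount * background) / (total +
#' pseudocount)`, `log_odds = log2(freq / background)`. The maximum
#' attainable score is the sum of column maxima.
#'
#' @param pfm A [motif_pfm()].
#' @param background Length-4 positive vector summing to 1 (A, C, G, T).
#' @param pseudocount Total pseudocount distributed by background
#'   (default 0.25).
#' @return Object of class `pwm`: `motif_id`, `log_odds` (4 x L),
#'   `background`, `max_score`, `family`.
#' @export
pfm_to_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.25) {
  stopifnot(inherits(pfm, "motif_pfm"))
  if (length(background) != 4L || any(background <= 0)) {
    stop("background must be 4 positive frequencies")
  }
  background <- background / sum(background)
  counts <- pfm$counts
  totals <- colSums(counts)
  freq <- sweep(counts + pseudocount * background, 2, totals + pseudocount, "/")
  lo <- log2(sweep(freq, 1, background, "/"))
  rownames(lo) <- c("A", "C", "G", "T")
  structure(list(
    motif_id = pfm$motif_id, log_odds = lo, background = background,
    max_score = sum(apply(lo, 2, max)), family = pfm$family
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (L = %d, max score %.3f)\n", x$motif_id,
              ncol(x$log_odds), x$max_score))
  invisible(x)
}

reverse_complement_pwm <- function(lo) {
  lo[c("T", "G", "C", "A"), rev(seq_len(ncol(lo))), drop = FALSE]
}

# per-window log-odds scores of one strand's matrix over an encoded sequence;
# ambiguous bases (code 5) take the background-weighted mean of the column.
scan_scores <- function(code, lo, background) {
  L <- ncol(lo)
  n <- length(code) - L + 1L
  if (n < 1L) return(numeric(0))
  cells <- rbind(lo, colSums(lo * background))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    sc <- sc + cells[cbind(code[j:(j + n - 1L)], j)]
  }
  sc
}

encode_dna <- function(seq) {
  code <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]],
                c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  code
}

#' Scan a sequence with a PWM
#'
#' Scores every window of both strands and reports windows with a log-odds
#' score of at least `threshold_frac` of the motif's maximum score.
#' Ambiguous bases contribute the background-weighted mean cell value of
#' their column.
#'
#' @param seq A single DNA string of length >= motif length.
#' @param pwm A `pwm` (or a `motif_pfm`, converted with defaults).
#' @param threshold_frac Match threshold as a fraction of the maximum score,
#'   in `(0, 1]` (default 0.8).
#' @return Data frame of hits: `offset` (0-based, on the forward strand),
#'   `strand`, `score`.
#' @export
scan_sequence <- function(seq, pwm, threshold_frac = 0.8) {
  if (inherits(pwm, "motif_pfm")) pwm <- pfm_to_pwm(pwm)
  stopifnot(inherits(pwm, "pwm"))
  if (!is.numeric(threshold_frac) || threshold_frac <= 0 || threshold_frac > 1) {
    stop("threshold_frac must lie in (0, 1]")
  }
  L <- ncol(pwm$log_odds)
  if (nchar(seq) < L) stop("sequence shorter than the motif")
  code <- encode_dna(seq)
  thr <- threshold_frac * pwm$max_score
  fwd <- scan_scores(code, pwm$log_odds, pwm$background)
  rev <- scan_scores(code, reverse_complement_pwm(pwm$log_odds), pwm$background)
  fi <- which(fwd >= thr)
  ri <- which(rev >= thr)
  hits <- rbind(
    data.frame(offset = fi - 1L, strand = rep("+", length(fi)),
               score = fwd[fi], stringsAsFactors = FALSE),
    data.frame(offset = ri - 1L, strand = rep("-", length(ri)),
               score = rev[ri], stringsAsFactors = FALSE)
  )
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

has_hit <- function(seqs, pwm, threshold_frac) {
  vapply(seqs, function(s) {
    if (nchar(s) < ncol(pwm$log_odds)) return(FALSE)
    nrow(scan_sequence(s, pwm, threshold_frac)) > 0L
  }, logical(1), USE.NAMES = FALSE)
}

#' Simple enrichment analysis of known motifs
#'
#' For each motif, counts the sequences (not windows) with at least one
#' match in the primary and control sets, tests enrichment in the primary
#' set with a one-sided Fisher exact test, and adjusts across motifs with
#' BH. The match threshold is a fixed fraction of the maximum log-odds
#' score — simpler and deterministic compared with optimized-threshold
#' schemes.
#'
#' @param primary_seqs,control_seqs Non-empty character vectors of
#'   sequences.
#' @param motifs List of `motif_pfm`/`pwm` objects.
#' @param threshold_frac Match threshold (default 0.8 of max score).
#' @param alpha Significance level on the BH q-value (default 0.05).
#' @param background Background base frequencies for the PWM transform.
#' @return Data frame with one row per motif: `motif_id`, `tf_family`,
#'   hit/total counts in both sets, `p`, `q`, `significant`.
#' @export
sea_enrichment <- function(primary_seqs, control_seqs, motifs,
                           threshold_frac = 0.8, alpha = 0.05,
                           background = rep(0.25, 4)) {
  if (!length(primary_seqs) || !length(control_seqs)) {
    stop("both sequence sets must be non-empty")
  }
  if (inherits(motifs, "motif_pfm") || inherits(motifs, "pwm")) motifs <- list(motifs)
  pwms <- lapply(motifs, function(m) {
    if (inherits(m, "pwm")) m else pfm_to_pwm(m, background = background)
  })
  rows <- lapply(pwms, function(w) {
    L <- ncol(w$log_odds)
    if (all(nchar(primary_seqs) < L)) {
      warning("motif ", w$motif_id, " longer than every primary sequence")
      return(data.frame(
        motif_id = w$motif_id, tf_family = ifelse(is.na(w$family), "unknown", w$family),
        n_primary_hit = 0L, n_primary = length(primary_seqs),
        n_control_hit = 0L, n_control = length(control_seqs),
        p = 1, stringsAsFactors = FALSE
      ))
    }
    hp <- sum(has_hit(primary_seqs, w, threshold_frac))
    hc <- sum(has_hit(control_seqs, w, threshold_frac))
    tab <- matrix(c(hp, length(primary_seqs) - hp,
                    hc, length(control_seqs) - hc), 2, byrow = TRUE)
    data.frame(
      motif_id = w$motif_id, tf_family = ifelse(is.na(w$family), "unknown", w$family),
      n_primary_hit = hp, n_primary = length(primary_seqs),
      n_control_hit = hc, n_control = length(control_seqs),
      p = stats::fisher.test(tab, alternative = "greater")$p.value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha
  rownames(out) <- NULL
  out
}

#' Per-family motif score table
#'
#' Groups motif enrichment results by transcription-factor family and
#' reports `-log10(q)` (q floored at 1e-300), the quantity plotted in
#' family-vs-significance summaries.
#'
#' @param results Output of [sea_enrichment()].
#' @param family_map Optional named character vector mapping motif ids to
#'   family labels; unmapped motifs fall back to the result's own family or
#'   `"unknown"`.
#' @return Data frame with columns `tf_family`, `motif_id`, `neglog10q`,
#'   sorted by family then descending significance.
#' @export
family_score_table <- function(results, family_map = NULL) {
  if (!nrow(results)) {
    return(data.frame(tf_family = character(), motif_id = character(),
                      neglog10q = numeric(), stringsAsFactors = FALSE))
  }
  fam <- results$tf_family
  if (!is.null(family_map)) {
    mapped <- family_map[results$motif_id]
    fam <- ifelse(is.na(mapped), fam, mapped)
  }
  fam[is.na(fam)] <- "unknown"
  out <- data.frame(
    tf_family = fam, motif_id = results$motif_id,
    neglog10q = -log10(pmax(results$q, 1e-300)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$tf_family, -out$neglog10q, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
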