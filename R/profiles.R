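# Coverage-level QC: binned-track rank correlations, strand-aware metagene
# profiles and fingerprint (cumulative enrichment) curves.

check_same_grid <- function(tracks) {
  ref <- tracks[[1]][, c("chrom", "start", "end")]
  for (t in tracks[-1]) {
    if (!identical(ref, t[, c("chrom", "start", "end")])) {
      stop("tracks are not on identical bin grids")
    }
  }
  invisible(TRUE)
}

#' Spearman correlation matrix of signal tracks
#'
#' Rank correlation (average ranks for ties) of paired bin values across a
#' set of tracks on identical bin grids — the standard replicate/mark
#' concordance heatmap input.
#'
#' @param tracks Named list (>= 2) of track data frames on the same grid.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(tracks) {
  if (!is.list(tracks) || length(tracks) < 2L) stop("need at least 2 tracks")
  for (t in tracks) validate_track(t)
  check_same_grid(tracks)
  m <- vapply(tracks, function(t) t$value, numeric(nrow(tracks[[1]])))
  if (is.null(colnames(m))) colnames(m) <- paste0("track", seq_along(tracks))
  rho <- stats::cor(m, method = "spearman")
  diag(rho) <- 1
  rho
}

#' Rebin a track to a coarser constant bin width
#'
#' Sums base-weighted signal into fixed-width bins; used to move from
#' generation-resolution tracks to the 10 kb bins of the correlation step.
#'
#' @param track Track data frame.
#' @param width New bin width in bp.
#' @return Track data frame on the coarser grid.
#' @export
rebin_track <- function(track, width) {
  validate_track(track)
  out <- lapply(split(track, track$chrom), function(tr) {
    lim <- max(tr$end)
    starts <- seq(0, lim - 1, by = width)
    val <- numeric(length(starts))
    bin_of <- findInterval(tr$start, starts)
    # bins are assumed not to straddle the coarser boundaries when width is a
    # multiple of the fine bin width; remainders accrue to the left bin.
    agg <- tapply(tr$value * (tr$end - tr$start), bin_of, sum)
    val[as.integer(names(agg))] <- as.numeric(agg)
    data.frame(chrom = tr$chrom[1], start = starts,
               end = pmin(starts + width, lim), value = val,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  out
}

# track value at arbitrary positions on one chromosome (0 outside bins)
track_values_at <- function(track_chrom, pos) {
  if (nrow(track_chrom) == 0L) return(numeric(length(pos)))
  idx <- findInterval(pos, track_chrom$start)
  val <- numeric(length(pos))
  ok <- idx >= 1L
  ok[ok] <- pos[ok] < track_chrom$end[idx[ok]]
  val[ok] <- track_chrom$value[idx[ok]]
  val
}

#' Metagene profile around gene bodies
#'
#' Samples a signal track strand-aware over a fixed-width upstream flank,
#' a length-normalized gene body and a downstream flank, and averages the
#' per-gene vectors. Genes whose body is shorter than `body_bins` bp are
#' skipped (their count is reported).
#'
#' @param track Track data frame.
#' @param genes Gene-model data frame (non-empty).
#' @param flank_bp Flank size in bp on each side (default 2000).
#' @param flank_bins Number of bins per flank (default 40).
#' @param body_bins Number of bins across the gene body (default 60).
#' @return Object of class `metagene_profile`: `bin_values`
#'   (length `2 * flank_bins + body_bins`), `bin_layout`, `n_genes`,
#'   `n_skipped`.
#' @export
metagene <- function(track, genes, flank_bp = 2000, flank_bins = 40L,
                     body_bins = 60L) {
  validate_track(track)
  validate_genes(genes)
  if (nrow(genes) == 0L) stop("empty gene set")
  by_chrom <- split(track, track$chrom)
  total_bins <- 2L * flank_bins + body_bins
  acc <- numeric(total_bins)
  used <- 0L
  skipped <- 0L
  for (g in seq_len(nrow(genes))) {
    glen <- genes$end[g] - genes$start[g]
    if (glen < body_bins) {
      skipped <- skipped + 1L
      next
    }
    tr <- by_chrom[[genes$chrom[g]]]
    if (is.null(tr)) tr <- track[0, , drop = FALSE]
    up_mid <- genes$start[g] - flank_bp + (seq_len(flank_bins) - 0.5) * (flank_bp / flank_bins)
    body_mid <- genes$start[g] + (seq_len(body_bins) - 0.5) * (glen / body_bins)
    down_mid <- genes$end[g] + (seq_len(flank_bins) - 0.5) * (flank_bp / flank_bins)
    pos <- c(up_mid, body_mid, down_mid)
    v <- track_values_at(tr, floor(pos))
    if (genes$strand[g] == "-") v <- rev(v)
    acc <- acc + v
    used <- used + 1L
  }
  if (used == 0L) stop("no gene long enough for the requested body binning")
  structure(list(
    bin_values = acc / used,
    bin_layout = c(flank_bp = flank_bp, flank_bins = flank_bins, body_bins = body_bins),
    n_genes = used, n_skipped = skipped
  ), class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene profile: %d genes (%d skipped), %d bins (%d flank + %d body + %d flank)\n",
              x$n_genes, x$n_skipped, length(x$bin_values),
              x$bin_layout["flank_bins"], x$bin_layout["body_bins"],
              x$bin_layout["flank_bins"]))
  invisible(x)
}

#' @method plot metagene_profile
#' @export
plot.metagene_profile <- function(x, ...) {
  fb <- x$bin_layout["flank_bins"]
  bb <- x$bin_layout["body_bins"]
  plot(seq_along(x$bin_values), x$bin_values, type = "l",
       xlab = "bin (flank | body | flank)", ylab = "mean signal", ...)
  abline(v = c(fb + 0.5, fb + bb + 0.5), lty = 2, col = "grey")
  invisible(x)
}

#' Fingerprint (cumulative enrichment) curve
#'
#' Sorts bins ascending by value and plots cumulative signal fraction
#' against cumulative bin fraction. A uniform track lies on the diagonal;
#' concentrated enrichment hugs the x-axis until the top bins. The curve is
#' non-decreasing and convex with area at most 0.5.
#'
#' @param track Track data frame with non-negative values.
#' @return Object of class `fingerprint_curve`: data frame with columns
#'   `frac_bins`, `frac_signal` (including the (0,0) origin).
#' @export
fingerprint <- function(track) {
  validate_track(track)
  if (nrow(track) == 0L) stop("empty track")
  if (any(track$value < 0)) stop("fingerprint requires non-negative values")
  total <- sum(track$value)
  if (total <= 0) stop("zero-signal track")
  v <- sort(track$value)
  n <- length(v)
  out <- data.frame(frac_bins = c(0, seq_len(n) / n),
                    frac_signal = c(0, cumsum(v) / total))
  class(out) <- c("fingerprint_curve", "data.frame")
  out
}

#' @method plot fingerprint_curve
#' @export
plot.fingerprint_curve <- function(x, ...) {
  plot(x$frac_bins, x$frac_signal, type = "l",
       xlab = "fraction of bins", ylab = "fraction of signal", ...)
  abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
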