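# Replicate consolidation: greedy replicate peak matching, the two-component
# Gaussian copula mixture behind the irreproducible discovery rate (IDR),
# and reciprocal-overlap intersection for broad domains.

#' Match peaks between two replicates
#'
#' Builds a one-to-one matching between replicate peak calls: all overlapping
#' pairs are candidates, taken greedily by descending overlap length (ties by
#' `(chrom, start)` of the replicate-1 peak); each peak is used at most once.
#'
#' @param rep1,rep2 Peak data frames from the same mark/tissue.
#' @return List with `pairs` (one row per matched pair: coordinates, scores
#'   and -log10 p of both peaks, `overlap_len`), and the unmatched rows of
#'   each replicate (`unmatched1`, `unmatched2`).
#' @export
match_replicate_peaks <- function(rep1, rep2) {
  rep1 <- as_peaks(rep1)
  rep2 <- as_peaks(rep2)
  cand <- overlap_pairs(rep1, rep2)
  if (nrow(cand)) {
    cand <- cand[order(-cand$overlap, rep1$chrom[cand$i], rep1$start[cand$i],
                       cand$i, cand$j), , drop = FALSE]
    used1 <- logical(nrow(rep1))
    used2 <- logical(nrow(rep2))
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (!used1[i] && !used2[j]) {
        used1[i] <- TRUE
        used2[j] <- TRUE
        keep[r] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[order(rep1$chrom[cand$i], rep1$start[cand$i]), , drop = FALSE]
  }
  pairs <- data.frame(
    chrom = rep1$chrom[cand$i],
    start1 = rep1$start[cand$i], end1 = rep1$end[cand$i],
    start2 = rep2$start[cand$j], end2 = rep2$end[cand$j],
    score1 = rep1$score[cand$i], score2 = rep2$score[cand$j],
    neglog10p1 = rep1$neglog10p[cand$i], neglog10p2 = rep2$neglog10p[cand$j],
    overlap_len = cand$overlap,
    mark = rep1$mark[cand$i], tissue = rep1$tissue[cand$i],
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL
  list(
    pairs = pairs,
    unmatched1 = rep1[setdiff(seq_len(nrow(rep1)), cand$i), , drop = FALSE],
    unmatched2 = rep2[setdiff(seq_len(nrow(rep2)), cand$j), , drop = FALSE]
  )
}

# mixture marginal CDF G(z) = pi1 * Phi((z - mu)/sigma) + (1 - pi1) * Phi(z)
mix_cdf <- function(z, pi1, mu, sigma) {
  pi1 * pnorm((z - mu) / sigma) + (1 - pi1) * pnorm(z)
}

# numerical inverse of the mixture marginal on a monotone grid
mix_quantile <- function(u, pi1, mu, sigma) {
  lo <- min(qnorm(min(u)), mu + sigma * qnorm(min(u))) - 1
  hi <- max(qnorm(max(u)), mu + sigma * qnorm(max(u))) + 1
  grid <- seq(lo, hi, length.out = 4096L)
  cdf <- mix_cdf(grid, pi1, mu, sigma)
  stats::approx(cdf, grid, xout = u, rule = 2, ties = "ordered")$y
}

bvn_density <- function(z1, z2, mu, sigma, rho) {
  d1 <- (z1 - mu) / sigma
  d2 <- (z2 - mu) / sigma
  q <- (d1^2 - 2 * rho * d1 * d2 + d2^2) / (1 - rho^2)
  exp(-q / 2) / (2 * pi * sigma^2 * sqrt(1 - rho^2))
}

#' Fit the IDR copula mixture model
#'
#' Fits the two-component Gaussian copula mixture that underlies the
#' irreproducible discovery rate: replicate scores are converted to average
#' ranks, then to uniform pseudo-values `u = (rank - 0.5)/n`, then to
#' pseudo-data `z = G^{-1}(u)` under the current mixture marginal
#' `G(z) = pi1 * Phi((z - mu)/sigma) + (1 - pi1) * Phi(z)`. Estimation uses
#' the two-level scheme of the reference method: an inner EM (E-step:
#' posterior reproducibility of each pair; CM-step: posterior-weighted
#' moment updates of `pi1`, `mu`, `sigma`, `rho`) runs to convergence on
#' fixed pseudo-data, then the pseudo-data are recomputed under the updated
#' marginal; the outer loop stops when the largest absolute parameter
#' change falls below `tol`. Parameters are clamped to the interior of
#' their domains. Rank ties are resolved by average ranks (no random
#' jitter), so the fit is deterministic. When the fitted reproducible
#' correlation collapses to ~0 the two components are not identifiable from
#' the rank dependence; the fit is flagged `degenerate` and every pair is
#' reported irreproducible.
#'
#' The local IDR of a pair is its posterior probability of belonging to the
#' irreproducible component; the global IDR is the running mean of the
#' sorted local IDRs, an FDR-like quantity used for thresholding.
#'
#' @param pairs Matched-pair data frame from [match_replicate_peaks()], the
#'   list it returns, or a two-column numeric matrix/data.frame of scores.
#' @param score_field Ranking statistic: `"auto"` prefers -log10 p when
#'   present, falling back to the enrichment score.
#' @param init Named starting values for `pi1`, `mu`, `sigma`, `rho`.
#' @param tol Convergence tolerance on the largest parameter change.
#' @param max_iter Maximum number of outer iterations.
#' @return An object of class `idr_fit` with elements `pi1`, `mu`, `sigma`,
#'   `rho`, `local_idr`, `global_idr`, `converged`, `n_iter`, `n` and the
#'   pairs used.
#' @examples
#' set.seed(1)
#' z <- matrix(rnorm(400), ncol = 2)
#' rep_idx <- sample(c(TRUE, FALSE), 200, TRUE, prob = c(0.7, 0.3))
#' z[rep_idx, ] <- rnorm(sum(rep_idx), 2.5, 1.3) + matrix(rnorm(sum(rep_idx) * 2, 0, 0.5), ncol = 2)
#' fit <- fit_idr(z)
#' coef(fit)
#' @export
fit_idr <- function(pairs, score_field = c("auto", "neglog10p", "score"),
                    init = c(pi1 = 0.7, mu = 2.6, sigma = 1.3, rho = 0.8),
                    tol = 1e-4, max_iter = 200L) {
  score_field <- match.arg(score_field)
  if (is.list(pairs) && !is.data.frame(pairs) && "pairs" %in% names(pairs)) {
    pairs <- pairs$pairs
  }
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs)
  if (ncol(pairs) == 2L && !"score1" %in% names(pairs) &&
      all(vapply(pairs, is.numeric, logical(1)))) {
    names(pairs) <- c("score1", "score2")
  }
  pick <- function(f1, f2) {
    if (all(c(f1, f2) %in% names(pairs)) &&
        all(is.finite(pairs[[f1]])) && all(is.finite(pairs[[f2]]))) {
      cbind(pairs[[f1]], pairs[[f2]])
    } else NULL
  }
  s <- switch(score_field,
    neglog10p = pick("neglog10p1", "neglog10p2"),
    score = pick("score1", "score2"),
    auto = {
      tmp <- pick("neglog10p1", "neglog10p2")
      if (is.null(tmp)) tmp <- pick("score1", "score2")
      tmp
    }
  )
  if (is.null(s)) stop("non-finite or missing scores for the requested score_field")
  n <- nrow(s)
  if (n < 50L) stop("insufficient data: need >= 50 matched pairs, got ", n)

  u1 <- (rank(s[, 1], ties.method = "average") - 0.5) / n
  u2 <- (rank(s[, 2], ties.method = "average") - 0.5) / n

  par <- c(pi1 = unname(init["pi1"]), mu = unname(init["mu"]),
           sigma = unname(init["sigma"]), rho = unname(init["rho"]))
  eps <- 1e-4
  e_step <- function(z1, z2, p) {
    f1 <- bvn_density(z1, z2, p["mu"], p["sigma"], p["rho"])
    f0 <- dnorm(z1) * dnorm(z2)
    K <- p["pi1"] * f1 / (p["pi1"] * f1 + (1 - p["pi1"]) * f0)
    K[!is.finite(K)] <- 0.5
    K
  }
  # two-level scheme: the inner EM runs to convergence on fixed pseudo-data,
  # then the pseudo-data are recomputed under the updated marginal (outer
  # iteration); the outer loop stops when the parameters stabilise
  converged <- FALSE
  iter <- 0L
  z1 <- z2 <- NULL
  K <- K_outer <- rep(par["pi1"], n)
  for (iter in seq_len(max_iter)) {
    z1 <- mix_quantile(u1, par["pi1"], par["mu"], par["sigma"])
    z2 <- mix_quantile(u2, par["pi1"], par["mu"], par["sigma"])
    inner <- par
    K_prev <- K
    for (it in seq_len(200L)) {
      K <- e_step(z1, z2, inner)
      sK <- sum(K)
      mu_new <- sum(K * (z1 + z2)) / (2 * sK)
      ss <- sum(K * ((z1 - mu_new)^2 + (z2 - mu_new)^2))
      sigma_new <- sqrt(ss / (2 * sK))
      rho_new <- sum(K * 2 * (z1 - mu_new) * (z2 - mu_new)) / max(ss, .Machine$double.eps)
      new <- c(
        pi1 = min(max(mean(K), eps), 1 - eps),
        mu = max(mu_new, eps),
        sigma = max(sigma_new, eps),
        rho = min(max(rho_new, eps), 1 - eps)
      )
      delta <- max(abs(new - inner))
      post_delta <- max(abs(K - K_prev))
      K_prev <- K
      inner <- new
      # posterior stability also terminates: a vanishing null component lets
      # its parameters drift while the classification is already fixed
      if (delta < tol || (it > 1L && post_delta < 1e-6)) break
    }
    outer_delta <- max(abs(inner - par))
    outer_post_delta <- max(abs(K - K_outer))
    K_outer <- K
    par <- inner
    if (outer_delta < tol || (iter > 1L && outer_post_delta < 1e-5)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("IDR EM did not converge within ", max_iter, " pseudo-data updates")
  }
  K <- e_step(z1, z2, par)
  degenerate <- par["rho"] <= 0.05
  if (degenerate) {
    # the reproducible component collapsed to zero correlation: the two
    # components are not identifiable from the rank dependence, so no pair
    # carries evidence of reproducibility
    warning("IDR fit degenerate (reproducible correlation ~ 0); ",
            "all pairs reported irreproducible")
    K <- rep(0, n)
  }
  local_idr <- pmin(pmax(1 - K, 0), 1)
  ord <- order(local_idr)
  global_sorted <- cumsum(local_idr[ord]) / seq_len(n)
  global_idr <- numeric(n)
  global_idr[ord] <- pmin(global_sorted, 1)
  structure(list(
    pi1 = unname(par["pi1"]), mu = unname(par["mu"]),
    sigma = unname(par["sigma"]), rho = unname(par["rho"]),
    local_idr = local_idr, global_idr = global_idr,
    converged = converged, degenerate = unname(degenerate), n_iter = iter, n = n,
    score_field = score_field, pairs = if (is.data.frame(pairs)) pairs else NULL
  ), class = "idr_fit")
}

#' @export
print.idr_fit <- function(x, ...) {
  cat("IDR copula mixture fit\n")
  cat(sprintf("  n pairs: %d   converged: %s (%d iterations)\n",
              x$n, x$converged, x$n_iter))
  cat(sprintf("  pi1 = %.3f  mu = %.3f  sigma = %.3f  rho = %.3f\n",
              x$pi1, x$mu, x$sigma, x$rho))
  cat(sprintf("  pairs at global IDR <= 0.05: %d   <= 0.10: %d\n",
              sum(x$global_idr <= 0.05), sum(x$global_idr <= 0.10)))
  invisible(x)
}

#' @method coef idr_fit
#' @export
coef.idr_fit <- function(object, ...) {
  c(pi1 = object$pi1, mu = object$mu, sigma = object$sigma, rho = object$rho)
}

#' @method summary idr_fit
#' @export
summary.idr_fit <- function(object, thresholds = c(0.01, 0.05, 0.1, 0.25), ...) {
  out <- list(
    coefficients = coef(object),
    n = object$n, converged = object$converged, n_iter = object$n_iter,
    passing = stats::setNames(
      vapply(thresholds, function(t) sum(object$global_idr <= t), numeric(1)),
      paste0("idr<=", thresholds)
    )
  )
  class(out) <- "summary.idr_fit"
  out
}

#' @export
print.summary.idr_fit <- function(x, ...) {
  cat("IDR copula mixture fit\n")
  print(round(x$coefficients, 4))
  cat(sprintf("n = %d, converged = %s after %d iterations\n", x$n, x$converged, x$n_iter))
  print(x$passing)
  invisible(x)
}

#' Rank-rank reproducibility plot for an IDR fit
#'
#' Plots replicate score ranks against each other, colouring pairs passing
#' the global IDR threshold (the conventional replicate-concordance view).
#'
#' @param x An `idr_fit`.
#' @param threshold Global IDR threshold used to split the colouring.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @method plot idr_fit
#' @export
plot.idr_fit <- function(x, threshold = 0.05, ...) {
  p <- x$pairs
  if (is.null(p) || !all(c("score1", "score2") %in% names(p))) {
    stop("fit carries no pair table to plot")
  }
  r1 <- rank(p$score1)
  r2 <- rank(p$score2)
  pass <- x$global_idr <= threshold
  plot(r1, r2, col = ifelse(pass, "black", "red"), pch = 20,
       xlab = "replicate 1 rank", ylab = "replicate 2 rank", ...)
  legend("topleft", pch = 20, col = c("black", "red"),
         legend = c(sprintf("IDR <= %g", threshold), sprintf("IDR > %g", threshold)),
         bty = "n")
  invisible(x)
}

#' Select replicable narrow peaks at a global IDR threshold
#'
#' Keeps matched pairs with global IDR at or below `threshold` and
#' consolidates each into a single peak: the union span of the pair, the
#' mean of the replicate scores, and `-log10(global IDR)` in the q-value
#' slot. The consolidated replicate label is `"consolidated"`.
#'
#' @param pairs Matched pairs (data frame or [match_replicate_peaks()] output).
#' @param model The corresponding `idr_fit`.
#' @param threshold Global IDR cutoff in `(0, 1]` (0.05 for narrow peaks,
#'   0.10 for mixed peak types).
#' @return Consolidated peak data frame.
#' @export
select_replicable_narrow <- function(pairs, model, threshold) {
  if (is.list(pairs) && !is.data.frame(pairs) && "pairs" %in% names(pairs)) {
    pairs <- pairs$pairs
  }
  stopifnot(inherits(model, "idr_fit"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]")
  }
  if (nrow(pairs) != model$n) stop("model does not cover the supplied pairs")
  keep <- which(model$global_idr <= threshold)
  out <- data.frame(
    chrom = pairs$chrom[keep],
    start = pmin(pairs$start1[keep], pairs$start2[keep]),
    end = pmax(pairs$end1[keep], pairs$end2[keep]),
    name = NA_character_,
    score = (pairs$score1[keep] + pairs$score2[keep]) / 2,
    strand = ".",
    neglog10p = NA_real_,
    neglog10q = -log10(pmax(model$global_idr[keep], 1e-300)),
    summit = NA_real_,
    mark = if ("mark" %in% names(pairs)) pairs$mark[keep] else NA_character_,
    tissue = if ("tissue" %in% names(pairs)) pairs$tissue[keep] else NA_character_,
    replicate = "consolidated",
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  as_peaks(out)
}

#' Replicable broad domains by reciprocal overlap
#'
#' Returns every replicate-1 domain having a replicate-2 overlap covering at
#' least `min_frac` of *both* domains (bedtools `-f 0.3 -r` semantics). The
#' whole replicate-1 domain is reported, labelled `"consolidated"`.
#'
#' @param rep1,rep2 Broad-peak data frames.
#' @param min_frac Reciprocal overlap fraction in `(0, 1]` (default 0.3).
#' @return Consolidated broad-peak data frame.
#' @export
replicable_broad <- function(rep1, rep2, min_frac = 0.3) {
  if (!is.numeric(min_frac) || min_frac <= 0 || min_frac > 1) {
    stop("min_frac must lie in (0, 1]")
  }
  rep1 <- as_peaks(rep1)
  rep2 <- as_peaks(rep2)
  out <- intersect_intervals(rep1, rep2, min_frac_a = min_frac,
                             min_frac_b = min_frac, reciprocal = TRUE,
                             mode = "whole_a")
  if (nrow(out)) out$replicate <- "consolidated"
  rownames(out) <- NULL
  as_peaks(out)
}

#' Scale a signal track to a reference total
#'
#' Multiplies every bin value by `reference_total / track_total` where the
#' track total is the base-weighted signal mass `sum(value * width)` — the
#' depth-matching step applied to replicate and input tracks before broad
#' peak calling.
#'
#' @param track Track data frame.
#' @param reference_total Target total signal (> 0).
#' @return Rescaled track.
#' @export
scale_track <- function(track, reference_total) {
  validate_track(track)
  total <- sum(track$value * (track$end - track$start))
  if (total <= 0) stop("zero-total track cannot be scaled")
  if (reference_total <= 0) stop("reference_total must be > 0")
  track$value <- track$value * (reference_total / total)
  track
}
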