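# Stage orchestration: a file-based pipeline over the package's functions
# with explicit dependency validation, deterministic key=value logs and
# idempotent outputs. Stages communicate through files under the run
# directory, so any stage can be rerun or inspected in isolation.

PIPELINE_STAGES <- c("simulate", "consolidate", "correlate", "metagene",
                     "feature-dist", "tissue-specific", "bivalent", "de",
                     "ora", "gsea", "enhancer-targets", "motif-enrich",
                     "evaluate")

STAGE_DEPS <- list(
  simulate = character(),
  consolidate = "simulate",
  correlate = "simulate",
  metagene = "simulate",
  "feature-dist" = c("simulate", "consolidate"),
  "tissue-specific" = c("simulate", "consolidate"),
  bivalent = c("simulate", "consolidate"),
  de = "simulate",
  ora = c("simulate", "tissue-specific"),
  gsea = c("simulate", "de"),
  "enhancer-targets" = c("simulate", "tissue-specific", "de"),
  "motif-enrich" = c("simulate", "tissue-specific"),
  evaluate = c("simulate", "tissue-specific", "bivalent", "de",
               "enhancer-targets", "motif-enrich")
)

#' Pipeline run configuration
#'
#' Bundles every threshold of the analysis in one place so that the
#' reference values are the shipped defaults: global IDR cutoffs of 0.05
#' (narrow H3K4me3) and 0.10 (mixed H3K56ac), 30% reciprocal overlap for
#' broad domains, the 1 TPM transcription cutoff, the both-contrast DE
#' filter (log2FC > 2, BH p.adj < 0.05), the 1.5 kb distal threshold, and
#' motif q < 0.05.
#'
#' @param outdir Run directory; stage outputs are written to
#'   `outdir/<stage>/`.
#' @param seed Seed for every stochastic stage.
#' @param idr_narrow,idr_mixed Global IDR cutoffs for narrow/mixed marks.
#' @param broad_frac Reciprocal overlap fraction for broad domains.
#' @param tpm Transcribed/untranscribed mean-TPM cutoff.
#' @param lfc,alpha Both-contrast DE filter thresholds.
#' @param distal Distal TSS-distance threshold in bp.
#' @param motif_q Motif enrichment q-value cutoff.
#' @param cor_bin Bin width (bp) for the track correlation matrix.
#' @param tracks Whether the simulate stage emits signal tracks (required
#'   by the correlate/metagene stages).
#' @param synthetic The [synthetic_config()] used by the simulate stage
#'   (its seed is overridden by `seed`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, idr_narrow = 0.05, idr_mixed = 0.10,
                       broad_frac = 0.3, tpm = 1, lfc = 2, alpha = 0.05,
                       distal = 1500, motif_q = 0.05, cor_bin = 10000,
                       tracks = TRUE, synthetic = synthetic_config()) {
  in_range <- function(v, lo, hi) is.numeric(v) && length(v) == 1L && v >= lo && v <= hi
  if (!in_range(idr_narrow, 1e-6, 1) || !in_range(idr_mixed, 1e-6, 1)) {
    stop("IDR thresholds must lie in (0, 1]")
  }
  if (!in_range(broad_frac, 1e-6, 1)) stop("broad_frac must lie in (0, 1]")
  if (!in_range(alpha, 1e-6, 1)) stop("alpha must lie in (0, 1]")
  if (!in_range(motif_q, 1e-6, 1)) stop("motif_q must lie in (0, 1]")
  if (distal < 0) stop("distal must be >= 0")
  if (tpm < 0 || lfc < 0) stop("tpm and lfc must be >= 0")
  synthetic$seed <- as.integer(seed)
  structure(list(
    outdir = outdir, seed = as.integer(seed), idr_narrow = idr_narrow,
    idr_mixed = idr_mixed, broad_frac = broad_frac, tpm = tpm, lfc = lfc,
    alpha = alpha, distal = distal, motif_q = motif_q, cor_bin = cor_bin,
    tracks = tracks, synthetic = synthetic
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run_config: outdir %s, seed %d\n", x$outdir, x$seed))
  cat(sprintf("  IDR narrow/mixed %.2g/%.2g, broad frac %.2g, TPM >= %g,\n",
              x$idr_narrow, x$idr_mixed, x$broad_frac, x$tpm))
  cat(sprintf("  DE log2FC > %g & padj < %g, distal > %g bp, motif q < %g\n",
              x$lfc, x$alpha, x$distal, x$motif_q))
  invisible(x)
}

stage_dir <- function(config, stage) file.path(config$outdir, stage)

mark_file_token <- function(mark) gsub(".", "", mark, fixed = TRUE)

is_broad_mark <- function(mark) mark %in% c("H3K27me3", "H2A.Z")

peak_path <- function(dir, tissue, mark, rep) {
  file.path(dir, sprintf("%s_%s_%s.%s", tissue, mark_file_token(mark), rep,
                         if (is_broad_mark(mark)) "broadPeak" else "narrowPeak"))
}

write_stage_log <- function(config, stage, inputs, counts) {
  entries <- c(
    sprintf("stage=%s", stage),
    sprintf("package_version=%s", as.character(utils::packageVersion("epitrichome"))),
    sprintf("seed=%d", config$seed)
  )
  inputs <- inputs[file.exists(inputs)]
  if (length(inputs)) {
    sums <- tools::md5sum(inputs)
    entries <- c(entries, sprintf("input_md5 %s=%s", basename(names(sums)), unname(sums)))
  }
  entries <- c(entries, sprintf("count %s=%s", names(counts),
                                vapply(counts, format, character(1), trim = TRUE)))
  writeLines(entries, file.path(stage_dir(config, stage), "log.txt"))
}

check_deps <- function(config, stage) {
  for (dep in STAGE_DEPS[[stage]]) {
    if (!file.exists(file.path(stage_dir(config, dep), "log.txt"))) {
      stop(sprintf("stage '%s' requires stage '%s' to have been run", stage, dep))
    }
  }
}

read_consolidated <- function(config, tissues = config$synthetic$tissues) {
  dir <- stage_dir(config, "consolidate")
  out <- lapply(tissues, function(ts) {
    byl <- lapply(MARKS, function(mk) {
      read_peaks(peak_path(dir, ts, mk, "consolidated"),
                 dialect = if (is_broad_mark(mk)) "broadPeak" else "narrowPeak",
                 mark = mk, tissue = ts, replicate = "consolidated")
    })
    names(byl) <- MARKS
    byl
  })
  names(out) <- tissues
  out
}

read_sim_genes <- function(config) {
  read_gene_models(file.path(stage_dir(config, "simulate"), "genes.gff3"), "gff3")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run one pipeline stage
#'
#' Validates the stage's dependencies (each upstream stage must have left
#' its log in the run directory), executes it, writes its outputs under
#' `outdir/<stage>/` and a deterministic `log.txt` of key=value records
#' (package version, seed, input checksums, summary counts). Deterministic
#' stages are idempotent: re-running yields byte-identical outputs.
#'
#' @param stage One of the pipeline stage names (see details in
#'   [run_pipeline()]).
#' @param config A [run_config()].
#' @return Named list of the stage's summary counts, invisibly.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  stopifnot(inherits(config, "run_config"))
  check_deps(config, stage)
  dir.create(stage_dir(config, stage), recursive = TRUE, showWarnings = FALSE)
  fn <- switch(stage,
    simulate = stage_simulate, consolidate = stage_consolidate,
    correlate = stage_correlate, metagene = stage_metagene,
    "feature-dist" = stage_feature_dist, "tissue-specific" = stage_tissue_specific,
    bivalent = stage_bivalent, de = stage_de, ora = stage_ora,
    gsea = stage_gsea, "enhancer-targets" = stage_enhancer_targets,
    "motif-enrich" = stage_motif_enrich, evaluate = stage_evaluate
  )
  res <- fn(config)
  write_stage_log(config, stage, res$inputs, res$counts)
  invisible(res$counts)
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order: simulate, consolidate,
#' correlate, metagene, feature-dist, tissue-specific, bivalent, de, ora,
#' gsea, enhancer-targets, motif-enrich, evaluate. Stages requiring signal
#' tracks are skipped when `config$tracks` is `FALSE`.
#'
#' @param config A [run_config()].
#' @param stages Stages to run (default all, in order).
#' @return Named list of per-stage summary counts.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  if (!config$tracks) stages <- setdiff(stages, c("correlate", "metagene"))
  out <- lapply(stages, function(s) run_stage(s, config))
  names(out) <- stages
  out
}

# --- stage implementations ------------------------------------------------

stage_simulate <- function(config) {
  bundle <- simulate_study(config$synthetic, tracks = config$tracks)
  write_bundle(bundle, stage_dir(config, "simulate"))
  n_peaks <- sum(unlist(lapply(bundle$peaks, function(t) {
    lapply(t, function(m) lapply(m, nrow))
  })))
  list(inputs = character(), counts = list(
    genes = nrow(bundle$genes), peaks_total = n_peaks,
    de_genes = nrow(bundle$manifest$de_gene),
    bivalent_genes = nrow(bundle$manifest$bivalent_gene),
    enhancer_pairs = nrow(bundle$manifest$enhancer_pair)
  ))
}

stage_consolidate <- function(config) {
  sim <- stage_dir(config, "simulate")
  out <- stage_dir(config, "consolidate")
  tissues <- config$synthetic$tissues
  counts <- list()
  inputs <- character()
  for (ts in tissues) {
    for (mk in MARKS) {
      paths <- vapply(seq_len(config$synthetic$n_chip_reps), function(r) {
        peak_path(file.path(sim, "peaks"), ts, mk, paste0("rep", r))
      }, character(1))
      inputs <- c(inputs, paths)
      dialect <- if (is_broad_mark(mk)) "broadPeak" else "narrowPeak"
      reps <- lapply(paths, read_peaks, dialect = dialect, mark = mk, tissue = ts)
      if (is_broad_mark(mk)) {
        cons <- replicable_broad(reps[[1]], reps[[2]], min_frac = config$broad_frac)
      } else {
        matched <- match_replicate_peaks(reps[[1]], reps[[2]])
        fit <- fit_idr(matched)
        thr <- if (mk == "H3K4me3") config$idr_narrow else config$idr_mixed
        cons <- select_replicable_narrow(matched, fit, thr)
      }
      cons$tissue <- ts
      cons$mark <- mk
      write_peaks(cons, peak_path(out, ts, mk, "consolidated"), dialect = dialect)
      counts[[sprintf("%s_%s", ts, mark_file_token(mk))]] <- nrow(cons)
    }
  }
  list(inputs = inputs, counts = counts)
}

read_sim_tracks <- function(config) {
  dir <- file.path(stage_dir(config, "simulate"), "tracks")
  files <- list.files(dir, pattern = "\\.bedGraph$", full.names = TRUE)
  if (!length(files)) stop("no tracks found; run simulate with tracks enabled")
  tracks <- lapply(files, read_signal)
  names(tracks) <- sub("\\.bedGraph$", "", basename(files))
  tracks
}

stage_correlate <- function(config) {
  tracks <- read_sim_tracks(config)
  coarse <- lapply(tracks, rebin_track, width = config$cor_bin)
  rho <- spearman_matrix(coarse)
  out <- file.path(stage_dir(config, "correlate"), "spearman_matrix.tsv")
  write.table(round(rho, 6), out, sep = "\t", quote = FALSE, col.names = NA)
  list(inputs = character(), counts = list(tracks = length(tracks)))
}

stage_metagene <- function(config) {
  genes <- read_sim_genes(config)
  expr <- read_expression(file.path(stage_dir(config, "simulate"), "tpm.tsv"))
  part <- partition_by_expression(expr, config$synthetic$tissues[1],
                                  tpm_threshold = config$tpm)
  tracks <- read_sim_tracks(config)
  focal <- config$synthetic$tissues[1]
  rows <- list()
  for (mk in MARKS) {
    tr <- tracks[[sprintf("%s_%s_rep1", focal, mk)]]
    for (set in c("transcribed", "untranscribed")) {
      gs <- genes[genes$gene_id %in% part[[set]], , drop = FALSE]
      prof <- metagene(tr, gs)
      rows[[paste(mk, set)]] <- data.frame(
        mark = mk, gene_set = set, bin = seq_along(prof$bin_values),
        value = round(prof$bin_values, 6), stringsAsFactors = FALSE
      )
    }
  }
  write_tsv(do.call(rbind, rows),
            file.path(stage_dir(config, "metagene"), "profiles.tsv"))
  list(inputs = character(), counts = list(profiles = length(rows)))
}

stage_feature_dist <- function(config) {
  genes <- read_sim_genes(config)
  cons <- read_consolidated(config)
  focal <- config$synthetic$tissues[1]
  rows <- lapply(MARKS, function(mk) {
    fd <- feature_distribution(cons[[focal]][[mk]], genes)
    data.frame(mark = mk, class = names(fd$counts),
               count = as.integer(fd$counts),
               fraction = round(fd$fractions, 6), stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows),
            file.path(stage_dir(config, "feature-dist"), "feature_distribution.tsv"))
  list(inputs = character(), counts = list(marks = length(MARKS)))
}

stage_tissue_specific <- function(config) {
  cons <- read_consolidated(config)
  focal <- config$synthetic$tissues[1]
  out <- stage_dir(config, "tissue-specific")
  counts <- list()
  for (mk in MARKS) {
    by_tissue <- lapply(cons, function(t) t[[mk]])
    ts_pk <- tissue_specific_chromatin(by_tissue, focal)
    dialect <- if (is_broad_mark(mk)) "broadPeak" else "narrowPeak"
    write_peaks(ts_pk, peak_path(out, focal, mk, "specific"), dialect = dialect)
    counts[[mark_file_token(mk)]] <- nrow(ts_pk)
  }
  list(inputs = character(), counts = counts)
}

read_tissue_specific <- function(config, mark) {
  focal <- config$synthetic$tissues[1]
  read_peaks(peak_path(stage_dir(config, "tissue-specific"), focal, mark, "specific"),
             dialect = if (is_broad_mark(mark)) "broadPeak" else "narrowPeak",
             mark = mark, tissue = focal, replicate = "consolidated")
}

stage_bivalent <- function(config) {
  genes <- read_sim_genes(config)
  cons <- read_consolidated(config)
  focal <- config$synthetic$tissues[1]
  biv <- bivalent_loci(cons[[focal]][["H3K4me3"]], cons[[focal]][["H3K27me3"]])
  states <- assign_marks_to_genes(genes, cons[[focal]])
  out <- stage_dir(config, "bivalent")
  write_tsv(biv$fragments, file.path(out, "fragments.tsv"))
  write_tsv(data.frame(gene_id = states$gene_id[states$bivalent],
                       stringsAsFactors = FALSE),
            file.path(out, "bivalent_genes.tsv"))
  list(inputs = character(), counts = list(
    fragments = nrow(biv$fragments),
    overlapping_peaks = biv$n_overlapping,
    bivalent_genes = sum(states$bivalent)
  ))
}

stage_de <- function(config) {
  expr <- read_expression(file.path(stage_dir(config, "simulate"), "tpm.tsv"))
  tissues <- config$synthetic$tissues
  out <- stage_dir(config, "de")
  de_list <- lapply(tissues[-1], function(other) {
    de <- simple_de(expr, tissues[1], other)
    write_de_table(de, file.path(out, sprintf("de_%s_vs_%s.tsv", tissues[1], other)))
    de
  })
  names(de_list) <- paste0(tissues[1], "_vs_", tissues[-1])
  sel <- filter_tissue_specific_de(de_list[[1]], de_list[[2]],
                                   min_lfc = config$lfc, alpha = config$alpha)
  writeLines(sort(sel), file.path(out, "tissue_specific_genes.txt"))
  counts <- c(lapply(de_list, function(de) {
    sum(de$log2fc > config$lfc & de$padj < config$alpha)
  }), list(both_contrasts = length(sel)))
  list(inputs = character(), counts = counts)
}

stage_ora <- function(config) {
  genes <- read_sim_genes(config)
  term_map <- read_term_map(file.path(stage_dir(config, "simulate"), "term_map.tsv"))
  k4 <- read_tissue_specific(config, "H3K4me3")
  states <- assign_marks_to_genes(genes, list(H3K4me3 = k4))
  query <- states$gene_id[states$H3K4me3]
  res <- ora_hypergeometric(query, term_map, genes$gene_id)
  write_tsv(res, file.path(stage_dir(config, "ora"), "ora_results.tsv"))
  list(inputs = character(), counts = list(
    query_genes = length(query), terms = nrow(res),
    significant = sum(res$padj < config$alpha)
  ))
}

stage_gsea <- function(config) {
  tissues <- config$synthetic$tissues
  de <- read_de_table(file.path(stage_dir(config, "de"),
                                sprintf("de_%s_vs_%s.tsv", tissues[1], tissues[2])))
  term_map <- read_term_map(file.path(stage_dir(config, "simulate"), "term_map.tsv"))
  scores <- stats::setNames(de$log2fc, de$gene_id)
  res <- gsea_preranked(scores, term_map[[1]], seed = config$seed)
  write_tsv(data.frame(term_id = names(term_map)[1], es = res$es, nes = res$nes,
                       p_value = res$p_value, n_hits = res$n_hits,
                       stringsAsFactors = FALSE),
            file.path(stage_dir(config, "gsea"), "gsea_results.tsv"))
  list(inputs = character(), counts = list(es_positive = as.integer(res$es > 0),
                                           significant = as.integer(res$p_value < config$alpha)))
}

stage_enhancer_targets <- function(config) {
  genes <- read_sim_genes(config)
  k56 <- read_tissue_specific(config, "H3K56ac")
  tissues <- config$synthetic$tissues
  de_tables <- lapply(tissues[-1], function(other) {
    read_de_table(file.path(stage_dir(config, "de"),
                            sprintf("de_%s_vs_%s.tsv", tissues[1], other)))
  })
  names(de_tables) <- paste0("vs_", tissues[-1])
  sel <- readLines(file.path(stage_dir(config, "de"), "tissue_specific_genes.txt"))
  res <- enhancer_target_pairs(k56, genes, sel, de_tables,
                               min_distance = config$distal)
  out <- stage_dir(config, "enhancer-targets")
  write_tsv(res$pairs, file.path(out, "enhancer_target_pairs.tsv"))
  write_tsv(res$rejects, file.path(out, "rejected_loci.tsv"))
  list(inputs = character(), counts = list(pairs = nrow(res$pairs),
                                           rejects = nrow(res$rejects)))
}

stage_motif_enrich <- function(config) {
  sim <- stage_dir(config, "simulate")
  genome <- read_fasta(file.path(sim, "genome.fa"))
  motifs <- read_jaspar(file.path(sim, "motifs.jaspar"))
  genes <- read_sim_genes(config)
  focal <- config$synthetic$tissues[1]
  k56_ts <- read_tissue_specific(config, "H3K56ac")
  distal <- distal_filter(k56_ts, genes, min_distance = config$distal)
  cons <- read_consolidated(config, tissues = focal)
  primary <- extract_peak_sequences(distal, genome)
  control <- extract_peak_sequences(cons[[focal]][["H3K56ac"]], genome)
  res <- sea_enrichment(primary, control, motifs, alpha = config$motif_q)
  fam <- family_score_table(res)
  out <- stage_dir(config, "motif-enrich")
  write_tsv(res, file.path(out, "motif_enrichment.tsv"))
  write_tsv(fam, file.path(out, "family_scores.tsv"))
  list(inputs = character(), counts = list(
    primary_seqs = length(primary), control_seqs = length(control),
    significant_motifs = sum(res$significant)
  ))
}

stage_evaluate <- function(config) {
  man_dir <- file.path(stage_dir(config, "simulate"), "manifest")
  manifest <- list(
    tissue_specific_peak = read.delim(file.path(man_dir, "tissue_specific_peak.tsv"),
                                      stringsAsFactors = FALSE),
    bivalent_gene = read.delim(file.path(man_dir, "bivalent_gene.tsv"),
                               stringsAsFactors = FALSE),
    de_gene = read.delim(file.path(man_dir, "de_gene.tsv"), stringsAsFactors = FALSE),
    enhancer_pair = read.delim(file.path(man_dir, "enhancer_pair.tsv"),
                               stringsAsFactors = FALSE),
    motif = read.delim(file.path(man_dir, "motif.tsv"), stringsAsFactors = FALSE)
  )
  ts_pred <- do.call(rbind, lapply(MARKS, function(mk) {
    p <- read_tissue_specific(config, mk)
    if (nrow(p)) p[, c("mark", "chrom", "start", "end")] else NULL
  }))
  biv_pred <- read.delim(file.path(stage_dir(config, "bivalent"), "bivalent_genes.tsv"),
                         stringsAsFactors = FALSE)
  de_pred <- readLines(file.path(stage_dir(config, "de"), "tissue_specific_genes.txt"))
  pair_pred <- read.delim(file.path(stage_dir(config, "enhancer-targets"),
                                    "enhancer_target_pairs.tsv"),
                          stringsAsFactors = FALSE)
  motif_res <- read.delim(file.path(stage_dir(config, "motif-enrich"),
                                    "motif_enrichment.tsv"), stringsAsFactors = FALSE)
  evals <- list(
    tissue_specific_peak = truth_eval(ts_pred, manifest, "tissue_specific_peak"),
    bivalent_gene = truth_eval(biv_pred, manifest, "bivalent_gene"),
    de_gene = truth_eval(de_pred, manifest, "de_gene"),
    enhancer_pair = truth_eval(pair_pred, manifest, "enhancer_pair"),
    motif = truth_eval(motif_res$motif_id[motif_res$significant], manifest, "motif")
  )
  df <- data.frame(
    entity = names(evals),
    precision = round(vapply(evals, `[[`, numeric(1), "precision"), 6),
    recall = round(vapply(evals, `[[`, numeric(1), "recall"), 6),
    f1 = round(vapply(evals, `[[`, numeric(1), "f1"), 6),
    n_predicted = vapply(evals, `[[`, numeric(1), "n_predicted"),
    n_truth = vapply(evals, `[[`, numeric(1), "n_truth"),
    stringsAsFactors = FALSE
  )
  write_tsv(df, file.path(stage_dir(config, "evaluate"), "evaluation.tsv"))
  counts <- stats::setNames(as.list(df$f1), paste0("f1_", df$entity))
  list(inputs = character(), counts = counts)
}
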