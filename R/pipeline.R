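#' Pipeline configuration
#'
#' Collects every threshold of the candidate-gene workflow with its default:
#' DEG gates (fold change >= 2, adjusted p < 0.05), FPKM abundance bins
#' (1/10/100), replicate QC threshold (sibling Spearman >= 0.95), clustering
#' (c = 4, m = 2, 10 restarts), QTN flank (100 kb), hotspot support (>= 2
#' QTLs from >= 2 studies) and the phase split ("auto" scores every
#' contiguous split; an explicit character vector of Phase-I stages overrides
#' it).
#'
#' @param min_fc,alpha DEG gates.
#' @param min_sibling_corr replicate QC threshold.
#' @param flank QTN window flank (bp).
#' @param min_support,require_distinct_studies hotspot rule.
#' @param clusters,fuzzifier,restarts fuzzy c-means settings.
#' @param phase "auto" or character vector of Phase-I stage names.
#' @param qtn_binding common-region predicate mode (see [call_candidates()]).
#' @param seed integer seed for clustering restarts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_fc = 2, alpha = 0.05, min_sibling_corr = 0.95,
                            flank = 1e5, min_support = 2,
                            require_distinct_studies = TRUE, clusters = 4,
                            fuzzifier = 2, restarts = 10, phase = "auto",
                            qtn_binding = "same_hotspot", seed = 1L) {
  structure(list(min_fc = min_fc, alpha = alpha,
                 min_sibling_corr = min_sibling_corr, flank = flank,
                 min_support = min_support,
                 require_distinct_studies = require_distinct_studies,
                 clusters = clusters, fuzzifier = fuzzifier,
                 restarts = restarts, phase = phase,
                 qtn_binding = qtn_binding, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end candidate-gene pipeline
#'
#' Composes the analysis stages on in-memory inputs: replicate QC and
#' exclusion, FPKM and stage means, per-stage line-contrast differential
#' expression, DEG set algebra, fuzzy clustering of the line-specific DEG
#' trajectories, the two-phase stage partition, and integration of the
#' Phase-I DEG union with QTL hotspots and QTN flanking windows.
#'
#' @param counts genes x samples count matrix.
#' @param samples sample sheet (sample, line, stage, replicate); stage order
#'   is the order of first appearance; the second line level is the
#'   numerator of fold changes.
#' @param annotation gene annotation data.frame (gene_id, chrom, start, end,
#'   exonic_length).
#' @param qtl,qtn compiled QTL/QTN tables (may be NULL to skip integration).
#' @param chrom_lengths named chromosome lengths; required with `qtl`/`qtn`.
#' @param tf_table optional gene_id/family table.
#' @param config a [pipeline_config()].
#' @return list of class `earphase_run` with elements `qc` (flags, excluded),
#'   `fpkm`, `stage_means`, `expressed_counts`, `de` (per-stage DE tables),
#'   `deg_sets`, `clusters` (per line), `phase`, `integration` (hotspots,
#'   windows, candidates) and `report` (the headline counts).
#' @export
run_pipeline <- function(counts, samples, annotation, qtl = NULL, qtn = NULL,
                         chrom_lengths = NULL, tf_table = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- unique(samples$stage)
  lines <- unique(samples$line)
  if (length(lines) != 2)
    stop("the pipeline contrasts exactly two lines", call. = FALSE)

  # --- QC: Spearman sibling correlation, replicate exclusion ---------------
  lengths <- stats::setNames(annotation$exonic_length, annotation$gene_id)
  fpkm_all <- compute_fpkm(counts, lengths)
  corr <- sample_correlation(fpkm_all, method = "spearman")
  flags <- suppressWarnings(
    flag_outlier_replicates(corr, samples, config$min_sibling_corr))
  excluded <- flags$sample
  keep <- !(samples$sample %in% excluded)
  samples_kept <- samples[keep, , drop = FALSE]
  counts_kept <- counts[, samples_kept$sample, drop = FALSE]
  fpkm <- fpkm_all[, samples_kept$sample, drop = FALSE]

  sm <- stage_means(fpkm, samples_kept)
  expressed <- classify_expression(sm)$expressed

  # --- differential expression per stage (line contrast) -------------------
  de <- list()
  stage_sets <- list()
  updown <- list()
  for (st in stages) {
    sel <- samples_kept$stage == st
    sub <- counts_kept[, sel, drop = FALSE]
    grp <- factor(samples_kept$line[sel], levels = lines)
    res <- nb_wald_contrast(sub, grp)
    de[[st]] <- res
    dg <- call_degs(res, config$min_fc, config$alpha)
    stage_sets[[st]] <- dg$all
    updown[[st]] <- dg
  }

  # --- clustering and phase split on line-specific DEG trajectories --------
  union_degs <- unique(unlist(stage_sets, use.names = FALSE))
  clusters <- list()
  phase <- NULL
  if (length(union_degs) >= config$clusters) {
    for (ln in lines) {
      sm_line <- sm[union_degs,
                    paste(ln, stages, sep = "."), drop = FALSE]
      colnames(sm_line) <- stages
      z <- standardize_profiles(sm_line)
      if (nrow(z$z) >= config$clusters)
        clusters[[ln]] <- fuzzy_cmeans(z$z, c = config$clusters,
                                       m = config$fuzzifier,
                                       seed = config$seed,
                                       restarts = config$restarts)
    }
  }
  if (identical(config$phase, "auto")) {
    # stage vectors: per-stage log2 stage-mean profile over the DEG union,
    # both lines stacked
    if (length(union_degs) >= 2) {
      sv <- do.call(rbind, lapply(stages, function(st) {
        unlist(lapply(lines, function(ln)
          log2(sm[union_degs, paste(ln, st, sep = ".")] + 1)))
      }))
      rownames(sv) <- stages
      phase <- score_phase_splits(sv)
    } else {
      stop("too few line-specific DEGs to choose a phase split; set ",
           "config$phase explicitly", call. = FALSE)
    }
    phase1_stages <- phase$phase1
  } else {
    phase1_stages <- config$phase
  }
  deg_sets <- build_deg_sets(stage_sets, phase1_stages)

  # --- integration ----------------------------------------------------------
  integration <- NULL
  if (!is.null(qtl)) {
    if (is.null(chrom_lengths))
      stop("chrom_lengths required for integration", call. = FALSE)
    qtl_v <- build_intervals(qtl, chrom_lengths)
    hotspots <- merge_hotspots(qtl_v, config$min_support,
                               config$require_distinct_studies)
    windows <- if (!is.null(qtn)) qtn_flanks(qtn, config$flank, chrom_lengths)
               else qtn_flanks(data.frame(qtn_id = character(),
                                          chrom = character(), pos = numeric()),
                               config$flank, chrom_lengths)
    candidates <- suppressWarnings(
      call_candidates(deg_sets$phase1, hotspots, windows, annotation,
                      qtn_binding = config$qtn_binding))
    tfs <- if (!is.null(tf_table)) annotate_tfs(candidates, tf_table) else NULL
    integration <- list(hotspots = hotspots, windows = windows,
                        candidates = candidates, tfs = tfs)
  }

  report <- list(
    n_samples = nrow(samples), n_excluded = length(excluded),
    expressed_per_stage = expressed,
    degs_per_stage = vapply(stage_sets, length, integer(1)),
    degs_up_per_stage = vapply(updown, function(d) length(d$up), integer(1)),
    degs_down_per_stage = vapply(updown, function(d) length(d$down), integer(1)),
    n_degs_union = length(deg_sets$union_all),
    n_degs_phase1 = length(deg_sets$phase1),
    n_degs_phase2 = length(deg_sets$phase2),
    phase1_stages = phase1_stages,
    cluster_sizes = lapply(clusters, function(cl) table(cl$cluster)),
    integration_counts = if (!is.null(integration))
      attr(integration$candidates, "counts") else NULL)

  structure(list(qc = list(correlation = corr, flags = flags,
                           excluded = excluded),
                 fpkm = fpkm, stage_means = sm, expressed_counts = expressed,
                 de = de, deg_sets = deg_sets, clusters = clusters,
                 phase = phase, integration = integration, report = report,
                 config = config),
            class = "earphase_run")
}

#' @export
print.earphase_run <- function(x, ...) {
  r <- x$report
  cat("earphase pipeline run\n")
  cat("  libraries:", r$n_samples, "(", r$n_excluded, "excluded by QC )\n")
  cat("  line-specific DEGs per stage:",
      paste(names(r$degs_per_stage), r$degs_per_stage, sep = "=",
            collapse = ", "), "\n")
  cat("  DEG union:", r$n_degs_union,
      "| Phase I:", r$n_degs_phase1, "| Phase II:", r$n_degs_phase2, "\n")
  cat("  Phase I stages:", paste(r$phase1_stages, collapse = ", "), "\n")
  if (!is.null(r$integration_counts)) {
    ic <- r$integration_counts
    cat("  integration: hotspot DEGs =", ic[["n_in_hotspot"]],
        "| QTN-window DEGs =", ic[["n_in_qtn_window"]],
        "| tier-1 =", ic[["n_tier1"]],
        "| common QTL+QTN =", ic[["n_common_region"]], "\n")
  }
  invisible(x)
}
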