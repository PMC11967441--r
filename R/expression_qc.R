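#' Fragments per kilobase per million mapped fragments
#'
#' \eqn{FPKM_{gj} = 10^9 \, c_{gj} / (L_g N_j)} where \eqn{L_g} is the exonic
#' length of gene g in bp and \eqn{N_j} the total assigned fragments of
#' library j (defaults to the column sums of `counts`, since mapping-level
#' totals are not available from a count matrix).
#'
#' @param counts genes x samples matrix of fragment counts.
#' @param lengths named numeric vector of exonic lengths (bp); must cover
#'   every gene in `counts`.
#' @param totals per-sample total fragments; defaults to `colSums(counts)`.
#' @return matrix of FPKM values with the dimnames of `counts`.
#' @export
compute_fpkm <- function(counts, lengths, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    stop("no length for gene(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  L <- lengths[rownames(counts)]
  if (any(L <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (any(totals <= 0)) stop("library totals must be positive", call. = FALSE)
  sweep(counts / L, 2, totals, "/") * 1e9
}

#' Per-line per-stage mean expression
#'
#' Averages the surviving biological replicates of each line x stage group;
#' the group mean is the stage expression level. Excluded samples (e.g. a
#' replicate removed by QC) are dropped before averaging.
#'
#' @param mat genes x samples expression matrix (FPKM or normalized counts).
#' @param samples sample sheet with columns sample, line, stage.
#' @param exclude character vector of sample ids to drop.
#' @return genes x (line.stage) matrix, columns named `<line>.<stage>` in the
#'   order of appearance in the sheet.
#' @export
stage_means <- function(mat, samples, exclude = character()) {
  expected <- unique(paste(samples$line, samples$stage, sep = "."))
  keep <- !(samples$sample %in% exclude)
  samples <- samples[keep, , drop = FALSE]
  mat <- mat[, samples$sample, drop = FALSE]
  grp <- factor(paste(samples$line, samples$stage, sep = "."),
                levels = expected)
  if (any(table(grp) == 0)) stop("a line x stage group has no surviving replicate",
                                 call. = FALSE)
  out <- sapply(levels(grp), function(g)
    rowMeans(mat[, grp == g, drop = FALSE]))
  rownames(out) <- rownames(mat)
  out
}

#' Abundance categories and expressed-gene counts
#'
#' Bins expression values into not_expressed (< 1), low (1 <= x < 10),
#' moderate (10 <= x < 100) and high (>= 100); a gene counts as expressed in a
#' column when its value is >= `min_expressed`.
#'
#' @param mat non-negative expression matrix (typically stage-mean FPKM).
#' @param thresholds increasing bin boundaries, default `c(1, 10, 100)`.
#' @param min_expressed expressed-gene threshold, default 1.
#' @return list with `bins` (character matrix of categories), `expressed`
#'   (per-column expressed-gene counts) and `bin_counts` (categories x columns).
#' @export
classify_expression <- function(mat, thresholds = c(1, 10, 100),
                                min_expressed = 1) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("expression values must be non-negative", call. = FALSE)
  labels <- c("not_expressed", "low", "moderate", "high")
  idx <- matrix(findInterval(mat, thresholds) + 1L, nrow(mat), ncol(mat))
  bins <- matrix(labels[idx], nrow(mat), ncol(mat), dimnames = dimnames(mat))
  expressed <- colSums(mat >= min_expressed)
  bin_counts <- sapply(seq_len(ncol(mat)), function(j)
    table(factor(bins[, j], levels = labels)))
  colnames(bin_counts) <- colnames(mat)
  list(bins = bins, expressed = expressed, bin_counts = bin_counts)
}

#' Pairwise sample correlation
#'
#' Pearson or Spearman correlation between sample columns, optionally on
#' log2(x + 1)-transformed values (the transform does not change Spearman).
#' Zero-variance columns give NA entries under Pearson rather than 0.
#'
#' @param mat genes x samples expression matrix.
#' @param method "pearson" or "spearman".
#' @param log_transform apply log2(x + 1) first (default TRUE).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(mat, method = c("pearson", "spearman"),
                               log_transform = TRUE) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least two samples", call. = FALSE)
  if (log_transform) mat <- log2(mat + 1)
  cc <- suppressWarnings(stats::cor(mat, method = method))
  diag(cc) <- 1
  cc
}

#' Sample-level principal component analysis
#'
#' Centered SVD of log2(x + 1)-transformed expression, after dropping genes
#' expressed in no sample. Samples are the observations.
#'
#' @param mat genes x samples expression matrix.
#' @param log_transform apply log2(x + 1) first (default TRUE).
#' @param min_expressed a gene is kept if any sample has value >= this
#'   (default: keep genes with any nonzero signal).
#' @return list with `scores` (samples x PCs), `variance_explained`
#'   (proportions, non-increasing) and `n_genes_used`.
#' @export
pca_samples <- function(mat, log_transform = TRUE, min_expressed = 0) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least two samples", call. = FALSE)
  keep <- apply(mat, 1, function(x) any(x > min_expressed))
  mat <- mat[keep, , drop = FALSE]
  if (log_transform) mat <- log2(mat + 1)
  nonconst <- apply(mat, 1, function(x) stats::sd(x) > 0)
  if (sum(nonconst) < 2)
    stop("fewer than two non-constant genes after filtering", call. = FALSE)
  pc <- stats::prcomp(t(mat[nonconst, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, variance_explained = ve, n_genes_used = sum(nonconst))
}

#' Flag replicate outliers by sibling correlation
#'
#' A replicate is flagged when its mean correlation with the other replicates
#' of the same line x stage group falls below `min_sibling_corr`. Groups of
#' size one are never flagged (a warning notes them). This makes the
#' visual replicate exclusion of the study design an explicit, reproducible
#' rule.
#'
#' @param corr sample correlation matrix (see [sample_correlation()]; the
#'   default QC method is Spearman on log2(x + 1)).
#' @param samples sample sheet with columns sample, line, stage.
#' @param min_sibling_corr threshold, default 0.95.
#' @return data.frame sample/line/stage/mean_sibling_corr for flagged samples
#'   (zero rows when none).
#' @export
flag_outlier_replicates <- function(corr, samples, min_sibling_corr = 0.95) {
  grp <- paste(samples$line, samples$stage, sep = ".")
  flags <- list()
  for (g in unique(grp)) {
    ids <- samples$sample[grp == g]
    if (length(ids) == 1) {
      warning("group ", g, " has a single replicate; cannot assess it",
              call. = FALSE)
      next
    }
    for (id in ids) {
      sib <- setdiff(ids, id)
      m <- mean(corr[id, sib])
      if (is.finite(m) && m < min_sibling_corr)
        flags[[length(flags) + 1]] <- data.frame(
          sample = id, line = samples$line[samples$sample == id],
          stage = samples$stage[samples$sample == id],
          mean_sibling_corr = m, stringsAsFactors = FALSE)
    }
  }
  if (!length(flags))
    return(data.frame(sample = character(), line = character(),
                      stage = character(), mean_sibling_corr = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, flags)
}

#' Relative expression by the 2^-ddCt method
#'
#' \eqn{\Delta Ct = Ct_{target} - Ct_{reference}} per sample;
#' \eqn{\Delta\Delta Ct = \Delta Ct_{sample} - \Delta Ct_{calibrator}};
#' relative expression is \eqn{2^{-\Delta\Delta Ct}}, so the calibrator maps
#' to 1.
#'
#' @param ct data.frame with columns sample, ct_target, ct_reference.
#' @param calibrator sample id used as the calibrator.
#' @return named numeric vector of relative expression values.
#' @export
ddct <- function(ct, calibrator) {
  req <- c("sample", "ct_target", "ct_reference")
  if (!all(req %in% names(ct)))
    stop("ct table needs columns sample, ct_target, ct_reference", call. = FALSE)
  if (!calibrator %in% ct$sample)
    stop("calibrator sample not present in the Ct table", call. = FALSE)
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference)))
    stop("Ct values must be finite", call. = FALSE)
  dct <- ct$ct_target - ct$ct_reference
  ddct <- dct - dct[ct$sample == calibrator][1]
  stats::setNames(2^(-ddct), ct$sample)
}
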