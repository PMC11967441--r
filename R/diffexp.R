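#' Median-of-ratios size factors
#'
#' For each sample j, \eqn{s_j} is the median over reference genes of
#' \eqn{c_{gj} / \tilde c_g}, where \eqn{\tilde c_g} is the geometric mean of
#' gene g across samples and reference genes are those with strictly positive
#' counts in every sample.
#'
#' @param counts genes x samples count matrix.
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene has positive counts in every sample; supply a ",
         "pseudo-reference or filter samples", call. = FALSE)
  loggeo <- rowMeans(log(counts[ref, , drop = FALSE]))
  s <- apply(counts[ref, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - loggeo)))
  stats::setNames(s, colnames(counts))
}

#' Method-of-moments NB dispersion estimates
#'
#' Gene-wise dispersion \eqn{\alpha_g} of the NB law \eqn{Var = \mu + \alpha
#' \mu^2}, estimated on size-factor-normalized counts. With `groups`
#' supplied, group means absorb the condition effect and the moments pool the
#' within-group residuals; otherwise moments are taken across all samples.
#' Estimates are floored at `alpha_floor` and optionally shrunk on the log
#' scale toward the trimmed mean of the positive raw estimates.
#'
#' With few replicates the gene-wise moment estimate is dominated by
#' sampling noise and falls below the true dispersion for about half the
#' genes, which makes downstream Wald tests anticonservative. As a
#' small-sample guard, when the smallest group has five or fewer replicates
#' the shrunken estimates are additionally floored at `center_floor` times
#' the trimmed-mean central dispersion (estimates above the floor are kept,
#' so genuinely noisy genes stay conservative). Set `center_floor = 0` to
#' obtain the bare moment estimator.
#'
#' @param counts genes x samples count matrix.
#' @param sf per-sample size factors (see [size_factors()]).
#' @param groups optional factor of sample conditions.
#' @param shrink shrinkage weight toward the trimmed-mean log-dispersion in
#'   \[0, 1\] (default 0.2).
#' @param center_floor multiplier of the central dispersion used as a lower
#'   bound in small designs; `NULL` (default) resolves to 1.3 when the
#'   smallest group has <= 5 replicates and 0 (disabled) otherwise.
#' @param alpha_floor lower bound, default 1e-8.
#' @return named numeric vector of dispersions.
#' @export
estimate_dispersions <- function(counts, sf, groups = NULL, shrink = 0.2,
                                 center_floor = NULL, alpha_floor = 1e-8) {
  norm <- sweep(as.matrix(counts), 2, sf, "/")
  if (is.null(groups)) groups <- factor(rep("all", ncol(norm)))
  groups <- droplevels(factor(groups))
  if (any(table(groups) < 2))
    stop("each group needs at least two replicates to estimate dispersion; ",
         "supply a global fallback instead", call. = FALSE)
  num <- 0; den <- 0
  for (g in levels(groups)) {
    sub <- norm[, groups == g, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    num <- num + (v - m)
    den <- den + m^2
  }
  raw <- num / pmax(den, .Machine$double.eps)
  alpha <- pmax(raw, alpha_floor)
  if (is.null(center_floor))
    center_floor <- if (min(table(groups)) <= 5) 1.3 else 0
  if ((shrink > 0 || center_floor > 0) && any(raw > 0)) {
    centre <- mean(log(alpha[raw > 0]), trim = 0.2)
    if (shrink > 0)
      alpha <- exp((1 - shrink) * log(alpha) + shrink * centre)
    if (center_floor > 0)
      alpha <- pmax(alpha, center_floor * exp(centre))
  }
  stats::setNames(pmax(alpha, alpha_floor), rownames(counts))
}

# Gene-wise NB MLE of the group mean on the log scale with fixed dispersion,
# Newton iterations vectorized across genes. Returns the fitted mean of
# normalized counts and the observed information of the log-mean.
.nb_fit_group <- function(k, sf, alpha, max_iter = 50, tol = 1e-10) {
  k <- as.matrix(k)
  q0 <- rowMeans(sweep(k, 2, sf, "/"))
  theta <- log(q0 + 0.1)
  for (it in seq_len(max_iter)) {
    mu <- exp(theta) %o% sf
    score <- rowSums((k - mu) / (1 + alpha * mu))
    info <- rowSums(mu * (1 + alpha * k) / (1 + alpha * mu)^2)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -2), 2)        # damp early oscillation
    theta <- theta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(theta) %o% sf
  list(q = exp(theta),
       info = rowSums(mu * (1 + alpha * k) / (1 + alpha * mu)^2))
}

#' Negative-binomial Wald contrast between two groups
#'
#' Per gene, the NB log-likelihood with fixed gene-wise dispersion is
#' maximized over the two group means (library sizes enter through the size
#' factors). The log2 fold change is
#' \eqn{\log_2((\hat\mu_B + \epsilon)/(\hat\mu_A + \epsilon))} with a
#' pseudo-mean \eqn{\epsilon = 0.5} normalized counts guarding all-zero
#' groups, and the Wald statistic divides the log fold change by its standard
#' error from the observed information; two-sided p-values use the normal
#' reference (`df = Inf`). A finite `df` refers the statistic to a t
#' distribution instead, an alternative small-sample guard; the default
#' pipeline relies on the dispersion `center_floor` of
#' [estimate_dispersions()] for calibration at few replicates.
#'
#' Genes whose total normalized count is below `min_count` are not tested
#' (`tested = FALSE`, NA statistics) and are excluded from multiple-testing
#' correction.
#'
#' @param counts genes x samples count matrix.
#' @param groups two-level factor (or coercible) over the columns; the log2
#'   fold change is second level over first.
#' @param sf size factors; computed by [size_factors()] when missing.
#' @param dispersions gene-wise dispersions; estimated by
#'   [estimate_dispersions()] with `groups` when missing.
#' @param min_count minimum total normalized count to test, default 10.
#' @param df degrees of freedom of the reference distribution; default
#'   `Inf` (normal).
#' @param pseudo_mean \eqn{\epsilon} guarding zero group means, default 0.5.
#' @return data.frame (one row per gene): baseMean, log2FoldChange, lfcSE,
#'   stat, pvalue, padj, tested.
#' @export
nb_wald_contrast <- function(counts, groups, sf = NULL, dispersions = NULL,
                             min_count = 10, df = Inf, pseudo_mean = 0.5) {
  counts <- as.matrix(counts)
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2)
    stop("groups must have exactly two levels", call. = FALSE)
  if (any(table(groups) < 1)) stop("both groups must be non-empty", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, sf, groups = groups)
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)
  tested <- rowSums(norm) >= min_count
  n <- nrow(counts)
  out <- data.frame(gene_id = rownames(counts), baseMean = base_mean,
                    log2FoldChange = NA_real_, lfcSE = NA_real_,
                    stat = NA_real_, pvalue = NA_real_, padj = NA_real_,
                    tested = tested, stringsAsFactors = FALSE)
  if (any(tested)) {
    a <- groups == levels(groups)[1]
    b <- groups == levels(groups)[2]
    alpha <- dispersions[tested]
    fa <- .nb_fit_group(counts[tested, a, drop = FALSE], sf[a], alpha)
    fb <- .nb_fit_group(counts[tested, b, drop = FALSE], sf[b], alpha)
    beta <- log(fb$q + pseudo_mean) - log(fa$q + pseudo_mean)
    se <- sqrt(1 / pmax(fa$info, 1e-12) + 1 / pmax(fb$info, 1e-12))
    stat <- beta / se
    p <- 2 * stats::pt(-abs(stat), df = df)
    out$log2FoldChange[tested] <- beta / log(2)
    out$lfcSE[tested] <- se / log(2)
    out$stat[tested] <- stat
    out$pvalue[tested] <- p
    out$padj[tested] <- bh_adjust(p)
  }
  rownames(out) <- NULL
  attr(out, "contrast") <- paste(levels(groups)[2], "vs", levels(groups)[1])
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: \eqn{padj_{(i)} = \min_{j \ge i} (m\, p_{(j)} /
#' j)} capped at 1, computed with [stats::p.adjust()].
#'
#' @param p numeric p-values in \[0, 1\] (untested genes excluded upstream).
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is a DEG iff its fold change is at least `min_fc` (inclusive, i.e.
#' \eqn{|log2FC| \ge \log_2 min\_fc}) AND its adjusted p-value is strictly
#' below `alpha`. Direction is the sign of the log2 fold change.
#'
#' @param result data.frame from [nb_wald_contrast()].
#' @param min_fc fold-change gate, default 2.
#' @param alpha adjusted-p gate, default 0.05.
#' @return list with character vectors `up`, `down` and `all`.
#' @export
call_degs <- function(result, min_fc = 2, alpha = 0.05) {
  ok <- result$tested & !is.na(result$padj) &
    abs(result$log2FoldChange) >= log2(min_fc) & result$padj < alpha
  up <- result$gene_id[ok & result$log2FoldChange > 0]
  down <- result$gene_id[ok & result$log2FoldChange < 0]
  list(up = up, down = down, all = c(up, down))
}

#' Assemble the DEG set algebra
#'
#' Builds the named set structure used by the pipeline from per-stage
#' line-specific DEG sets: the all-stage union, the Phase I and Phase II
#' unions under a contiguous stage partition, and the exclusive Venn regions
#' of the per-stage sets.
#'
#' @param stage_sets named list (one entry per stage, in stage order) of
#'   character vectors of line-specific DEG ids.
#' @param phase1_stages character vector of stage names forming Phase I; the
#'   remaining stages are Phase II.
#' @return list with `per_stage`, `union_all`, `phase1`, `phase2`,
#'   `phase1_stages`, `phase2_stages` and `venn` (see [venn_partition()]).
#' @export
build_deg_sets <- function(stage_sets, phase1_stages) {
  stages <- names(stage_sets)
  if (is.null(stages) || any(!nzchar(stages)))
    stop("stage_sets must be named by stage", call. = FALSE)
  if (!all(phase1_stages %in% stages))
    stop("phase1_stages must name stages present in stage_sets", call. = FALSE)
  k <- match(phase1_stages, stages)
  if (!identical(sort(k), seq_len(length(k))) )
    stop("Phase I must be a contiguous prefix of the stage order", call. = FALSE)
  phase2_stages <- setdiff(stages, phase1_stages)
  u <- function(ss) unique(unlist(ss, use.names = FALSE))
  list(per_stage = stage_sets,
       union_all = u(stage_sets),
       phase1 = u(stage_sets[phase1_stages]),
       phase2 = u(stage_sets[phase2_stages]),
       phase1_stages = phase1_stages, phase2_stages = phase2_stages,
       venn = venn_partition(stage_sets))
}

#' Exclusive Venn regions of k named sets
#'
#' Assigns every element of the union to exactly one region keyed by its
#' membership signature (set names joined by `&`), and reports region sizes.
#'
#' @param sets named list of up to six character vectors.
#' @return list with `regions` (named list of member vectors) and `sizes`
#'   (named integer vector).
#' @export
venn_partition <- function(sets) {
  if (length(sets) == 0) stop("need at least one set", call. = FALSE)
  if (length(sets) > 6) stop("at most six sets supported", call. = FALSE)
  if (is.null(names(sets))) stop("sets must be named", call. = FALSE)
  universe <- unique(unlist(sets, use.names = FALSE))
  if (!length(universe))
    return(list(regions = stats::setNames(list(), character()),
                sizes = stats::setNames(integer(), character())))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  sig <- apply(member, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  regions <- split(universe, sig)
  sizes <- vapply(regions, length, integer(1))
  list(regions = regions, sizes = sizes)
}
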