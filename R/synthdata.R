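#' Simulation configuration for the synthetic KRN experiment
#'
#' Builds the configuration object consumed by [simulate_experiment()] and
#' [simulate_genetic_maps()]. Defaults reproduce the study design the pipeline
#' targets: two maize inbred lines sampled at five early ear developmental
#' stages (V6 through V10) with three biological replicates each, i.e. 30
#' libraries, on a 10-chromosome genome with B73 RefGen_v4 chromosome lengths.
#'
#' Counts are negative binomial with \eqn{Var = \mu + \alpha \mu^2}. A fraction
#' `de_fraction` of genes carries a line effect with \eqn{|log2FC| \ge 1} drawn
#' from a truncated normal; every gene follows one of four temporal archetypes
#' whose regime changes after `phase_shift_stage` so that the two-phase
#' structure of the stages is recoverable downstream.
#'
#' @param n_lines number of inbred lines (the pipeline assumes 2).
#' @param stages ordered character vector of stage labels.
#' @param n_reps biological replicates per line x stage.
#' @param n_genes number of genes.
#' @param de_fraction proportion of genes with a true line effect.
#' @param lfc_location,lfc_scale location/scale of the truncated-normal draw
#'   of \eqn{|log2FC|} (truncated below at 1).
#' @param dispersion_meanlog,dispersion_sdlog lognormal parameters of the NB
#'   dispersion \eqn{\alpha}.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of the
#'   relative baseline abundance; the wide default spread yields replicate
#'   rank correlations near 0.97, typical of well-behaved bulk libraries.
#' @param libsize_range length-2 numeric, min/max total fragments per library.
#' @param archetype_weights length-4 proportions over the temporal archetypes;
#'   must sum to 1.
#' @param archetype_amplitude amplitude (log2 units) of the stage effects.
#' @param phase_shift_stage index after which the temporal regime changes.
#' @param n_studies number of QTL mapping studies to emulate.
#' @param n_qtl_per_study QTLs contributed by each study.
#' @param hotspot_spec list of planted hotspots, each a list with `chrom`
#'   (index), `start`, `end`, `support` (number of member QTLs, >= 2). `NULL`
#'   plants five hotspots with supports 2,2,3,4,5 at deterministic positions.
#' @param n_qtns number of trait-associated single positions.
#' @param qtn_in_hotspot_fraction fraction of QTNs placed inside planted
#'   hotspots.
#' @param qtn_flank flank used downstream (bp); kept here so QTN placement
#'   outside hotspots stays clear of them by at least this margin.
#' @param chrom_lengths named numeric vector of 10 chromosome lengths (bp).
#' @param seed integer seed governing all draws via named substreams.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 2,
                       stages = paste0("V", 6:10),
                       n_reps = 3,
                       n_genes = 20000,
                       de_fraction = 0.15,
                       lfc_location = 2,
                       lfc_scale = 0.5,
                       dispersion_meanlog = log(0.1),
                       dispersion_sdlog = 0.5,
                       baseline_meanlog = log(20),
                       baseline_sdlog = 2.3,
                       libsize_range = c(15e6, 25e6),
                       archetype_weights = rep(0.25, 4),
                       archetype_amplitude = 1,
                       phase_shift_stage = 3,
                       n_studies = 9,
                       n_qtl_per_study = 10,
                       hotspot_spec = NULL,
                       n_qtns = 40,
                       qtn_in_hotspot_fraction = 0.3,
                       qtn_flank = 1e5,
                       chrom_lengths = maize_v4_chrom_lengths(),
                       seed = 1L) {
  stopifnot(n_lines >= 1, n_reps >= 1, n_genes >= 1, length(stages) >= 2)
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must lie in [0, 1]", call. = FALSE)
  if (abs(sum(archetype_weights) - 1) > 1e-8)
    stop("archetype_weights must sum to 1", call. = FALSE)
  if (length(archetype_weights) != 4)
    stop("exactly four temporal archetypes are modelled", call. = FALSE)
  if (any(chrom_lengths <= 0)) stop("chrom_lengths must be positive", call. = FALSE)
  if (length(libsize_range) != 2 || libsize_range[1] > libsize_range[2] ||
      libsize_range[1] <= 0)
    stop("libsize_range must be an increasing positive pair", call. = FALSE)
  if (phase_shift_stage < 1 || phase_shift_stage >= length(stages))
    stop("phase_shift_stage must split the stages into two non-empty phases",
         call. = FALSE)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  cfg <- list(
    n_lines = n_lines, stages = stages, n_reps = n_reps, n_genes = n_genes,
    de_fraction = de_fraction, lfc_location = lfc_location,
    lfc_scale = lfc_scale, dispersion_meanlog = dispersion_meanlog,
    dispersion_sdlog = dispersion_sdlog, baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog, libsize_range = libsize_range,
    archetype_weights = archetype_weights,
    archetype_amplitude = archetype_amplitude,
    phase_shift_stage = phase_shift_stage,
    n_studies = n_studies, n_qtl_per_study = n_qtl_per_study,
    hotspot_spec = hotspot_spec, n_qtns = n_qtns,
    qtn_in_hotspot_fraction = qtn_in_hotspot_fraction, qtn_flank = qtn_flank,
    chrom_lengths = chrom_lengths, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' B73 RefGen_v4 chromosome lengths
#'
#' Lengths in bp of the ten maize chromosomes in the B73 RefGen_v4 assembly,
#' used as the default synthetic genome.
#' @return named numeric vector of length 10.
#' @export
maize_v4_chrom_lengths <- function() {
  c(chr1 = 307041717, chr2 = 244442276, chr3 = 235667834, chr4 = 246994605,
    chr5 = 223902240, chr6 = 174033170, chr7 = 182381542, chr8 = 181122637,
    chr9 = 159769782, chr10 = 150982314)
}

# Deterministic substream seed per component so modules can be regenerated
# independently from one global seed. Kept below 2^31.
.substream <- function(seed, component) {
  offsets <- c(expression = 11L, annotation = 29L, qtl = 47L, qtn = 83L)
  as.integer((as.numeric(seed) * 7919 + offsets[[component]]) %% 2147483647)
}

# Archetype stage effects on the log2 scale; regime change after `shift`.
# 1 rise-to-mid-then-fall, 2 flat-then-spike-at-last, 3 spike-just-after-shift,
# 4 monotone decline then uptick.
.archetype_profiles <- function(n_stages, shift, amplitude) {
  t_pre <- seq_len(shift)
  t_post <- seq(shift + 1, n_stages)
  p <- matrix(0, 4, n_stages)
  p[1, t_pre] <- seq(-1, 1, length.out = length(t_pre))
  p[1, t_post] <- seq(0, -1, length.out = length(t_post))
  p[2, ] <- 0; p[2, n_stages] <- 2
  p[3, ] <- 0; p[3, shift + 1] <- 2
  if (shift + 2 <= n_stages) p[3, seq(shift + 2, n_stages)] <- 0.5
  p[4, t_pre] <- seq(1, 0, length.out = length(t_pre))
  p[4, t_post] <- c(seq(-1, -0.5, length.out = length(t_post)))
  p * amplitude
}

#' Simulate the comparative RNA-seq experiment
#'
#' Draws NB counts for `n_lines` x `stages` x `n_reps` libraries with a planted
#' line effect in a `de_fraction` of genes, four temporal archetypes with a
#' regime change between `phase_shift_stage` and the next stage, and a
#' non-overlapping gene annotation on the synthetic chromosomes. Deterministic
#' given `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return list with `counts` (integer matrix genes x samples), `samples`
#'   (data.frame sample/line/stage/replicate), `annotation` (data.frame
#'   gene_id/chrom/start/end/strand/exonic_length, 1-based inclusive), and
#'   `truth` (list with `is_de`, `log2fc`, `archetype`, per-gene spans).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ann <- .simulate_annotation(config)
  withr_seed <- .substream(config$seed, "expression")
  set.seed(withr_seed)
  G <- config$n_genes
  n_stages <- length(config$stages)
  lines <- if (config$n_lines == 2) c("P", "D") else LETTERS[seq_len(config$n_lines)]

  samples <- expand.grid(replicate = seq_len(config$n_reps),
                         stage = config$stages, line = lines,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("line", "stage", "replicate")]
  samples$sample <- sprintf("%s_%s_%d", samples$line, samples$stage,
                            samples$replicate)
  samples <- samples[, c("sample", "line", "stage", "replicate")]

  # gene-level parameters
  base <- rlnorm(G, config$baseline_meanlog, config$baseline_sdlog)
  alpha <- rlnorm(G, config$dispersion_meanlog, config$dispersion_sdlog)
  archetype <- sample.int(4, G, replace = TRUE, prob = config$archetype_weights)
  is_de <- runif(G) < config$de_fraction
  lfc <- numeric(G)
  n_de <- sum(is_de)
  if (n_de > 0) {
    mag <- numeric(n_de)
    todo <- seq_len(n_de)
    while (length(todo)) {                               # truncate |lfc| at 1
      draw <- rnorm(length(todo), config$lfc_location, config$lfc_scale)
      ok <- draw >= 1
      mag[todo[ok]] <- draw[ok]
      todo <- todo[!ok]
    }
    lfc[is_de] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
  }
  prof <- .archetype_profiles(n_stages, config$phase_shift_stage,
                              config$archetype_amplitude)

  # per-gene per-stage per-line relative expression (log2 scale effects)
  n_samp <- nrow(samples)
  counts <- matrix(0L, G, n_samp, dimnames = list(ann$gene_id, samples$sample))
  stage_idx <- match(samples$stage, config$stages)
  line_idx <- match(samples$line, lines)
  # per-library target totals are drawn inside a margin of 4 sd of the
  # predicted total (from that library's own mean shares) so realized totals
  # stay inside libsize_range
  centre <- mean(config$libsize_range)
  width <- diff(config$libsize_range)
  u <- runif(n_samp)
  for (j in seq_len(n_samp)) {
    eff <- prof[cbind(archetype, rep(stage_idx[j], G))]
    if (line_idx[j] == 2) eff <- eff + lfc
    q <- base * 2^eff
    p <- q / sum(q)
    # cap any transcript at ~2% of the library so the total concentrates
    for (pass in 1:3) p <- pmin(p, 0.02) / sum(pmin(p, 0.02))
    sd_tot <- sqrt(centre + sum(alpha * p^2) * centre^2)
    margin <- min(0.45 * width, max(0.02 * width, 4 * sd_tot))
    target <- config$libsize_range[1] + margin + u[j] * (width - 2 * margin)
    mu <- p * target
    counts[, j] <- as.integer(rnbinom(G, mu = mu, size = 1 / alpha))
  }

  truth <- list(is_de = stats::setNames(is_de, ann$gene_id),
                log2fc = stats::setNames(lfc, ann$gene_id),
                archetype = stats::setNames(archetype, ann$gene_id),
                dispersion = stats::setNames(alpha, ann$gene_id),
                gene_span = ann[, c("gene_id", "chrom", "start", "end")])
  list(counts = counts, samples = samples, annotation = ann, truth = truth)
}

# Non-overlapping gene placement: genes are laid out along chromosomes in
# order with lognormal spans (around 3 kb) and random intergenic gaps.
.simulate_annotation <- function(config) {
  set.seed(.substream(config$seed, "annotation"))
  G <- config$n_genes
  chroms <- names(config$chrom_lengths)
  span <- pmax(200, round(rlnorm(G, log(3000), 0.5)))
  chrom <- sample(chroms, G, replace = TRUE,
                  prob = config$chrom_lengths / sum(config$chrom_lengths))
  start <- integer(G); end <- integer(G)
  for (ch in chroms) {
    idx <- which(chrom == ch)
    if (!length(idx)) next
    L <- config$chrom_lengths[[ch]]
    need <- sum(span[idx])
    if (need >= L)
      stop("chromosome ", ch, " too short for the requested gene content",
           call. = FALSE)
    # distribute the free space as random gaps before each gene
    gaps <- as.vector(rmultinom(1, size = max(0, floor(L - need)),
                                prob = rep(1, length(idx) + 1)))
    pos <- 1L
    for (k in seq_along(idx)) {
      pos <- pos + gaps[k]
      start[idx[k]] <- pos
      end[idx[k]] <- pos + span[idx[k]] - 1L
      pos <- pos + span[idx[k]]
    }
  }
  exonic <- pmin(span, pmax(150, round(rlnorm(G, log(1500), 0.4))))
  ann <- data.frame(chrom = chrom, start = start, end = end,
                    strand = sample(c("+", "-"), G, replace = TRUE),
                    exonic_length = exonic, stringsAsFactors = FALSE)
  ann <- ann[order(match(ann$chrom, chroms), ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  cbind(data.frame(gene_id = sprintf("GENE%05d", seq_len(G)),
                   stringsAsFactors = FALSE), ann)
}

.default_hotspot_spec <- function(config) {
  # deterministic positions: mid-chromosome regions, supports 2,2,3,4,5
  supports <- c(2L, 2L, 3L, 4L, 5L)
  chroms <- names(config$chrom_lengths)
  lapply(seq_along(supports), function(i) {
    ch <- chroms[((i - 1) %% length(chroms)) + 1]
    L <- config$chrom_lengths[[ch]]
    centre <- round(L * (0.25 + 0.1 * i))
    width <- 2e6
    list(chrom = ch, start = max(1, centre - width / 2),
         end = min(L, centre + width / 2), support = supports[i])
  })
}

#' Simulate compiled QTL and QTN tables with planted hotspots
#'
#' Emulates a multi-study compilation of KRN-linked QTL intervals and
#' trait-associated QTN positions. Each planted hotspot is realized by
#' `support` QTLs from distinct study ids, all covering the planted region;
#' background QTLs are rejection-placed so they overlap nothing, making the
#' planted hotspots exactly the recoverable ones. QTNs are placed inside
#' planted hotspots with probability `qtn_in_hotspot_fraction`, otherwise well
#' clear of them. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return list with `qtl` (data.frame qtl_id/study_id/chrom/start/end/lod/pve),
#'   `qtn` (data.frame qtn_id/study_id/chrom/pos) and `truth` (planted hotspot
#'   intervals with member ids and support; per-QTN hotspot membership).
#' @export
simulate_genetic_maps <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$hotspot_spec
  if (is.null(spec)) spec <- .default_hotspot_spec(config)
  for (h in spec) {
    if (!h$chrom %in% names(config$chrom_lengths))
      stop("hotspot_spec chromosome ", h$chrom, " not in the genome", call. = FALSE)
    if (h$end > config$chrom_lengths[[h$chrom]])
      stop("hotspot_spec region exceeds chromosome ", h$chrom, call. = FALSE)
    if (h$support < 2)
      stop("planted hotspots need support >= 2", call. = FALSE)
  }
  if (config$n_studies == 0) {
    empty_qtl <- data.frame(qtl_id = character(), study_id = character(),
                            chrom = character(), start = numeric(),
                            end = numeric(), lod = numeric(), pve = numeric(),
                            stringsAsFactors = FALSE)
    empty_qtn <- data.frame(qtn_id = character(), study_id = character(),
                            chrom = character(), pos = numeric(),
                            stringsAsFactors = FALSE)
    return(list(qtl = empty_qtl, qtn = empty_qtn,
                truth = list(hotspots = NULL, qtn_in_hotspot = logical())))
  }
  set.seed(.substream(config$seed, "qtl"))
  studies <- sprintf("study%02d", seq_len(config$n_studies))
  qtl <- list()
  planted <- list()
  for (i in seq_along(spec)) {
    h <- spec[[i]]
    if (h$support > config$n_studies)
      stop("hotspot support exceeds the number of studies", call. = FALSE)
    members <- sample(studies, h$support)
    L <- config$chrom_lengths[[h$chrom]]
    # each member covers the planted region with jittered flanks, so members
    # overlap pairwise and the merged span covers the region
    ext_l <- round(runif(h$support, 0, 5e5))
    ext_r <- round(runif(h$support, 0, 5e5))
    st <- pmax(1, h$start - ext_l)
    en <- pmin(L, h$end + ext_r)
    qtl[[length(qtl) + 1]] <- data.frame(
      qtl_id = sprintf("HSQTL_%d_%d", i, seq_len(h$support)),
      study_id = members, chrom = h$chrom, start = st, end = en,
      lod = round(runif(h$support, 2.6, 27.6), 2),
      pve = round(runif(h$support, 1.51, 28.43), 2),
      stringsAsFactors = FALSE)
    planted[[i]] <- list(chrom = h$chrom, start = min(st), end = max(en),
                         planted_start = h$start, planted_end = h$end,
                         support = h$support,
                         members = qtl[[length(qtl)]]$qtl_id)
  }
  qtl <- do.call(rbind, qtl)
  # background QTLs: rejection-placed to overlap nothing already placed
  n_bg <- max(0, config$n_studies * config$n_qtl_per_study - nrow(qtl))
  occupied <- qtl
  bg <- list()
  attempts <- 0
  while (length(bg) < n_bg && attempts < n_bg * 200) {
    attempts <- attempts + 1
    ch <- sample(names(config$chrom_lengths), 1)
    L <- config$chrom_lengths[[ch]]
    w <- min(round(rlnorm(1, log(3e6), 0.8)), floor(L / 2))
    st <- floor(runif(1, 1, L - w))
    en <- st + w - 1
    same <- occupied[occupied$chrom == ch, , drop = FALSE]
    if (nrow(same) == 0 || all(en < same$start | st > same$end)) {
      rec <- data.frame(qtl_id = sprintf("BGQTL_%03d", length(bg) + 1),
                        study_id = sample(studies, 1), chrom = ch,
                        start = st, end = en,
                        lod = round(runif(1, 2.6, 27.6), 2),
                        pve = round(runif(1, 1.51, 28.43), 2),
                        stringsAsFactors = FALSE)
      bg[[length(bg) + 1]] <- rec
      occupied <- rbind(occupied, rec)
    }
  }
  qtl <- rbind(qtl, do.call(rbind, bg))
  rownames(qtl) <- NULL

  # QTNs
  set.seed(.substream(config$seed, "qtn"))
  n_in <- round(config$n_qtns * config$qtn_in_hotspot_fraction)
  qtn_chrom <- character(config$n_qtns)
  qtn_pos <- numeric(config$n_qtns)
  in_hot <- logical(config$n_qtns)
  for (k in seq_len(config$n_qtns)) {
    if (k <= n_in && length(planted)) {
      h <- planted[[sample.int(length(planted), 1)]]
      qtn_chrom[k] <- h$chrom
      qtn_pos[k] <- floor(runif(1, h$planted_start, h$planted_end))
      in_hot[k] <- TRUE
    } else {
      repeat {
        ch <- sample(names(config$chrom_lengths), 1)
        L <- config$chrom_lengths[[ch]]
        pos <- floor(runif(1, 1, L))
        clear <- TRUE
        for (h in planted) {
          if (h$chrom == ch && pos >= h$start - config$qtn_flank &&
              pos <= h$end + config$qtn_flank) { clear <- FALSE; break }
        }
        if (clear) { qtn_chrom[k] <- ch; qtn_pos[k] <- pos; break }
      }
    }
  }
  qtn <- data.frame(qtn_id = sprintf("QTN%03d", seq_len(config$n_qtns)),
                    study_id = sample(studies, config$n_qtns, replace = TRUE),
                    chrom = qtn_chrom, pos = qtn_pos, stringsAsFactors = FALSE)
  list(qtl = qtl, qtn = qtn,
       truth = list(hotspots = planted,
                    qtn_in_hotspot = stats::setNames(in_hot, qtn$qtn_id)))
}

#' Write the synthetic dataset to plain-text files
#'
#' Writes counts TSV (gene_id plus one column per sample), sample sheet TSV,
#' annotation TSV, QTL and QTN TSVs and a truth JSON under `dir`.
#'
#' @param sim result of [simulate_experiment()].
#' @param maps result of [simulate_genetic_maps()] or `NULL`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths written.
#' @export
write_synthetic_data <- function(sim, maps = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.json"))
  counts_df <- data.frame(gene_id = rownames(sim$counts), sim$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(counts_df, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$samples, paths["samples"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$gene_span <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  if (!is.null(maps)) {
    paths <- c(paths, qtl = file.path(dir, "qtl.tsv"),
               qtn = file.path(dir, "qtn.tsv"))
    utils::write.table(maps$qtl, paths["qtl"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(maps$qtn, paths["qtn"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
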