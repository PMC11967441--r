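# Brute-force per-bp oracles for interval operations, independent of the
# package's GenomicRanges-based implementation. Only usable on small
# chromosomes (<= 1e5 bp).

# single-linkage merge of intervals on one chromosome via bp occupancy
bp_merge_chrom <- function(start, end, chrom_len) {
  occ <- logical(chrom_len)
  for (i in seq_along(start)) occ[start[i]:end[i]] <- TRUE
  r <- rle(occ)
  pos <- cumsum(c(1, r$lengths))
  comp_start <- pos[-length(pos)][r$values]
  comp_end <- (pos[-1] - 1)[r$values]
  membership <- lapply(seq_along(comp_start), function(k)
    which(start <= comp_end[k] & end >= comp_start[k]))
  list(start = comp_start, end = comp_end, members = membership)
}

# hotspot oracle over a multi-chromosome QTL table
bp_hotspots <- function(qtl, chrom_lengths, min_support = 2,
                        require_distinct_studies = TRUE) {
  out <- list()
  for (ch in unique(qtl$chrom)) {
    sub <- qtl[qtl$chrom == ch, , drop = FALSE]
    cc <- bp_merge_chrom(sub$start, sub$end, chrom_lengths[[ch]])
    for (k in seq_along(cc$start)) {
      idx <- cc$members[[k]]
      ok <- length(idx) >= min_support &&
        (!require_distinct_studies || length(unique(sub$study_id[idx])) >= 2)
      if (ok)
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = min(sub$start[idx]), end = max(sub$end[idx]),
          support = length(idx),
          n_studies = length(unique(sub$study_id[idx])),
          members = paste(sort(sub$qtl_id[idx]), collapse = ","),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      support = integer(), n_studies = integer(),
                      members = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# per-bp overlap oracle: gene vs region membership via bp occupancy vectors
bp_overlap <- function(annotation, regions, id_col = "region_id",
                       chrom_lengths = NULL) {
  pairs <- list()
  for (j in seq_len(nrow(regions))) {
    len <- if (is.null(chrom_lengths)) max(regions$end[j], annotation$end)
           else chrom_lengths[[regions$chrom[j]]]
    occ <- logical(len)
    occ[regions$start[j]:regions$end[j]] <- TRUE
    same <- which(annotation$chrom == regions$chrom[j])
    for (i in same) {
      if (any(occ[annotation$start[i]:min(annotation$end[i], len)]))
        pairs[[length(pairs) + 1]] <- data.frame(
          gene_id = annotation$gene_id[i], region_id = regions[[id_col]][j],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(pairs))
    return(data.frame(gene_id = character(), region_id = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, pairs)
}

# direct evaluation of the candidate predicate
bp_candidates <- function(deg_set, hotspots, windows, annotation,
                          qtn_binding = "same_hotspot") {
  ann <- annotation[annotation$gene_id %in% deg_set, , drop = FALSE]
  tier1 <- character(); common <- character()
  for (i in seq_len(nrow(ann))) {
    hs_ids <- character(); win_ids <- character()
    for (j in seq_len(nrow(hotspots)))
      if (ann$chrom[i] == hotspots$chrom[j] &&
          ann$start[i] <= hotspots$end[j] && ann$end[i] >= hotspots$start[j])
        hs_ids <- c(hs_ids, hotspots$hotspot_id[j])
    for (j in seq_len(nrow(windows)))
      if (ann$chrom[i] == windows$chrom[j] &&
          ann$start[i] <= windows$end[j] && ann$end[i] >= windows$start[j])
        win_ids <- c(win_ids, windows$qtn_id[j])
    if (length(hs_ids) || length(win_ids)) tier1 <- c(tier1, ann$gene_id[i])
    if (length(hs_ids) && length(win_ids)) {
      is_common <- FALSE
      for (q in win_ids) {
        w <- windows[windows$qtn_id == q, ]
        host <- hotspots$hotspot_id[hotspots$chrom == w$chrom &
                                      hotspots$start <= w$pos &
                                      hotspots$end >= w$pos]
        hit <- if (qtn_binding == "any") length(host) > 0
               else length(intersect(host, hs_ids)) > 0
        if (hit) { is_common <- TRUE; break }
      }
      if (is_common) common <- c(common, ann$gene_id[i])
    }
  }
  list(tier1 = sort(tier1), common = sort(common))
}

# random interval instance on small chromosomes
random_instance <- function(seed, n_chrom = 2, max_len = 1e5) {
  set.seed(seed)
  chrom_lengths <- stats::setNames(
    sample(seq(1000, max_len), n_chrom), paste0("c", seq_len(n_chrom)))
  n_qtl <- sample(3:12, 1)
  ch <- sample(names(chrom_lengths), n_qtl, replace = TRUE)
  st <- en <- integer(n_qtl)
  for (i in seq_len(n_qtl)) {
    L <- chrom_lengths[[ch[i]]]
    st[i] <- sample(L, 1)
    en[i] <- min(L, st[i] + sample(ceiling(L / 3), 1))
  }
  qtl <- data.frame(qtl_id = sprintf("q%02d", seq_len(n_qtl)),
                    study_id = sample(sprintf("s%d", 1:4), n_qtl, TRUE),
                    chrom = ch, start = st, end = en, stringsAsFactors = FALSE)
  n_gene <- sample(5:25, 1)
  gch <- sample(names(chrom_lengths), n_gene, replace = TRUE)
  gst <- gen <- integer(n_gene)
  for (i in seq_len(n_gene)) {
    L <- chrom_lengths[[gch[i]]]
    gst[i] <- sample(L, 1)
    gen[i] <- min(L, gst[i] + sample(200, 1))
  }
  ann <- data.frame(gene_id = sprintf("g%03d", seq_len(n_gene)),
                    chrom = gch, start = gst, end = gen,
                    stringsAsFactors = FALSE)
  n_qtn <- sample(2:8, 1)
  qch <- sample(names(chrom_lengths), n_qtn, replace = TRUE)
  qtn <- data.frame(qtn_id = sprintf("n%02d", seq_len(n_qtn)),
                    chrom = qch,
                    pos = vapply(qch, function(c_) sample(chrom_lengths[[c_]], 1),
                                 numeric(1)),
                    stringsAsFactors = FALSE)
  list(chrom_lengths = chrom_lengths, qtl = qtl, annotation = ann, qtn = qtn)
}
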