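#' Validate a compiled QTL table
#'
#' Checks compiled QTL intervals against the genome: unknown chromosomes are
#' an error, reversed coordinates are swapped with a warning, records missing
#' coordinates are skipped with a warning, and duplicate
#' (study, chrom, start, end) records are collapsed with a warning. All
#' coordinates are 1-based inclusive on one genome build.
#'
#' @param qtl data.frame with columns qtl_id, study_id, chrom, start, end and
#'   optionally lod, pve.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @return validated data.frame; attribute `n_skipped` counts dropped records.
#' @export
build_intervals <- function(qtl, chrom_lengths) {
  req <- c("qtl_id", "study_id", "chrom", "start", "end")
  if (!all(req %in% names(qtl)))
    stop("QTL table needs columns ", paste(req, collapse = ", "), call. = FALSE)
  bad_chrom <- setdiff(unique(qtl$chrom), names(chrom_lengths))
  if (length(bad_chrom))
    stop("unknown chromosome(s) in QTL table: ",
         paste(bad_chrom, collapse = ", "), call. = FALSE)
  miss <- !is.finite(qtl$start) | !is.finite(qtl$end)
  if (any(miss)) {
    warning(sum(miss), " QTL record(s) missing coordinates skipped",
            call. = FALSE)
    qtl <- qtl[!miss, , drop = FALSE]
  }
  rev <- qtl$start > qtl$end
  if (any(rev)) {
    warning(sum(rev), " QTL record(s) had start > end; coordinates swapped",
            call. = FALSE)
    tmp <- qtl$start[rev]
    qtl$start[rev] <- qtl$end[rev]
    qtl$end[rev] <- tmp
  }
  if (any(c("lod", "pve") %in% names(qtl))) {
    for (col in intersect(c("lod", "pve"), names(qtl)))
      if (any(qtl[[col]] < 0, na.rm = TRUE))
        stop(col, " must be non-negative when present", call. = FALSE)
  }
  key <- paste(qtl$study_id, qtl$chrom, qtl$start, qtl$end)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate QTL record(s) collapsed",
            call. = FALSE)
    qtl <- qtl[!duplicated(key), , drop = FALSE]
  }
  rownames(qtl) <- NULL
  attr(qtl, "n_skipped") <- sum(miss)
  qtl
}

.qtl_granges <- function(qtl, chrom_lengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = qtl$chrom,
    ranges = IRanges::IRanges(start = as.integer(qtl$start),
                              end = as.integer(qtl$end)))
  S4Vectors::mcols(gr)$qtl_id <- qtl$qtl_id
  S4Vectors::mcols(gr)$study_id <- qtl$study_id
  gr
}

#' Merge overlapping cross-study QTLs into hotspots
#'
#' Per chromosome, overlapping QTL intervals (sharing at least one bp; pure
#' abutment does not merge) are joined by single linkage into clusters. A
#' cluster is emitted as a hotspot iff it has at least `min_support` member
#' QTLs and, when `require_distinct_studies`, members from at least two
#' distinct studies — the repeated-detection rule defining a QTL hotspot.
#' The hotspot span is the minimal interval covering all members.
#'
#' @param qtl validated QTL data.frame (see [build_intervals()]).
#' @param min_support minimum member QTLs, default 2.
#' @param require_distinct_studies demand >= 2 distinct study ids (default
#'   TRUE); set FALSE to count repeated detections within one study.
#' @return data.frame hotspot_id/chrom/start/end/support/n_studies/members
#'   (comma-joined qtl_ids), sorted by chromosome then start.
#' @export
merge_hotspots <- function(qtl, min_support = 2, require_distinct_studies = TRUE) {
  empty <- data.frame(hotspot_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), support = integer(),
                      n_studies = integer(), members = character(),
                      stringsAsFactors = FALSE)
  if (nrow(qtl) == 0) return(empty)
  gr <- .qtl_granges(qtl)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE,
                               ignore.strand = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  keep <- logical(length(red))
  support <- integer(length(red))
  n_studies <- integer(length(red))
  members <- character(length(red))
  for (i in seq_along(red)) {
    idx <- revmap[[i]]
    support[i] <- length(idx)
    n_studies[i] <- length(unique(qtl$study_id[idx]))
    members[i] <- paste(qtl$qtl_id[idx], collapse = ",")
    keep[i] <- support[i] >= min_support &&
      (!require_distinct_studies || n_studies[i] >= 2)
  }
  if (!any(keep)) return(empty)
  red <- red[keep]
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red),
                    end = GenomicRanges::end(red),
                    support = support[keep], n_studies = n_studies[keep],
                    members = members[keep], stringsAsFactors = FALSE)
  chrom_rank <- match(out$chrom, unique(qtl$chrom))
  out <- out[order(chrom_rank, out$start), , drop = FALSE]
  out <- cbind(data.frame(hotspot_id = sprintf("HS%02d", seq_len(nrow(out))),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Flanking windows around QTNs
#'
#' One window per QTN: \eqn{[\max(1, pos - flank), \min(L, pos + flank)]},
#' 1-based inclusive, clamped at chromosome ends and never merged with other
#' windows so per-QTN evidence is preserved. The default 100 kb flank gives
#' the 200 kb region surrounding each trait-associated variant.
#'
#' @param qtn data.frame with columns qtn_id, chrom, pos.
#' @param flank bp each side, default 1e5.
#' @param chrom_lengths named vector of chromosome lengths.
#' @return data.frame qtn_id/chrom/start/end/pos.
#' @export
qtn_flanks <- function(qtn, flank = 1e5, chrom_lengths) {
  if (nrow(qtn) == 0)
    return(data.frame(qtn_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), pos = numeric(),
                      stringsAsFactors = FALSE))
  bad <- setdiff(unique(qtn$chrom), names(chrom_lengths))
  if (length(bad))
    stop("unknown chromosome(s) in QTN table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  L <- chrom_lengths[qtn$chrom]
  if (any(qtn$pos < 1 | qtn$pos > L))
    stop("QTN position outside its chromosome", call. = FALSE)
  data.frame(qtn_id = qtn$qtn_id, chrom = qtn$chrom,
             start = pmax(1, qtn$pos - flank),
             end = pmin(L, qtn$pos + flank),
             pos = qtn$pos, stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlap genes with genomic regions
#'
#' Assigns a gene to a region iff their spans share at least one bp (strand
#' ignored; both on the same build, 1-based inclusive).
#'
#' @param annotation data.frame gene_id/chrom/start/end.
#' @param regions data.frame with chrom/start/end and an id column (first
#'   column, or `region_id`).
#' @param validate_chroms error when annotation and regions share no
#'   chromosome name (default TRUE: such inputs usually mean mismatched
#'   naming schemes, e.g. "1" vs "chr1").
#' @return data.frame gene_id/region_id, one row per overlapping pair.
#' @export
overlap_genes <- function(annotation, regions, validate_chroms = TRUE) {
  id_col <- if ("region_id" %in% names(regions)) "region_id" else names(regions)[1]
  if (nrow(regions) == 0 || nrow(annotation) == 0)
    return(data.frame(gene_id = character(), region_id = character(),
                      stringsAsFactors = FALSE))
  shared <- union(annotation$chrom, regions$chrom)
  if (validate_chroms &&
      length(intersect(annotation$chrom, regions$chrom)) == 0) {
    unmatched <- setdiff(regions$chrom, annotation$chrom)
    stop("no chromosome shared between annotation and regions; unmatched: ",
         paste(utils::head(unmatched, 10), collapse = ", "), call. = FALSE)
  }
  # shared seqlevels so findOverlaps can compare the two sets
  gg <- GenomicRanges::GRanges(factor(annotation$chrom, levels = shared),
          IRanges::IRanges(as.integer(annotation$start),
                           as.integer(annotation$end)))
  rg <- GenomicRanges::GRanges(factor(regions$chrom, levels = shared),
          IRanges::IRanges(as.integer(regions$start),
                           as.integer(regions$end)))
  hits <- GenomicRanges::findOverlaps(gg, rg, ignore.strand = TRUE)
  data.frame(gene_id = annotation$gene_id[S4Vectors::queryHits(hits)],
             region_id = regions[[id_col]][S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Call candidate genes from DEGs, hotspots and QTN windows
#'
#' Tier-1 candidates are Phase-I line-specific DEGs lying in at least one QTL
#' hotspot or at least one QTN flanking window (any-overlap). A candidate is
#' in a common QTL+QTN region when it lies in a hotspot AND in the window of
#' a QTN located inside a hotspot: with `qtn_binding = "same_hotspot"`
#' (default, the strict reading) the QTN must sit inside one of the hotspots
#' containing the gene; `"any"` only requires both kinds of evidence.
#'
#' @param deg_set character vector of DEG ids (Phase-I line-specific DEGs).
#' @param hotspots data.frame from [merge_hotspots()].
#' @param windows data.frame from [qtn_flanks()].
#' @param annotation data.frame gene_id/chrom/start/end covering `deg_set`
#'   (ids absent from the annotation are reported and skipped).
#' @param qtn_binding "same_hotspot" or "any".
#' @return data.frame gene_id/in_hotspot/in_qtn_window/common_region with
#'   comma-joined evidence ids; attributes `counts` (tier tallies) and
#'   `missing` (DEG ids not in the annotation). Only genes with some evidence
#'   are returned.
#' @export
call_candidates <- function(deg_set, hotspots, windows, annotation,
                            qtn_binding = c("same_hotspot", "any")) {
  qtn_binding <- match.arg(qtn_binding)
  if (length(deg_set) == 0)
    warning("empty DEG set; no candidates can be called", call. = FALSE)
  missing <- setdiff(deg_set, annotation$gene_id)
  if (length(missing))
    warning(length(missing), " DEG id(s) absent from the annotation skipped",
            call. = FALSE)
  ann <- annotation[annotation$gene_id %in% deg_set, , drop = FALSE]
  hot_hits <- if (nrow(hotspots)) {
    h <- hotspots; names(h)[names(h) == "hotspot_id"] <- "region_id"
    overlap_genes(ann, h[, c("region_id", "chrom", "start", "end")],
                  validate_chroms = FALSE)
  } else data.frame(gene_id = character(), region_id = character())
  win_hits <- if (nrow(windows)) {
    w <- windows; names(w)[names(w) == "qtn_id"] <- "region_id"
    overlap_genes(ann, w[, c("region_id", "chrom", "start", "end")],
                  validate_chroms = FALSE)
  } else data.frame(gene_id = character(), region_id = character())

  # which QTNs sit inside which hotspot
  qtn_host <- list()
  if (nrow(windows) && nrow(hotspots)) {
    for (i in seq_len(nrow(windows))) {
      inside <- hotspots$chrom == windows$chrom[i] &
        hotspots$start <= windows$pos[i] & hotspots$end >= windows$pos[i]
      qtn_host[[windows$qtn_id[i]]] <- hotspots$hotspot_id[inside]
    }
  }
  genes <- union(hot_hits$gene_id, win_hits$gene_id)
  if (!length(genes)) {
    out <- data.frame(gene_id = character(), in_hotspot = character(),
                      in_qtn_window = character(), common_region = logical(),
                      stringsAsFactors = FALSE)
  } else {
    hs_by_gene <- split(hot_hits$region_id, hot_hits$gene_id)
    win_by_gene <- split(win_hits$region_id, win_hits$gene_id)
    common <- vapply(genes, function(g) {
      hs <- hs_by_gene[[g]]; ws <- win_by_gene[[g]]
      if (is.null(hs) || is.null(ws)) return(FALSE)
      if (qtn_binding == "any")
        return(any(vapply(ws, function(q) length(qtn_host[[q]]) > 0, logical(1))))
      any(vapply(ws, function(q) length(intersect(qtn_host[[q]], hs)) > 0,
                 logical(1)))
    }, logical(1))
    out <- data.frame(
      gene_id = genes,
      in_hotspot = vapply(genes, function(g)
        paste(hs_by_gene[[g]], collapse = ","), character(1)),
      in_qtn_window = vapply(genes, function(g)
        paste(win_by_gene[[g]], collapse = ","), character(1)),
      common_region = common, stringsAsFactors = FALSE, row.names = NULL)
  }
  attr(out, "counts") <- c(
    n_deg = length(deg_set),
    n_in_hotspot = length(unique(hot_hits$gene_id)),
    n_in_qtn_window = length(unique(win_hits$gene_id)),
    n_tier1 = nrow(out),
    n_common_region = sum(out$common_region))
  attr(out, "missing") <- missing
  out
}

#' Annotate candidates with transcription-factor families
#'
#' Joins a gene-to-family table onto the candidate table (genes absent from
#' the table are non-TF) and tallies families, optionally split by
#' per-stage up/down direction of the underlying DEG calls.
#'
#' @param candidates data.frame from [call_candidates()].
#' @param tf_table data.frame gene_id/family.
#' @param directions optional data.frame gene_id/stage/direction
#'   ("up"/"down") used for the per-stage split of the tally.
#' @return list with `candidates` (input plus `tf_family` column, NA for
#'   non-TF) and `tally` (family counts; with `directions`, a family x
#'   stage:direction table).
#' @export
annotate_tfs <- function(candidates, tf_table, directions = NULL) {
  fam <- tf_table$family[match(candidates$gene_id, tf_table$gene_id)]
  out <- candidates
  out$tf_family <- fam
  tf <- out[!is.na(out$tf_family), , drop = FALSE]
  if (is.null(directions) || nrow(tf) == 0) {
    tally <- table(tf$tf_family)
  } else {
    d <- directions[directions$gene_id %in% tf$gene_id, , drop = FALSE]
    d$family <- tf$tf_family[match(d$gene_id, tf$gene_id)]
    tally <- table(d$family, paste(d$stage, d$direction, sep = ":"))
  }
  list(candidates = out, tally = tally)
}
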