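#' Read a gene-level count matrix
#'
#' TSV with a `gene_id` column followed by one integer column per sample.
#'
#' @param path file path.
#' @return integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  m
}

#' Read a sample sheet
#'
#' TSV with columns sample, line, stage, replicate.
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "line", "stage", "replicate")
  if (!all(req %in% names(df)))
    stop("sample sheet needs columns ", paste(req, collapse = ", "), call. = FALSE)
  df
}

#' Read a gene annotation
#'
#' Either a BED-like TSV with columns gene_id, chrom, start, end (1-based
#' inclusive; optional strand, exonic_length) or, for paths ending in
#' `.gff3`/`.gff`, gene features parsed with rtracklayer. When the GFF3
#' carries no exonic length, the span width is used.
#'
#' @param path file path.
#' @return data.frame gene_id/chrom/start/end/strand/exonic_length.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    id <- if (!is.null(gr$ID)) gr$ID else gr$Name
    return(data.frame(gene_id = as.character(id),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      exonic_length = GenomicRanges::width(gr),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "start", "end")
  if (!all(req %in% names(df)))
    stop("annotation needs columns ", paste(req, collapse = ", "), call. = FALSE)
  if (is.null(df$exonic_length)) df$exonic_length <- df$end - df$start + 1
  df
}

#' Read a compiled QTL table
#' @param path TSV with columns qtl_id, study_id, chrom, start, end and
#'   optionally lod, pve.
#' @return data.frame.
#' @export
read_qtl_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("qtl_id", "study_id", "chrom", "start", "end")
  if (!all(req %in% names(df)))
    stop("QTL table needs columns ", paste(req, collapse = ", "), call. = FALSE)
  df
}

#' Read a compiled QTN table
#' @param path TSV with columns qtn_id, chrom, pos (study_id optional).
#' @return data.frame.
#' @export
read_qtn_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("qtn_id", "chrom", "pos")
  if (!all(req %in% names(df)))
    stop("QTN table needs columns ", paste(req, collapse = ", "), call. = FALSE)
  df
}

#' Write intervals as BED
#'
#' Converts 1-based inclusive intervals to 0-based half-open BED at the
#' writer boundary.
#'
#' @param df data.frame with chrom/start/end and an id column (first column
#'   or `region_id`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(df, path) {
  id_col <- if ("region_id" %in% names(df)) "region_id" else names(df)[1]
  bed <- data.frame(chrom = df$chrom, start = df$start - 1, end = df$end,
                    name = df[[id_col]])
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
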