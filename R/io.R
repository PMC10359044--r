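#' Write a count matrix and its sample sheet to TSV
#'
#' The matrix file has `feature_id` as its first column followed by one column
#' per sample; the sample sheet has columns `sample_id`, `condition`, `batch`.
#'
#' @param m a [count_matrix()].
#' @param counts_path,samples_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_count_matrix <- function(m, counts_path, samples_path) {
  df <- data.frame(feature_id = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(m$samples, samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_path, samples_path))
}

#' Read a count matrix and sample sheet written by [write_count_matrix()]
#'
#' @param counts_path,samples_path input file paths.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  count_matrix(counts[, samples$sample_id, drop = FALSE], samples)
}

#' Write gene sets in GMT format
#'
#' One line per set: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param sets named list of character vectors of gene ids.
#' @param path output path.
#' @param descriptions optional character vector parallel to `sets`.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("gene sets must be named")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return Named list of character vectors; descriptions kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop("malformed GMT line(s): ", paste(bad, collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "descriptions") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' Write a locus or gene annotation as BED6
#'
#' Intervals are stored 0-based half-open internally, which is BED's own
#' convention, so coordinates pass through unchanged. The score column carries
#' 0; the name column carries the locus/gene id.
#'
#' @param ann annotation data.frame (`chrom`, `start`, `end`, `strand` plus an
#'   id column).
#' @param path output path.
#' @param id_col name of the id column (`"locus_id"` or `"gene_id"`).
#' @return Invisibly, `path`.
#' @export
write_annotation_bed <- function(ann, path, id_col = "locus_id") {
  validate_annotation(ann, id_col)
  bed <- data.frame(ann$chrom, ann$start, ann$end, ann[[id_col]], 0L,
                    ifelse(ann$strand %in% c("+", "-"), ann$strand, "."))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a locus or gene annotation as GTF
#'
#' Internal 0-based half-open coordinates are converted to GTF's 1-based
#' closed convention. The family (loci) or symbol/biotype (genes) fields are
#' emitted as attributes.
#'
#' @inheritParams write_annotation_bed
#' @return Invisibly, `path`.
#' @export
write_annotation_gtf <- function(ann, path, id_col = "locus_id") {
  gr <- annotation_to_granges(ann, id_col)
  S4Vectors::mcols(gr)$source <- "hervscope"
  S4Vectors::mcols(gr)$type <- if (id_col == "locus_id") "exon" else "gene"
  if (id_col == "locus_id") {
    S4Vectors::mcols(gr)$locus_id <- ann$locus_id
    if (!is.null(ann$family)) S4Vectors::mcols(gr)$family <- ann$family
  } else {
    S4Vectors::mcols(gr)$gene_id <- ann$gene_id
    if (!is.null(ann$biotype)) S4Vectors::mcols(gr)$gene_biotype <- ann$biotype
  }
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a locus annotation from BED or GTF
#'
#' Coordinates are converted back to the package's internal 0-based half-open
#' representation. For GTF input the `family` attribute is recovered when
#' present; for BED the family is parsed from the locus name.
#'
#' @param path annotation file (`.bed` or `.gtf`).
#' @param id_col id column to populate.
#' @return Annotation data.frame.
#' @export
read_annotation <- function(path, id_col = "locus_id") {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  id <- if (!is.null(mc[[id_col]])) as.character(mc[[id_col]])
        else if (!is.null(mc$name)) as.character(mc$name)
        else names(gr)
  ann <- data.frame(
    id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  names(ann)[1] <- id_col
  ann$strand[ann$strand == "*"] <- "."
  if (id_col == "locus_id") {
    ann$family <- if (!is.null(mc$family)) as.character(mc$family)
                  else parse_locus_name(ann$locus_id)$family
  }
  ann
}
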