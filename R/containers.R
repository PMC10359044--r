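#' Construct a count matrix with sample metadata
#'
#' Bundles an integer features x samples count matrix with its sample sheet.
#' Columns of `counts` must line up with rows of `samples`; the `condition`
#' column distinguishes case from control and `batch` records provenance.
#'
#' @param counts integer matrix, features in rows (rownames = feature ids),
#'   samples in columns.
#' @param samples data.frame with at least `sample_id`, `condition`
#'   (`"case"`/`"control"`) and `batch`; an optional `library_size_factor`
#'   column records the simulated sequencing depth multiplier.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have feature ids as rownames")
  if (anyDuplicated(rownames(counts))) stop("feature ids must be unique")
  if (!is.data.frame(samples)) stop("samples must be a data.frame")
  req <- c("sample_id", "condition", "batch")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (ncol(counts) != nrow(samples)) stop("ncol(counts) must equal nrow(samples)")
  if (anyDuplicated(samples$sample_id)) stop("sample ids must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integral")
  storage.mode(counts) <- "double"
  colnames(counts) <- samples$sample_id
  samples$condition <- as.character(samples$condition)
  samples$batch <- as.character(samples$batch)
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("conditions:", paste(sprintf("%s=%d", names(table(x$samples$condition)),
                                   table(x$samples$condition)), collapse = " "), "\n")
  cat("batches:   ", paste(unique(x$samples$batch), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Replace the count slot, keeping metadata and class. Internal.
set_counts <- function(m, counts) {
  m$counts <- counts
  m
}

# Subset features of a count_matrix by row index or name. Internal.
subset_features <- function(m, idx) {
  m$counts <- m$counts[idx, , drop = FALSE]
  m
}

validate_annotation <- function(ann, id_col) {
  req <- c(id_col, "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann[[id_col]])) stop("duplicate ids in annotation")
  if (any(ann$start >= ann$end)) stop("annotation intervals must satisfy start < end")
  invisible(ann)
}

# Annotation data.frame (0-based half-open) -> GRanges (1-based closed).
annotation_to_granges <- function(ann, id_col) {
  validate_annotation(ann, id_col)
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ifelse(ann$strand %in% c("+", "-"), ann$strand, "*")
  )
  names(gr) <- ann[[id_col]]
  gr
}
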