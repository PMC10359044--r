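#' Map HERV loci to their closest upstream, downstream and intersecting genes
#'
#' Works in genomic coordinates (0-based half-open), strand-agnostic by
#' default: the upstream gene is the nearest gene ending at or before the
#' locus start (`distance = locus_start - gene_end`), the downstream gene
#' the nearest gene starting at or after the locus end
#' (`distance = gene_start - locus_end`). Adjacent genes (distance 0,
#' non-overlapping) count as flanking; genes overlapping the locus by at
#' least one base are intersecting. Ties are broken toward the
#' lexicographically smaller gene id.
#'
#' @param loci locus annotation data.frame.
#' @param genes gene annotation data.frame.
#' @param stranded if `TRUE`, upstream/downstream are flipped for loci on
#'   the minus strand (transcript-relative orientation).
#' @return data.frame with one row per locus: `herv_id`, `upstream_gene`,
#'   `upstream_dist`, `downstream_gene`, `downstream_dist` (NA when the
#'   flank is empty) and `intersecting` (comma-separated gene ids, `""` when
#'   none).
#' @export
map_proximal_genes <- function(loci, genes, stranded = FALSE) {
  validate_annotation(loci, "locus_id")
  if (nrow(genes)) validate_annotation(genes, "gene_id")
  out <- data.frame(herv_id = loci$locus_id,
                    upstream_gene = NA_character_, upstream_dist = NA_real_,
                    downstream_gene = NA_character_, downstream_dist = NA_real_,
                    intersecting = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(loci))) {
    g <- genes[genes$chrom == loci$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    ls <- loci$start[i]; le <- loci$end[i]
    ov <- g$start < le & g$end > ls
    if (any(ov))
      out$intersecting[i] <- paste(sort(g$gene_id[ov]), collapse = ",")
    up <- which(g$end <= ls)
    if (length(up)) {
      d <- ls - g$end[up]
      best <- up[order(d, g$gene_id[up])][1]
      out$upstream_gene[i] <- g$gene_id[best]
      out$upstream_dist[i] <- ls - g$end[best]
    }
    dn <- which(g$start >= le)
    if (length(dn)) {
      d <- g$start[dn] - le
      best <- dn[order(d, g$gene_id[dn])][1]
      out$downstream_gene[i] <- g$gene_id[best]
      out$downstream_dist[i] <- g$start[best] - le
    }
    if (stranded && loci$strand[i] == "-") {
      tmp <- out[i, c("upstream_gene", "upstream_dist")]
      out[i, c("upstream_gene", "upstream_dist")] <-
        out[i, c("downstream_gene", "downstream_dist")]
      out[i, c("downstream_gene", "downstream_dist")] <- tmp
    }
  }
  out
}

#' Transfer DE coefficients from HERV loci to their proximal genes
#'
#' Each differentially expressed HERV's log2 fold change is assigned to its
#' upstream, downstream and intersecting genes. A gene receiving scores from
#' several HERVs keeps the one of largest absolute value (`"max_abs"`,
#' default) or their mean (`"mean"`).
#'
#' @param de data.frame with `feature_id` and `log2fc` (HERV rows; if a
#'   `status` column is present only `status != "ns"` rows are used).
#' @param pmap proximal map from [map_proximal_genes()].
#' @param collision collision rule for multiply-hit genes.
#' @return Named numeric vector of per-gene scores.
#' @export
transfer_scores <- function(de, pmap, collision = c("max_abs", "mean")) {
  collision <- match.arg(collision)
  if (!is.null(de$status)) de <- de[de$status != "ns", , drop = FALSE]
  pmap <- pmap[pmap$herv_id %in% de$feature_id, , drop = FALSE]
  if (!nrow(pmap)) return(stats::setNames(numeric(0), character(0)))
  miss <- setdiff(pmap$herv_id, de$feature_id)
  if (length(miss)) stop("no DE coefficient for: ", paste(miss, collapse = ", "))
  lfc <- de$log2fc[match(pmap$herv_id, de$feature_id)]

  gene <- character(0); score <- numeric(0)
  add <- function(gs, s) {
    gs <- gs[!is.na(gs) & nzchar(gs)]
    if (length(gs)) { gene <<- c(gene, gs); score <<- c(score, rep(s, length(gs))) }
  }
  for (r in seq_len(nrow(pmap))) {
    add(pmap$upstream_gene[r], lfc[r])
    add(pmap$downstream_gene[r], lfc[r])
    add(strsplit(pmap$intersecting[r], ",", fixed = TRUE)[[1]], lfc[r])
  }
  if (!length(gene)) return(stats::setNames(numeric(0), character(0)))
  out <- vapply(split(score, gene), function(s) {
    if (collision == "mean") mean(s) else s[which.max(abs(s))]
  }, numeric(1))
  out[order(names(out))]
}

#' Rank-based pathway enrichment of transferred gene scores
#'
#' Per pathway, member scores are compared with non-member scores over the
#' full scored universe by a two-sample Wilcoxon rank-sum test (exact
#' enumeration when the scored universe has at most 10 genes and no ties,
#' normal approximation with tie correction otherwise), two-sided. BH
#' q-values are computed over tested pathways; the median member score is
#' reported for directionality.
#'
#' @param scores named numeric vector of gene scores (from
#'   [transfer_scores()]).
#' @param pathways named list of gene sets (e.g. [read_gmt()]).
#' @param min_size minimum number of scored member genes for a pathway to be
#'   tested.
#' @return data.frame with `pathway_id`, `n_matched`, `median_score`,
#'   `rank_stat` (the rank-sum W statistic), `p`, `q`; skipped pathways are
#'   listed in `attr(, "skipped")`.
#' @export
pathway_enrichment <- function(scores, pathways, min_size = 3) {
  if (!length(scores)) stop("empty score map")
  universe <- names(scores)
  rows <- list(); skipped <- character(0)
  for (pw in names(pathways)) {
    members <- intersect(pathways[[pw]], universe)
    if (length(members) < min_size || length(members) == length(universe)) {
      skipped <- c(skipped, pw); next
    }
    ms <- scores[members]
    ns <- scores[setdiff(universe, members)]
    exact <- length(universe) <= 10 && !anyDuplicated(scores)
    wt <- suppressWarnings(stats::wilcox.test(ms, ns, exact = exact,
                                              correct = !exact))
    rows[[pw]] <- data.frame(pathway_id = pw, n_matched = length(ms),
                             median_score = stats::median(ms),
                             rank_stat = unname(wt$statistic), p = wt$p.value,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(pathway_id = character(), n_matched = integer(),
                      median_score = numeric(), rank_stat = numeric(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p)
  attr(out, "skipped") <- skipped
  out
}
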