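#' Pearson correlation with t-distribution p-value
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @return List with `r`, `p`, `n` and `flagged` (`TRUE` with `r = NA` when
#'   either vector has zero variance, rather than a silent NaN).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), flagged = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), flagged = FALSE)
}

#' Per-sample summed expression of a gene signature
#'
#' @param vst_matrix numeric matrix (features x samples) of
#'   variance-stabilized values.
#' @param gene_list character vector of signature gene ids; members absent
#'   from the matrix are reported in a message.
#' @return Named numeric vector, one value per sample.
#' @export
signature_sum <- function(vst_matrix, gene_list) {
  present <- intersect(gene_list, rownames(vst_matrix))
  if (!length(present)) stop("no signature gene present in the matrix")
  absent <- setdiff(gene_list, present)
  if (length(absent))
    message(length(absent), " signature gene(s) absent: ",
            paste(utils::head(absent, 5), collapse = ", "))
  colSums(vst_matrix[present, , drop = FALSE])
}

#' Correlate each HERV locus with a target gene or signature
#'
#' Per locus, the Pearson correlation of its expression profile with the
#' target profile is computed; BH q-values are taken over the tested loci.
#' The summary counts loci significant at `alpha` (on q by default, raw p
#' with `use_adjusted = FALSE`) and how many of those are positive.
#'
#' @param vst_matrix numeric matrix (features x samples).
#' @param loci character vector of locus ids (rows of the matrix).
#' @param target a gene id (row of the matrix) or a numeric per-sample
#'   vector such as [signature_sum()] output.
#' @param alpha significance level.
#' @param use_adjusted significance on BH q (`TRUE`) or raw p.
#' @return data.frame with `unit_id`, `target`, `r`, `p`, `q`, `n`,
#'   `flagged`; summary list (`n_significant`, `n_positive_of_significant`)
#'   in `attr(, "summary")`.
#' @export
locus_target_correlations <- function(vst_matrix, loci, target, alpha = 0.05,
                                      use_adjusted = TRUE) {
  if (!length(loci)) stop("empty locus set")
  missing_loci <- setdiff(loci, rownames(vst_matrix))
  if (length(missing_loci))
    stop("loci absent from matrix: ", paste(missing_loci, collapse = ", "))
  if (is.character(target)) {
    if (!target %in% rownames(vst_matrix))
      stop("target gene ", target, " absent from matrix")
    tname <- target
    tvec <- vst_matrix[target, ]
  } else {
    tname <- "signature"
    tvec <- as.numeric(target)
    if (length(tvec) != ncol(vst_matrix))
      stop("target vector length must equal the number of samples")
  }
  res <- lapply(loci, function(l) pearson_correlation(vst_matrix[l, ], tvec))
  out <- data.frame(
    unit_id = loci, target = tname,
    r = vapply(res, `[[`, numeric(1), "r"),
    p = vapply(res, `[[`, numeric(1), "p"),
    n = vapply(res, `[[`, numeric(1), "n"),
    flagged = vapply(res, `[[`, logical(1), "flagged"),
    stringsAsFactors = FALSE
  )
  out$q <- NA_real_
  ok <- !out$flagged
  if (any(ok)) out$q[ok] <- bh_adjust(out$p[ok])
  crit <- if (use_adjusted) out$q else out$p
  sig <- ok & crit < alpha
  attr(out, "summary") <- list(n_significant = sum(sig),
                               n_positive_of_significant = sum(sig & out$r > 0))
  out
}

#' Correlate a HERV family's summed expression with a target
#'
#' The family's loci rows are summed per sample and the sum is correlated
#' with the target. This is the family-level counterpart of
#' [locus_target_correlations()]; when only a few loci of a large family
#' track the target, the family sum dilutes the signal.
#'
#' @param vst_matrix numeric matrix (features x samples).
#' @param family_map named character vector mapping locus id to family.
#' @param family family name to test.
#' @param target as in [locus_target_correlations()].
#' @return List with `r`, `p`, `n`, `flagged` and `n_loci` (family loci
#'   found in the matrix).
#' @export
family_sum_correlation <- function(vst_matrix, family_map, family, target) {
  loci <- names(family_map)[family_map == family]
  loci <- intersect(loci, rownames(vst_matrix))
  if (!length(loci)) stop("unknown family or no loci in matrix: ", family)
  fsum <- colSums(vst_matrix[loci, , drop = FALSE])
  tvec <- if (is.character(target)) vst_matrix[target, ] else as.numeric(target)
  out <- pearson_correlation(fsum, tvec)
  out$n_loci <- length(loci)
  out
}

#' Rank gene-HERV association strength
#'
#' Scores every gene x HERV pair by squared Pearson correlation of their
#' expression profiles (a deterministic association importance; alternative
#' importance functions can be plugged in) and returns the strongest pairs.
#' Gene-gene and HERV-HERV pairs are never emitted. Constant rows get
#' importance 0 and are flagged.
#'
#' @param vst_matrix numeric matrix (features x samples).
#' @param gene_ids,herv_ids row names of the gene and HERV features.
#' @param top_k number of top pairs to return.
#' @param importance_fun function(gene_profile, herv_profile) -> scalar;
#'   defaults to squared Pearson correlation.
#' @return data.frame with `gene`, `herv`, `importance`, sorted by
#'   importance descending with lexicographic (gene, herv) tie-break.
#' @export
rank_gene_herv_associations <- function(vst_matrix, gene_ids, herv_ids,
                                        top_k = 5, importance_fun = NULL) {
  if (!length(gene_ids) || !length(herv_ids)) stop("both feature sets must be nonempty")
  stopifnot(all(gene_ids %in% rownames(vst_matrix)),
            all(herv_ids %in% rownames(vst_matrix)))
  G <- vst_matrix[gene_ids, , drop = FALSE]
  H <- vst_matrix[herv_ids, , drop = FALSE]
  if (is.null(importance_fun)) {
    const_g <- apply(G, 1, stats::sd) == 0
    const_h <- apply(H, 1, stats::sd) == 0
    imp <- suppressWarnings(stats::cor(t(G), t(H))^2)
    imp[const_g, ] <- 0
    imp[, const_h] <- 0
    imp[is.na(imp)] <- 0
  } else {
    imp <- matrix(0, length(gene_ids), length(herv_ids),
                  dimnames = list(gene_ids, herv_ids))
    for (g in gene_ids) for (h in herv_ids)
      imp[g, h] <- importance_fun(vst_matrix[g, ], vst_matrix[h, ])
  }
  out <- data.frame(gene = rep(gene_ids, times = length(herv_ids)),
                    herv = rep(herv_ids, each = length(gene_ids)),
                    importance = as.numeric(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$gene, out$herv), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}
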