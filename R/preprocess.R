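#' Remove genes on the Y chromosome
#'
#' Features annotated to chromosome Y (aliases `"Y"`, `"chrY"`) are dropped
#' to avoid sex-driven variance. The rule applies to genes only: features
#' absent from the gene annotation (e.g. HERV loci) are retained even when
#' they are located on Y, and a message notes any retained Y-located
#' features.
#'
#' @param m a [count_matrix()].
#' @param genes gene annotation data.frame (`gene_id`, `chrom`, ...).
#' @return The filtered [count_matrix()], feature order preserved.
#' @export
drop_y_genes <- function(m, genes) {
  idx <- match(rownames(m$counts), genes$gene_id)
  on_y <- !is.na(idx) & genes$chrom[idx] %in% c("Y", "chrY")
  unannotated <- is.na(idx)
  if (any(unannotated))
    message(sum(unannotated), " feature(s) absent from gene annotation; retained")
  subset_features(m, !on_y)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: the geometric mean across samples is
#' computed per feature (features with any zero excluded), and each sample's
#' factor is the median over included features of its count divided by that
#' reference.
#'
#' @param m a [count_matrix()] or bare counts matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(m) {
  counts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos))
    stop("no feature is nonzero in every sample; consider a pseudo-reference fallback")
  ref <- exp(rowMeans(log(counts[all_pos, , drop = FALSE])))
  apply(counts[all_pos, , drop = FALSE], 2, function(col) stats::median(col / ref))
}

# Geometric per-sample depth factors: exp of the mean log ratio to the
# per-feature geometric mean, over features positive in all samples. Smoother
# than the median under strongly bimodal per-feature batch shifts, where the
# median snaps to one mode. Internal to batch_adjust.
.depth_factors <- function(counts) {
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos)) return(rep(1, ncol(counts)))
  lc <- log(counts[all_pos, , drop = FALSE])
  ref <- rowMeans(lc)
  exp(colMeans(lc - ref))
}

# Method-of-moments NB dispersion on normalized counts within groups,
# pooled per feature with a floor. Internal.
.pooled_dispersion <- function(norm, groups, floor = 1e-4) {
  disp <- rep(floor, nrow(norm))
  num <- numeric(nrow(norm)); den <- numeric(nrow(norm))
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2) next
    mu <- rowMeans(norm[, cols, drop = FALSE])
    v <- apply(norm[, cols, drop = FALSE], 1, stats::var)
    ok <- mu > 0
    a <- ifelse(ok, (v - mu) / mu^2, 0)
    num <- num + length(cols) * pmax(a, 0)
    den <- den + length(cols)
  }
  pmax(ifelse(den > 0, num / den, floor), floor)
}

#' Adjust counts for batch effects by negative-binomial quantile matching
#'
#' Per feature, batch- and condition-specific means are estimated on
#' size-factor-normalized counts; a multiplicative batch factor is derived
#' from the deviation of each batch's means from the condition-wise pooled
#' (geometric) means. Each observed count is then mapped through the CDF of
#' its batch-specific negative binomial to a quantile, and back through the
#' inverse CDF of the batch-free target distribution, which retains the
#' condition effect. Output counts are integral and non-negative.
#'
#' With a single batch the input is returned unchanged. A batch lacking
#' either condition makes batch and condition non-identifiable and is
#' refused.
#'
#' @param m a [count_matrix()] with `batch` and `condition` metadata.
#' @param dispersion_floor lower bound for the per-feature
#'   method-of-moments dispersion estimate.
#' @return A batch-adjusted [count_matrix()].
#' @export
batch_adjust <- function(m, dispersion_floor = 1e-4) {
  samples <- m$samples
  batches <- unique(samples$batch)
  if (length(batches) < 2) return(m)
  tab <- table(samples$batch, samples$condition)
  if (any(tab == 0))
    stop("batch/condition confounding: batch(es) ",
         paste(rownames(tab)[apply(tab == 0, 1, any)], collapse = ", "),
         " lack one condition; adjustment refused")

  sf <- .depth_factors(m$counts)
  norm <- sweep(m$counts, 2, sf, "/")
  conds <- unique(samples$condition)
  grp <- paste(samples$batch, samples$condition)

  eps <- 1e-8
  # per-feature log means per (batch, condition)
  logmean <- function(cols) log(pmax(rowMeans(norm[, cols, drop = FALSE]), eps))
  lm_bc <- sapply(unique(grp), function(g) logmean(which(grp == g)))
  n_bc <- table(grp)[colnames(lm_bc)]

  # pooled per-condition log mean (weighted over batches) and batch factors
  lm_c <- sapply(conds, function(cc) {
    cols <- grep(paste0(" ", cc, "$"), colnames(lm_bc))
    w <- as.numeric(n_bc[cols]); w <- w / sum(w)
    lm_bc[, cols, drop = FALSE] %*% w
  })
  colnames(lm_c) <- conds
  log_g <- sapply(batches, function(b) {
    cols <- grep(paste0("^", b, " "), colnames(lm_bc))
    cc <- sub("^.* ", "", colnames(lm_bc)[cols])
    rowMeans(lm_bc[, cols, drop = FALSE] - lm_c[, cc, drop = FALSE])
  })
  colnames(log_g) <- batches

  alpha <- .pooled_dispersion(norm, grp, floor = dispersion_floor)

  mu_tgt <- exp(lm_c[, match(samples$condition, conds), drop = FALSE]) *
    rep(sf, each = nrow(norm))
  mu_src <- mu_tgt * exp(log_g[, match(samples$batch, batches), drop = FALSE])

  y <- m$counts
  size <- 1 / alpha
  # mid-quantile through the source CDF, back through the target inverse CDF
  p <- stats::pnbinom(y - 1, mu = mu_src, size = size) +
    0.5 * stats::dnbinom(y, mu = mu_src, size = size)
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  adj <- stats::qnbinom(p, mu = mu_tgt, size = size)

  zero_feat <- rowSums(y) == 0
  adj[zero_feat, ] <- 0
  dimnames(adj) <- dimnames(y)
  set_counts(m, adj)
}

#' Adaptive low-expression filter maximizing within-condition Jaccard similarity
#'
#' Counts are normalized by [size_factors()]; over a grid of thresholds the
#' matrix is binarized (`normalized > s`) and, for every within-condition
#' sample pair, the Jaccard index of the binary feature vectors is computed.
#' The threshold maximizing the mean Jaccard index is selected (ties broken
#' toward the smallest threshold) and features exceeding it in at least one
#' sample are retained.
#'
#' The grid is the set of distinct positive normalized values up to their
#' 95th percentile, thinned to at most `grid_cap` points. The Jaccard index
#' of two all-zero vectors is defined as 0 so that degenerate
#' filter-everything thresholds can never win.
#'
#' @param m a [count_matrix()].
#' @param grid_cap maximum number of candidate thresholds.
#' @return List with `filtered` (the retained [count_matrix()]), `threshold`
#'   (s*), and `curve` (data.frame `threshold`, `mean_jaccard`).
#' @export
jaccard_filter <- function(m, grid_cap = 200) {
  if (all(m$counts == 0)) stop("all-zero count matrix")
  cond_sizes <- table(m$samples$condition)
  if (max(cond_sizes) < 2)
    stop("need >= 2 samples in at least one condition")
  sf <- size_factors(m)
  norm <- sweep(m$counts, 2, sf, "/")

  vals <- sort(unique(as.numeric(norm[norm > 0])))
  vals <- vals[vals <= stats::quantile(vals, 0.95)]
  if (!length(vals)) vals <- sort(unique(as.numeric(norm[norm > 0])))[1]
  if (length(vals) > grid_cap)
    vals <- vals[unique(as.integer(round(seq(1, length(vals), length.out = grid_cap))))]
  # thresholds sit just below each grid value so "> s" keeps that value
  grid <- c(0, vals) - .Machine$double.eps^0.5
  grid <- unique(pmax(grid, 0))

  pair_cols <- list()
  for (cc in names(cond_sizes)[cond_sizes >= 2]) {
    cols <- which(m$samples$condition == cc)
    pair_cols <- c(pair_cols, utils::combn(cols, 2, simplify = FALSE))
  }

  mean_j <- vapply(grid, function(s) {
    B <- norm > s
    js <- vapply(pair_cols, function(pr) {
      a <- B[, pr[1]]; b <- B[, pr[2]]
      un <- sum(a | b)
      if (un == 0) 0 else sum(a & b) / un
    }, numeric(1))
    mean(js)
  }, numeric(1))

  s_star <- grid[which.max(mean_j)]
  keep <- apply(norm, 1, function(r) any(r > s_star))
  list(filtered = subset_features(m, keep),
       threshold = s_star,
       curve = data.frame(threshold = grid, mean_jaccard = mean_j))
}

#' Variance-stabilizing transform
#'
#' `log2(count / size_factor + 1)`: monotone in the counts, zero maps to
#' zero, and the variance of replicate measurements grows sublinearly with
#' the mean on NB data.
#'
#' @param m a [count_matrix()] or bare counts matrix.
#' @param factors per-sample positive size factors; defaults to
#'   [size_factors()] of `m`.
#' @return Numeric matrix of transformed values (features x samples).
#' @export
vst <- function(m, factors = NULL) {
  counts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  if (is.null(factors)) factors <- size_factors(counts)
  stopifnot(all(factors > 0), length(factors) == ncol(counts))
  log2(sweep(counts, 2, factors, "/") + 1)
}

#' PCA of samples for quality control
#'
#' Features are centered, the sample-space principal components are computed
#' by SVD, and the per-component variance-explained fractions are reported.
#' Used to visualize batch structure before and after [batch_adjust()].
#'
#' @param x numeric matrix, features x samples (typically [vst()] output).
#' @param n_components number of components to return.
#' @return A `pca_result`: list with `scores` (samples x components) and
#'   `variance_explained` (fractions, non-increasing).
#' @export
pca_qc <- function(x, n_components = 2) {
  if (ncol(x) < 2) stop("need >= 2 samples")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-12)
  if (n_components > rank) {
    warning("n_components exceeds rank (", rank, "); truncated")
    n_components <- rank
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 variance_explained = ve[seq_len(n_components)]),
            class = "pca_result")
}

#' Default preprocessing pipeline
#'
#' Chains [drop_y_genes()], [batch_adjust()] and [jaccard_filter()] in the
#' standard order; each stage can be skipped.
#'
#' @param m a [count_matrix()].
#' @param genes gene annotation (for Y-chromosome removal); `NULL` skips it.
#' @param skip_batch,skip_filter skip the respective stage.
#' @return List with `matrix` (the processed [count_matrix()]),
#'   `size_factors`, `jaccard_threshold` and `jaccard_curve`.
#' @export
preprocess_counts <- function(m, genes = NULL, skip_batch = FALSE,
                              skip_filter = FALSE) {
  if (!is.null(genes)) m <- drop_y_genes(m, genes)
  if (!skip_batch) m <- batch_adjust(m)
  thr <- NA_real_; curve <- NULL
  if (!skip_filter) {
    jf <- jaccard_filter(m)
    m <- jf$filtered; thr <- jf$threshold; curve <- jf$curve
  }
  list(matrix = m, size_factors = size_factors(m),
       jaccard_threshold = thr, jaccard_curve = curve)
}
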