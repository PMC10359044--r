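#' Negative-binomial Wald test for differential expression
#'
#' Per feature, a negative-binomial GLM with log link is fit with a single
#' condition coefficient (case vs control) and `log(size_factor)` offsets.
#' Dispersions are estimated by method of moments on normalized counts,
#' floored at 1e-8, and shrunk 50/50 toward the mean estimate of features in
#' the same expression decile. The Wald statistic is the coefficient divided
#' by its standard error, with a two-sided normal p-value; fold changes are
#' reported on the log2 scale.
#'
#' @param m a [count_matrix()] with both conditions present (>= 2 samples
#'   each).
#' @param factors per-sample size factors; defaults to [size_factors()].
#' @return data.frame with `feature_id`, `base_mean`, `log2fc`, `se`,
#'   `wald`, `p` and an `all_zero` flag. All-zero features get `log2fc = 0`,
#'   `p = 1`.
#' @export
nb_wald_de <- function(m, factors = NULL) {
  tab <- table(m$samples$condition)
  if (!all(c("case", "control") %in% names(tab)) || any(tab < 2))
    stop("both conditions must be present with >= 2 samples each")
  if (is.null(factors)) factors <- size_factors(m)
  # rescale factors to geometric mean 1 so dispersion estimates (and hence
  # the reported fold changes) are invariant to a global factor rescaling
  factors <- factors / exp(mean(log(factors)))
  counts <- m$counts
  norm <- sweep(counts, 2, factors, "/")
  cond <- factor(m$samples$condition, levels = c("control", "case"))

  mu <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  raw_disp <- ifelse(mu > 0, pmax((v - mu) / mu^2, 1e-8), 1e-8)
  dec <- cut(rank(mu, ties.method = "first"), breaks = 10, labels = FALSE)
  trend <- ave(raw_disp, dec, FUN = mean)
  disp <- 0.5 * raw_disp + 0.5 * trend

  off <- log(factors)
  n_feat <- nrow(counts)
  log2fc <- se <- wald <- p <- numeric(n_feat)
  all_zero <- rowSums(counts) == 0
  ln2 <- log(2)
  for (i in seq_len(n_feat)) {
    if (all_zero[i]) { log2fc[i] <- 0; se[i] <- NA; wald[i] <- 0; p[i] <- 1; next }
    fit <- suppressWarnings(stats::glm(
      counts[i, ] ~ cond, offset = off,
      family = MASS::negative.binomial(theta = 1 / disp[i])))
    cf <- summary(fit, dispersion = 1)$coefficients
    b <- cf["condcase", "Estimate"]; s <- cf["condcase", "Std. Error"]
    log2fc[i] <- b / ln2; se[i] <- s / ln2
    wald[i] <- b / s
    p[i] <- 2 * stats::pnorm(-abs(wald[i]))
  }
  data.frame(feature_id = rownames(counts), base_mean = mu,
             log2fc = log2fc, se = se, wald = wald, p = p,
             all_zero = all_zero, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, capped at 1, order-preserving against the input
#' indexing.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify differential-expression results at an FDR threshold
#'
#' Adds BH-adjusted q-values (if absent) and a `status` column: `up` iff
#' `q < fdr_threshold` and `log2fc > 0`, `down` iff `q < fdr_threshold` and
#' `log2fc < 0`, otherwise `ns`. The inequality is strict: a q-value exactly
#' at the threshold is not significant. The conventional defaults are 0.2
#' for HERV loci and 0.05 for genes.
#'
#' @param results data.frame from [nb_wald_de()] (columns `log2fc`, `p`,
#'   optionally `q`).
#' @param fdr_threshold FDR cutoff.
#' @return The input with `q` and `status` columns; a summary list
#'   (`n_up`, `n_down`, `n_ns`) in `attr(, "summary")`.
#' @export
classify_de <- function(results, fdr_threshold = 0.2) {
  if (is.null(results$q)) results$q <- bh_adjust(results$p)
  results$status <- ifelse(results$q < fdr_threshold & results$log2fc > 0, "up",
                    ifelse(results$q < fdr_threshold & results$log2fc < 0, "down",
                           "ns"))
  attr(results, "summary") <- list(n_up = sum(results$status == "up"),
                                   n_down = sum(results$status == "down"),
                                   n_ns = sum(results$status == "ns"))
  results
}
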