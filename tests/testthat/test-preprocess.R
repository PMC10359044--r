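make_cm <- function(counts, condition = NULL, batch = NULL) {
  n <- ncol(counts)
  if (is.null(condition)) condition <- rep(c("control", "case"), length.out = n)
  if (is.null(batch)) batch <- rep("B1", n)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("F%03d", seq_len(nrow(counts)))
  count_matrix(counts, data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                                  condition = condition, batch = batch,
                                  stringsAsFactors = FALSE))
}

test_that("Y-chromosome removal applies to genes only", {
  counts <- matrix(5L, 5, 4)
  rownames(counts) <- c("G1", "G2", "G3", "HML2_1q1", "HML2_Yq1")
  m <- make_cm(counts)
  genes <- data.frame(gene_id = c("G1", "G2", "G3"),
                      chrom = c("chr1", "chrY", "Y"),
                      start = 0L, end = 10L, strand = "+",
                      stringsAsFactors = FALSE)
  expect_message(out <- drop_y_genes(m, genes), "absent")
  # G2 and G3 removed; the Y-located HERV locus is retained (gene rule only)
  expect_identical(rownames(out$counts), c("G1", "HML2_1q1", "HML2_Yq1"))
  expect_identical(out$counts, m$counts[c(1, 4, 5), ])

  no_y <- data.frame(gene_id = c("G1", "G2", "G3"), chrom = "chr1",
                     start = 0L, end = 10L, strand = "+")
  expect_identical(suppressMessages(drop_y_genes(m, no_y))$counts, m$counts)
})

test_that("median-of-ratios size factors match closed forms", {
  x <- matrix(c(4, 10, 20, 4, 10, 20), 3, 2)
  m <- make_cm(x)
  expect_equal(unname(size_factors(m)), c(1, 1))

  y <- matrix(c(4, 10, 20, 8, 20, 40), 3, 2)
  expect_equal(unname(size_factors(make_cm(y))), c(1 / sqrt(2), sqrt(2)))

  # the ratio to the per-feature geometric mean cancels a global rescaling,
  # so the factors are invariant when every sample is scaled by the same c
  expect_equal(unname(size_factors(make_cm(3 * y))), c(1 / sqrt(2), sqrt(2)))
  # scaling a single sample scales its ratios (and hence its factor) by c,
  # up to the c^(1/n) change it induces in the geometric-mean reference
  y2 <- y; y2[, 2] <- 4 * y2[, 2]
  expect_equal(unname(size_factors(make_cm(y2))),
               c(1 / sqrt(2), 4 * sqrt(2)) / 4^(1 / 2))

  allz <- matrix(c(0L, 5L, 5L, 0L), 2, 2)
  expect_error(size_factors(make_cm(allz)), "pseudo-reference")
})

test_that("batch adjustment is the identity for a single batch and guards confounding", {
  design <- make_design(4, seed = 1)
  sim <- simulate_counts(design, 50, frac_de = 0, seed = 2)
  expect_identical(batch_adjust(sim$matrix), sim$matrix)

  conf <- make_cm(matrix(rpois(40, 50), 5, 8),
                  condition = rep(c("control", "case"), each = 4),
                  batch = rep(c("B1", "B2"), each = 4))
  expect_error(batch_adjust(conf), "confound")
})

test_that("batch adjustment removes a planted shift and preserves support", {
  design <- make_design(10, n_batches = 2, seed = 3)
  sim <- simulate_counts(design, 400, frac_de = 0, dispersion = 0.005,
                         batch_log2_shift = 1, seed = 4,
                         baseline_range = c(300, 1000))
  adj <- batch_adjust(sim$matrix)
  expect_true(all(adj$counts >= 0))
  expect_true(all(adj$counts == round(adj$counts)))
  expect_identical(adj$samples, sim$matrix$samples)

  b <- sim$matrix$samples$batch
  ratio_before <- rowMeans(sim$matrix$counts[, b == "B2"]) /
    rowMeans(sim$matrix$counts[, b == "B1"])
  ratio_after <- rowMeans(adj$counts[, b == "B2"]) /
    rowMeans(adj$counts[, b == "B1"])
  # planted 2x (random sign) shifts collapse toward 1
  expect_gt(mean(abs(log2(ratio_before)) > 0.5), 0.9)
  expect_gt(mean(ratio_after > 0.9 & ratio_after < 1.1), 0.95)
})

test_that("batch adjustment preserves a planted condition effect", {
  design <- make_design(10, n_batches = 2, seed = 5)
  sim <- simulate_counts(design, 300, frac_de = 1, lfc_magnitude = 1,
                         dispersion = 0.05, batch_log2_shift = 1, seed = 6)
  adj <- batch_adjust(sim$matrix)
  case <- adj$samples$condition == "case"
  lfc <- log2(rowMeans(adj$counts[, case]) + 0.5) -
    log2(rowMeans(adj$counts[, !case]) + 0.5)
  med <- median(abs(lfc))
  expect_gt(med, 0.8)
  expect_lt(med, 1.2)
})

test_that("zero counts never map to negative counts", {
  design <- make_design(5, n_batches = 2, seed = 7)
  sim <- simulate_counts(design, 100, frac_de = 0, dispersion = 2,
                         batch_log2_shift = 1, seed = 8,
                         baseline_range = c(1, 10))
  adj <- batch_adjust(sim$matrix)
  expect_true(all(adj$counts >= 0))
  zero_feat <- rowSums(sim$matrix$counts) == 0
  if (any(zero_feat)) expect_true(all(adj$counts[zero_feat, ] == 0))
})

test_that("jaccard filter: bounds, trivial instance, and threshold contract", {
  # identical binary vectors give Jaccard 1 at any threshold; the argmax tie
  # resolves to the grid minimum and nothing is removed
  x <- matrix(100L, 20, 6)
  m <- make_cm(x)
  jf <- jaccard_filter(m)
  expect_equal(nrow(jf$filtered$counts), 20)
  expect_equal(jf$threshold, min(jf$curve$threshold))
  expect_true(all(jf$curve$mean_jaccard <= 1))

  expect_error(jaccard_filter(make_cm(matrix(0L, 3, 4))), "all-zero")

  # no feature whose minimum normalized count exceeds s* is ever removed
  set.seed(1)
  y <- matrix(rpois(600, 30) + 1L, 100, 6)
  mj <- jaccard_filter(make_cm(y))
  norm <- sweep(y, 2, size_factors(make_cm(y)), "/")
  always_above <- apply(norm, 1, min) > mj$threshold
  expect_true(all(rownames(y)[always_above] %in% rownames(mj$filtered$counts)))
})

test_that("jaccard filter separates informative from noise features", {
  set.seed(42)
  informative <- matrix(rpois(100 * 10, 100), 100, 10)
  noise <- matrix(rbinom(100 * 10, 1, 0.3), 100, 10)
  counts <- rbind(informative, noise)
  rownames(counts) <- c(sprintf("INF%03d", 1:100), sprintf("NOI%03d", 1:100))
  m <- count_matrix(counts, data.frame(
    sample_id = sprintf("S%02d", 1:10),
    condition = rep(c("control", "case"), each = 5),
    batch = "B1", stringsAsFactors = FALSE))
  jf <- jaccard_filter(m)
  kept <- rownames(jf$filtered$counts)
  expect_equal(sum(grepl("^INF", kept)), 100)
  expect_lte(sum(grepl("^NOI", kept)), 10)
})

test_that("vst follows its defining formula and preserves ordering", {
  x <- matrix(c(0L, 7L, 3L, 1L), 2, 2, dimnames = list(c("a", "b"), NULL))
  v <- vst(x, factors = c(1, 1))
  expect_equal(unname(v["a", 1]), 0)
  expect_equal(unname(v["b", 1]), 3)  # log2(7 + 1)
  expect_equal(v, log2(x + 1))
  # monotone within a sample
  set.seed(2)
  y <- matrix(rpois(50, 20), 10, 5,
              dimnames = list(sprintf("f%d", 1:10), NULL))
  vv <- vst(y, factors = rep(2, 5))
  for (j in 1:5) expect_equal(order(vv[, j]), order(y[, j]))
})

test_that("vst variance grows sublinearly with the mean", {
  design <- make_design(10, seed = 9)
  tiers <- c(20, 200, 2000)
  vratio <- sapply(tiers, function(mu) {
    sim <- simulate_counts(design, 200, frac_de = 0, dispersion = 0.1,
                           baseline_range = c(mu, mu), seed = 10)
    v <- vst(sim$matrix, factors = rep(1, 20))
    median(apply(v, 1, var))
  })
  # raw-count variance spans two orders of magnitude; transformed it is flat
  expect_lt(max(vratio) / min(vratio), 3)
})

test_that("PCA QC: degenerate geometry, duplication invariance, truncation", {
  # samples on a line through the centroid: PC1 carries all the variance
  base <- rnorm(30)
  x <- outer(base, c(-3, -1, 1, 3))
  p <- pca_qc(x, 1)
  expect_gt(p$variance_explained[1], 0.999)

  # full-rank data: variance fractions are non-increasing and sum to <= 1
  set.seed(31)
  xf <- matrix(rnorm(30 * 6), 30, 6)
  pf <- pca_qc(xf, 4)
  expect_true(all(diff(pf$variance_explained) <= 1e-12))
  expect_lte(sum(pf$variance_explained), 1 + 1e-12)

  # duplicating features scales scores by sqrt(2), directions unchanged
  p2 <- pca_qc(rbind(xf, xf), 4)
  expect_equal(abs(p2$scores) / sqrt(2), abs(pf$scores), tolerance = 1e-8)

  expect_warning(pca_qc(x, 4), "rank")
})

test_that("batch separation on PC1 collapses after adjustment", {
  design <- make_design(10, n_batches = 2, seed = 11)
  sim <- simulate_counts(design, 400, frac_de = 0, dispersion = 0.05,
                         batch_log2_shift = 1, seed = 12)
  b <- sim$matrix$samples$batch
  t_of <- function(m) {
    sc <- pca_qc(vst(m), 2)$scores[, 1]
    abs(t.test(sc[b == "B1"], sc[b == "B2"])$statistic)
  }
  t_before <- t_of(sim$matrix)
  t_after <- t_of(batch_adjust(sim$matrix))
  expect_lt(t_after, 0.5 * t_before)
})

test_that("the staged pipeline preserves sample metadata and order", {
  design <- make_design(6, n_batches = 2, seed = 13)
  sim <- simulate_counts(design, 150, frac_de = 0.1, batch_log2_shift = 0.5,
                         seed = 14)
  out <- preprocess_counts(sim$matrix)
  expect_identical(out$matrix$samples, sim$matrix$samples)
  expect_true(nrow(out$matrix$counts) <= 150)
  expect_false(is.na(out$jaccard_threshold))
})
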