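test_that("SAM loading matches records to overlapping loci with best-score reduction", {
  ann <- two_locus_annotation()
  # f1: two alignments in locus A (scores 50, 40), one in B (45)
  # f2: single alignment outside all loci
  recs <- data.frame(
    qname = c("f1", "f1", "f1", "f2"),
    flag = c(0L, 256L, 256L, 0L),
    rname = "chr1",
    pos = c(1101L, 1301L, 5101L, 9001L),
    cigar = "50M",
    score = c(50L, 40L, 45L, 30L),
    stringsAsFactors = FALSE
  )
  sam <- write_test_sam(recs, attr(ann, "chrom_lengths"))
  fam <- load_alignments(sam, ann)
  expect_setequal(fam$locus_ids, c("HML2_1q1", "MER101_1q2", "no_feature"))
  expect_equal(as.numeric(fam$score["f1", "HML2_1q1"]), 50)
  expect_equal(as.numeric(fam$score["f1", "MER101_1q2"]), 45)
  expect_equal(as.numeric(fam$score["f2", "no_feature"]), 30)
  expect_equal(as.numeric(fam$n_candidates[c("f1", "f2")]), c(2, 1))
})

test_that("SAM loading errors on missing score tags and warns on empty input", {
  ann <- two_locus_annotation()
  recs <- data.frame(qname = "f1", flag = 0L, rname = "chr1", pos = 1101L,
                     cigar = "50M", score = 50L, stringsAsFactors = FALSE)
  sam <- write_test_sam(recs, attr(ann, "chrom_lengths"), as_tag = FALSE)
  expect_error(load_alignments(sam, ann), "AS")

  empty <- write_test_sam(recs[0, ], attr(ann, "chrom_lengths"))
  expect_warning(fam <- load_alignments(empty, ann), "no mapped")
  expect_length(fam$fragment_ids, 0)
})

test_that("unmapped records are ignored", {
  ann <- two_locus_annotation()
  recs <- data.frame(
    qname = c("f1", "f3"),
    flag = c(0L, 4L),
    rname = c("chr1", "chr1"),
    pos = c(1101L, 1201L),
    cigar = "50M",
    score = c(50L, 10L),
    stringsAsFactors = FALSE
  )
  sam <- write_test_sam(recs, attr(ann, "chrom_lengths"))
  fam <- load_alignments(sam, ann)
  expect_identical(fam$fragment_ids, "f1")
})

test_that("single-candidate fragments get posterior 1 regardless of the prior", {
  entries <- data.frame(fragment = c("f1", "f2", "f2"),
                        locus = c("A", "A", "B"),
                        score = c(50, 50, 50))
  fam <- fragment_assignments(entries)
  for (tp in c(0, 100, 200000)) {
    res <- em_reassign(fam, em_config(theta_prior = tp))
    expect_equal(as.numeric(res$posterior["f1", "A"]), 1, tolerance = 1e-12)
  }
})

test_that("symmetric tied instance yields the symmetric solution in one pass", {
  entries <- data.frame(fragment = rep(c("f1", "f2"), each = 2),
                        locus = rep(c("A", "B"), 2),
                        score = 50)
  fam <- fragment_assignments(entries)
  res <- em_reassign(fam, em_config(theta_prior = 1))
  expect_equal(unname(res$pi), c(0.5, 0.5), tolerance = 1e-9)
  expect_true(all(abs(as.matrix(res$posterior) - 0.5) < 1e-9))
  expect_true(res$converged)

  # a single all-tied fragment converges immediately, not an error
  one <- fragment_assignments(data.frame(fragment = "f1", locus = c("A", "B"),
                                         score = c(40, 40)))
  r1 <- em_reassign(one, em_config(theta_prior = 2))
  expect_equal(r1$n_iter, 1)
  expect_true(r1$converged)
})

test_that("closed-form stationary point: 2 unique A, 1 unique B, 1 tied", {
  entries <- data.frame(
    fragment = c("f1", "f2", "f3", "f4", "f4"),
    locus = c("A", "A", "B", "A", "B"),
    score = 50
  )
  fam <- fragment_assignments(entries)
  res <- em_reassign(fam, em_config(theta_prior = 0, tol = 1e-12, max_iter = 2000))
  expect_equal(as.numeric(res$pi["A"]), 2 / 3, tolerance = 1e-3)
  expect_equal(as.numeric(res$posterior["f4", "A"]), 2 / 3, tolerance = 1e-3)
  # and the independent grid search lands on the same maximum
  L <- matrix(0, 4, 2, dimnames = list(c("f1", "f2", "f3", "f4"), c("A", "B")))
  L["f1", "A"] <- L["f2", "A"] <- L["f3", "B"] <- 1
  L["f4", ] <- 1
  expect_equal(grid_search_pi(L, theta = 0)[1], 2 / 3, tolerance = 2e-3)
})

test_that("EM agrees with dense grid search on random tiny instances", {
  thetas <- c(0, 0.5, 2)
  for (seed in 1:15) {
    inst <- random_em_instance(seed)
    theta_total <- thetas[1 + seed %% 3] * ncol(inst$L)
    res <- em_reassign(inst$fam,
                       em_config(theta_prior = theta_total, tol = 1e-12,
                                 max_iter = 5000))
    oracle <- grid_search_pi(inst$L, theta = theta_total / ncol(inst$L))
    expect_lt(max(abs(res$pi - oracle)), 5e-3,
              label = sprintf("seed %d max pi deviation", seed))
  }
})

test_that("penalized log-likelihood trace is non-decreasing (monotone EM)", {
  for (seed in 1:100) {
    inst <- random_em_instance(seed + 1000)
    res <- em_reassign(inst$fam, em_config(theta_prior = (seed %% 5) * 0.7,
                                           tol = 1e-10, max_iter = 300))
    expect_true(all(diff(res$objective_trace) > -1e-9),
                label = sprintf("seed %d monotonicity", seed))
    expect_equal(sum(res$pi), 1, tolerance = 1e-9)
    expect_true(all(abs(Matrix::rowSums(res$posterior) - 1) < 1e-9))
  }
})

test_that("posterior counting modes: best, fractional, unique, tie exclusion", {
  entries <- data.frame(
    fragment = c("f1", "f1", "f2", "f2", "f3"),
    locus = c("A", "B", "A", "B", "B"),
    score = c(60, 40, 55, 50, 50)
  )
  fam <- fragment_assignments(entries)
  res <- em_reassign(fam, em_config(theta_prior = 0, tol = 1e-10))

  frac <- counts_from_posterior(res, "fractional")
  expect_equal(sum(frac), 3, tolerance = 1e-9)
  expect_equal(unname(frac), unname(Matrix::colSums(res$posterior)))

  uniq <- counts_from_posterior(res, "unique")
  expect_equal(as.numeric(uniq[c("A", "B")]), c(0, 1))

  best <- counts_from_posterior(res, "best")
  expect_equal(sum(best) + length(attr(best, "ties")), 3)
  expect_error(counts_from_posterior(res, "nonsense"))

  # exact posterior tie -> excluded and reported
  tied <- fragment_assignments(data.frame(fragment = c("t1", "t1"),
                                          locus = c("A", "B"), score = 50))
  tres <- em_reassign(tied, em_config(theta_prior = 1))
  tbest <- counts_from_posterior(tres, "best")
  expect_equal(sum(tbest), 0)
  expect_identical(attr(tbest, "ties"), "t1")
})

test_that("hand-checked fractional counts", {
  # posteriors (A:.9,B:.1), (A:.6,B:.4), (B:1) -> A = 1.5, B = 1.5
  W <- Matrix::sparseMatrix(i = c(1, 1, 2, 2, 3), j = c(1, 2, 1, 2, 2),
                            x = c(0.9, 0.1, 0.6, 0.4, 1),
                            dimnames = list(c("f1", "f2", "f3"), c("A", "B")))
  res <- structure(list(posterior = W, n_candidates = c(2, 2, 1)),
                   class = "em_result")
  frac <- counts_from_posterior(res, "fractional")
  expect_equal(as.numeric(frac[c("A", "B")]), c(1.5, 1.5))
})

test_that("quantification recovers planted proportions from simulated fragments", {
  ann <- make_toy_annotation(n_loci = 20, n_genes = 0, n_chromosomes = 4,
                             frac_intragenic = 0, seed = 13)
  set.seed(17)
  pi_true <- prop.table(runif(20, 0.5, 2))
  names(pi_true) <- ann$loci$locus_id
  sim <- simulate_fragments(ann$loci, pi_true, n_fragments = 4000,
                            ambiguity_rate = 0.3, score_gap = 5, seed = 19)
  q <- quantify_loci(sim$sam, ann$loci, mode = "best",
                     config = em_config(theta_prior = 0))
  pi_hat <- q$result$pi[names(pi_true)]
  expect_lt(sum(abs(pi_hat - pi_true)), 0.08)
  expect_equal(q$report$n_fragments, 4000)

  # unique fragments always land on their sole (true) candidate
  uniq <- counts_from_posterior(q$result, "unique")
  truth_uniq <- table(sim$truth$true_locus[!sim$truth$ambiguous])
  expect_equal(as.numeric(uniq[names(truth_uniq)]), as.numeric(truth_uniq))
})
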