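# hervscope

Locus-specific expression analysis of human endogenous retroviruses (HERVs)
from bulk RNA-Seq, in R.

HERV loci within a family are so similar in sequence that a large share of
RNA-Seq fragments align acceptably to several loci at once. Counting only
uniquely mapped reads systematically undercounts repetitive loci and biases
locus-to-locus comparisons, which is fatal for any analysis that needs
*locus-level* resolution — for instance asking which individual proviral
insertions are dysregulated in disease, which genes sit next to them, and
which loci track immune gene expression. hervscope is written for
transcriptomics analysts who need that resolution: it resolves the
multi-mapping ambiguity probabilistically and carries locus-level counts
through a complete, testable differential-expression and association
pipeline.

## The model at the core

Fragment reassignment is a Bayesian mixture over loci fit by
expectation-maximization. With mixture weights $\pi$ on the $K$ candidate
loci (plus a reserved `no_feature` component) and alignment scores $s_{fk}$
(SAM `AS` tag, higher is better), fragment $f$'s candidate likelihood is

$$L(f,k) = \exp(s_{fk}/\sigma),$$

and the EM maximizes the Dirichlet-penalized log-likelihood

$$\ell(\pi) = \sum_f \log \sum_k \pi_k\, L(f,k) \;+\; \sum_k \theta \log \pi_k,
\qquad \theta = \texttt{theta\_prior}/K,$$

via posteriors $w_{fk} \propto \pi_k L(f,k)$ and MAP updates
$\pi_k \propto \sum_f w_{fk} + \theta$. The objective is concave, the EM
trace provably non-decreasing, and the result is checked in the test suite
against dense grid-search maximization. Posteriors become locus counts in
three modes: `best` (argmax, exact ties excluded deterministically),
`fractional`, and `unique`.

Around that core the package provides, as separately callable stages:

* **Synthetic data** — toy annotations (BED/GTF), multi-mapped SAM with
  recorded fragment-origin truth, NB count matrices with planted fold
  changes and per-feature batch shifts, GMT pathway sets. Every generator is
  a pure function of its seed.
* **Preprocessing** — Y-chromosome gene removal, NB quantile-matching batch
  adjustment, adaptive Jaccard-index low-expression filtering,
  median-of-ratios size factors, VST, PCA QC.
* **Differential expression** — per-feature NB Wald tests with
  moment/decile-shrunk dispersions, BH FDR, up/down/ns classification.
* **HERV summaries** — locus-name parsing (`MER101_6q27d` → family MER101,
  band 6q27, copy d), family over-representation ratios among DE loci,
  per-chromosome DE distributions.
* **Proximal enrichment** — closest upstream/downstream/intersecting gene
  mapping (validated against a brute-force oracle), DE-coefficient transfer,
  Wilcoxon rank-sum pathway enrichment over GMT sets.
* **Association** — locus- and family-level Pearson correlation with a
  target gene or a summed interferon-signature score; gene×HERV association
  ranking by squared-correlation importance.

## Worked example

```r
library(hervscope)

# 1. toy annotation: 20 HERV loci among 30 genes on 3 chromosomes
ann <- make_toy_annotation(n_loci = 20, n_genes = 30, n_chromosomes = 3,
                           frac_intragenic = 0.25, seed = 7)

# 2. simulate 5,000 fragments, 30% multi-mapped, and reassign them by EM
pi_true <- setNames(prop.table(rep(c(3, 1), 10)), ann$loci$locus_id)
sim <- simulate_fragments(ann$loci, pi_true, n_fragments = 5000,
                          ambiguity_rate = 0.3, score_gap = 5, seed = 8)
q <- quantify_loci(sim$sam, ann$loci, mode = "best",
                   config = em_config(theta_prior = 0))
str(q$report)
#> List of 7
#>  $ n_fragments    : int 5000
#>  $ n_unique       : int 3483
#>  $ n_ambiguous    : int 1517
#>  $ n_no_feature   : int 0
#>  $ n_ties_excluded: int 0
#>  $ n_iter         : num 8
#>  $ converged      : logi TRUE
sum(abs(q$result$pi[names(pi_true)] - pi_true))   # L1 error vs truth
#> 0.047
head(q$counts, 3)
#>      locus_id family count
#> 1    HML2_1p1   HML2   430
#> 2   HERVH_1p1  HERVH    99
#> 3 MER101_1p2b MER101   382

# 3. a 2-condition, 2-batch count matrix with planted effects
design <- make_design(8, n_batches = 2, seed = 9)
cm <- simulate_counts(design, n_features = 400, frac_de = 0.1,
                      lfc_magnitude = 1.5, dispersion = 0.1,
                      batch_log2_shift = 1, seed = 10)

# 4. preprocess (batch adjustment + adaptive filter), then DE at FDR < 0.05
prep <- preprocess_counts(cm$matrix)
de <- classify_de(nb_wald_de(prep$matrix), fdr_threshold = 0.05)
attr(de, "summary")
#> $n_up
#> [1] 21
#> $n_down
#> [1] 20
#> $n_ns
#> [1] 359
hits <- de$feature_id[de$status != "ns"]
length(intersect(hits, cm$truth$true_de_set))     # of 40 planted DE features
#> 40
```

Reading the numbers: 1,517 of 5,000 simulated fragments were ambiguous, yet
the EM recovers the 20 planted locus proportions to a total L1 error of
0.047 and the run converges in 8 iterations with no tie exclusions. On the
count side, all 40 planted differentially expressed features are recovered
at FDR < 0.05 (41 calls, one false positive), after batch adjustment of a
planted 2× per-feature batch shift. Downstream, `family_enrichment()`,
`map_proximal_genes()` + `pathway_enrichment()`, and
`locus_target_correlations()` take these outputs directly; see the methods
vignette (`vignettes/hervscope-methods.Rmd`) for the models and conventions
behind every stage.

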