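---
title: "hervscope: models and methods for locus-level HERV expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hervscope: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hervscope)
```

## The problem

Human endogenous retroviruses (HERVs) are remnants of ancient retroviral
integrations that make up a substantial fraction of the human genome. Many
retain transcriptional activity, and locus-specific dysregulation has been
implicated in neurodegenerative and inflammatory disease. Quantifying HERV
expression from bulk RNA-Seq is hard for one structural reason: proviral
loci within a family are highly similar in sequence, so a large share of
fragments align acceptably to several loci. Summing only uniquely mapped
reads undercounts systematically and biases comparisons between loci.

hervscope implements a complete locus-level analysis chain around this
problem: probabilistic reassignment of multi-mapped fragments to individual
loci, count preprocessing (batch adjustment, adaptive filtering), negative
binomial differential expression, family-level and positional summaries of
the differentially expressed loci, transfer of DE coefficients to proximal
genes with rank-based pathway enrichment, and locus-level correlation with
immune gene signatures. A synthetic-data module generates every input with
recorded ground truth, so each stage is validated by parameter recovery
rather than by eyeballing.

## Fragment reassignment: mixture model and EM

Let $K$ be the number of candidate loci (plus a reserved `no_feature`
component for alignments that overlap no annotated locus) and $\pi$ a
probability vector on those components. Fragment $f$ is modeled as arising
from locus $k$ with prior probability $\pi_k$; conditional on $k$, its
alignment evidence has likelihood

$$L(f,k) = \exp\left(\frac{s_{fk}}{\sigma}\right),$$

where $s_{fk}$ is the best alignment score of $f$ against locus $k$ (the
`AS` tag; higher is better) and $\sigma$ is `score_scale`. Non-candidate
loci have $L(f,k)=0$. Any positive monotone map of scores preserves which
locus maximizes the likelihood; the exponential is chosen because it keeps
the EM algebra in standard exponential-family form, and $\sigma$ (default
10) controls how strongly score gaps are believed: a decoy alignment scoring
$\Delta$ below the best one carries relative weight $e^{-\Delta/\sigma}$.
Scores are shifted per fragment by their row maximum before exponentiation,
which cannot overflow and changes neither posteriors nor the argmax of the
objective.

The penalized log-likelihood is

$$\ell(\pi) = \sum_f \log \sum_k \pi_k L(f,k) + \sum_k \theta \log \pi_k,
\qquad \theta = \frac{\texttt{theta\_prior}}{K},$$

a symmetric Dirichlet MAP term. The E-step computes posteriors
$w_{fk} \propto \pi_k L(f,k)$; the M-step updates
$\pi_k \propto \sum_f w_{fk} + \theta$. Because $\ell$ is concave on the
simplex (log of a linear function plus a concave penalty), the EM trace is
non-decreasing and the maximizer is unique; the test suite verifies both
properties, the latter against a dense grid search oracle on small
instances. Convergence is declared when $\max_k |\Delta\pi_k| <$ `tol`
(default `1e-6`) or after `max_iter` (default 200) iterations.

**Prior scale.** The default `theta_prior = 200000` is a total pseudo-count
calibrated to production libraries of tens of millions of fragments, where
it acts as a mild regularizer. The prior's influence scales as
$\theta / (n + \texttt{theta\_prior})$, so on a toy instance of $10^4$
fragments the same value pins $\pi$ near uniform by construction. All
parameter-recovery analyses in this package therefore run with
`theta_prior = 0`; the default is kept for fidelity to production-scale use
and is always overridable.

**Counting modes.** `best` assigns each fragment to its argmax-posterior
locus and *excludes* fragments whose top posteriors tie exactly (reported in
a tie ledger) — a deterministic rule that needs no random tie-breaking.
`fractional` sums posterior weights; `unique` counts single-candidate
fragments only. Unique fragments are assigned to their sole candidate under
every mode.

**Overlap rule.** An alignment is a candidate for every locus its reference
interval overlaps by at least one base, all with the same score; strand is
ignored by default (`stranded = TRUE` restricts candidates to the
alignment's strand). Coordinates are 0-based half-open internally, 1-based
closed on GTF output and in SAM, 0-based half-open in BED — the native
convention of each format.

## Preprocessing

The default order is Y-gene removal, batch adjustment, adaptive filtering;
each stage is individually callable.

**Y-chromosome removal** applies to annotated genes only: HERV loci are
retained even when located on Y, because the rule exists to remove
sex-driven *gene* variance, and unannotated features are deliberately left
untouched (and logged).

**Size factors** are DESeq2-style median-of-ratios: each sample's factor is
the median, over features nonzero in all samples, of the count divided by
the feature's geometric mean. Note the formula is invariant to a global
rescaling of all counts (the geometric-mean reference rescales too) — the
relevant scale property is that scaling one sample scales its factor.

**Batch adjustment** models each feature's counts as negative binomial with
batch- and condition-specific means. On depth-normalized counts it
estimates per-(batch, condition) means, derives a multiplicative batch
factor per feature as the geometric deviation of a batch's means from the
condition-wise pooled means, and maps each observed count through the CDF of
its batch-specific NB to a mid-quantile and back through the inverse CDF of
the pooled, batch-free NB. This preserves the condition effect (the target
retains condition-specific means), keeps counts integral and non-negative,
and maps zeros to zeros or small counts. Dispersions are per-feature method
of moments pooled across (batch, condition) groups with a floor of `1e-4`.
Internally the depth normalization uses geometric mean-of-log-ratios rather
than the median: when batch shifts have per-feature random signs the
per-feature ratio distribution is bimodal and a median snaps to one mode,
leaving a residual global offset, while the geometric mean stays nearly
unbiased. Adjustment refuses to run when some batch lacks one condition
(batch and condition would be non-identifiable) and is the identity for a
single batch.

**Adaptive Jaccard filter.** Low, scattered counts are uninformative and
inflate multiple-testing burdens. Counts are normalized by size factors and
binarized at each threshold of a grid (the distinct positive normalized
values up to their 95th percentile, thinned to at most 200 points); for
every within-condition sample pair the Jaccard index of the binary vectors
is computed, and the threshold maximizing the mean index is chosen. Features
exceeding the chosen threshold in at least one sample are retained. Two
conventions matter: the Jaccard index of two all-zero vectors is defined as
0, so the degenerate "filter everything" threshold can never win; and argmax
ties resolve to the smallest threshold, retaining more features.

**VST.** $\log_2(\text{count}/\text{factor} + 1)$: monotone, zero maps to
zero, and replicate variance grows sublinearly with the mean on NB data
(checked across mean tiers in the tests). Correlation, PCA and association
ranking all operate on this scale.

**PCA QC** centers features and computes sample scores by SVD, reporting
variance-explained fractions. The package's batch-adjustment validation
quantifies the usual before/after picture: the two-sample $t$ statistic of
PC1 scores between batches must drop by at least half after adjustment (in
practice it collapses by orders of magnitude on the simulated conditions).

## Differential expression

Per feature, a negative binomial GLM with log link, a single
condition coefficient (case vs control) and $\log(\text{size factor})$
offsets. The full empirical-Bayes dispersion machinery of the established
DE packages is intentionally out of scope; dispersion is estimated by
method of moments on normalized counts, $\hat\alpha_i = \max((s_i^2 -
\bar\mu_i)/\bar\mu_i^2,\ 10^{-8})$, then shrunk 50/50 toward the mean
estimate of the feature's expression decile. Size factors are rescaled to
geometric mean 1 before estimation so results are invariant to a global
factor rescaling. The simplified estimator is validated behaviorally: on
null simulations (1,000 features, 10+10 samples, dispersion 0.1) the
rejection rate at $p<0.05$ must fall in $[0.03, 0.07]$, and planted
$\log_2$ fold changes of 1 must be recovered with median in $[0.8, 1.2]$.

The Wald statistic is coefficient over standard error with a two-sided
normal $p$; coefficients are fit on the natural-log scale and reported as
$\log_2$. BH adjustment is the standard step-up (delegated to `p.adjust`,
and checked exactly against a brute-force implementation of the step-up
definition in the tests). Classification uses strict inequality — a q-value
exactly at the threshold is not significant — with conventional defaults of
0.2 for HERV loci and 0.05 for genes, both exposed.

## Family and positional summaries

Locus names follow the `FAMILY_band[letter]` convention (`MER101_6q27d`:
family MER101, cytoband 6q27, copy d). Family membership comes from the
annotation's `family` field, falling back to name parsing.

Family over-representation is the descriptive ratio
$\text{freq}_{DE}/\text{freq}_{db}$ per family. Under proportional sampling
every ratio is 1, so 1 is the algebraically consistent expected value and is
returned as such; because some displays use the unnormalized count ratio
$\text{total}_{db}/\text{total}_{DE}$ as a reference line instead, that
number is also attached separately (`db_over_de`) rather than silently
conflated — the two only coincide when $\text{freq}$ is read as a count. An
optional per-family hypergeometric test (BH-adjusted) is available behind a
flag; the primary output is descriptive, matching field practice. The
per-chromosome DE/database table is emitted in a form suitable for circular
genome plots; rendering is out of scope.

## Proximal genes and pathway enrichment

HERVs are hypothesized to act on nearby genes through their promoter-capable
LTRs, so DE coefficients are transferred to genomic neighbors. Upstream and
downstream are *genomic* (left/right of the locus), not
transcript-strand-relative, because flank distance — not promoter
directionality — is the modeled quantity; a `stranded` mode flips flanks for
minus-strand loci for users who want transcript-relative orientation.
Distances are between interval ends; adjacency (distance 0, non-overlapping)
is flanking, not intersecting; ties break toward the smaller gene id. The
implementation is validated by exact agreement with a brute-force all-pairs
scan on random instances.

Only DE loci transfer their coefficients. A gene hit by several DE HERVs
keeps the score of largest absolute value (the strongest signal; `mean` is
available), and the collision is logged. Pathway enrichment is a two-sample
Wilcoxon rank-sum of member vs non-member scores over the scored universe —
the member-vs-nonmember framing is the defensible reading of rank-based
"scores against all ranks" enrichment — with exact enumeration when the
universe has at most 10 genes without ties and a tie-corrected normal
approximation otherwise, two-sided, BH-adjusted across tested pathways.
Pathways with fewer than `min_size` (default 3) scored members, or spanning
the whole universe, are skipped and reported. Being rank-based, the
p-values are invariant to strictly monotone transforms of the scores.

## Correlation analyses

Locus-level association with an immune target (a TLR8-style receptor
transcript, or the per-sample *sum* of an interferon-stimulated-gene
signature) uses Pearson correlation with the $t$-based p-value on $n-2$
degrees of freedom; zero-variance profiles yield a flagged record, never a
silent `NaN`. Per-locus results carry BH q-values, with a summary counting
significant loci and the positive fraction among them. Significance defaults
to adjusted q at $\alpha = 0.05$; raw-p mode is exposed since either
convention appears in practice. Family-level correlation sums the family's
loci first — the package's dilution analyses demonstrate why locus-level
resolution matters: when 2 of 30 family members track the target, the family
sum's p-value exceeds the best locus-level p-value in ≥90% of simulations.

Gene–HERV association ranking scores all gene × HERV pairs by squared
Pearson correlation of their VST profiles — a deterministic,
dependency-free importance that preserves the contract (rank cross-type
pairs by association strength; never emit gene–gene or HERV–HERV pairs) —
with a plug-in interface for alternative importance functions such as
tree-ensemble importances. Ties break lexicographically on the pair id.

## The synthetic-data generator

The generator is the package's study design, not a tuning knob; its
defaults are the simulated study conditions.

* **Annotation** (`make_toy_annotation`): up to 5 chromosomes of 1 Mb;
  non-overlapping genes of 2–8 kb separated by 1.5–5 kb gaps; loci of
  0.3–1.2 kb, a configurable fraction placed inside gene bodies and the rest
  in intergenic space so flanks are well defined; family labels drawn from a
  skewed weight vector mirroring the strongly unequal family sizes of real
  proviral databases; names follow the `FAMILY_band[letter]` convention.
* **Fragments** (`simulate_fragments`): single-end, one record per
  candidate locus, true locus drawn from a supplied simplex, reads placed
  uniformly within the locus. With probability `ambiguity_rate` a fragment
  gains 1–3 decoy alignments on other loci whose score deficit is
  Poisson(`score_gap`) below the true score (`score_gap = 0` gives exact
  ties); integer deficits match integer `AS` tags. Truth tables record each
  fragment's origin.
* **Counts** (`simulate_counts`): NB counts with log-uniform baselines,
  planted random-sign $\log_2$ fold changes on a `frac_de` fraction, and
  per-feature random-sign multiplicative batch shifts
  ($2^{\pm\text{shift}}$) in non-reference batches. The random signs matter:
  a shift uniform across features is absorbed entirely by depth
  normalization and would leave nothing for batch adjustment or PCA to
  detect; per-feature signs create genuine multivariate batch structure, as
  recorded feature-by-feature in the truth's `batch_factor`.
* **Pathways** (`make_pathway_db`): named gene sets sampled without
  replacement within a set, round-tripping through GMT.

All generators save and restore the caller's RNG state and are pure
functions of their arguments including the seed (the fragment simulator's
SAM output is byte-identical across runs).

What the generator does *not* emulate — read sequences and errors,
splicing, paired-end structure, positional coverage bias, correlated
biological covariates, and the long-tailed library-size and dispersion
heterogeneity of real cohorts. Passing recovery tests on these conditions
demonstrates that the estimators are correct and calibrated under their
stated models; it does not certify performance on real tissue data, where
model misspecification (especially dispersion heterogeneity and residual
confounding) dominates.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly rather than by accident: empty SAM
input warns and returns an empty matrix; missing `AS` tags are an error
naming the tag; all-zero features get $p = 1$ and zero fold change, flagged;
zero-variance correlation inputs are flagged records; confounded batch
designs are refused with the confounding named. EM likelihoods are
row-max-shifted before exponentiation; a non-finite likelihood raises an
error suggesting a larger `score_scale`.

Validation problem sizes were chosen so the full suite runs in well under
fifteen minutes on one CPU while keeping every statistical check adequately
powered: 10,000 fragments over 20 loci for proportion recovery (L1 error
below 0.05), 1,000 features at 10+10 samples for DE calibration, 500
features for batch adjustment, 100-seed replications for the dilution and
chi-square properties, and dense grid searches at step $10^{-3}$ on
instances of at most 3 loci and 5 fragments for the EM oracle.

## Known limitations

* The dispersion estimator is deliberately simpler than full
  empirical-Bayes shrinkage; it is calibrated at the simulated sample sizes
  but will be less efficient than the established DE packages at very small
  $n$ or with strong dispersion trends.
* Batch adjustment assumes multiplicative batch effects on the mean and a
  shared dispersion across batches per feature; batch-specific dispersion
  changes are normalized only through the quantile map.
* The EM operates on alignment scores as given; it cannot rescue fragments
  whose true locus was never among the reported alignments.
* Squared Pearson importance captures linear association only; nonlinear
  gene–HERV relationships need a plug-in importance function.
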