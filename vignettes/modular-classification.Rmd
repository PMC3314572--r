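---
title: "Module-based discriminant analysis of expression data: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module-based discriminant analysis of expression data: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modlda)
```

This vignette is the package's own account of the statistics it implements:
the model and its assumptions, the tunable parameters and their defaults,
the numerical conventions, what the synthetic-data generator does and does
not emulate, and the known limitations — including one structural property
of the module-search criterion that a user should understand before relying
on discovered modules.

## Model and assumptions

Expression profiles $x_j \in \mathbb{R}^p$ (log-scale values; any
preprocessing such as RMA or log-ratio transformation is the caller's
responsibility) from class $k \in \{A, B\}$ are modelled as
$N(\mu_k, \Sigma)$ with a shared covariance. The defining assumption is that
$\Sigma$ is block-diagonal over $C$ disjoint gene modules, so the LDA
discriminant decomposes into a sum of small per-module quadratic forms:

$$
LP(x) = \sum_{c=1}^{C}\Big(x_c - \tfrac{1}{2}(\hat\mu_{Ac} +
\hat\mu_{Bc})\Big)^{\!\top} \hat\Sigma_c^{-1}\, (\hat\mu_{Ac} - \hat\mu_{Bc}),
$$

with assignment to class A iff $LP \ge \log(n_B/n_A)$. Because the rule is
asymmetric in A and B, the mapping of class names onto A/B is explicit and
stable: lexicographically first name → A unless overridden
(`expression_dataset(..., class_a = )`). Two limiting cases anchor the
implementation and are enforced by tests: one all-gene module without
shrinkage (and $n > p$) reproduces classical full LDA; $p$ singleton modules
reproduce DLDA exactly.

### Covariance estimation within a block

Each block uses the pooled estimate
$\hat\Sigma_c = \{(n_A-1)S_{Ac} + (n_B-1)S_{Bc}\}/(n_A+n_B-2)$. By default a
stabilising shrinkage replaces every off-diagonal entry by
$\hat\sigma_i\hat\sigma_{i'}\hat r_c$, where $\hat\sigma_i^2$ is taken from
the diagonal of $\hat\Sigma_c$ (one reasonable reading; a separately
computed per-gene estimate would differ only in degrees-of-freedom
conventions) and $\hat r_c$ is the median of the block's pairwise pooled
correlations — computed from within-class-centered data, consistent with the
pooled $\hat\Sigma_c$ itself. With an even number of gene pairs the median
averages the two central values (R's default). The switch
`mlda_fit(..., shrink = FALSE)` disables shrinkage, which is also what makes
the exact full-LDA reduction attainable.

Blocks are inverted through the SVD; singular values below
`rel_tol = 1e-8` times the largest are zeroed and their reciprocals set to
zero, giving the Moore–Penrose pseudo-inverse whenever a block has more
genes than samples. The tolerance is relative, so rescaling the data leaves
the decision unchanged; `1e-8` sits well above double-precision noise and
well below any plausible genuine eigenvalue of a covariance block at these
sizes.

## Module discovery

The co-expression network is the gene–gene Pearson correlation matrix. Its
default mode centers each gene **within its class** before correlating: a
pure mean-shift between classes would otherwise register as co-expression
between any two differential genes, and the pooled covariance the classifier
uses is also a within-class quantity. The plain all-sample correlation is
available as `mode = "overall"` for comparison.

For a seed gene $i^*$ and cutoff $r$, the candidate module is
$C_r(i^*) = \{s : |\mathrm{corr}(x_{i^*}, x_s)| \ge r\}$; the chosen cutoff
maximises the average $|T|$ over the candidate set. The grid of cutoffs
defaults to $0.50, 0.55, \ldots, 0.95$ — a coarse scan that keeps the search
cheap; it is configurable. Two determinism conventions: ties on the average
break toward the **largest** cutoff (the smallest, most parsimonious
module), and the seed-ranking itself breaks $|T|$ ties by gene order.
Disjointness — required for a block-diagonal covariance — is imposed by
processing seeds in rank order and letting earlier (stronger) seeds claim
genes first; later searches run on the unclaimed remainder.

### A structural property the user should know

The candidate set always contains the seed, so the average $|T|$ of any
non-singleton candidate is a weighted mix of the seed's statistic and its
neighbours'. A seed that is the strongest gene among its candidates can
therefore never gain from adding members: the maximiser is the singleton
$\{i^*\}$, and the largest-cutoff tie rule seals even exact ties. Since
seeds are by construction the top-ranked genes, and rank-order
disjointification removes earlier modules' genes from later searches, **the
discovered module set degenerates to singletons whenever the seed is a local
$|T|$ maximum — which top-$m$ seed selection guarantees**. Modules grow only
when a seed's neighbourhood contains a *higher*-scoring gene, which can
happen for externally supplied seeds (e.g. a known pathway anchor) but not
for seeds taken from the top of the ranking.

Two consequences. First, in the automatic pipeline MLDA's behaviour
coincides with DLDA on the selected seeds, and MPCLR reduces to logistic
regression on standardised seed genes; the full block machinery is exercised
by supplying explicit modules via `module_set_from_list()` (known pathways,
planted blocks, external clusterings). Second, planted-block recovery by the
automatic search is structurally limited: on data with five planted blocks
of sizes 5–20 the mean Jaccard overlap between discovered modules and true
blocks equals the mean inverse block size ($\approx 0.10$), a deterministic
consequence of the singleton property, not a sampling artefact. The test
suite and `scripts/acceptance.R` measure and report this value as-is rather
than quietly redefining the search rule.

## MPCLR

Stage two of the alternative classifier standardises each module's genes to
zero mean and unit variance on the training samples (the stored constants
are reused verbatim at prediction time), takes the SVD of the $n \times p_c$
matrix, and uses the first right singular vector as loadings. SVD signs are
arbitrary, so the largest-magnitude loading is forced positive; the logistic
stage would absorb either sign, but determinism requires a convention. Stage
three fits $\mathrm{logit}\, p_j = \beta_0 + \sum_c \beta_c PC1_{cj}$ with
$Y = 1$ for class A, by IRLS (`stats::glm.fit`, binomial family, iteration
cap 100). Complete separation — common when a module carries a strong signal
— leaves the likelihood without a finite maximiser; the fit stops at the
iteration cap, the model records `separation = TRUE`, and predictions remain
well defined. No penalisation is added, keeping the plain model. The
classification cutoff is $p \ge 0.5$ → class A, the natural symmetric
choice; boundary cases go to A, mirroring the MLDA rule.

## Baselines

DLDA and DQDA use per-gene pooled and per-class variances respectively; DQDA
includes the $\log(n_k/n)$ prior term so that unequal class sizes are
handled consistently with MLDA's threshold. 1NN uses Euclidean distance on
the selected genes with index-order tie-breaking. In cross-validation the
baselines take the top-$m$ seed genes as their feature set, so every method
sees the same selection pressure.

## Cross-validation protocol

`run_cv()` performs repeats × k-fold CV (defaults 10 × 10). Folds are
stratified by class — the fold counts of each class differ by at most one,
and a load-balancing assignment keeps global fold sizes within one of each
other (so $k = n$ degenerates to leave-one-out); unstratified splits are
available by flag. Everything — statistics, seed ranking, correlation
matrix, module search, classifier — is refit inside each training fold;
the held-out fold only ever meets the fitted model. Error is computed per
repeat (each sample predicted exactly once) and the mean over repeats is
reported. A classifier failure inside any fold aborts the run with the
repeat and fold named; silently skipping failed folds would bias the
average. The entire result, including fold assignments and the per-sample
prediction log, is reproducible bit-for-bit from the `seed` argument.

## Synthetic data

`simulate_expression()` draws each class from a multivariate normal with
unit-variance compound-symmetry blocks: a block of size $s$ with parameter
$\rho$ is generated as $\sqrt{\rho}\,f + \sqrt{1-\rho}\,e$ with a shared
factor $f$, giving pairwise correlation exactly $\rho$; blocks are mutually
independent and background genes are white noise. Class separation adds
$\delta$ (in gene-sd units) to each block's seed gene in group A — by
default only the seed, so that any module recovery must come from the
correlation structure rather than from shared differential expression;
`shift = "all"` shifts whole blocks. Default block parameters used across
the tests (sizes roughly 5–20, $\rho = 0.8$) sit inside the range typical of
tightly co-expressed modules in microarray data, where observed within-module
average correlations cluster around 0.65–0.85 and modules span a few to a
few dozen genes. The generator does **not** emulate probe-level noise, batch
effects, heavy-tailed expression, or missingness — so green tests certify
the estimators and the protocol, not robustness to those artefacts.

Study sizes were chosen to keep every check fast while leaving no
qualitative behaviour untested: $n = 100$, $p = 80{-}100$ with five planted
blocks for the end-to-end runs; 10 × 10-fold CV; 20 simulation replicates
for recovery; toy instances of 3–10 genes for the exhaustive module-search
oracle. The label-permutation null is averaged over three permutations
because a single permuted split of $n = 100$ has a Monte-Carlo spread of
several error-rate points; three tighten the band without changing the
expectation.

## Numerical conventions, degenerate inputs

* Genes with zero pooled variance get non-finite statistics, are excluded
  from ranking and from the network (with warnings naming them); inside a
  fitted block they raise an error instead, since upstream filtering should
  have removed them.
* The SAM fudge constant defaults to the median of the gene-wise standard
  errors; a fixed value or another percentile can be supplied. $s_0 = 0$
  reproduces the plain t statistic exactly.
* Boundary decisions ($LP$ exactly at threshold, $p$ exactly 0.5) go to
  class A.
* Model files store doubles as 17-significant-digit strings inside JSON, the
  shortest representation guaranteed to round-trip IEEE doubles, so a
  reloaded model re-predicts bit-identically; files are versioned and
  truncation or version mismatch raises an explicit error.
* All simulation and CV randomness flows through a single seed argument and
  restores the caller's RNG state afterwards.

## Known limitations

* Strictly two-class; no multi-class extension.
* The module-search degeneracy described above: automatic top-$m$ seeding
  yields singleton modules, so the block-covariance advantage of MLDA over
  DLDA materialises only with externally supplied module structure.
* Modules are hard partitions; no overlapping or soft assignments.
* The compound-symmetry shrinkage target is aggressive for modules whose
  true correlation structure is heterogeneous.
* No handling of missing values by design — inputs are validated complete.
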