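---
title: "Models and methods: linking protein divergence to ovariole-number evolution"
author: "ovarioleEvo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovarioleEvo)
options(ovarioleEvo.verbose = FALSE)
```

# The scientific question

Ovariole number -- the count of egg-producing tubes per female ovary -- is
one of the fastest-diverging reproductive traits in *Drosophila*: within the
*melanogaster* subgroup alone it ranges from about 17 (*D. sechellia*) to
about 39 (*D. melanogaster*) per female. This package implements a
multilayered molecular-evolution analysis that asks whether protein-coding
genes with experimentally supported roles in ovariole formation (signaling
genes from RNAi screens, genes upregulated in larval-ovary somatic cells in
bulk and single-cell RNA-seq) show elevated rates of protein evolution
(dN/dS), branch-specific positive selection, narrow expression breadth
(high tau), and -- through phylogenetic regression -- whether their
per-branch dN/dS predicts ovariole number per species.

# The codon substitution engine

## Model

Sequence evolution is modelled on the 61 sense codons of the universal code
(stop codons are excluded from the state space). The instantaneous rate
from codon $i$ to codon $j$ follows the Goldman--Yang parameterisation:

$$
q_{ij} =
\begin{cases}
0 & \text{more than one nucleotide differs}\\
\pi_j & \text{synonymous transversion}\\
\kappa \pi_j & \text{synonymous transition}\\
\omega \pi_j & \text{nonsynonymous transversion}\\
\kappa \omega \pi_j & \text{nonsynonymous transition,}
\end{cases}
$$

with $\kappa$ the transition/transversion rate ratio, $\omega =$ dN/dS, and
$\pi_j$ the equilibrium frequency of the target codon. Each branch's matrix
is scaled so that branch lengths are measured in expected substitutions per
codon. Codon frequencies are equal ($1/61$) by default; the empirical F3x4
estimator (`f3x4Freqs()`) is available as an option. The default is a
deliberate, documented choice -- the corresponding setting used to produce
the published genome-wide values is not recorded anywhere, which is one
reason those per-gene numbers are treated as inputs rather than as
reproduction targets (see *Limitations*).

Likelihoods are computed by Felsenstein pruning over compressed codon site
patterns, with transition probabilities obtained from the eigendecomposition
of the symmetrised rate matrix. The model is time-reversible, so fits
operate on the unrooted tree (`fitM0()` and `fitFreeRatio()` unroot rooted
input automatically; the placement of a root is not identifiable and is
only meaningful for the Brownian-motion covariance used in regression).

## Fitted models

* **M0**: one shared $\omega$ for all branches and sites -- the gene-wide
  rate of protein divergence used by all genome-median screens.
* **Free-ratio**: an independent $\omega$ per branch. Each branch's
  substitution flux is decomposed into dN and dS by dividing the
  nonsynonymous and synonymous components by the site proportions of the
  same model at $\omega = 1$; by construction dN/dS equals the branch
  $\omega$ whenever both are finite.
* **Branch-site model A**: four site classes -- 0 (purifying,
  $0 < \omega_0 < 1$ everywhere), 1 (neutral), 2a and 2b (foreground
  $\omega_2 \ge 1$, background $\omega_0$ or 1) -- on a designated
  foreground branch. The test statistic is $2\Delta\ell$ between model A
  and its null ($\omega_2 = 1$), referred to the upper tail of
  $\chi^2_1$. This is deliberately the plain 1-df convention (not the
  50:50 boundary mixture); it is conservative, which the type-I
  calibration study below confirms. No per-site empirical-Bayes
  identification is computed, and no multiple-testing correction is
  applied across genes or branches -- both choices mirror the screening
  character of the analysis.

## Sentinel conventions

Per-branch estimates are reported with the rate-table sentinel dialect:

* `GT1` (printed `">1"`): dS below the low-divergence threshold while dN is
  above it -- the ratio diverges and the branch is reported simply as
  dN/dS > 1, inferring positive selection;
* `LOWDIV` (printed `"-"`): both dN and dS below the threshold -- too
  little divergence to determine the ratio.

The threshold defaults to 0.001 substitutions per site and is configurable
everywhere it is used. The classification is total: exactly one of
VALUE/GT1/LOWDIV applies to any nonnegative (dN, dS) pair.

## Optimisation

Fits use a branch-at-a-time scheme: global parameters ($\kappa$, and the
shared $\omega$ for M0) are optimised by Nelder--Mead on the log scale with
full-tree evaluations, alternating with per-branch sweeps that optimise
each branch against the edge-local likelihood (the complement of the tree
is held fixed, so a sweep costs one matrix product per trial value).
Branch lengths are initialised from mean pairwise codon p-distances. For
the free-ratio model the shared-omega fit runs first and the per-branch
omegas are released afterwards -- releasing them from the start makes the
early sweeps prone to boundary collapse. Within a branch, the branch
length is optimised on the linear scale (the gradient stays informative as
$t \to 0$) and omega on the log scale (the surface is a long flat ridge in
$\omega$ for branches with few synonymous changes). Sweeps stop when the
log-likelihood improves by less than a relative tolerance of $10^{-8}$
(`control$reltol`), with $\omega$ bounded in $[0, 999]$ and branch lengths
in $[10^{-9}, 5]$.

The branch-site fit estimates $\kappa$ and branch lengths once under M0
and holds them fixed while the mixture parameters
($p_0, p_1, \omega_0, \omega_2$) *and the foreground branch length* are
optimised for both hypotheses -- the foreground length is the one length
directly confounded with the selection signal, so it is always
re-estimated. This is a tractability choice: it makes a five-species test
run in about a second instead of minutes, at some cost in power (not in
test size -- the alternative is seeded from the null optimum, so the
statistic can only be under-, never over-stated). Two starts are used for
the alternative: the null solution (guaranteeing nesting at the
$\omega_2 = 1$ boundary) and a selection-leaning start with appreciable
class-2 mass, which escapes the $p_2 \approx 0$ plateau where the
$\omega_2$ gradient vanishes.

# Expression specificity (tau)

For a gene with expression $x_i$ over $n$ conditions,
$\tau = \sum_i (1 - x_i/\max_i x_i) / (n - 1)$: 1 means single-condition
expression, 0 uniform expression. The index is computed on the raw
expression values exactly as the formula states; a `log2(x + 1)`
pre-transform is exposed but off by default, because no transform is part
of the printed definition. Genes whose maximum is zero are excluded with a
logged count. "Highly specific" means $\tau$ strictly above 0.90.

Cell-type transcriptome similarity is summarised by average-linkage
agglomerative clustering of per-gene standardized expression profiles
(mean 0, sd 1 per gene; zero-variance genes dropped with a logged count).
The distance between condition profiles is Euclidean by default with a
correlation-distance option -- the GUI originally used for this step does
not record its metric, so the default is stated here rather than inherited.
Ties break deterministically by lexicographic condition label.

# Screens and enrichment

The screens compose as in the source analysis: genome-median fold screens
(`foldScreen`, threshold $\ge$ fold $\times$ median M0 $\omega$; 1.5-fold
for the conserved signaling set, 2.2-fold $\approx$ the absolute 0.20 cut
for the expression-derived sets), per-branch absolute/fold screens
(`hawaiianBranchScreen`, strict $> 0.33$ absolute rule), branch-maximum
attribution with GT1 dominance (`branchMax`), saturation filtering (dN or
dS $\ge 1.5$ excluded as unreliable; records with neither dN nor dS above
0.001 excluded as uninformative), top-N upregulation ranking, cross-dataset
overlap, and exclusive upregulation under cell-type pooling (SH = SHa+SHm,
TF = TFa+TFp). Threshold direction follows the published wording in each
case: fold screens use $\ge$, the absolute branch cut and the tau cut are
strict. Every screen logs genes in/out and its active thresholds, and
returns a criteria trace from which the pass decision can be reconstructed.

Enrichment of positive selection in a gene set against the genome-wide
frequency uses a one-tailed Pearson goodness-of-fit test on the 2-cell
table; "one-tailed" halves the $\chi^2_1$ tail in the enrichment direction.
Both the uncorrected and the Yates-corrected variants are exposed because
the published P-values are internally inconsistent on this point: 6/27 vs
12.0% reproduces the printed 0.05 *without* the correction, while 2/8 vs
5.4% reproduces the printed 0.047 *with* it. The default is uncorrected;
the corrected variant is also the one that tracks the exact one-sided
binomial test (within 0.02 for $n \ge 25$, $np_0 \ge 3$, in the
enrichment regime).

# Phylogenetic regression

`pglsFit()` solves the generalized least squares problem
$\hat\beta = (X^\top V^{-1} X)^{-1} X^\top V^{-1} y$ with design $(1, x)$,
where $V$ is the Brownian-motion tip covariance (`bmCovariance`: shared
root-to-MRCA path lengths; equal to `ape::vcv`, which the tests use as an
independent cross-check). No Pagel's $\lambda$ or other transformation is
estimated: plain Brownian motion, matching the stated use of a vcv matrix.
The slope P-value is a two-sided t test at $n - 2$ df (3 df for five
species). With a star phylogeny the fit reduces exactly to ordinary least
squares.

Sentinel branches enter the regression through an explicit imputation:
GT1 $\to$ 1.5, LOWDIV $\to$ 0. These defaults are not arbitrary -- they are
the unique values consistent with the published prediction tables
(back-solving the printed predictions for genes with sentinel branches,
e.g. a LOWDIV branch whose prediction equals the intercept forces 0, and a
GT1 branch back-solves to 1.50), verified across every affected row before
being frozen. Genes with GT1 sentinels on two or more branches are
rejected as untestable (near-zero dS in several branches), matching the
treatment of the one such gene in the source tables; both values and the
exclusion rule are configurable and logged. `pglsPredict()` returns
$\hat y = \text{intercept} + \text{slope} \times \omega$, rounded to two
decimals for display parity with the published tables.

# The synthetic-data generators

Every input the pipeline consumes can be generated
(`simulateCodonAlignment`, `simulateExpression`, `simulateGenomeRates`,
`simulatePhenotypeOnTree`), each a pure function of its parameters and a
mandatory seed. The generators emulate the statistical structure the
analysis assumes:

* codon alignments evolve by exact transition-probability sampling along
  each branch (matrix exponential of the branch's scaled generator -- not
  an event-by-event simulation, which would be slower for no accuracy
  gain at these branch lengths); site-class mixtures share one
  class-weighted rate normalisation per branch, as in the inference model,
  so purifying classes accumulate proportionally fewer substitutions;
* expression matrices draw a breadth $k$ per gene and give expressed
  conditions log-normal values, so realised tau concentrates on the
  closed form $(n-k)/(n-1)$ from above as the value noise shrinks;
* genome-wide rate tables draw M0 $\omega$ from a right-skewed gamma
  scaled to a target median of 0.09 -- the genome-wide median implied by
  the published "0.20 $\approx$ 2.2 $\times$ median" screening threshold --
  with per-branch positive-selection flags at specified frequencies and
  plantable rapid genes at known identities;
* tip phenotypes are linear in $\omega$ plus multivariate-normal residuals
  with covariance $\sigma^2 V$.

What the generators do **not** emulate: alignment error, indels and gaps,
ortholog misassignment, GC-biased codon usage, rate variation beyond the
modelled site classes, and expression measurement error structure. Passing
the validation studies therefore demonstrates internal correctness of the
estimators under the model's own assumptions, not robustness to the
artefacts of real genome-scale data.

The five-taxon study tree bundled as `melanogasterTree()` carries the
subgroup topology with synthetic stand-in branch lengths on the
substitutions-per-codon scale (the maximum-likelihood branch lengths behind
the published analysis are not printed anywhere); `ovarioleNumbers()`
carries the reported mean ovariole counts per female.

# Validation studies and problem sizes

The test suite validates the engine at these sizes, chosen to give stable
Monte-Carlo estimates on a single CPU:

* exhaustive-enumeration equality of the pruning likelihood on all tree
  shapes with $\le 3$ tips and $\le 3$ codon columns (tolerance $10^{-9}$);
* M0 recovery: 50 replicates of 5,000 codons at $\omega = 0.2$,
  $\kappa = 2$; the median absolute relative error of $\hat\omega$ must
  stay within 10%;
* free-ratio attribution: 100 replicates of 2,000 codons with one terminal
  branch planted at $\omega = 0.8$ against 0.1 elsewhere; the planted
  branch must be the branch maximum in at least 95;
* branch-site calibration: 300 null replicates (purifying + neutral site
  mixture, no selected class). The instance is a three-taxon core of the
  study clade at 150 codons -- the small-tree, short-alignment regime is
  the one where the $\chi^2_1$ approximation is most stressed by the
  boundary, so calibrating there is the conservative check; the empirical
  rejection rate at $\alpha = 0.05$ must not exceed 0.08 (in practice it
  is far lower, because the boundary null makes the 1-df reference
  conservative). A five-taxon spot check accompanies it in the unit tests;
* PGLS: star-tree equality with OLS to $10^{-10}$; slope recovery centred
  on the generating slope over 200 Brownian simulations; covariance equal
  to brute-force MRCA path sums on random trees.

`scripts/acceptance.R` re-runs scaled-down versions of the stochastic
studies (sizes recorded in its output) plus all exact reproductions.

# Known limitations

* Published per-gene M0 and branch values for real genes are consumed from
  the bundled tables, not recomputed: recomputation would require the
  original five-species genome alignments and the exact runtime settings
  of the original pipeline, neither of which is published. Likewise the
  published PGLS P-values depend on unpublished ML branch lengths, so the
  package reproduces the prediction arithmetic exactly but not the fit
  P-values.
* The branch-site procedure fixes background branch lengths at their M0
  estimates; this trades some power (detectably at weak effect sizes, e.g.
  $\omega_2 = 4$ on 10% of sites at 2,000 codons) for large speedups, and
  never inflates the test size.
* Site models (M1a/M2a/M7/M8), codon gamma rate variation, ancestral
  reconstruction and BEB site identification are out of scope.
* The clustering step exposes Euclidean and correlation distances only.

# Session info

```{r}
sessionInfo()
```
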