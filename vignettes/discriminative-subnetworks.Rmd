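---
title: "Discovering multi-class discriminative subnetworks with covernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering multi-class discriminative subnetworks with covernet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covernet)
```

## The problem

Progressive diseases such as colorectal cancer are staged into more than
two clinical classes, but most network-based marker-discovery methods
only handle binary phenotypes (case versus control). `covernet`
searches a protein-protein interaction (PPI) network for *subnetworks*
— connected groups of genes — whose aggregate expression discriminates
multiple phenotype classes, either all at once or one class against the
rest, and uses them as features to predict the class of new samples.

Throughout, $E_i(j)$ is the (normalized) expression of gene $g_i$ in
sample $s_j$, $C(j) \in T$ is the sample's class, $U(t)$ the samples of
class $t$, and $G(V, \varepsilon)$ an undirected PPI network. A gene
set $S$ is a subnetwork of interest when each member is within $\ell$
network hops of the rest of the set; `covernet` uses the neighborhood
reading of this constraint (a candidate joins when it is within $\ell$
hops of the current subnetwork), and $\ell = \infty$ turns the search
network-free.

## Discriminative power

The *activity* of $S$ is the per-sample mean expression
$E_S = \sum_{g_i \in S} E_i / |S|$: an additive signature, which
commits the method to subnetworks whose members shift in the same
direction in the class of interest. Discriminative power is measured by
plug-in mutual information (base 2) between the discretized activity
and the phenotype:

* all-vs-all: $\Delta_{ava}(S) = I(E_S, C)$,
* one-vs-all: $\Delta_{ova}^{(t)}(S) = I(E_S, C^{(t)})$, where
  $C^{(t)}$ is the binary indicator of class $t$.

The discretization of $E_S$ is not prescribed by the information
measures themselves; `covernet` uses equal-frequency bins at empirical
quantiles with $\lceil \log_2 |U| \rceil + 1$ bins by default
(configurable). Equal-frequency binning is robust to outliers and ties
always share a bin, so degenerate (constant) activities occupy a single
bin and carry zero information.

## The cover-based search

Instead of re-evaluating mutual information for every candidate, the
one-vs-all search works on a ternary quantization of expression.
With $\mu_i$ and $\sigma_i$ the mean and *population* standard
deviation of gene $i$ across all samples,

$$\hat E_i(j) = \begin{cases} +1 & E_i(j) > \mu_i + \alpha\,\sigma_i \\
-1 & E_i(j) < \mu_i - \alpha\,\sigma_i \\ 0 & \text{otherwise,}
\end{cases}$$

with strict inequalities, so boundary values and zero-variance genes
quantize to 0. Gene $g_i$ *positively covers* sample $s_j$ when
$\hat E_i(j) = +1$ and *negatively covers* it when $\hat E_i(j) = -1$;
$P_i^{(t)}$ and $N_i^{(t)}$ collect the class-$t$ samples covered in
each direction. For a binary quantized profile, the mutual information
with $C^{(t)}$ grows with the gap $\bigl||P_i^{(t)}| - |N_i^{(t)}|\bigr|$,
which is what licenses replacing the information objective with a
covering objective.

Seeded at each gene and direction, the greedy growth

1. picks the target class $t$ maximizing the covered fraction
   $|P_i^{(t)}| / |U(t)|$ (ties to the lexicographically smallest
   label; a seed covering nothing anywhere emits no subnetwork),
2. tracks the uncovered samples $M = U(t) \setminus P_i^{(t)}$,
3. repeatedly adds, from the $\ell$-hop neighborhood of the current
   subnetwork, the gene maximizing
   $|P_j^{(t)} \cap M| - |N_j^{(t)} \cap M|$, breaking ties by minimum
   positive background coverage $\sum_{t' \neq t} |P_k^{(t')}|$ and
   then by gene identifier,
4. stops when $M = \emptyset$, the neighborhood is exhausted, the best
   gain is non-positive, or the size cap is reached.

Two readings of the step-3 score are possible from its usual notation
(a difference of cardinalities versus the cardinality of a set
difference); `covernet` uses the difference of cardinalities, which is
the reading consistent with the cardinality-gap monotonicity above and
with the intent of penalizing genes that cover the target class in the
wrong direction. The non-positive-gain stop and the size cap (default
20) are guards this implementation adds so that "minimal" covers are
not padded with useless genes and network-free runs stay bounded;
`early_stop = FALSE` and `max_size = Inf` restore the covering-only
stopping rule. The negative-direction search is the same algorithm
with $P$ and $N$ exchanged.

The additive comparator (`grow_additive`, `discover_additive_all`)
greedily adds the neighborhood gene that most improves
$\Delta_{ova}$ or $\Delta_{ava}$, stopping when the best improvement is
at or below `min_improvement` (default 0.01 bits; the threshold is
user-defined by construction and no canonical value exists). For the
one-vs-all objective the target class is fixed when the seed is scored;
letting it drift during growth would make scores across steps
incomparable.

## Statistical significance

Observed subnetwork scores are compared against two permutation nulls,
each built by rerunning the *entire* discovery on randomized data:
label permutation (class labels shuffled across samples) and profile
permutation (expression rows reassigned to genes, which also decouples
profiles from network positions). Pooling the best subnetworks
discoverable on each null dataset makes the background a max-statistic
construction, so it implicitly accounts for the multiplicity of the
search. Because random covers grow better scores at larger sizes,
p-values are *size-stratified*: the p-value of $S$ is the fraction of
background subnetworks of equal size with strictly greater score. Thin
strata are widened to neighboring sizes until at least 20 background
values are available (sizes adjacent in count have near-identical null
behavior). A subnetwork is significant when both p-values fall below
the threshold (default 0.05). The plain counting estimator can return
p = 0, as conventionally reported for empirical nulls of this type.
Defaults of 100 permutations per null and a 0.05 threshold are package
choices; both are exposed.

## Classification

Features are either the top-$k$ subnetworks per class and direction
(default $k = 1$, so $2k|T|$ features; all-vs-all subnetworks have no
class axis and contribute the top $2k|T|$ overall) or all dual-test
significant subnetworks. Each feature is the subnetwork's activity;
the classifier is Gaussian naive Bayes written in this package:
per-class maximum-likelihood means and variances (floored at $10^{-9}$),
priors equal to training frequencies, posterior ties to the smallest
class label. Evaluation is stratified 10-fold cross-validation (fold
sizes within a class differ by at most one) or cross-dataset
prediction. By default features are discovered once on the full
dataset before cross-validation — this replicates the
discover-then-validate protocol of the subnetwork-marker literature and
*leaks feature-selection information across folds*; pass a
`discover_fun` to `stratified_kfold_cv()` for nested, leakage-free
selection. Per-class precision (column-wise) and recall (row-wise) are
reported exactly and as two-decimal *truncated* strings, because
truncation — not rounding — is what reproduces how such tables are
conventionally printed; weighted averages weight classes by their
actual sizes, so weighted recall equals overall accuracy.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 2 | dysregulation threshold, in per-gene SD units |
| `ell` | 3 | hop bound for the candidate neighborhood; `Inf` = network-free |
| `bins` | $\lceil \log_2 |U| \rceil + 1$ | equal-frequency activity bins |
| `max_size` | 20 | subnetwork size cap (cover search) |
| `min_improvement` | 0.01 bits | additive-search stopping threshold |
| `n_perms` | 100 | permutations per null |
| `threshold` | 0.05 | significance level per null |
| `k` | 1 | features per class and direction |

The $\alpha = 2$ and $\ell = 3$ defaults follow the reported sweet spot
for four-stage expression data: looser neighborhoods widen the search
with no further gain past three hops, and two standard deviations marks
per-sample dysregulation conservatively.

## The synthetic generator

`synthetic_config()` emulates the structure the method assumes: a
preferential-attachment network (heavy-tailed degrees, like real PPI
networks), classes of sizes 44/94/91/61 by default (the four-stage
distribution of a 290-sample cohort), and per-class connected modules
of 5 genes grown by randomized BFS, whose expression is shifted by
`effect_size` times the noise SD in exactly one class (alternating
up/down across classes by default, so both search directions are
exercised; modules are gene-disjoint across classes). Baseline
expression is i.i.d. Gaussian noise.

It deliberately does **not** emulate microarray realities: correlated
gene noise, batch effects, probe-level summarization, heavy-tailed
intensity distributions, or partially dysregulated modules. Passing
recovery and classification tests on these data therefore shows the
machinery is correct under its own model, not that the method will
perform identically on real expression data.

A property worth understanding (it drives one deliberately strict
recovery check): with `effect_size = 2` and `alpha = 2`, a planted
gene's positive-cover rate in its target class is modest, not
near-certain. The planted shift inflates the pooled $\mu_i$ and
$\sigma_i$ that set the quantization thresholds — for a class holding
fraction $p$ of samples, the threshold sits at
$2p + 2\sqrt{1 + 4p(1-p)}$ noise SDs, so a gene shifted by 2 SDs
covers only roughly 10–20% of its class. Minimal covers built from
such genes must recruit background genes to finish covering the class,
which caps gene-set recovery (Jaccard against the plant) even though
the class signal itself remains strong — the classification tests
succeed under exactly these conditions. The same marginality makes the
dual permutation test occasionally pass subnetworks for only a subset
of classes on a given replicate; a significant-features classifier
then lacks features for the dropped classes and its accuracy suffers
accordingly. Raising `effect_size` relative to `alpha`, or lowering
`alpha`, moves per-gene cover rates up, and set-level recovery and
per-class significance stability with them.

## Numerical and testing choices

Deterministic behavior is part of every contract: searches contain no
randomness, all ties break lexicographically, and every stochastic
component (generator, permutations, folds) takes an explicit seed and
restores the caller's RNG state. Entropy uses $0 \log 0 = 0$;
mutual information is computed as $H(X) + H(Y) - H(X, Y)$ and clamped
at 0 against rounding. Missing values are hard errors everywhere —
no handling for them is defined by the model.

The test suite sizes its simulations to run on one CPU in minutes:
module recovery and the end-to-end classification check use the full
default conditions (300 genes; 20 and 10 replicate seeds, with 8
permutations per null in the latter), and significance calibration
uses 120-gene null datasets with 50 permutations per null
(significance at a 0.05 threshold only needs enough permutations for
the empirical fraction to fall below it). These sizes are the package's
documented study conditions for its own properties.

## A complete run

```{r, eval = FALSE}
cfg <- synthetic_config(rng_seed = 1)      # 300 genes, stages A-D
G <- generate_network(cfg)
plants <- plant_class_subnetworks(G, cfg)
dat <- generate_expression(G, plants, cfg)

subs <- discover_all(dat$expression, dat$labels, G = G)   # COBALT
bg_l <- build_background(dat$expression, dat$labels, G,
                         n_perms = 100, mode = "label", rng_seed = 2)
bg_p <- build_background(dat$expression, dat$labels, G,
                         n_perms = 100, mode = "profile", rng_seed = 3)
ann <- assess_significance(subs, bg_l, bg_p)
feats <- select_significant(ann)
M <- stratified_kfold_cv(dat$expression, dat$labels, feats,
                         folds = 10, rng_seed = 4)
precision_recall(M)
```

## Known limitations

* The additive activity commits to same-direction dysregulation; the
  framework does not model combinatorial expression states.
* Edge confidence scores are not used; every interaction counts alike.
* The default evaluation protocol leaks feature selection across folds
  (see above); nested mode is slower but unbiased.
* Probe-to-gene mapping and normalization are the caller's
  responsibility; expression is consumed as given (an optional
  per-gene z-scoring step is available for activity aggregation).
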