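---
title: "Methods: explainable unsupervised anomaly detection for claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable unsupervised anomaly detection for claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claimscope)
```

## The problem

Health insurers receive a stream of per-action billing records: one row per
medical act, identifying the (pseudonymous) practitioner, categorical
attributes such as discipline, location and the billing (nomenclature) code,
and numerical attributes such as the billed amount. Providers with unusual
resource use — over-use of particular codes, activity far outside their
specialty, inflated amounts — are rare, labels are scarce and expensive, and
investigators need to know *why* a provider was flagged before they act.
claimscope implements an unsupervised, explainable workflow for this setting:
embed, aggregate, detect with an ensemble, rank by consensus, and explain
with Shapley attributions plus plain population comparisons.

## Categorical embeddings

High-cardinality categoricals (billing-code vocabularies run from a handful
to hundreds of thousands of values) make one-hot encoding explode the feature
space and degrade distance-based detectors. claimscope instead embeds
categorical values with latent semantic analysis. A binary co-occurrence
matrix $X \in \{0,1\}^{c \times p}$ is built with one row per (column, token)
pair pooled over all categorical columns and one column per action; entry
$(i, j)$ is 1 iff value $i$ appears in action $j$ (strictly presence, not a
count). A rank-$k$ truncated SVD $X \approx C S P^\top$ yields the category
embedding $CS = XP \in \mathbb{R}^{c \times k}$, one row per value, which is
then l2-normalised so cosine similarity is a dot product.

Numerically, the top-$k$ triplets are obtained from the symmetric
eigendecomposition of the smaller Gram matrix ($XX^\top$ when $c \le p$,
$X^\top X$ otherwise), built sparsely; this is exact and fast for the
vocabulary sizes the package targets (up to a few thousand categories), and
the test suite cross-checks it against a dense SVD on small matrices. Two
numerical conventions matter:

* **Sign.** Singular vectors are defined up to sign. Each component's sign is
  fixed so that the largest-magnitude entry of the action-side vector is
  positive (ties broken by lowest index), making embeddings bit-reproducible
  across runs and action orderings.
* **Rank deficiency.** If the requested $k$ exceeds the numerical rank the
  table is truncated to the rank with a warning rather than padded with
  noise components.

The default is $k = 3$: small embeddings already capture the code–discipline
co-occurrence structure that matters here, and enlarging $k$ mostly adds
dimensions for the detectors to wade through. Values never seen at fit time
map to the zero vector — a neutral contribution under mean aggregation.

## Provider profiles

Each provider's actions collapse into one fixed-length row: every numerical
feature contributes six statistics (sum, mean, median, standard deviation,
minimum, maximum — population-form sd, so singleton providers get 0), and
every categorical feature contributes the mean of its per-action embedding
vectors. For $m$ numerical and $q$ categorical features the profile has
$d = 6m + kq$ columns; a group map records which expanded columns belong to
which original feature, which the explanation stage relies on. Missing
numerical cells are excluded from the statistics, never imputed as zero; an
entity with no observed value for a feature is an error rather than a silent
zero. Missing categorical cells become the reserved token `"__missing__"`
and are embedded like any other value.

Columns are then standardized: subtract the column mean, divide by the
column (population) standard deviation. The written account of this step can
be read two ways — dividing by the variance or by the standard deviation —
and claimscope uses the standard z-score, which is the only choice that
leaves every column dimensionless and unit-variance. Constant columns are
divided by 1 and flagged, so they standardize to all-zero without breaking
the group map; the fitted (mean, scale) pairs are stored for held-out rows.

## Detector battery

Three scorers are implemented natively, chosen because they are simple,
oracle-verifiable and cover distinct method families:

* **kNN** (`knn_score`): mean Euclidean distance to the $k$ nearest other
  profiles (default $k = 20$). Standardization is precisely what makes
  unweighted Euclidean distance meaningful here.
* **Histogram** (`hist_score`): per dimension an equal-width histogram
  (default 10 bins) over the observed range; score
  $= \sum_d -\log(\text{density}_d + \varepsilon)$ with
  $\varepsilon = 10^{-12}$ guarding empty bins. Zero-range dimensions
  contribute 0.
* **ECDF tail** (`ecdf_tail_score`): parameter-free; per dimension the
  smaller of the left tail $\#\{x \le z\}/n$ and right tail
  $\#\{x \ge z\}/n$ at the sample's value, scored as
  $\sum_d -\log(\text{tail}_d)$. Training rows always have tail $\ge 1/n$,
  so the $\varepsilon$ floor only matters for out-of-sample rows.

Everything else (LOF, isolation forests, one-class SVMs, autoencoders, ...)
attaches through the adapter contract: `fit(X, spec)` on the full profile
matrix returning per-entity scores (higher = more anomalous) and optionally
a scorer for modified rows so the detector can also be explained. A failing
adapter is dropped with a warning; the run continues. Rankings are evaluated
with the exact Mann–Whitney AUROC (ties count one half), which is immune to
the heavy class imbalance of this domain.

## Consensus ranking

Each detector nominates its top-$k$ scoring entities (default $k = 50$, a
plausible expert-review workload; ties at the boundary break by
lexicographic entity ID so the sets are deterministic). Entities are ranked
by how many detectors nominate them. Counts are the only fusion — raw scores
across heterogeneous detectors are not averaged. Count ties resolve by mean
per-detector dense rank, then entity ID; this secondary key is a
determinism device, not a scientific claim.

## Shapley explanations

For a flagged entity, each detector's score is attributed to the *original*
features with Shapley values. The coalition value of a feature subset $S$ is
the mean detector score over a background set (default 100 profile rows
sampled without replacement, seeded) with the features in $S$ set to the
entity's values and the rest left at background values — the standard
interventional formulation, applicable to any detector that can score
modified rows.

Attribution is computed directly at the group level: a player is an original
feature, and joining a coalition toggles all of its expanded columns (six
statistics or $k$ embedding dimensions) at once. By additivity this
coincides, for the exact estimator, with attributing each expanded column
separately and summing per feature — the route kept in
`group_attributions()` for attributions imported from external explainers —
while cutting enumeration cost from $2^d$ to $2^{(\#\text{features})}$.
Exact enumeration is used up to 12 groups; beyond that a permutation-
sampling estimator (`monte_carlo_shapley`) provides unbiased estimates with
per-group standard errors shrinking as $1/\sqrt{\text{permutations}}$.
The exact engine satisfies efficiency
($\sum_j \phi_j + \text{base} = \text{score}$), dummy, symmetry and
linearity to $10^{-9}$ on constructed score functions in the test suite.

Different detectors score on incommensurable scales, so before averaging
across models each grouped importance vector is rescaled to unit l1 norm
(preserving sign; all-zero vectors stay zero) and the consensus importance
is the componentwise mean. l1 was chosen because it makes "fraction of the
total attribution" comparable across models without distorting signs.

## Reports

The expert-facing report pairs the consensus importance ranking with
univariate comparisons for the top-$m$ features (default 5): categorical
features show the entity's token distribution against the action-weighted
population distribution; numerical features show the entity's six aggregate
statistics against the population mean and standard deviation of each
statistic, with z-scores (degenerate statistics are flagged and reported as
z = 0). The billing-code feature can be forced into every report regardless
of rank, since investigators always want the nomenclature distribution.
JSON renders round-trip losslessly; the HTML render embeds a hand-built SVG
bar chart so output is byte-stable.

## Synthetic benchmark

Real claims data is restricted, so the package ships a generator whose
defaults mirror the scale *ratios* of a national GP claims database at desk
scale: 2000 providers, negative-binomial action counts (mean 100, dispersion
5), three specialties, a billing-code column of cardinality 600 with
Zipf-weighted specialty-specific vocabularies plus a thin shared tail, a
discipline column tied to the specialty, a location column of cardinality 8,
and log-normal billed amounts (positive and right-skewed, as billing amounts
are) whose scale differs by specialty. Prevalence of planted anomalies is
0.3%, split over three archetypes that perturb *action-level sampling* —
billing-code odds multiplied by 20, half of the actions resampled from the
orthopedics profile, amounts multiplied by 5 — so an anomaly must survive
embedding and aggregation to be detectable, exercising the entire pipeline.
Each entity draws from its own RNG substream derived from the global seed,
so growing the population leaves existing entities bit-identical.

What the generator deliberately does not model: temporal burstiness and
seasonality, correlations between categorical columns beyond the shared
specialty, code vocabularies in the hundreds of thousands, and the unknown
distributional quirks of real billing data. Passing benchmarks therefore
demonstrate that the machinery works end-to-end and that the embedding
pipeline dominates the one-hot baseline *under these conditions*; they do
not certify performance on any particular insurer's data.

## Problem sizes and numerical choices

The shipped checks run the benchmark at 2000 entities over 5 seeds for
detection quality, 150 entities for explanation-recovery and determinism
checks, Monte-Carlo Shapley at 2000 permutations on 6–8 group instances, and
oracle comparisons at up to 200 entities — sizes at which every quantity is
recomputed from scratch in about a minute on one core. Other defaults worth
knowing: activity filter threshold 50 with a *strict* inequality (an entity
with exactly 50 actions is dropped); the per-period variant requires every
covered period to exceed the threshold and is off by default, since either
reading of "per year" is defensible; detector hyperparameters
($k = 20$ neighbours, 10 bins) follow common practice for these families
rather than any tuned value.

## Known limitations

* The Gram-matrix SVD densifies a $\min(c, p)^2$ matrix; for vocabularies in
  the $10^5$ range a Lanczos-style solver would be needed.
* The ECDF-tail scorer uses the symmetric min-tail form; the published
  three-way (left/right/skew-corrected) aggregation of ECOD is available
  only through an adapter.
* Monte-Carlo attribution cost scales with
  permutations × groups × background rows; explaining many entities with
  many features calls for smaller backgrounds.
* Consensus counts depend on one global top-$k$; per-detector $k$ values are
  not supported.
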