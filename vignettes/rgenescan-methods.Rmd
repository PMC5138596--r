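---
title: "Methods: descriptors, balancing and evaluation in rgenescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptors, balancing and evaluation in rgenescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgenescan)
```

## The problem

Resistance (R) genes — genes whose protein products contribute to immune and
defense function (antimicrobial peptides, MHC molecules, interferons,
lectins, receptor proteins, ...) — are scattered across protein databases
and are costly to identify experimentally. `rgenescan` frames their
recognition as binary protein-sequence classification: positive examples are
curated R-gene products, negatives are drawn from unrelated protein
families, and a classifier trained on physicochemical sequence descriptors
scores new proteomes. The package implements the complete workflow: sequence
curation (redundancy removal), two descriptor families, class-imbalance
handling, Random-Forest classification with pluggable baselines, the full
binary evaluation suite, and a synthetic-sequence generator that makes every
stage testable without any database access.

## The 188-D descriptor

The workhorse descriptor concatenates:

* **Amino-acid composition (20)** — `100 * count(residue) / L` for each of
  the 20 canonical residues in the fixed alphabetical order A, C, D, ..., Y.
* **CTD blocks (8 x 21)** — each of eight physicochemical properties
  partitions the alphabet into three disjoint groups, and contributes:
  * *Composition* (3): percent of residues in each group.
  * *Transition* (3): for the unordered group pairs (1,2), (1,3), (2,3),
    `100 * (N_jk + N_kj) / (L - 1)`, where `N_jk` counts adjacent positions
    with group j followed by group k.
  * *Distribution* (15): per group, the positions of the first, 25%, 50%,
    75% and last occurrence, each as `100 * position / L`; the q-th
    occurrence index is `max(1, ceiling(f * n_j))` for
    `f in {0, .25, .5, .75, 1}`. Ceiling (rather than rounding) is used
    because it is monotone and gives the natural degenerate behavior: a
    group with a single occurrence fills all five slots with the same value,
    and an absent group yields five zeros.

Total: `20 + 8 * 21 = 188` components, all on the percent scale (0-100).

### Property partitions

The three-group partitions are the classical CTD tables of the
protein-classification literature (hydrophobicity, polarity, polarizability,
charge, surface tension, secondary-structure propensity, solvent
accessibility). Because published CTD implementations differ in small ways,
the registry was validated against a worked example: a 363-residue
photosystem-II D1 protein whose composition row and
hydrophobicity/van-der-Waals composition triples are known to four decimals.
The hydrophobicity table
(polar `RKEDQN` | neutral `GASTPHY` | hydrophobic `CLVIMFW`) reproduces the
worked triple exactly. The textbook van-der-Waals-volume table does **not**
(it yields 41.05/34.71/24.24 against the reference 41.32/39.12/19.56);
the unique chemically plausible partition that does is

```
group 1: C D E I L M N Q V   (mid-size)
group 2: A G P S T           (small)
group 3: F H K R W Y         (large / aromatic + basic)
```

which the registry ships as the default for `normalized_vdw_volume`. It
differs from the textbook table in placing cysteine with the mid-size
residues and methionine outside the largest group — defensible on raw
side-chain volumes, where cysteine (~109 A^3) sits above the small
cluster. Only order-free components (AAC and the C triples) can be
validated this way; transition and distribution values depend on residue
order, and the available reference rows for them are not internally
consistent (two disjoint groups would claim the same first-occurrence
position), so they were left out of the validation. `read_partition_table()`
loads alternate tables so other conventions can be tested against the same
example; a candidate table that fails the reproduction should be flagged,
not silently adjusted.

Wildcard residues (`X`, the sanitized form of B/Z/U/O/etc. under the default
`map_to_x` policy) belong to no group: they contribute to no count, but stay
in the denominators (`L`, `L - 1`). Whole-record dropping is available but
not the default, because it would silently change dataset sizes.

## Pseudo amino acid composition (Pse-AAC)

The type-I (series-correlation) Pse-AAC vector has `20 + lambda` components.
With residue frequencies `f_i = count_i / L` and lag-`j` correlation factors

```
e_j = (1 / (L - j)) * sum_{i=1..L-j} Theta(r_i, r_{i+j})
```

where `Theta` is the mean over three property scales of the squared
difference of standardized per-residue values, the vector is

```
p_u = f_u / (sum f + omega * sum e)          for u <= 20
p_{20+j} = omega * e_j / (sum f + omega * sum e)
```

so it always sums to 1, and `lambda = 0` reduces exactly to normalized
amino-acid composition. Defaults are `lambda = 10` (hence 30 components),
`omega = 0.05`, and the standard scale triple: hydrophobicity, Hopp-Woods
hydrophilicity and side-chain mass, each standardized to zero mean and unit
population variance over the 20 residues so `Theta` is unit-free. The
amphiphilic (type-II) variant with `20 + 2 * lambda` components is out of
scope; the type-I choice is the one consistent with a 30-component vector at
a conventional lag of 10, and `lambda`/`omega`/scales are all exposed in
`pseaac_config()` for sensitivity analysis.

## Redundancy removal

Curated positive sets contain many near-duplicates, which inflate apparent
accuracy through train/test leakage. `cluster_greedy()` implements greedy
incremental clustering: sequences are sorted by decreasing length (ties by
id), and each joins the first cluster whose representative it matches at or
above the threshold, else founds its own. Identity is defined as the number
of identical positions in an identity-maximizing global alignment (match 1,
mismatch 0, linear gap penalty 1) divided by the **shorter** sequence's
length — the convention of greedy clustering tools. The default threshold is
0.70.

Two documented consequences of the greedy strategy: representatives are not
guaranteed to be mutually below the threshold (only removed members are
guaranteed close to a representative), and the shorter-length denominator
means a short random sequence can reach substantial identity to a much
longer one purely by gapping. The family fixture generator therefore draws
ancestors in a narrow length band (log-normal around 200 residues, sdlog
0.15), where the measured null (cross-family) identity stays below ~0.35 —
far from the 0.70 threshold — while 10% per-site mutation keeps within-family
identity near 0.9 (copies against the ancestor) and 0.81 (copies against
each other). No k-mer prefilter is applied; the all-pairs-to-representatives
cost `O(n * clusters * L^2)` is acceptable at the scales this package
targets.

## Class balancing

Curated positives and negatives are rarely balanced. Two strategies:

* **Random under-sampling** (`under_sample()`): the majority class is
  sampled uniformly without replacement down to the minority size; leftover
  majority instances become a hold-out set. With 6720 positives and 10028
  negatives this yields a 6720/6720 training set and a 3308-negative
  hold-out, reproducibly per seed.
* **Per-instance weighting** (`weighted_sample()`): every instance is kept
  and weighted. Auto mode uses inverse class frequency normalized to mean
  weight 1 (equal per-class mass); fixed mode takes explicit class weights —
  e.g. 10 for positives and 7 for negatives when the class ratio is roughly
  7:10, which makes the two class masses nearly equal
  (67,200 vs 70,196, within 5%). The Random-Forest backend consumes weights
  as bootstrap case weights, the natural equivalent of instance-weighted
  learning for resampling learners.

## Classification and evaluation

The default learner is a Random Forest (`ranger` backend): 100 trees,
`mtry = floor(sqrt(p))`, `min.node.size = 1` (so small benchmark sets are
actually split), probability output, single-threaded with a fixed seed so
results are bit-reproducible. SVM and naive Bayes baselines are available
behind the same `learner_spec()` interface; ensemble-selection
meta-classifiers are deliberately not re-implemented.

Evaluation reports sensitivity `SN = TP/(TP+FN)`, specificity
`SP = TN/(TN+FP)` (fractions), overall accuracy `Acc = 100 (TP+TN)/m`
(percent), Matthews correlation

```
MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))
```

and ROC area via the rank (concordance) statistic with ties counted half —
identical to trapezoidal integration on tie-free scores. Conventions for
degenerate inputs: an empty class makes SN or SP `NaN` with a warning (never
a silent 0), while a zero marginal makes MCC 0 with a warning (the explicit,
logged convention). On any per-class-balanced evaluation,
`Acc = 100 (SN + SP)/2` holds exactly — a useful consistency identity for
published balanced benchmarks.

Cross-validation (`cross_validate()`) is stratified, with predictions pooled
over folds and scored once, matching the reporting style of benchmark tables
that print a single SN/SP/Acc/MCC per method; per-fold averaging would give
slightly different numbers. Fold assignment and per-fold training derive
from one seed.

## Synthetic data: what it does and does not emulate

`generate_dataset()` draws residues i.i.d.: negatives from a database-like
background frequency vector, positives from the background shifted by a
total-variation distance `effect` toward a designated residue subset
(default `{K, R, C, W}`). `effect = 0` gives the exact null (identical
distributions); the feasible maximum is `1 - mass(subset)`. Lengths are
log-normal (median 250, sdlog 0.5) clipped to [50, 1000], a typical protein
length scale. Generation is deterministic per seed down to the FASTA bytes.

This model exercises composition-driven separability (AAC, CTD composition)
and the full pipeline mechanics. It deliberately does **not** emulate
positional motifs, domain architecture, phylogenetic correlation, or
homology between train and test sets — so a high accuracy on synthetic data
demonstrates that the machinery recovers a planted compositional signal, not
that real R-gene recognition reaches that accuracy. Conversely the null
check (CV accuracy within the chance band at `effect = 0`) guards against
leakage anywhere in the feature/CV plumbing.

Problem sizes used by the automated checks were chosen to make the
statistics meaningful at desk scale: 200 + 200 sequences at `effect = 0.5`
for signal recovery (a strong, cleanly separable shift), 500 + 500 at
`effect = 0` for the null band (the binomial 3-sigma band on 1000 instances
is about +/- 4.7 points around 50%), and 10 families x 5 copies at 10%
mutation for clustering recovery.

## Numerical and design choices

* Percent scale everywhere in the 188-D descriptor (reference tables print
  percents); Pse-AAC is a probability vector.
* Transition denominator `L - 1`; a length-1 sequence reports zero
  transitions with a message rather than erroring, so batch extraction over
  heterogeneous inputs survives.
* Alignment scoring for identity: match 1, mismatch 0, linear gap 1 —
  identity-maximizing rather than similarity-maximizing; no substitution
  matrix, since the quantity of interest is exact identity.
* Tie-breaks: clustering order is (length desc, id asc), making results
  independent of input order.
* Under-sampling, CV folds, forest training and sequence generation each
  restore the caller's RNG state; all randomness flows through explicit
  seeds.
* Duplicate ids are errors everywhere (label joins must be unambiguous);
  conflicting pos/neg label sources are errors, not overwrites.

## Known limitations

* The descriptor registry fixes group *order* per property; alternate
  orderings of the same partition produce permuted (but equivalent)
  feature vectors, so models and features must come from the same registry.
* Greedy clustering approximates, but does not reproduce, the exact cluster
  membership of word-indexed tools on real data.
* The weighted-balancing path assumes a weight-aware learner; for the
  baseline learners without weight support the weights are currently
  ignored rather than emulated by resampling.
* Real-data accuracies reported for this method family were obtained on
  full curated corpora; nothing at synthetic desk scale estimates them.
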