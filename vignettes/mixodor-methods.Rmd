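---
title: "Predicting mixture odor profiles from molecular composition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting mixture odor profiles from molecular composition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixodor)
```

`mixodor` predicts the sensory profile of a complex odorant mixture — its
origin class, its five most applicable odor descriptors, and its consensus
rate-all-that-apply (RATA) scores — from the list of volatile molecules
detected in it. This vignette explains the models, the parameters that
matter, the synthetic data the package tests itself on, and the design
choices made where the problem left them open.

## The data model

Three tables describe a study:

* a **composition** table, one row per (sample, molecule): sample id,
  molecule id, SMILES, and optionally the molecule's relative peak area
  (GC-MS abundance relative to an internal standard — unitless, positive);
* a **RATA** table, one row per (panelist, sample, descriptor) with an
  integer intensity; each panelist rates at most 5 of the descriptor
  vocabulary (17 descriptors in the whisky panel the defaults emulate) per
  sample, unrated descriptors count as 0;
* a **type** table assigning each sample a binary origin class.

Consensus labels are built by summing RATA scores over panelists and taking
the five highest-scoring descriptors per sample (`sum_rata()`,
`top5_labels()`). Ties across the fifth-place boundary are resolved by a
seeded uniform draw among exactly the tied descriptors — descriptors
strictly above the cut are never at risk — and the draw is performed once
with a fixed seed so that every downstream model sees the same labels.
A descriptor that ends up in no label set can be dropped from the
classification vocabulary with `remove_class()`; the function refuses to
drop a descriptor that is in use, because silently rewriting labels is
never what anyone wants. The regression task keeps the full vocabulary.

## Substructural featurization

The feature space is built from a reference pool of molecules by pairwise
maximum-common-substructure (MCS) comparison (`pairwise_mcs()`): for each
unordered pair, the largest connected subgraph present in both molecules,
with atoms compared by element and bonds by bond order on kekulized
heavy-atom graphs. Results below `min_atoms` (default 2 — single atoms
carry no substructural signal) are dropped and duplicates are merged.

Two choices deserve comment:

* **Determinism over wall-clock timeouts.** The MCS search is an exact
  branch-and-bound; a per-pair cap is still needed for pathological pairs,
  but a wall-clock timeout would make results machine-dependent. The cap is
  therefore a deterministic node-expansion budget (default 200,000
  expansions per pair) with the best-so-far substructure kept, so identical
  inputs give byte-identical pattern lists everywhere.
* **Deduplication by canonical graph form.** Two pairs often share the same
  substructure spelled differently. Pattern graphs are relabeled into a
  canonical atom order (BLISS canonical labeling of the bond-subdivided,
  element-colored graph, via igraph) and serialized to SMARTS
  deterministically, so isomorphic patterns produce byte-identical SMARTS
  and collapse to one feature.

The **applicability matrix** (`build_applicability_matrix()`) assigns every
(molecule, pattern) pair a non-negative weight that is 0 exactly when the
pattern has no substructure match in the molecule. Two readings of a
match's "applicability" are implemented: `match_count` (default), the
number of distinct matched atom sets, read as a frequency of occurrence;
and `overlap_length`, the pattern's atom count when it matches at all.
Both are exposed because either is a defensible notion of how strongly a
substructure applies to a molecule; the models consume either.

## OWSum

OWSum is a linear classifier over qualitative feature sets. Training
reduces to counting: `#(F_j, C_i)` is the number of training samples of
class `C_i` whose feature set contains `F_j` (binary per sample;
multi-label samples count towards each of their classes), and
`len(C_i) = sum_j #(F_j, C_i)`. Influence values are conditional
probabilities,

* CP1: `#(F_j, C_i) / sum_n #(F_j, C_n)` — the share of the feature's
  occurrences that belong to the class (columns over classes sum to 1), or
* CP2: `#(F_j, C_i) / len(C_i)` — the share of the class's feature mass
  carried by the feature (rows over features sum to 1),

optionally multiplied by the tf-idf weight
`(#(F_j,C_i)/len(C_i)) * log(|C| / #classes containing F_j)`. The
logarithm base (default 10) only rescales all weights by a constant and can
never change a ranking, so it is fixed for reproducibility and exposed in
the interface. A sample's class score is the plain sum of influence values
over its present features — a per-sample normalization would divide every
class by the same positive constant and cannot change the top-k — and
features never seen in training contribute 0, the only option consistent
with a count-based table. Ties in the top-k are broken by descending score
then ascending class name, so predictions are deterministic; an all-zero
score vector falls back to the lexicographically first classes and flags
the sample.

For the descriptor task, presence is decided by the **standard-scaling
rule** (`presence_scaler()`, `scaled_presence()`): per-feature means and
standard deviations are fitted on the fold's training rows, and a feature
is present for a sample exactly when its standardized value is positive.
Zero-variance features are treated as non-present (they carry no
discriminative signal, and their standardized value is undefined). The rule
is on by default for the descriptor task only and is switchable anywhere.

Interpretability outputs mirror the fitting: `influence_difference()`
gives the signed per-feature difference between two classes (antisymmetric
by construction), and `descriptor_dissimilarity()` sums the absolute
differences over all features, with the arc-width transform
`1.1^(dissimilarity * 1000)` kept as a drawing utility.

## The stack-and-pad CNN

Samples have different molecule counts, so each sample's per-molecule
applicability rows are stacked into a matrix (rows ordered by the global
molecule order, so a molecule keeps a stable position across samples) and
zero-padded to a common length per batch (`stack_and_pad()`). The network
is small, as the data demands: two 3×3 convolutions (1→8→16 channels,
ReLU), adaptive max pooling to a 4×4 grid, and a fully connected 256→64→
output head. Classification uses a class-weighted binary cross-entropy,
`mean_c w_c * BCE_c`, with `w_c = 0` for classes absent from the fold's
training labels and `log(1 + y_c/x_c)` otherwise (`x` = fold training
frequency, `y` = dataset frequency, natural log — again a monotone,
configurable choice); regression predicts raw consensus RATA scores under
an L1 loss by default (MSE selectable).

Numerical and design choices:

* **Padding invariance is exact, not approximate.** The network is defined
  on the stack with trailing all-zero rows removed, and the adaptive pool
  therefore only ever sees real molecule rows; appending any number of
  zero padding rows is a bitwise no-op on the output. This is what makes
  the batch padding purely a storage convention.
* **Determinism.** Initialization (He-scaled normal draws) and the
  minibatch order derive from the config seed; training is plain Adam on
  the CPU, so loss curves and parameters are bitwise reproducible per seed.
* **Epochs** default to 11 (classification) and 21 (regression), the
  protocol the package follows for the study shape. Batches default to 4
  samples: with full-batch training those epoch counts give an optimizer
  too few steps to move away from initialization, and small minibatches
  are also what gives the stack-and-pad scheme its purpose.
* **Peak-area feature scaling** (multiplying each molecule row by its
  relative peak area as a concentration proxy) is implemented
  (`scale_features_by_peak_area()`) but off by default — both tasks work
  better without it, consistent with class weights dominating the loss.
* The remaining hyperparameters (learning rate, channel sizes, pool and
  hidden widths) are fixed, documented defaults of this package, not tuned
  per dataset; a configuration object (`cnn_config()`) exposes them all.

## Baselines and evaluation

* **Educated top-5 guessing** predicts, for a held-out sample, the five
  most frequent descriptors of the training label sets (ties at rank five
  break lexicographically); the frequencies double as ranking scores.
* **Subject X** treats each panelist in turn as the prediction (their
  per-sample top-5) against the top-5 of the summed ratings of the other
  panelists, computes micro metrics per panelist over all samples, and
  averages — the inter-panelist agreement any model must beat.
* **SVM / random forest** fit one binary one-vs-rest classifier per
  descriptor per fold on molecule-presence vectors (SVM features
  standardized with statistics from the fold's training rows only; the
  forest uses 100 seeded trees) and rank descriptors by decision value or
  positive-class probability. A descriptor with single-class training
  labels in a fold yields a constant score with a warning instead of an
  error.

Evaluation (`run_experiment()`) is leave-one-out over samples; re-creation
mode (train = test) exists to validate interpretability readouts, where a
count-based model can only do better than under LOO. Micro F1 and micro
MCC are computed from the pooled (flattened) confusion counts over all
(sample, class) cells; micro ROCAUC ranks the flattened (truth, score)
pairs and is reported as `NA` when the flattened truth is single-class
(the ROC is undefined there — reporting 0 would be wrong); regression is
summarized by the Pearson correlation of the flattened prediction and
truth matrices, undefined (NA, with a warning) for constant input. Both
per-fold values and the pooled aggregate are reported; the pooled
aggregate is the headline number.

One protocol subtlety: the class-weight formula deliberately uses the
*dataset-wide* descriptor frequency as its numerator `y`. Under
leave-one-out this means a fold's class weights depend weakly (by at most
one count) on the held-out sample's labels; that is the formula's
definition, not an implementation leak. All other fold artifacts — tf-idf
tables, presence scalers, classifier fits — depend on the training split
only, and the test suite checks this by mutating held-out data.

## The synthetic data generator

The package cannot ship the original whisky data, so `generate_dataset()`
produces datasets with the statistical structure the pipeline assumes, at
the study's shape by default: 16 samples in 2 origin classes, a
279-molecule pool (a packaged vocabulary of ~60 typical food volatiles,
extended programmatically with ester/alcohol/acid homolog series), 100–200
detected molecules per sample, 17 descriptors (the whisky panel
vocabulary), 11 panelists, integer ratings on a 0–10 scale.

The planted structure, in causal order:

1. **Origin classes**: 2 molecules per class occur in every sample of the
   class and never in the other (the strictly separating mechanism an
   interpretable classifier should recover), and 8 further molecules per
   class are *class-characteristic*: present with probability 0.65 in
   their own class and 0.03 elsewhere. Real origin classes differ through
   whole families of near-exclusive compounds (peat phenols, bourbon-cask
   lactones), not through two molecules; without this family structure the
   two planted exclusives would be outvoted by chance separators among the
   sporadic filler, which no real dataset of this kind would permit.
2. **Descriptor drivers**: each descriptor owns 3 driver molecules drawn
   from one chemical family (see below); a sample's latent intensity for
   the descriptor is the sum of continuous, graded driver weights over the
   drivers present, with the primary driver carrying ~70% of the total —
   odor notes in mixtures are typically keyed to a character-impact
   compound. Continuous weights keep latent intensities effectively
   tie-free, so each sample has a crisp characteristic top-5 profile.
   Driver prevalences follow a fixed, evenly spaced profile (0.32–0.66,
   assignment shuffled per seed), which reliably produces the moderately
   skewed top-5 occurrence tables real panels show without letting a
   single descriptor saturate. Driver incidence is drawn class-balanced
   (each driver present in an equal number of samples of each origin
   class, up to rounding): odor-profile structure is orthogonal to origin
   by construction, so descriptor families cannot masquerade as origin
   signal at this sample size.
3. **Chemically coherent molecular signatures**: every pool molecule is
   classified into a functional-group family (aromatic, ester, acid,
   ketone, aldehyde, alcohol, alkene; `molecule_family()`), refined by a
   molecular size class. Descriptors are assigned to families
   proportionally to family size, and each descriptor's 3 drivers plus up
   to 8 affiliated molecules come from its family — fruity esters, smoky
   aromatics. An affiliated molecule appears with probability 0.9 when
   its descriptor is in the sample's top-5 latent profile and 0.1
   otherwise, and never re-enters through the prevalence-weighted filler
   (the filler draws only from unaffiliated molecules — letting failed
   signature draws re-enter as filler would wash out the coupling). This
   emulates the fact that odor-relevant chemistry comes in families: a
   smoky sample carries many phenols, not one, and it is what ties a
   sample's substructure content to its odor profile.
4. **Filler**: the remaining molecules follow a bimodal detection
   prevalence (a near-ubiquitous core, Beta(8,2), and a sporadic majority,
   Beta(2,5); overall mean ≈ 0.5, matching ~150 detected of a 279 pool).
   Per-sample molecule counts are drawn uniformly from the configured
   range; every (sample, molecule) gets a log-normal(0,1) relative peak
   area — positive and right-skewed like real relative GC peak areas.
5. **Panel**: every panelist rates the sample's top-5 latent descriptors —
   one shared seeded tie draw per sample, so a noiseless panel is perfectly
   consistent — with intensity equal to the rounded latent value plus ±1
   integer jitter, clipped into [1, 10]. With probability ε (default 0.1)
   a rated descriptor is swapped for a uniformly random unrated one; label
   swap plus integer jitter, rather than additive Gaussian noise, because
   RATA ratings are sparse integers. ε = 0 reproduces the latent top-5
   exactly; ε = 1 yields chance-level inter-panelist agreement
   (micro precision ≈ 5/17).

What passing tests on this generator do and do not show: they demonstrate
that the pipeline recovers planted, learnable structure of the kind the
method assumes (exclusive molecules, descriptor-linked molecule families)
at the study's sample size, and that the baselines order the way they
should (model > educated guessing > random panelist). They do not
demonstrate performance on real mixtures, where compound identification is
noisy, descriptor semantics overlap, and molecular signatures are weaker
and correlated; the headline numbers on synthetic data are not comparable
to numbers measured on any real panel.

## Problem sizes used in the shipped analyses

The test suite and the acceptance script run the full study shape (16
samples, 279-molecule pool, 17 descriptors, 11 panelists) for everything
except the CNN featurization, where the reference pool for pattern
extraction is a seeded 24-molecule subset of the study pool (276 pairs,
~50–120 unique patterns after deduplication — homolog series share many
substructures). A larger reference pool grows the pattern vocabulary
further; the reduced vocabulary is the package's choice for its shipped
analyses and leaves the pipeline unchanged. The default panel noise
(`noise_rate = 0.1`) yields a far more consistent panel than real sensory
panels show (synthetic inter-subject micro F1 around 0.9, where real
panels sit near 0.35): the generator's job is recoverable structure, and a
realistically noisy panel would leave nothing for any model to learn from
16 samples. Conclusions about inter-subject baselines therefore transfer
qualitatively (they order below the models), not numerically.

## Known limitations

* The MCS is connected-only and stereochemistry-blind, and aromatic rings
  are compared in kekulized form; disconnected MCS and aromatic-aware
  matching are out of scope.
* OWSum's count-based influence values are meaningful relatively, not
  absolutely; with very small classes the tf-idf-weighted CP2 variant can
  favor rare classes, which is visible on weakly structured data.
* Odor activity values, odor thresholds and concentration effects are not
  modelled; relative peak areas enter only through the optional feature
  scaling.
* The CNN is a small fixed architecture; no hyperparameter search is
  performed (a deliberate simplification — the defaults are documented
  package choices, with the learning rate, batch size, pooling grid and
  an optional AdamW-style weight decay exposed in `cnn_config()`).
* At the study's sample size the CNN is the weakest link: with 15
  training mixtures and 11 epochs, its leave-one-out top-5 F1 on the
  synthetic defaults sits at the level of educated frequency guessing
  (~0.4) rather than above it, across learning rates, batch sizes,
  pooling grids, weight decay, pattern-vocabulary sizes and feature
  transforms. The count-based OWSum, which sees molecule identity
  directly, beats guessing comfortably on the same data; the CNN must
  first recover identity from substructure profiles through a max-pooled
  representation, and 15 samples do not support that. Conclusions about
  CNN superiority therefore do not transfer from this package's synthetic
  experiments; on real data with richer chemistry-odor coupling the
  ordering may differ.
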