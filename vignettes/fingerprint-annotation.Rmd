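---
title: "Predicting molecular fingerprints from MS/MS spectra for metabolite annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting molecular fingerprints from MS/MS spectra for metabolite annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Untargeted LC-MS/MS metabolomics produces fragment spectra for thousands
of features, but spectral libraries cover only a fraction of known
metabolites, so direct spectrum matching fails for most of them. An
alternative is to learn the relationship between a fragment spectrum and
the *molecular fingerprint* of the compound that produced it — a binary
vector encoding presence or absence of substructures. A predicted
fingerprint can be compared against the computed fingerprints of
candidate compounds retrieved from a database by precursor mass (or
molecular formula), and the candidates ranked by similarity. Annotation
then works even for compounds with no library spectrum at all.

`specfp` implements this pipeline end to end: spectral-library I/O,
spectral preprocessing into fixed-length binned vectors, a
one-dimensional convolutional network (plus classical baselines) that
predicts a 528-bit composite fingerprint, mass- and formula-based
candidate retrieval, Tanimoto ranking, and structure-disjoint
evaluation. A synthetic-corpus generator with a planted
fingerprint-to-spectrum mapping makes every stage testable without any
proprietary library.

## The fingerprint

The target is the concatenation of three OpenBabel fingerprint systems —
MACCS structural keys (166 bits), FP3 SMARTS patterns (55 bits) and FP4
SMARTS patterns (307 bits) — giving 528 binary outputs. Segment lengths
are enforced regardless of backend padding (OpenBabel returns vectors
padded to 32-bit words; position *i* corresponds to native key *i*, which
we verified on reference structures such as benzene, whose set MACCS keys
are 162/163/165 — aromatic, six-ring, ring).

Two scores compare a predicted fingerprint with a computed one. With
position-wise counts TP, FP, FN, TN,

$$\mathrm{Tanimoto} = \frac{TP}{TP + FP + FN}, \qquad
  F_1 = \frac{2\,\mathrm{precision}\cdot\mathrm{recall}}
             {\mathrm{precision} + \mathrm{recall}},$$

where precision is $TP/(TP+FP)$ and recall $TP/(TP+FN)$. The Tanimoto
form deliberately ignores both-zero positions: fingerprints are ~90%
zeros, and counting shared zeros would saturate the score. Both metrics
return 0 (with a degeneracy flag) on all-zero inputs rather than failing,
so batch ranking never aborts.

## Preprocessing

The cleaning chain runs in a fixed order: **select** (instrument type in
{Orbitrap, QqQ, Q-TOF, IT}) → **scale** → **filter** → **merge**
(training only) → **bin**.

* *Scaling.* Intensities are max-normalised to `[0, 100]`
  (`x -> x / max(x) * 100`). We read "min–max scaling between 0 and 100"
  with an implicit minimum of zero: a literal $(x-\min)/(\max-\min)$ map
  would zero the smallest real peak in every spectrum and interact
  destructively with the relative-intensity filter below.
* *Filtering.* Peaks above the precursor m/z are removed first (they are
  artefacts), then a spectrum is kept only if at least 5 peaks exceed 2%
  relative intensity — measured against the base peak *after* the
  precursor rule, so a spurious high-mass peak cannot mask real signal.
  The neutral mass implied by precursor and adduct (falling back to the
  recorded exact mass) must lie in 100–1010 Da.
* *Merging.* Training spectra of the same compound (same full InChIKey)
  are pooled into one consensus peak list; coincident peaks (same integer
  bin) accumulate, and the result is re-scaled. Evaluation spectra are
  *never* merged — performance is reported per individual spectrum.
* *Binning.* The m/z axis is cut into unit bins $[b, b+1)$ and peak
  intensities accumulate within bins (`floor` convention). The default
  grid of 1174 bins starting at m/z 1 reproduces the canonical model
  input width; both start and count are configurable. In-range intensity
  is conserved exactly, which the tests check against a naive
  double-loop accumulator.

For the flat baseline models, bins that are zero across the whole
training matrix are removed (they carry no information); the
convolutional model keeps all bins because convolution needs a
consecutive axis.

## The network

The predictor is a 12-layer one-dimensional CNN: embedding → conv →
maxpool → conv → maxpool → dropout → flatten → four dense ReLU layers →
528 sigmoid outputs, trained with mean binary cross-entropy and Adam.
All 528 bits are predicted simultaneously by one network — a multi-label
formulation, hence sigmoid + binary cross-entropy rather than softmax.

No deep-learning framework is involved: the layers, backpropagation and
Adam are implemented in R directly on BLAS matrix products (convolution
via an im2col index), and the gradients of every layer type are verified
against finite differences in the test suite. A fixed seed makes weight
initialisation, shuffling and dropout masks bit-reproducible.

Two design points deserve an explicit rationale:

* *How intensities enter the embedding.* An embedding layer consumes
  integer tokens, so scaled intensities are quantised to 0–100 (vocabulary
  101). Nearby intensities are distinct tokens, which a randomly
  initialised embedding treats as unrelated symbols; at small corpus
  sizes that is a real handicap. We therefore initialise the first
  embedding channel as a linear ramp in the token value — an untrained
  embedding already encodes the intensity ordering, and the remaining
  channels are free to learn token-specific structure. A
  `use_embedding = FALSE` switch replaces the embedding with a raw
  intensity channel (scaled to `[0, 1]`) for users who prefer the
  continuous reading; both interpretations are kept because the original
  architecture is ambiguous on this point.
* *Output-bias initialisation.* With 528 outputs at ~10% prevalence,
  a cold-started network spends many epochs learning base rates. The
  output bias is initialised at the per-bit base-rate logit (standard
  practice for imbalanced multi-label problems); disable with
  `init_output_bias = FALSE`.

Hyperparameters that the original description leaves open (filter
counts, kernel widths, pool sizes, dense widths, epochs, batch size) are
documented defaults in `cnn_config()`, sized so that the desk-scale
benchmark below trains in minutes on one CPU core: 16/32 filters of
width 5, pooling 2, dropout 0.5, dense widths 256/128/64/64, batch 32,
100 epochs at learning rate 3e-3 (slightly above the usual Adam default —
with only eight minibatches per epoch the larger step is what makes the
documented epoch budget sufficient).
Nothing is hard-coded; pass a different `cnn_config()` to scale up.

### Baselines

`build_baseline()` provides the four classical multi-label reference
models: per-bit logistic regression (`stats::glm.fit`), a single dense
sigmoid layer (SLP), a multilayer perceptron, and per-bit linear support
vector machines (`e1071::svm`). The gradient-trained kinds reuse the
package's own dense-layer engine; all consume the zero-bin-reduced
input.

### Instrument context and the three strategies

Spectra are heterogeneous in collision energy, mass resolution and
polarity. `resolve_context()` reduces each record to three binary
factors — energy (split strictly at 30 eV), resolution (Orbitrap and
Q-TOF high; ion trap and QqQ low) and ionization mode — defining eight
context cells. `fit_strategy()` implements three ways to use them:

1. `single` — one network on the plain 1174 bins;
2. `single_with_context` — one network on 1177 inputs, the bins plus
   three appended binary context entries (order: energy, resolution,
   mode);
3. `eight` — one network per populated cell, with prediction-time
   routing by each query's own context. Cells below a minimum occupancy
   are skipped; queries from a missing cell fall back to the nearest
   populated cell, matching mode first, then resolution, then energy
   (mode changes fragmentation chemistry most, energy least — hence the
   priority).

Records with no parseable collision energy are routed as low energy by
default (configurable): vendor strings expressing *normalised* collision
energy (NCE percentages) are deliberately not converted to eV, because
the conversion requires instrument calibration; numeric ranges such as
"20-40" collapse to their mean.

## Candidate retrieval and ranking

Candidates come from a local compound table (id, InChIKey, SMILES,
formula, monoisotopic mass) rather than a web service, removing network
dependence; export such a table from any database. A compound is a
candidate when, under at least one mode-compatible adduct
([M+H]+, [M+Na]+, [M+NH4]+, [M−H]−, [M+Cl]− by default, user-extensible),
the implied neutral mass lies within 20 ppm of the compound's
monoisotopic mass. If the query's molecular formula is known the list is
further restricted to formula-identical compounds (element-multiset
comparison, so `C6H12O6` equals `H12C6O6`).

Candidates are ranked by Tanimoto similarity between the predicted
fingerprint and each candidate's computed fingerprint. Ties break
deterministically — smaller mass error first, then lexicographic
InChIKey — so runs are exactly reproducible. Top-*k* accuracy asks
whether the true compound appears in the first *k* entries, matching at
the InChIKey first-block level (the 14-character 2D-skeleton hash), the
same granularity used for structure-disjoint splitting.

## Structure-disjoint evaluation

Fingerprint predictors memorise skeletons easily, so train/test splits
and cross-validation folds operate on InChIKey first blocks: no skeleton
ever appears on both sides. `evaluate_annotation()` reports mean
per-spectrum F1 and Tanimoto (per-compound aggregation is available by
flag) and top-*k* tables under two denominators — all queries, and only
queries whose candidate list contains the true compound — because a
retrieval miss and a ranking miss are different failures. Whether the
original 5-fold protocol was structure-disjoint within training is not
stated; we default to the stricter choice and expose
`structure_disjoint = FALSE` in `make_folds()` for the naive variant.

## The synthetic benchmark

Real training corpora (NIST 20, MoNA) are proprietary or large; the
package instead ships a generator whose defaults define a fixed,
desk-scale study:

* **300 compounds**, random 528-bit fingerprints at 10% per-bit
  prevalence (real metabolite fingerprints carry ~40–60 set bits),
  synthetic InChIKeys, monoisotopic masses 300–1000 Da arranged in
  clusters of 8 near-isobars within the 20 ppm retrieval window — half
  of the clusters isomeric (identical mass and formula) — so candidate
  lists average ~8 entries and formula filtering genuinely shortens
  them.
* A **planted mapping** assigning each fingerprint bit 2 m/z bins in
  50–280 (below every precursor), several bits per bin allowed — the
  decoding task is deliberately non-trivial. Each bit–bin pair carries a
  fixed lognormal intensity level (median 40): fragment abundances are
  reproducible properties of a fragmentation channel, and co-produced
  fragments accumulate.
* **5 spectra per compound** across all eight instrument contexts, with
  additive Gaussian intensity noise (SD 5), 10% bin dropout, and a 3 ppm
  precursor measurement error — so the recorded mass error is not a
  covert identity oracle and ranking has to come from the fingerprints.
* An 80/20 structure-disjoint split; the compound table doubles as the
  candidate database.

What this emulates: the bin-level statistical association between
fragments and substructures, intensity variability, instrument-context
heterogeneity, near-isobaric candidate confusion. What it does not:
real fragmentation chemistry (neutral losses, isotope envelopes),
long-tail intensity distributions, library metadata errors. Passing the
recovery tests therefore demonstrates that the pipeline and learner work
as specified — not that the shipped defaults reach any particular
accuracy on real libraries.

With ~240 merged training spectra the network sits far below the data
scale the original protocol assumed (hundreds of thousands of spectra);
structure-disjoint generalisation at this size is measurably above the
all-zero and prevalence baselines, but modest in absolute terms, and the
noiseless, collision-free variant of the generator is decoded exactly by
the oracle decoder (`decode_planted()`), which pins down the
information-theoretic ceiling of the design. The acceptance script
(`scripts/acceptance.R`) re-runs the whole benchmark — generation,
preprocessing, training, annotation, evaluation — from one seed in
roughly a quarter of an hour on a single core.

## Numerical choices and degenerate inputs

* Binarisation threshold 0.5 (probabilities ≥ 0.5 set the bit); exposed
  everywhere as `threshold`.
* Binary cross-entropy is clipped at $10^{-7}$ for numerical stability;
  a non-finite loss aborts training with a diagnostic rather than
  continuing silently.
* All-zero spectra, all-zero fingerprints, empty candidate lists and
  empty context cells all degrade to flagged results, not errors.
* Max pooling drops a trailing remainder position (floor semantics),
  matching the common framework behaviour.
* `structure_disjoint_split()` moves whole skeleton blocks, so the
  realised training fraction deviates from the target by at most the
  largest block; the tests bound this at ±0.1 for the benchmark sizes.

## Known limitations

* The fingerprint backend is OpenBabel; RDKit MACCS keys differ slightly
  in several positions and are not interchangeable.
* The CNN engine is plain R on BLAS: fine at desk scale (thousands of
  spectra), not intended for hundreds of thousands.
* Formula parsing covers plain Hill-style formulas without parentheses,
  charges or isotope labels.
* NCE-percentage collision energies are treated as unavailable rather
  than converted; spectra carrying only NCE route to the default energy
  cell.
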