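---
title: "Kernel-based metabolite identification with fingerMS: models, parameters and design choices"
author: "fingerMS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-based metabolite identification with fingerMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fingerMS)
```

## Overview

fingerMS identifies small molecules from tandem mass spectra in two stages:
a bank of kernel SVMs predicts a binary substructure fingerprint from the
MS/MS spectrum, and candidate molecules from a user-supplied database are
ranked by how likely their database fingerprints are to have generated the
prediction. This vignette documents the underlying models, every tunable
parameter that matters, the numerical choices, what the synthetic data
generator does and does not emulate, and the known limitations.

## The spectrum model and the probability product kernel

A mass spectrum is a set of peaks $\chi = \{(\mu_k, \iota_k)\}_{k=1}^{l_\chi}$
with intensities normalized to sum to one. Measured peak positions are noisy,
so each peak is modelled as a two-dimensional Gaussian centred at the
measurement with a covariance $\Sigma = \mathrm{diag}(\sigma_m^2, \sigma_i^2)$
shared by all peaks, and the spectrum as the *uniform mixture* of its peak
Gaussians. The similarity of two spectra is the probability product kernel —
the inner product of the two mixture densities:

$$K_{peaks}(\chi, \chi') = \frac{1}{l_\chi l_{\chi'}}
  \sum_{k}\sum_{k'} \int
  \mathcal{N}(x;\chi(k),\Sigma)\,\mathcal{N}(x;\chi'(k'),\Sigma)\,dx,
  \qquad
  \int \mathcal{N}(x;p,\Sigma)\mathcal{N}(x;q,\Sigma)\,dx
  = \mathcal{N}(p-q;0,2\Sigma),$$

evaluated entirely in closed form (`peakPairIntegral()`), with no numerical
integration. Mixture weights are not prescribed by the underlying model
description; we use uniform weights $1/l_\chi$ so the spectrum is a proper
probability density, which yields the $1/(l_\chi l_{\chi'})$ prefactor.

Two alternative peak representations reuse the same machinery:

* **mloss** — each fragment is replaced by its neutral loss
  $\mu_{prec}-\mu_k$ against the precursor, capturing the cleaved portion.
  Fragments *above* the precursor produce negative losses; they indicate
  adduct or isotope peaks above the assumed precursor and are dropped with a
  warning rather than reflected. A fragment exactly at the precursor maps to
  a zero loss, retained at a tiny positive epsilon because the container
  requires positive masses.
* **diff** — a pseudo-spectrum of all pairwise peak differences: for each
  unordered pair $i<j$ a pseudo-peak at $(\mu_j-\mu_i,\ \iota_i\iota_j)$.
  The intensity coordinate of a difference is not uniquely defined by the
  model; the product $\iota_i\iota_j$ was chosen because it is symmetric in
  the pair and automatically down-weights combinations involving noise
  peaks. This representation has $\binom{l}{2}$ pseudo-peaks — quadratically
  more than the other two variants — which is its documented cost.

Each variant is cosine-normalized, $\tilde K(x,y) = K(x,y)/\sqrt{K(x,x)K(y,y)}$,
before combination, because raw values scale with $1/(\sigma_m\sigma_i)$ and
with peak counts; normalization puts all variants on the common $(0,1]$
scale. `gramMatrix()` averages the normalized variants (rather than summing)
so that a normalized square Gram has diagonal exactly one regardless of how
many variants are active; positive semidefiniteness is unaffected by the
positive scaling. The default combination `peaks + mloss` is the recommended
general-purpose choice; `diff` is available but costs quadratically more.

### Kernel parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `sigmaMass` | mass sd of the peak Gaussian (Da) | 0.01 | high-resolution instruments; use ~0.5 for nominal-mass data |
| `sigmaIntensity` | intensity sd (sum-to-one scale) | 0.05 | typical relative-intensity variation after normalization |
| `variants` | kernel variant set | `peaks`, `mloss` | best accuracy/cost balance |
| `normalize` | cosine normalization | `TRUE` | makes variants commensurable |

Both sigmas can instead be *estimated from replicate spectra*
(`estimatePeakVariances()`): peaks of replicates of the same molecule are
greedily matched to the first replicate within a coarse 0.5 Da tolerance and
the pooled within-cluster variances are used, floored at $10^{-4}$ Da and
$10^{-3}$ so that identical replicates cannot produce a degenerate kernel.

Intensity normalization is sum-to-one throughout. This is a deliberate
choice: the mixture model gives intensities probability semantics, and the
same convention is applied to simulated isotope envelopes so MS1 and MS2
handling agree.

## Fingerprints

Molecules are encoded as ±1 vectors over 528 substructure keys — the
OpenBabel families FP3 (55), FP4 (307) and MACCS (166) concatenated in a
frozen order. OpenBabel reports word-padded bit vectors (64/512/256 bits);
only the documented leading bits of each family are kept. Bits that take a
single value across all training molecules carry no information and are
masked out (`effectiveBitMask()`); the mask travels with the model. A hash
of the ordered key names is stored in every model bundle and candidate
table, and retrieval refuses to run when the hashes disagree — bit order can
never silently differ between a model and a database.

Labels are coded ±1 (not 0/1) to match the SVM formulation directly. The
fingerprint similarity utility is the Tanimoto coefficient on positive-bit
sets; two all-negative vectors are defined to have similarity 1 (identical
empty sets) with a logged message.

## Per-bit SVMs, C selection and reliability scores

One soft-margin SVM is trained per effective bit on the precomputed Gram
matrix. The dual is solved by kernlab's SMO; the package stores the products
$\alpha_{ij}y_{ij}$, the support indices and the bias, so prediction is an
explicit kernel expansion owned by the package. The classical SVM decision
function includes a bias term and we keep it, even though the compact
expansion formula is often written without one. A decision value of exactly
zero maps to +1 (a fixed, documented tie rule). Bits whose training labels
are single-class are represented as constant predictors rather than dropped,
keeping the predicted vector length stable across folds.

The cost C is selected per bit from the grid $2^{-5},\dots,2^{10}$ by
*grouped inner cross-validation* within the training partition (5 inner
folds by default), with ties broken toward the smaller C. Whether C should
be selected on inner folds or on the outer training fold directly is
genuinely ambiguous; inner grouped CV was chosen because it never evaluates
C on data used for the final fit of that fold.

Reliability scores $w_j$ are the held-out accuracies of a 10-fold
molecule-grouped cross-validation: *all spectra of one molecule are confined
to the same fold*, because spectra of the same compound at different
collision energies are highly correlated and splitting them across folds
inflates accuracy. $w_j$ is plain accuracy, not balanced accuracy — with
imbalanced bits a constant predictor can reach the majority fraction, which
is the appropriate observation probability for the scoring model below, but
users should be aware that a high $w_j$ on a 95/5 bit is not evidence of
discrimination. Bits evaluable in no fold fall back to the uninformative
$w_j = 0.5$.

All fold assignments derive from a single integer seed; molecules are
shuffled and dealt round-robin, which balances molecule counts per fold to
within one.

## Candidate scoring

Given the predicted fingerprint $\hat y$ and reliabilities $w$, a candidate
with database fingerprint $y$ scores

$$\log P(\hat y \mid y) = \sum_j \big[\, [y_j = \hat y_j]\log w_j +
 [y_j \neq \hat y_j]\log(1-w_j) \,\big].$$

This treats each bit as an independent observation channel with accuracy
$w_j$; summed over the $2^m$ possible predictions the probabilities add to
one exactly, a property the tests verify exhaustively for $m \le 12$.
Scores are computed and kept in log space — products over hundreds of bits
underflow double precision. Reliabilities are clipped into
$[10^{-6}, 1-10^{-6}]$ so $w_j \in \{0,1\}$ cannot produce infinite scores.
Masked (ineffective) bits are excluded from scoring entirely.

Candidates are first filtered by a ppm mass window
$|m_{cand}-m|/m \cdot 10^6 \le \text{ppm}$ around the neutral exact mass.
When the mass is not given it is estimated from MS1 as the most abundant
peak minus the proton mass ($m_p = 1.007276466$ Da) in positive mode (plus
$m_p$ in negative mode); ties on maximal abundance go to the lower mass
because the monoisotopic peak precedes its isotope peaks. Only the
protonation adducts [M+H]+ / [M−H]− are assumed — other adducts (e.g.
[M+Na]+, [M+2H]2+) occur in practice, and since no general selection rule
exists the exact mass is exposed as an input so callers can override the
assumption.

Ranking ties (identical fingerprints give identical scores) are broken by
ascending molecule identifier: ties are real and expected, and a
deterministic rule is required for reproducibility and testing.

## Isotope patterns

For an element with $r$ stable isotopes, $l$ atoms generate
$\binom{l+r-1}{r-1}$ isotopologues whose abundances follow the multinomial
distribution over the natural isotope abundances; molecule patterns are the
convolution of the per-element patterns (masses add, abundances multiply).
The isotope table (CHNOPS + Na, Cl, K) is embedded as a constants table —
no network lookups — and can be overridden from a YAML file. Entries closer
than `mergeTol` (default $10^{-4}$ Da, the high-resolution regime) are
merged by abundance-weighted mean mass; entries below `pruneBelow` (default
$10^{-5}$) are pruned and the pattern renormalized. Intermediate convolution
steps prune at one thousandth of the final threshold so the result is exact
to well within the requested precision; with `pruneBelow = 0` the pattern is
exact and its abundances sum to one to $10^{-9}$.

Matching against an observed MS1 envelope converts the pattern to a
spectrum (adduct shift by the same proton constant, abundances sum-to-one
normalized — the same convention as MS2 intensities) and evaluates the
cosine-normalized peaks-variant kernel, giving a score in $(0,1]$. The mass
sigma for MS1 matching is a separate configuration value
(`isotope_sigma_mass`) defaulting to the MS2 value, since MS1 accuracy may
differ by instrument. Fingerprint and isotope rankings are fused by average
rank, minimum rank, or isotope-first reranking in which isotope-score ties
(molecules sharing a formula share a pattern) are broken by the fingerprint
score.

## The synthetic world

`generateToyWorld()` creates self-contained validation problems: molecules
with ±1 fingerprints, CHNO formulas whose monoisotopic mass (from the
embedded table) is the exact mass, and fragment spectra in which **every +1
bit plants a characteristic fragment peak at a bit-specific mass**. This
makes bits statistically learnable from spectra by construction, giving the
SVM layer a recoverable signal without any real training data. Key
generator conditions:

* bit masses spread over 60–150 Da with spacing far above the kernel's mass
  sigma; per-bit +1 fractions drawn in [0.3, 0.7], so every bit passes the
  effective-bit mask; fingerprint rows are perturbed until unique and every
  molecule has at least one positive bit;
* each molecule also carries a few uninformative decoy peaks; each of the
  `spectraPerMolecule` simulated collision energies keeps a random subset of
  planted (85%) and decoy (60%) peaks;
* masses get Gaussian jitter (default sd 0.003 Da) and intensities
  log-normal jitter (sd 0.1);
* all sampling runs through one seeded generator; regeneration with the
  same seed is bit-identical and the global RNG state is restored.

What the generator does **not** emulate: real fragmentation chemistry
(neutral-loss series, rearrangements), correlated bits, mass-dependent
noise, adducts other than [M+H]+, isotope peaks inside MS/MS spectra, and
the long-tailed candidate multiplicities of real databases. Passing tests
on toy worlds therefore demonstrate the correctness and statistical sanity
of the pipeline, not field performance on biological samples.

## Evaluation utilities and problem sizes

`learningCurve()` reproduces the training-size analysis: per outer fold,
increasing fractions of the remaining molecules are used for training, and
held-out bit error plus the mean relative rank (rank of the true molecule
divided by candidate count) are reported. Ranking inside this experiment
uses a uniform reliability of 0.75 per bit so the rank metric isolates
predicted-fingerprint quality from reliability estimation.
`energyPoolingAccuracy()` compares training on a single simulated collision
energy against pooling all energies, evaluated on the same held-out split.

The shipped tests and the acceptance script run these experiments at sizes
chosen to make the qualitative properties clearly observable while keeping
a full run in the minutes range on one core: 100 molecules × 20 bits ×
2 spectra for the learning curve (training fractions 20/60/100%, 10 outer
folds, fixed C = 1 — the full C grid is the production default but adds
nothing to a monotonicity check on planted signal), 40 molecules × 3
energies × 5 seeds for the pooling comparison, and 200 candidates over 12
bits for retrieval recovery. The 12-bit choice is deliberate: 200 unique
fingerprints among 4096 possible configurations populate the space densely
enough that each step of the reliability sweep (w = 0.6, 0.8, 0.95, 1.0)
visibly moves the mean rank; in a sparse 32-bit space the rank saturates at
1 long before w reaches 1 and the sweep would be uninformative.

## Numerical choices

* Proton mass fixed at 1.007276466 Da in one constants table used by mass
  estimation, loss transforms and isotope shifts alike.
* Carbon isotope abundances use the classical 98.890%/1.110% values; other
  elements use standard IUPAC terrestrial values.
* Duplicate peak masses are merged (intensities summed) at construction, so
  spectra always have strictly increasing masses.
* The SMO termination tolerance defaults to $10^{-4}$; Gram symmetry is
  exact by construction, PSD is asserted to
  $\lambda_{min} \ge -10^{-9}\,\mathrm{tr}(K)/n$.
* Model bundles are plain text with numbers at 15 significant digits and no
  timestamps, so retraining with the same seed reproduces a bundle byte for
  byte.

## Known limitations

* Only singly-charged protonation adducts are modelled; multiply charged
  species and adduct selection are out of scope.
* The fingerprint vocabulary is fixed to the three OpenBabel families;
  richer fingerprint sets would reduce database fingerprint collisions
  (many real molecules share a 528-bit fingerprint).
* Bits are scored as independent observation channels; dependencies between
  substructure keys are ignored by the Poisson-binomial model.
* Accuracy-based reliabilities conflate class imbalance with predictability
  (see above).
* The isotope simulator uses the multinomial/convolution model without
  fine-structure resolution and assumes charge 1.
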