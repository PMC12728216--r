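---
title: "Methods and design choices in metalloscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in metalloscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalloscreen)
```

`metalloscreen` models the data-analysis half of a Direct-to-Biology
metal-complex discovery campaign. This vignette records the models, the
conventions, and the places where the design was genuinely open — and what
the synthetic-data generators do and do not establish.

## Combinatorial bookkeeping

Triazole ligand formation is represented as exact integer element
accounting: an amine R–NH₂ is converted in situ to the azide R–N₃ (two
hydrogens leave, two nitrogens arrive) and cycloaddition with the alkyne
conserves everything else, so

> ligand = amine + alkyne + 2 N − 2 H.

This identity is enforced, not assumed: every enumerated ligand is checked
against its parents in the tests, and a hydrogen underflow (an amine with
fewer than two hydrogens) is an error. Complex cations are
`fragment + ligand + axial` with the fragment compositions
[Ir(ppy)₂]⁺, [IrCp\*Cl]⁺, [Ru(p-cymene)Cl]⁺, [Re(CO)₃]⁺/[Mn(CO)₃]⁺ (the
latter two with a 1-methylbenzimidazole axial ligand, C₈H₈N₂). The
compatibility matrix — Tz-4-P to all five scaffolds, Tz-1-MP only to IrCp\*
and RuCy — reflects which couplings actually proceed; incompatible pairs
are skipped, not errors.

The shipped registries contain the building blocks identifiable from the
campaign description; the remainder are *placeholders* with chemically
plausible formulas, flagged `placeholder = TRUE`. Every count (96, 96, 192,
480, 672, 384) and every pipeline behaviour is independent of the
placeholder identities; only per-compound masses depend on them, and those
are exercised against the registry actually supplied.

## Masses and isotope patterns

The monoisotopic mass is the sum of most-abundant-isotope masses — for
polyisotopic metals (¹⁰²Ru, ¹⁹³Ir, ¹⁸⁷Re) this is the envelope's anchor
rather than the lightest isotopologue, which is what target-ion matching on
an ion trap wants. Ion m/z subtracts one electron mass (0.000549 Da) per
charge; at ±0.5 Th matching tolerance this is cheap correctness.

Isotope patterns are built by per-element convolution of the shipped
IUPAC-2021 table, using binary exponentiation on atom counts so large H/C
counts stay cheap. Numerical choices:

- centroids closer than `merge_width` (default 0.01 Th) merge into
  abundance-weighted centroids;
- peaks below `prune` (default 1e-4) of the base peak are dropped, but the
  base peak itself is never pruned and is pinned at exactly 100 to absorb
  floating-point drift;
- a relative floor of 1e-12 inside the convolution bounds intermediate peak
  growth.

The tests compare the engine against brute-force isotopologue enumeration
(every atom independently picks an isotope) for formulas with at most six
polyisotopic atoms, aggregating both spectra to nominal-mass clusters
before comparing: the aggregation removes any dependence on merge
tie-breaking between the two independent code paths, which would otherwise
dominate a 1e-6 comparison.

Expected ion species follow the per-scaffold rule seen in practice: every
complex is matched on [M]⁺; IrCp\* complexes are additionally matched on
the MeCN adduct [M − Cl + C₂H₃N]²⁺ and reported as the aggregate of both.
Other solvent adducts (for example Mn solvento species) are not matched by
default but can be supplied through `expected_ions(extra = ...)`.

## LC-MS characterization

Peak picking is deliberately simple and fully documented, because the
upstream description of the instrument scripts does not pin a model:
moving-average smoothing (5 points), local maxima above a robust noise gate
(baseline median + 3 × a first-difference MAD noise estimate) and above 1%
of the global maximum, bounds at flanking minima or the baseline crossing,
and trapezoidal integration of the *raw* signal above a straight local
baseline. Conversion is area-percent at 254 nm:

- `area` — matched area / all UV peak area;
- `aggregate` — the same after summing several matched species (IrCp\*);
- `normalized` — matched area / area of MS-identified peaks only. This is
  our reading of "normalized to 100%" for the weakly UV-absorbing RuCy
  libraries: renormalization over identified peaks, excluding unassigned
  area. It is an interpretation, and it is confined to one mode flag.

Peaks below 1% of the tallest peak are excluded from totals as integration
noise (configurable). Retention-time matching between EIC and UV apexes
uses a 0.1 min window, ties broken toward the larger UV peak and flagged
`multiple-candidates`; unmatched targets are flagged `not-found` and score
a conversion of 0.

## Plate analytics

*Dilution grids.* Concentration reporting follows the printed convention:
round half away from zero to two decimals at ≥ 0.1 µM, to two significant
figures below. This reproduces every printed grid value (3.125 → 3.13,
0.78125 → 0.78, 0.195 → 0.20, 0.0488 → 0.049), where a flat
three-significant-figure rule would not (it would print 0.781). The raw
power-of-two grid remains available (`report = FALSE`).

*MIC.* "Complete inhibition" is operationalized as growth ≤ 10% of control
— the threshold is configurable since no numeric definition is given
upstream. The call is the *highest contiguous inhibited block* rule: the
MIC is the lowest concentration inhibited with every higher concentration
also inhibited, which resolves non-monotone series (an isolated inhibited
well below a growing one does not set the MIC) and makes the MIC monotone
under added high-concentration inhibition. Replicates are averaged before
calling; per-replicate calls remain available by calling per replicate.

*Dose-response.* The 4PL model is
`resp = bottom + (top − bottom)/(1 + (ec50/c)^hill)`; the sign of `hill`
encodes direction, so viability (decreasing) and normalized haemolysis
(increasing) use one parameterization. Initialization takes the asymptotes
from the response extremes, the EC50 from the half-range crossing, and
|hill| = 1; optimization is bounded L-BFGS-B on `(bottom, top, log ec50,
hill)`. Flat responses (range < 2% of scale) are flagged `failed` rather
than fitted. `ec_at()` inverts the fitted curve analytically; the analytic
identity HC50 = 50, hill = 1 ⇒ HC10 = 50/9 = 5.56 µM is a frozen test.

*Therapeutic index.* TI = min(CC50, HC10)/MIC, with a censored HC10
entering as +∞ and rounding half away from zero (7.3/0.20 = 36.5 → 37 —
banker's rounding would print 36). TI arithmetic uses the printed
two-decimal grid values, not exact powers of two: 11.9/0.39 → 31 whereas
11.9/0.390625 → 30. Both conventions were fixed because together they
reproduce all six printed TI entries exactly; that check is the package's
acceptance test, not an input to further tuning.

## Kinetics

Δfl is final − initial (no dead-time extrapolation: the first recorded
plate-reader point is the initial measurement); Δabs is global maximum −
final, tolerating mixing transients at the start of the trace. Both are
invariant to baseline offsets. Hit thresholds are strict for fluorescence
(> 15000 a.u.) and inclusive for total conversion (Δabs ≥ 2.0 A.U.).
Replicate traces are averaged point-wise before summarizing. The
monitoring-wavelength discrepancy in the source assay descriptions (374 vs
384 nm) is carried as channel metadata, not resolved. Stability is the
absolute % change of absorbance at 320 nm, stable below 10%.

## Fingerprints and the SVM

The published 598-bit metal-complex fingerprint is defined in prior work we
do not restate; the module ships a same-width *emulation* under a version
tag (`emulated-0.1`): 5 scaffold one-hot bits, 13 donor-environment bits
(ligand class, chelate ring size, halide/carbonyl/axial features), and 580
bits filled by hashing ligand tokens (SMILES n-grams when available,
element-count tokens otherwise) with a small deterministic polynomial hash.
Determinism is platform-independent because the hash stays in exact-integer
double range. True bit definitions can replace the emulation without
touching the modelling code.

The SVM is linear by necessity and by design: support-vector feature
importance needs the primal weight vector `w = Σ αᵢyᵢxᵢ`, and no SVM
library is assumed in the runtime environment, so the package implements
dual coordinate descent (L1 hinge loss, box constraint `0 ≤ α ≤ C`,
deterministic sweep order, bias as an augmented feature). Default `C = 1`.
Cross-validation is stratified with a recorded fold assignment and seed;
metrics are AUC (rank statistic), precision, recall and F1 at the sign
threshold, reported per fold and as mean ± SD.

## What the generators emulate — and what a green test establishes

Every generator is a deterministic function of parameters and seed and
serializes its truth.

- **Chromatograms**: Gaussian peaks (SD 0.05 min, a typical short-column
  width) sampled at 2 Hz UV / 1 Hz MS, areas proportional to true
  conversion fractions, one impurity peak absorbing the remainder,
  Gaussian UV baseline noise and scaled-Poisson MS centroid noise. Not
  emulated: tailing, ion suppression, carry-over, retention drift. A green
  round-trip shows the pipeline recovers truth under its own peak model,
  not that it is robust to instrument pathology.
- **MIC plates**: full growth below the true MIC, suppression at and above
  it, a logistic transition one dilution step wide centred half a step
  below the MIC, 2% well noise. The transition width is the sharpest
  realistic one; wider transitions would stress the threshold choice.
- **Dose-response**: the 4PL itself plus Gaussian percent noise — so
  recovery tests measure the optimizer, not model misspecification.
- **Activity datasets**: background bits are sparse Bernoulli(0.01) — the
  sparsity regime of real structural fingerprints — causal bits are
  commoner (Bernoulli(0.5)), and the default rule (six ±2 weights,
  intercept −1) is deterministic with a unit margin. These defaults were
  fixed once, as the stated world for the property checks: in this world a
  separable rule yields fold AUCs of 1, five flipped labels per hundred
  cost roughly the Bayes gap, and a mean cross-validated AUC ≥ 0.9 at
  n = 192 is the typical outcome, not a lucky seed. With dense background
  bits (0.5) the same checks fail for any linear learner at this sample
  size — a margin, not a bug, and the reason the generator's bit density
  is part of its stated world. The published campaign metrics
  (AUC 0.83 ± 0.05 etc.) are *not* reproduced here: they require the
  authors' assay table and exact fingerprint bits; the property suite is
  the substitute, and only the report format (mean ± SD over 5 stratified
  folds) is mirrored.

## Known limitations

- No chromatographic alignment across runs, no MS/MS, no MS-intensity
  quantitation; UV integration carries the linear-baseline assumption.
- The fingerprint emulation shares only width and block philosophy with
  the published descriptor; learned importances name emulated bits.
- cLogP, when not supplied, is a labelled crude proxy; descriptor
  correlations are reported with both Pearson and Spearman to soften
  linearity assumptions.
- No reaction-yield prediction, coordination-geometry modelling,
  photophysics, or rate-constant fitting.
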