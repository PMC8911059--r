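---
title: "FTIR hyperspectral chemometrics for colitis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FTIR hyperspectral chemometrics for colitis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectroinflame)
```

# Scope

`spectroinflame` implements a complete desk-scale analysis chain for FTIR
microspectroscopic imaging of inflamed bowel tissue: synthetic generation of
labelled hyperspectral cohorts, spectral preprocessing, band-integration
biochemistry with Welch tests, binary PLS-DA discrimination with VIP
biomarker scoring, multi-class severity classification by a stacked
ensemble, and neural-network layer segmentation. Because real murine colitis
imaging datasets of this kind are not freely redistributable, the package
ships a generative model of such data; every downstream method is exercised
and validated against that generator's known ground truth.

This vignette is the package's methodological record: the models, their
assumptions, the tunable parameters, the numerical choices, and what the
synthetic validation does and does not demonstrate.

# The synthetic tissue model

A spectrum is a sum of Gaussian absorbance bands plus a smooth baseline and
white noise:

$$A(\nu) = \sum_b a_b\, m_{\mathrm{layer}}(b)\, m_{\mathrm{sev}}(b)\,
  (1 + \varepsilon_b)\, e^{-(\nu - c_b)^2 / 2\sigma_b^2}
  + \beta(\nu) + \eta(\nu)$$

* **Band table.** Thirteen bands at the canonical tissue assignments of the
  1800–800 cm⁻¹ fingerprint region: amide I α-helix 1650 and β-sheet
  1635, amide II 1545, protein 1481, lipid ester 1739, the collagen triplet
  1280/1230/1200, glycogen 1151/1076/1028, RNA 1115 and DNA 960 cm⁻¹.
  Centres are the literature assignments; widths (8–16 cm⁻¹ sigma) and base
  amplitudes (0.07–1.0 AU) are generator defaults chosen to give amide I an
  order-of-magnitude dominance, as in tissue.
* **Layer chemistry** (`default_layer_chemistry()`). Mucosa (MC), submucosa
  (SubMC) and muscularis propria (MP) are distinguished by: α-helix dominant
  in MC/MP vs β-sheet in SubMC; collagen strongest in SubMC; glycogen
  highest in MC; nucleic acids depleted in MP; total protein greatest in MP.
  Config validation enforces that every layer pair differs by at least 20%
  in at least one band, so the layers stay machine-distinguishable.
* **Severity effects** (`default_severity_effects()`). Protein
  1.00/1.15/1.30/1.50, collagen 1.00/1.10/1.20/1.35, DNA and RNA
  1.00/1.20/1.45/1.80, glycogen 1.00/0.90/0.75/0.60 across
  control/mild/moderate/severe. Directions follow the characteristic
  biochemistry of worsening colitis (protein, collagen and nucleic acids up;
  glycogen down with goblet-cell loss); magnitudes are deliberate defaults
  with overlapping adjacent classes so that the middle severities are
  genuinely hard to separate. Monotonicity in the stated directions is
  enforced at config validation.
* **Nuisance terms.** A per-pixel random quadratic baseline
  (`baseline_amplitude`, default 0.1 AU) makes rubber-band correction
  non-trivial; per-band amplitude jitter (`amplitude_jitter_cv`, default
  0.08) models local compositional variability; iid Gaussian noise
  (`noise_sd`, default 0.005 AU) matches the noise floor of co-added
  focal-plane-array tissue measurements; an animal-level log-amplitude
  effect (`animal_sd`, default 0.05) correlates all spectra from one animal.
* **Axis.** 1900 → 700 cm⁻¹ stored descending at 4 cm⁻¹ point spacing — an
  8 cm⁻¹-resolution acquisition digitised at half the resolution, the usual
  convention. The acquisition resolution itself is not modelled (no
  line-shape convolution); spacing is a config parameter, not a claim.

Seeds are split hierarchically (animal → section → layer) with a
deterministic string-hash (`derive_seed()`), so enlarging one class never
perturbs another class's draws and every stage is independently
reproducible.

One modelling caveat surfaced by the generator itself: the printed RNA
quantification window (1120–1080 cm⁻¹) overlaps the wing of the glycogen
1076 band, whose severity effect runs the opposite way. The integrated RNA
window is therefore *not* monotone in severity even in the noiseless model —
the same spectral-overlap confound the band assignments warn about. Tests
assert monotone behaviour for the unconfounded windows and for the isolated
RNA component.

# Preprocessing

Two mode-specific chains share the crop and background-removal stages, so
both operate on identical surviving pixel sets:

* **quantification**: crop (1801–798 cm⁻¹, closed window) → background
  removal → rubber-band baseline correction → averaging;
* **classification**: crop → background removal → Savitzky–Golay second
  derivative (9 points, 3rd order) → SNV → averaging → SNV.

Numerical choices:

* **Rubber-band correction** subtracts the lower convex hull of
  $(\nu, A)$, computed by Andrew's monotone chain and interpolated linearly
  between hull vertices. The corrected spectrum is non-negative and exactly
  zero at hull vertices, and the operator is invariant to added affine
  baselines. The test suite checks it against an independent brute-force
  pairwise-chord oracle on hundreds of random spectra. Collinear hull
  candidates are dropped (cross product ≤ 0), which is tie-stable.
* **Savitzky–Golay** uses least-squares polynomial filter coefficients
  (`signal::sgolay`), with the derivative scaled by the signed axis step to
  the power $-d$ so results are spacing-independent (d²A/dν² in AU·cm²
  regardless of digitisation). Edges are handled with the off-centre
  least-squares fits over the first/last window — the standard SG edge
  treatment — which keeps the filter *exact* for polynomials up to the
  fitting order at every point, edges included; reflect padding would
  sacrifice that exactness at the boundary.
* **SNV** centres and scales each spectrum to unit sample standard
  deviation ($n-1$ denominator) over the whole spectral region (per
  spectrum, not per cohort). A constant spectrum raises a typed degenerate
  error. Because a mean of unit-variance spectra has variance below one,
  the classification chain re-applies SNV (idempotent) after averaging so
  every emitted representative is exactly SNV-scaled.
* **Background removal**: a pixel is background when its rubber-band
  corrected amide-I integrated area falls below a fraction (default 0.10)
  of the image maximum; amide I is used because it is the dominant tissue
  band. An image losing all pixels raises `EmptyTissueError`.
* **Averaging** to representatives uses a seeded random partition into
  exactly `n_avg` (default 25) near-equal bins (sizes differ by ≤ 1); with
  fewer pixels than bins, each pixel is its own representative. The seeded
  partition is the reproducible reading of "approximately 25 spectra per
  sample".

# Biochemical quantification

Band areas are trapezoidal integrals over closed wavenumber windows of
rubber-band-corrected (not derivative) spectra: amide I 1700–1600, amide II
1580–1510, collagen 1300–1200, glycogen 1250–1000, RNA 1120–1080, DNA
979–948 cm⁻¹. Group comparisons aggregate one area per record (the mean
over its representatives) before an unpaired Welch t-test — records
(imaged sections), not pixels, are the statistical unit, which avoids
pseudo-replication from thousands of correlated pixels. No multiple-testing
correction is applied by default; callers comparing many bands can Holm-
adjust the collected p-values. The Welch p-value is calibrated: under a
null generator (severity effects disabled) the type-I error at α = 0.05 is
within 0.05 ± 0.02 over 1000 simulated cohort comparisons, and the p agrees
with a permutation oracle at sample sizes where the t reference law is
accurate. At very small discrete samples (e.g. 4 + 4 with ties) the
t-distribution p and the exact permutation p differ substantially — an
inherent property of the asymptotic reference, not of the implementation.

# PLS-DA with VIP scores

The binary discriminator is PLS1 by NIPALS on mean-centred spectra with
±1-coded classes and X-deflation per component; the regression vector maps
a centred spectrum to a continuous score thresholded at 0. With all
components retained the coefficients coincide with ordinary least squares
(checked against `lm.fit` as an oracle). Cross-validation uses venetian
blinds: samples sorted by class then record id, every k-th sample (default
10 blinds) forming a fold, which keeps folds class-balanced; the number of
latent variables is the smallest count attaining the global minimum CV
error (parsimony tie-break). VIP scores use the x-weights convention,

$$\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a w_{aj}^2 / \sum_a \mathrm{SSY}_a},$$

whose squared mean is identically 1; wavenumbers above 1 are flagged
significant. Contiguous significant runs are merged into bands and followed
up with Welch tests on integrated areas (runs) or peak intensities
(isolated points), severe vs control per record.

# Severity classification

The four-class problem uses PCA reduction (components to ≥ 95% cumulative
variance, fitted on the training partition only; test data are centred with
the training mean), four probabilistic base learners, and a stacked
ensemble:

* ANN: single hidden layer, logistic units, softmax output. The default
  width is 25 units: with record-level training sets of order 10² rows on a
  few dozen PCA scores, wider layers (e.g. 100 units ≈ 5000 weights under
  BFGS) are heavily overparameterised and an order of magnitude slower for
  no accuracy gain. Width is config-overridable.
* SVM: radial-basis kernel, cost 1, pairwise-coupled class probabilities.
* Random forest: 500 trees, √p features per split.
* kNN: k = 5, Euclidean distance on the reduced scores.

Stacking generates out-of-fold base probabilities by inner stratified
5-fold CV grouped by record, selects per class the base kind with the best
out-of-fold one-vs-rest AUROC (winners deduplicated), fits a multinomial
logistic meta-learner on the concatenated out-of-fold probabilities, and
refits the selected bases on all training data. Evaluation is 10 repeated
stratified 70/30 hold-outs at the record level — all spectra of one record
stay on one side of every split, including inner folds, so near-duplicate
representatives can never leak — with per-class one-vs-rest AUROC (rank
formulation with midranks, invariant under monotone score transforms) and
one-vs-rest classification accuracy averaged over repeats.

Under the default severity multipliers the hardest classes are the middle
ones, as intended; which of mild or moderate ends up weakest follows from
the multiplier geometry. On the log scale the control→mild gaps for
glycogen (0.105) and DNA/RNA (0.182) are the smallest of their rows, so the
mild class is squeezed at least as hard as moderate, and measured hold-outs
show mild and moderate trading places as the lowest-AUROC class across
seeds rather than moderate being reliably the minimum.

# Layer segmentation

A deliberately frugal classifier mirrors image-level tissue mapping: a
single-hidden-layer network (15 units) trained on exactly 10
classification-preprocessed pixel spectra per layer for 100 epochs, applied
pixel-wise (argmax probability) with background pixels passed through. On
independent synthetic images at default noise, held-out pixel accuracy
exceeds 0.9 (asserted in the acceptance suite).

# Problem sizes and determinism

Defaults emulate a realistic study: 3 animals per class, 2 sections per
animal, 25 representative spectra per layer and section. The test and
acceptance suites run the same machinery at reduced spectra-per-record
counts (3–10) and 10–24-pixel-wide images — sizes chosen so the full
pipeline, repeated hold-outs included, completes on a single CPU in
minutes; all statistical properties asserted are scale-free. Every stage is
deterministic given the configuration and a global seed; the pipeline
manifest records content hashes per stage, and identical config + seed
reproduce identical hashes.

# What synthetic validation does not show

The generator is a test harness, not a tissue simulator. It omits Mie and
resonant-Mie scattering, paraffin residues, atmospheric compensation
artefacts, instrument line-shape effects, spatial correlation between
neighbouring pixels, and any non-Gaussian band shapes (Voigt profiles are a
one-line swap). Perfect synthetic separability (e.g. 100% cross-validated
sensitivity) therefore demonstrates correctness of the machinery — not
expected field performance on real tissue, where published figures of this
kind sit around the low 90s. Conclusions about real colitis biology require
real data; the package's claim is that, given such data in its containers,
every method applied to them is implemented correctly.
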