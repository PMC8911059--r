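# spectroinflame

Chemometric analysis of FTIR hyperspectral images of inflamed bowel tissue,
for spectroscopists and computational pathologists who want a tested,
reproducible R implementation of the standard colitis imaging workflow:
band-integration biochemistry, PLS-DA biomarker discovery, multi-class
severity classification, and neural-network layer segmentation — plus a
synthetic data generator so the whole chain runs and is validated without
access to restricted animal imaging data.

## What it computes

Working on absorbance spectra A(ν) over the 1800–800 cm⁻¹ fingerprint
region:

* **Preprocessing** — crop to 1801–798 cm⁻¹; rubber-band baseline
  correction (subtraction of the lower convex hull of (ν, A)); Savitzky–
  Golay second derivatives (9-point, 3rd-order, scaled by the axis step so
  the output is d²A/dν²); standard normal variate (SNV) normalisation;
  amide-I-based background removal; seeded averaging to ~25 representative
  spectra per sample.
* **Biochemistry** — trapezoidal band areas ∫A dν for amide I
  (1700–1600 cm⁻¹), amide II (1580–1510), collagen (1300–1200), glycogen
  (1250–1000), RNA (1120–1080) and DNA (979–948); per-pixel chemical maps;
  Welch t-tests (Welch–Satterthwaite df) between severity groups with the
  imaged section as the statistical unit.
* **PLS-DA** — NIPALS PLS1 on second-derivative SNV spectra with ±1 class
  coding; venetian-blind cross-validation; latent-variable selection at the
  CV-error minimum; variable importance in projection,
  VIP_j = √(p Σₐ SSYₐ w²ₐⱼ / Σₐ SSYₐ), with VIP > 1 flagging biomarker
  wavenumbers; cross-validated sensitivity/specificity.
* **Severity classification** — PCA to ≥95% variance, ANN/SVM/RF/kNN base
  learners, stacked ensemble with a multinomial-logistic meta-learner on
  out-of-fold probabilities, evaluated by 10 repeated stratified 70/30
  record-level hold-outs with per-class one-vs-rest AUROC (Mann–Whitney
  rank form) and classification accuracy.
* **Layer segmentation** — a single-hidden-layer network trained on 10
  pixel spectra per bowel layer (mucosa, submucosa, muscularis propria) for
  100 epochs, applied pixel-wise to whole images.
* **Synthetic cohorts** — Gaussian-band tissue spectra with layer- and
  severity-dependent chemistry, random baselines, amplitude jitter, animal
  random effects and sensor noise, generated from hierarchically split
  seeds.

See `vignettes/ftir-colitis-workflow.Rmd` for the full methodological
account.

## Worked example

```r
library(spectroinflame)

gen <- generator_config(seed = 101)
cohort <- synth_cohort(gen, c(control = 3, severe = 3),
                       sections_per_animal = 2, spectra_per_layer = 10,
                       seed = 101)

# protein accumulation in severe colitis, mucosal layer
compare_groups(cohort, default_band_table()$amide_I,
               "severe", "control", layer = "MC")
#> Welch t = 13.4, df = 5.61, p = 1.79e-05, mean diff = 23.72 (n = 6, 6)

# severe-vs-control PLS-DA on the submucosa
cm <- cohort_matrix(cohort, layer = "SubMC", classes = c("control", "severe"))
curve <- venetian_cv(cm$X, cm$y, max_lv = 8, n_blinds = 10,
                     ids = cm$meta$record)
n_lv <- select_n_lv(curve)
ev <- plsda_cv_eval(cm$X, cm$y, n_lv, n_blinds = 10, ids = cm$meta$record,
                    positive = "severe")
#> selected LVs: 1 | CV sensitivity: 100.0% | CV specificity: 100.0%
```

The Welch line says the mean amide-I integrated area of severe-colitis
sections exceeds controls by 23.7 AU·cm⁻¹ — a large, highly significant
protein increase (6 sections per group). The PLS-DA line reports
out-of-fold performance of the venetian-blind cross-validation at the
selected model size; on synthetic data the classes are fully separable, and
the VIP > 1 wavenumbers concentrate inside the amide-I window
(1644–1632 cm⁻¹ here), i.e. the model discriminates on protein bands, as it
should. `run_pipeline(default_run_config(seed))` executes the entire
workflow (quantification → PLS-DA → severity ensemble → segmentation) and
returns a manifest of per-stage content hashes for reproducibility checks.

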