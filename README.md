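# fetalsource

Source attribution of fetal gut metabolites from matched multi-tissue
LC-MS metabolomics.

## The problem

Microbiome-associated metabolites — secondary bile acids, short-chain
fatty acids, aromatic lactic acids — are detectable in the fetal
intestine during the second trimester, before the fetus has a microbiome
of its own. Are they vertically transmitted from the maternal circulation,
or produced locally in the fetal gut lumen? `fetalsource` implements a
complete, tested analysis pipeline for this question, designed for
matched maternal–fetal tissue panels: maternal decidua, placental villi
(PV), fetal small/large intestine (pooled as the GI supergroup) and
meconium.

The core inference is a **correlation contrast**. For a metabolite panel,
let ρ<sub>Dec,GI</sub> be the Pearson correlation between the panel
abundance vectors of a decidua sample and a GI sample, and
ρ<sub>Mec,GI</sub> the GI/meconium analogue. Maternally transmitted
panels satisfy ρ<sub>Dec,GI</sub> > ρ<sub>Mec,GI</sub>; locally produced
panels the reverse. The two correlation samples are compared with a Welch
two-sample t-test, with xenobiotics (host cannot synthesise them:
necessarily maternal) and fetal-derived metabolites (necessarily local)
as positive and negative controls.

Around this the package provides:

* **Preprocessing** faithful to untargeted LC-MS practice: blank-peak
  removal (median study > 3 × median blank), QC-based linear drift
  correction over injection order, isomer deduplication by largest log2
  IQR, log2 + quantile normalization, half-minimum imputation.
* **Moderated differential abundance** between tissue supergroups:
  pooled-variance contrasts, empirical-Bayes variance shrinkage
  (moment/trigamma estimation of the scaled inverse-chi-square prior),
  moderated t, Benjamini–Hochberg q-values, volcano classification at
  |log2 FC| > 2.5 and q < 0.05.
* **Tissue-enrichment ANOVA** with Tukey HSD post hoc and a
  gestational-age-adjusted nested-model re-test.
* **Gestational-age trends** per tissue (OLS slope, Pearson r, BH within
  tissue) with origin interpretation for the GI tract: significant
  negative microbial trends point to maternal circulation, positive
  trends to fetal synthesis.
* **Targeted validation** helpers: calibration curves, back-calculated
  concentrations, spike recovery, QC RSD, signal-to-noise LOD/LOQ.
* A **synthetic cohort generator** with ground-truth origin labels,
  emulating the study structure (49 study samples over 24 subjects,
  8/8/3/11/8/11 per tissue, gestational ages 14–23 weeks, blanks, QC
  drift, contaminant peaks, isomer duplicates, detection-limit
  missingness), so every stage is verifiable by parameter recovery. The
  analytic panel correlation `expected_profile_correlation()` serves as
  an independent oracle.

See the vignette (`vignettes/source-attribution.Rmd`) for the model, the
generator's assumptions and all numerical conventions.

## Worked example

```r
library(fetalsource)

sim <- generate_dataset(sim_config(), seed = 7)   # 65 x 330 raw matrix
pp  <- preprocess(sim$dataset, seed = 7)
pp$report
#>   n_samples_in n_samples_out n_metabolites_in n_metabolites_out
#> 1           65            49              330               285
#>   n_blank_removed n_unnamed_dropped n_isomer_collapsed n_imputed_cells
#> 1              15                20                 10             785

att <- attribute_all_panels(pp$dataset)
att[, c("panel", "mean_rho_dec_gi", "mean_rho_mec_gi", "p_value", "label")]
#>           panel mean_rho_dec_gi mean_rho_mec_gi       p_value    label
#> 1     microbial       0.8048524       0.2246781 4.228620e-139 maternal
#> 2    xenobiotic       0.7719632       0.1568628 2.619463e-139 maternal
#> 3 fetal_derived      -0.1395605       0.7820227  1.127808e-43    local
```

Reading: the 49 located study samples survive filtering; the 15 planted
blank-dominant contaminants, 20 unnamed peaks and 10 isomer duplicates
are removed. Across all 88 decidua/GI and 209 GI/meconium sample pairs,
the microbial panel correlates far more strongly with the maternal side
(mean ρ 0.80 vs 0.22), so it is labelled `maternal` — and the two control
panels land on their known answers.

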