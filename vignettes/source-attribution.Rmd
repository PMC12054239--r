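---
title: "Inferring the source of fetal gut metabolites from matched multi-tissue metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the source of fetal gut metabolites from matched multi-tissue metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalsource)
```

## The question and the inferential idea

During the second trimester the fetal intestine already contains
microbiome-associated metabolites — secondary bile acids, short-chain fatty
acids (SCFA), aromatic lactic acids — although the fetus itself carries no
established microbiome. Two origins are possible for a compound found in
fetal gut (GI) tissue: vertical transmission from the maternal circulation
across the placenta, or local production within the fetal gut lumen.

With matched tissue samples per subject — maternal decidua, placental villi
(PV), fetal small/large intestine (the GI supergroup) and the meconium that
fills it — the two hypotheses make opposite predictions about *sample
profile correlations* over a metabolite panel. Write $\rho_{Dec,GI}$ for
the Pearson correlation between the panel abundance vector of a decidua
sample and that of a GI sample, and $\rho_{Mec,GI}$ for the GI/meconium
analogue. Maternally transmitted compounds should couple the GI tissue to
the maternal side, $\rho_{Dec,GI} > \rho_{Mec,GI}$; locally produced
compounds should couple it to the lumen, $\rho_{Dec,GI} < \rho_{Mec,GI}$.
Two panels act as controls with known answers: xenobiotics (compounds the
human host cannot synthesise, necessarily maternal) and fetal-derived
metabolites (necessarily local). The package's `attribute_all_panels()`
computes both correlation samples for each panel and contrasts them with a
Welch two-sample t-test, labelling the panel `maternal`, `local` or
`indeterminate`.

Three further analyses complete the picture:

* **moderated differential abundance** (`run_differential()`) between
  tissue supergroups, with empirical-Bayes variance shrinkage,
  Benjamini–Hochberg q-values and volcano classification at
  $|\log_2 FC| > 2.5$, $q < 0.05$ (strict inequalities, read directly from
  the stated thresholds);
* **tissue-enrichment ANOVA** (`run_tissue_anova()`): per metabolite, a
  one-way ANOVA across the four supergroups, Tukey HSD post hoc pairwise
  tests, a gestational-age-adjusted re-test, and a pattern call
  (`enriched_<tissue>` / `no_difference` / `mixed`);
* **gestational-age trends** (`run_age_trends()`): per tissue and
  metabolite, the OLS slope and Pearson $r$ of log2 abundance against
  gestational age. In the GI tract a significant negative trend for a
  microbial metabolite is a maternal-circulation signature (wash-out as
  gestation advances), a significant positive trend indicates increasing
  fetal synthesis.

## The moderated test

For metabolite $g$ contrasted between groups $A$ and $B$ (sizes $n_A$,
$n_B$), the pooled within-group variance $s_g^2$ on $d_g = n_A + n_B - 2$
degrees of freedom is shrunk toward a prior $(d_0, s_0^2)$:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
  t_g = \frac{\bar x_A - \bar x_B}{\tilde s_g \sqrt{1/n_A + 1/n_B}},$$

with $t_g$ referred to a t distribution on $d_0 + d_g$ degrees of freedom.
The prior is estimated by matching the first two moments of $\log s_g^2$
to a scaled-F model: after subtracting the known chi-square sampling
contribution ($\psi'(d_g/2)$), the residual spread of $\log s_g^2$
identifies $d_0$ through the trigamma function (inverted by Newton
iteration, absolute step tolerance $10^{-10}$), and $s_0^2$ follows from
the mean. Two degenerate contracts are fixed: exactly equal variances give
$d_0 = \infty$ with $s_0^2$ the common value, and a vanishing moment
equation likewise degenerates to full shrinkage. $d_0 = 0$ recovers the
ordinary pooled t-test. The test suite cross-checks the whole chain
against an independent implementation of the same empirical-Bayes recipe.

## The synthetic cohort generator

No raw data accompany the study design this package implements, so every
stage is validated against a generator whose ground truth is known. On the
log2 scale, metabolite $m$ of origin class $c$, in sample $i$ of fine
tissue $t$ (supergroup $g$) from subject $s$ at gestational age $a_s$:

$$x_{m,i} = \lambda_{c,g}\,\mu_m + \tau_{c,g}\, z_{m,t,s}
  + \gamma_{m,g}\,(a_s - \bar a) + \varepsilon_{m,i}$$

* $\mu_m \sim N(0, \sigma_{profile}^2)$ is the latent source profile
  shared by all samples ($\sigma_{profile} = 1.5$ log2 units — a broad but
  realistic metabolite-to-metabolite spread);
* $\lambda_{c,g} \in [0,1]$ attenuates the profile along each tissue path
  and $\tau_{c,g}$ distorts it per subject and tissue. Maternal classes
  keep the profile on the maternal side (decidua $(1.0, 0.1)$, PV
  $(0.8, 0.3)$, GI $(0.6, 0.4)$) and lose it along the meconium path
  ($(0.3, 1.2)$; xenobiotics $(0.2, 1.2)$). Locally produced (fetal)
  classes mirror this: meconium $(1.0, 0.1)$, GI $(0.6, 0.4)$, decidua
  decoupled at $(0.3, 1.2)$. These values were fixed once so that the
  analytic subject-level correlations (below) reproduce the qualitative
  contrast the design expects — strong decidua–GI coupling near 0.86
  against weak meconium–GI coupling near 0.30 for maternal panels, and the
  mirror image for fetal panels;
* $\gamma_{m,g}$ plants gestational-age trends. The default pattern gives
  two secondary bile acids and one SCFA a $-0.3$ log2/week slope in GI and
  three primary bile acids $+0.3$, zero elsewhere. The magnitude follows a
  power calculation done before any testing: with 11 GI samples, ages
  spanning 14–23 weeks (sd $\approx 3.2$) and residual sd
  $\sqrt{\tau^2 + \sigma^2} \approx 0.5$, a 0.3 log2/week slope yields
  $r \approx 0.87$ and comfortable power after BH adjustment within the
  tested panel. Age is centred at the cohort mean so planted trends do not
  shift the overall intensity scale;
* $\varepsilon \sim N(0, 0.3^2)$ is measurement noise.

Raw intensities are $2^{x + 15}$ — a single global scale, deliberately
without per-metabolite baselines, so that the large-panel Pearson
correlation between two samples sharing $\mu$ has the closed form
implemented in `expected_profile_correlation()`:

$$\rho_{ab} = \frac{\lambda_a \lambda_b \sigma^2}
 {\sqrt{(\lambda_a^2\sigma^2 + \tau_a^2 + \sigma_n^2)
        (\lambda_b^2\sigma^2 + \tau_b^2 + \sigma_n^2)}}.$$

This analytic value is the oracle against which the generator's empirical
panel correlations are tested (Monte-Carlo convergence at 10,000
metabolites, tolerance 0.01).

The sample frame is fixed: 49 study samples over 24 subjects
(8 decidua, 8 SI, 3 LI, 11 SI-meconium, 8 LI-meconium, 11 PV), one subject
carrying all six tissues, and gestational ages arranged so that 23-week
subjects contribute 4 decidua, 3 GI and 7 meconium samples. This
reproduces the cohort's combinatorial structure exactly: 88 decidua/GI and
209 GI/meconium pairs over all samples, and 12 / 21 pairs at 23 weeks.
LC-MS artifacts are layered on top: 7 blanks (low methanol background),
8 pooled QC injections interleaved every ten study samples, blank-dominant
contaminant peaks, a multiplicative instrument drift of 0.02 log2 units
per injection applied to *every* injection, isomeric duplicate peaks,
unnamed peaks, one study sample without location information (65 columns
in the raw matrix), and left-censored missingness.

**Why left-censoring rather than missing-at-random.** Half-minimum
imputation — the rule this pipeline implements — presumes that a missing
value was missing *because it was low* (below the detection limit). If the
generator instead removed cells uniformly at random, every imputed cell
would sit at the metabolite's global minimum minus one log2 unit, i.e. a
guaranteed large negative outlier; with eleven GI samples a single such
outlier routinely destroys an age-trend fit, and the generator would be
testing the pipeline against an artifact of its own inconsistency rather
than against measurement reality. The generator therefore censors the
lowest cells of each metabolite at the configured expected rate (default
0.05), which is also the more faithful emulation of LC-MS dropout.
Intensity-independent missingness remains available by setting
`missing_rate = 0` and introducing missing cells externally.

What the generator does **not** emulate: chromatographic peak shapes,
adduct/isotope structure, batch effects beyond linear drift, non-Gaussian
abundance distributions, and intensity-dependent measurement noise.
Passing the recovery suites therefore demonstrates correctness of the
statistical machinery under the stated model, not performance on any
particular real cohort.

## Preprocessing: order and numerical choices

`preprocess()` runs: blank-peak removal → QC drift correction → sample
filtering → isomer deduplication → log2 + quantile normalization →
half-minimum imputation. The first two steps necessarily run while blanks
and QCs are still in the matrix; filtering then retains located study
samples only. The report reconciles exactly:
`metabolites_in − blank_removed − unnamed_dropped − isomer_collapsed =
metabolites_out`.

* **Blank rule**: a metabolite is dropped when its median study intensity
  is below `blank_ratio` (default 3) times its median blank intensity —
  a common convention where no explicit threshold is standard; metabolites
  absent from blanks are always kept.
* **QC drift**: log2 QC intensity is regressed on injection order — the
  standard drift axis given QC interleaving — and every sample is divided
  by $2^{b(\text{order} - \overline{\text{order}}_{QC})}$, preserving the
  mean QC level. Fitting on the log scale matches multiplicative drift and
  keeps the correction strictly positive; metabolites with fewer than
  three usable QC values are left uncorrected and counted.
* **Isomer deduplication**: unnamed peaks are dropped; within an isomer
  group the member with the largest IQR (25–75% quartiles, type-7) of
  log2 intensity across study samples is kept; exact ties keep the first
  in input order (a deterministic rule where none is standard). Retained
  values are never altered.
* **Quantile normalization** maps every sample onto the mean sorted
  distribution, ranks preserved, ties averaged; samples containing missing
  values are normalized against an interpolated reference, and missing
  cells stay missing. Normalization precedes imputation (the defensible
  ordering when imputation is a last-resort fill); zero intensities cannot
  be log-transformed and are converted to missing with a warning. The
  operation is idempotent to 1e-9 and its defining property — identical
  sorted per-sample vectors — is asserted in the tests.
* **Imputation**: each missing cell receives half the metabolite's minimum
  observed intensity times $(1 + u)$, $u \sim U(0, 0.1)$, under an
  explicit seed. On log2 matrices the rule acts on the intensity scale
  ($\min - 1 + \log_2(1+u)$), keeping imputed values strictly below the
  observed minimum.

## Attribution: pairing modes and test choices

Pair enumeration offers three modes: `all_pairs` (every cross-tissue
combination, including cross-subject pairs — the mode that yields the
88/209 counts), `subject_matched` and `age_matched` (both subjects at a
stated age, default 23 weeks). Pearson correlation on log2-normalized
abundances is the default (Spearman by flag); no Fisher z-transform is
applied by default since the contrast tests raw correlations.
The two-sample test is Welch's, the safer choice under unequal pair
counts and variances.

Two statistical caveats are documented rather than "fixed": in `all_pairs`
mode each sample participates in many pairs, so the correlation values are
not independent and the t-test there is anticonservative — it is used for
effect description, while calibration claims are made only for the
subject-matched mode. Even subject-matched decidua/GI and GI/meconium sets
share GI samples, which makes the Welch test mildly *conservative* (the
shared noise cancels in the difference); the measured type-I error under
the no-difference generator sits slightly below the nominal 0.05, within
the 0.05 ± 0.03 calibration band asserted in the acceptance suite. The
no-difference generator sets both the decidua and meconium paths to
$(\lambda, \tau) = (0.65, 0.4)$ — a moderate common coupling chosen to
avoid the skew of correlations near 1 — and zeroes the planted age
slopes.

Per-panel (not per-metabolite) verdicts are intentional: the correlation
contrast is a property of a panel's joint profile; single-metabolite
origin calls from profile correlations are out of scope, as are
mixed-effect or permutation corrections for pair dependence.

## ANOVA and trend conventions

Tukey HSD is the default post hoc method (Bonferroni over MSE-pooled
pairwise t-tests is available); ANOVA q-values are BH within
the analysed panel batch. The pattern rule is: `no_difference` iff the
ANOVA q-value is ≥ 0.05; `enriched_X` iff group X has the highest mean
*and* all three of its pairwise Tukey comparisons are significant;
otherwise `mixed`. The age-adjusted re-test is the nested-model F-test of
`abundance ~ age` against `abundance ~ age + group`; with a constant age
vector it reduces exactly to the plain ANOVA. Age-trend q-values are BH
within each tissue, consistent with reporting trends per tissue column;
the trend table reports both the OLS slope (log2 units/week) and Pearson
$r$, which for a simple regression is the standardized slope.

Degenerate inputs have fixed contracts throughout: all-identical ANOVA
groups give $F = 0$, $p = 1$ with a flag; zero-variance trend responses
give slope 0, $r = 0$, $p = 1$; constant panel vectors raise an undefined
correlation error which `attribute_all_panels()` converts into a dropped
pair (warning) or an indeterminate panel.

## Problem sizes in the verification suites

The recovery suites run at the cohort's own scale: 100 replicate cohorts
(65 samples × 330 peaks) for origin-label recovery, 1000 replicates for
subject-matched type-I calibration, 100 for the planted trend-sign
pattern, and 20 two-group simulations of 2000 metabolites (100 planted
4-log2-unit effects) for volcano sensitivity/FDR. The shrinkage-prior
recovery test uses 5000 simulated variances against a planted
$(d_0 = 4, s_0^2 = 0.25)$. These sizes give Monte-Carlo standard errors
well inside each asserted band while keeping the default suite fast.

## Worked example

```{r example, eval = FALSE}
library(fetalsource)

sim <- generate_dataset(sim_config(), seed = 7)
pp <- preprocess(sim$dataset, seed = 7)
pp$report

att <- attribute_all_panels(pp$dataset)
att[, c("panel", "mean_rho_dec_gi", "mean_rho_mec_gi", "p_value", "label")]

trends <- run_age_trends(pp$dataset, tissues = "GI")
subset(trends, q < 0.05)
```

## Known limitations

* Panel labels summarise a whole panel; heterogeneous panels (some
  members maternal, some local) dilute toward `indeterminate`.
* The all-pairs t-test ignores pair dependence (see above).
* The unpaired two-group contrast ignores subject matching across tissue
  groups; with partially matched designs this loses some power but avoids
  modelling incomplete pairing.
* Calibration-curve quantification implements plain OLS; weighted (1/x)
  calibration is not provided.
* Annotation (metabolite identification) is carried as metadata only;
  nothing in the package performs spectral matching.
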