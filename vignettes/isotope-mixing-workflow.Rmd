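---
title: "Tracing fatty-acid origin by natural-abundance carbon isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing fatty-acid origin by natural-abundance carbon isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnltrace)
library(dplyr)
```

## The measurement problem

Palmitic acid (PAM, 16:0) in tissue is either incorporated directly from
dietary fat or built by de novo lipogenesis (DNL) from acetyl-CoA, whose
carbon comes mostly from dietary sugars. C4-plant carbohydrates are
naturally enriched in ^13^C relative to C3-plant fats, so the two candidate
sources of tissue PAM carbon carry distinct natural-abundance signatures.
Measuring the δ^13^C of individual fatty acids (compound-specific isotope
analysis, CSIA, by GC-C-IRMS) therefore reads out fatty-acid origin without
any isotope label — provided the raw instrument values are carefully
normalized, corrected, and interpreted through a mixing model. This
vignette walks through each modelling decision in that chain.

## δ notation and conversions

All isotopic values are carried as δ^13^C in mUr (milli-Urey, identical to
per mil) relative to VPDB, whose ^13^C/^12^C ratio is 0.0112372
(`iso_constants()$r_vpdb`). Working in δ keeps natural-abundance numbers
readable (−30 to −10 mUr rather than ratios with five leading decimals);
`delta_to_ratio()`, `ratio_to_atom_fraction()` and friends convert exactly
and monotonically, and atom fractions are stored as fractions and presented
as %^13^C (`pct_13c()`) only at the surface. Values are never rounded
internally; two-decimal rounding belongs to presentation.

## VPDB normalization

Each instrument sequence includes injections of certified reference
materials. `fit_normalization()` regresses certified on measured deltas by
OLS so the fitted line applies directly to unknowns without inversion. The
wording "measured vs. true" in common lab protocols does not fix the
regression direction; with the R^2^ > 0.999 typical of well-behaved
sequences the two directions are numerically indistinguishable, and we
document the true-on-measured choice rather than infer it. The 0.999 R^2^
gate is a *warning*, not an exclusion: a low R^2^ is a QC observation about
a sequence, and the analyst decides what to do with it. Certified CRM
values are configuration (the shipped `crm_reference_values()` are
synthetic placeholders spanning the natural-abundance range); one
calibration is fitted per sequence, mirroring per-sequence CRM injection.

## Methyl correction

FAME derivatization adds one exogenous methyl carbon. The carbon mass
balance

$$n_{FAME}\,\delta^{13}C_{FAME} = \delta^{13}C_{ME} + n_{FA}\,\delta^{13}C_{FA}$$

treats the methyl carbon with an explicit weight of one carbon (dimensional
consistency requires it even where the printed form of such corrections
omits $n_{ME}=1$). `correct_fame_delta()` inverts the balance; the default
methyl delta is −41.56 mUr, the package-wide constant determined from a
methylated/unmethylated 17:0 pair, and `methyl_delta()` re-derives it from
any such standard pair when a batch measures its own. The correction is
linear with slope $n_{FAME}/n_{FA} > 1$, so SD propagation
(`sd * n_{FAME}/n_{FA}`) is exact, and its magnitude shrinks with chain
length as one methyl carbon is diluted among more fatty-acid carbons.

## Quantification

`quantify_sample()` applies the internal-standard area-ratio rule with
response factors defaulting to unity for every FAME — fidelity to routine
GC-FID/IRMS practice — while accepting a per-species table for labs that
calibrate them. The exogenous 17:0 standard is excluded from the
relative-percent denominator, and zero-area analytes are kept as zeros so
composition denominators stay comparable across samples.

## End-member signatures

The "dietary sugars" end-member pools the diet's carbohydrate components.
Two pooling modes exist because "weighted average" is genuinely ambiguous:
*replicate* mode (the default) takes the arithmetic mean and sample SD
(n−1) of the component deltas and reproduces the published −11.15 ± 0.65
mUr signature of the shipped diet table exactly; *energy* mode weights by
% energy and lands within 0.1 mUr (−11.06). Both are available;
the default follows the printed signature. Soybean-oil fatty acids (1.2%
energy, present only to avoid essential-fatty-acid deficiency) and protein
are excluded from end-member construction: casein's −23.88 mUr is carried
in the diet table for completeness, but protein carbon routing into
lipogenesis is outside this model.

The fat end-member is the diet's own measured delta for the target fatty
acid. The low-PAM diet contains no palmitate, so it has no end-member of
its own; `fat_endmember()` substitutes the mean of the other diets'
dietary-PAM deltas (−29.57 mUr, SDs pooled quadratically) and flags every
downstream estimate `substituted_endmember = TRUE` so the provenance is
never silent.

## The mixing model

With sugar and fat end-members $\delta_s$ and $\delta_f$, the sugar-derived
(DNL) fraction of a tissue pool is

$$f = \frac{\delta_{tissue} - \delta_f}{\delta_s - \delta_f}.$$

This two-source linear model is a deliberate simplification: it does not
correct for the circulating blood pool and cannot separate hepatic from
local tissue DNL — questions that need mixed modelling over blood-corrected
data. What it does support is the bound-type inference the natural-abundance
contrast licenses: with a ~18.5 mUr end-member separation, brain δ^13^C-PAM
between −14.79 and −16.47 mUr implies a DNL fraction above 70% for every
combination of the measured end-members (`reproduce_anchors()` recomputes
this).

Numerical choices:

* **Mixing space.** δ-space mixing is the default; atom-fraction-space
  mixing (`space = "atom_fraction"`) differs by under 0.1% of the fraction
  at natural abundance because the δ→fraction map is nearly affine over a
  20 mUr span. Both are implemented; the tests assert their agreement.
* **Clamping.** Tissue values outside the end-member interval (real data:
  other depleted substrates feeding acetyl-CoA) give raw fractions outside
  [0, 1]; these are clamped and flagged rather than modelled with a third
  source we cannot identify from two end-members.
* **Degeneracy.** End-members closer than 1 mUr (configurable) make the
  fraction ill-conditioned; the model refuses rather than returning noise.
* **Uncertainty.** First-order propagation,
  $\mathrm{var}(f) = [\sigma_t^2 + f^2\sigma_s^2 + (1-f)^2\sigma_f^2] /
  (\delta_s-\delta_f)^2$, is exact to first order and the default; a seeded
  Monte-Carlo (10,000 draws, default seed 20240117, draws truncated to the
  physical bounds) cross-checks it. The tests require the two interval
  types to agree within 15% of interval width at sub-mUr SDs.

## Statistics

The statistical layer mirrors the conventions of diet × development
studies: ROUT outlier screening before analysis; fixed-effects two-way
diet × time ANOVA with Tukey's test on the interaction cells only when the
interaction is significant at α = 0.05; and, for single-timepoint
contrasts, a Shapiro–Wilk gate (per group, α = 0.05) routing to one-way
ANOVA or Kruskal–Wallis. Type-III sums of squares (sum-to-zero contrasts)
are used because litter sizes make real designs mildly unbalanced; on
balanced data they coincide with the sequential table, which is how the
implementation is verified against the reference routines. Males are the
primary stratum (`run_pipeline()` filters to `sex == "M"` when a sex column
is present), matching studies powered on male pups; females can be analysed
by passing the full table to the stats functions directly.

ROUT is implemented for the constant (one-sample) model, the only form the
group-comparison workflow needs: location is the median, scale the robust
SD of residuals (68.27th percentile of absolute residuals, inflated by
n/(n−1)), and residuals are tested outermost-first against a
Benjamini–Hochberg-style threshold $Q\,i/n$ (default Q = 1%), stopping at
the first non-significant point. The tests verify it flags a gross deviate,
spares ≥98% of pure Gaussian samples at n = 8, and agrees with a
leave-one-out robust-z oracle.

## The study simulator

`generate_study()` forward-simulates a three-diet (LP/MP/HP) developmental
feeding study: true tissue deltas from two-pool mixing with
cell-specific true fractions, the forward methyl balance, per-sequence
affine instrument drift plus noise, CRM injections through the same drift,
and peak tables laid down so quantification recovers the configured
composition. Defaults: four timepoints (P0–P35), six animals per
diet-timepoint cell, brain and liver per animal, biological SD 0.5 mUr,
instrument SD 0.3 mUr, CRM noise 0.05 mUr, drift slope 1.02 and intercept
0.8 mUr, one sequence per timepoint-tissue batch. The default true-fraction
profiles (`default_f_true()`) encode the qualitative structure the pipeline
must detect — LP > MP > HP everywhere, liver more responsive than brain,
LP brain rising and HP brain falling with age — and are generator
parameters, not estimates of any real study's group means. Pre-weaning
milk carry-over appears as stomach-content PAM ranges (low 21–28%, medium
25–35%, high 31–41%).

What the simulator does *not* emulate: chromatographic signal and peak
integration (inputs are integrated areas), litter as a random effect,
within-animal correlation between tissues beyond the shared diet, drifting
response factors, or any third isotopic source. Passing recovery tests on
synthetic data therefore demonstrates correctness of the computational
chain under the stated noise model, not robustness to every artefact of
real chromatography.

Test problem sizes were chosen to keep the full suite comfortably
desk-scale while leaving Monte-Carlo standard errors well inside the
asserted tolerances: 1000 replicates for calibration-gate and ROUT
frequencies and for ANOVA type-I calibration, 60 replicate studies for
full-chain fraction recovery (recovery tolerance 0.03 against a replicate
SE of ~0.002).

## Known limitations

* Two sources only; no Bayesian ≥3-source mixing, no blood-pool
  correction, no hepatic/local DNL split.
* The methyl-carbon delta is a batch constant; kinetic fractionation of
  the methylation reaction itself is not modelled.
* The dietary-sugars SD pools component means, not replicate-level
  variance; diets whose carbohydrate sources differ isotopically between
  batches need their own table.
* ROUT covers the constant model only, by design; regression-model ROUT
  is out of scope.
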