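# dnltrace

Compound-specific carbon isotope tracing of fatty-acid origin.

## The problem

Palmitic acid (PAM, 16:0) in a growing animal's brain can arrive two ways:
taken up directly from dietary fat, or synthesized de novo (de novo
lipogenesis, DNL) from acetyl-CoA derived mainly from dietary sugars.
Because C4-plant sugars (corn-derived glucose polymers, sucrose) are
naturally enriched in ¹³C relative to C3-plant fats, the two sources carry
distinct natural-abundance carbon isotope signatures, and the δ¹³C of a
tissue fatty acid measured by GC-C-IRMS reveals where its carbon came from
— no tracer needed. `dnltrace` implements the full analysis chain for such
compound-specific isotope analysis (CSIA) studies, aimed at lipid
biochemists and isotope-ecology-style mixing modellers working in R.

## The model

δ notation expresses a ¹³C/¹²C ratio *R* against the VPDB standard
(*R*<sub>VPDB</sub> = 0.0112372):

δ¹³C = 1000 · (*R*/*R*<sub>VPDB</sub> − 1)  [mUr ≡ ‰]

The pipeline stages are:

1. **VPDB normalization** — per-sequence OLS fit of certified reference
   material (CRM) deltas, certified on measured, applied to unknowns, with
   an R² > 0.999 quality gate.
2. **Methyl correction** — FAME derivatization adds one methyl carbon; the
   carbon mass balance *n*<sub>FAME</sub>·δ¹³C<sub>FAME</sub> =
   δ¹³C<sub>ME</sub> + *n*<sub>FA</sub>·δ¹³C<sub>FA</sub> (default
   δ¹³C<sub>ME</sub> = −41.56 mUr) recovers the native fatty-acid delta.
3. **Quantification** — internal-standard (17:0) area ratios give amounts,
   µg/g concentrations and relative percents.
4. **End-members** — pooled "dietary sugars" signature (−11.15 ± 0.65 mUr
   for the shipped three-diet table) and per-diet dietary-PAM signatures.
5. **Mixing** — the two-end-member fraction
   *f* = (δ<sub>tissue</sub> − δ<sub>fat</sub>) / (δ<sub>sugar</sub> −
   δ<sub>fat</sub>) apportions a tissue pool to DNL from sugars, with
   delta-method or Monte-Carlo uncertainty.
6. **Statistics** — ROUT outlier screening, type-III diet × time ANOVA
   with conditional Tukey post hoc, and Shapiro-gated one-way
   ANOVA/Kruskal–Wallis.

A forward simulator (`generate_study()`) produces synthetic bundles with
known ground truth for every stage, so round trips and parameter recovery
are testable end to end.

## Worked example

```r
library(dnltrace)
library(dplyr)

sugar_signature()
#>   label          delta_mur sd_mur n_members
#> 1 dietary sugars     -11.2  0.651         3

res <- generate_study(generator_config()) |> run_pipeline()
res$mixing |> group_by(diet) |> summarise(mean_fraction = mean(fraction_sugar))
#>   diet  mean_fraction
#> 1 HP            0.590
#> 2 LP            0.873
#> 3 MP            0.725

tidy(res$stats$brain)
#>   term              df statistic  p.value
#> 1 diet               2   110.    8.17e-21
#> 2 timepoint          3     0.757 5.23e- 1
#> 3 diet:timepoint     6     1.37  2.43e- 1

dose_response_profile(filter(res$mixing, tissue == "brain"))$monotone
#> [1] TRUE
```

The pooled dietary-sugars end-member sits at −11.15 mUr with a 0.65 mUr
spread; in the simulated study the recovered DNL fraction is largest on the
low-PAM diet and smallest on the high-PAM diet (0.87 vs 0.59 across both
tissues here), the diet main effect dominates the brain ANOVA
(p ≈ 8 × 10⁻²¹), and the LP ≥ MP ≥ HP dose-response ordering is recovered.

## Scope

The mixing model is deliberately a two-source linear model in delta space;
it does not correct for the circulating blood pool, does not split hepatic
from local brain DNL, and does not model additional depleted acetyl-CoA
sources (ketones, ketogenic amino acids) beyond clamping and flagging
out-of-range fractions. See the methods vignette
(`vignettes/isotope-mixing-workflow.Rmd`) for assumptions, parameter
choices and limitations.
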