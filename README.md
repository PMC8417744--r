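# synerflux

Analytics for two-stage drug-synergy discovery in acute myeloid leukemia
(AML): a primary ATP-bioluminescence viability screen scored with the Bliss
independence model, a secondary direct-infusion mass-spectrometry (DIMS)
metabolomics screen scored with a PCA-based multivariate synergy statistic
(PEDS), and stable-isotope-tracer metabolic flux analysis (MFA) with
Bayesian posterior sampling. The package is aimed at screening and
metabolomics groups who want the full analysis path — plate readouts to
flux effect sizes — as tested, reusable R functions, exercisable end to end
on synthetic data.

## What it computes

**Bliss synergy screening.** Relative viabilities are plate luminescence
means (after Dixon's Q replicate outlier removal) over the control mean,
kept uncapped (values above 1 are informative). For a drug *A* combined
with a partner *P*,

    Bliss index = v_A · v_P − v_AP

so positive values mean the combination kills more than independence
predicts; indices ≥ 0.1 flag strong synergism. Hits must spare stromal
cells (viability > 0.8 in both arms for every normal line) while showing
synergy (Bliss > 0.1) or efficacy (viability < 0.5 in both arms) in
leukemia lines; hit sets are unioned across oxygen conditions.

**DIMS feature cleaning.** Centroided peaks are annotated against a formula
database by mass accuracy (±5 ppm, protonated/deprotonated adducts), then
cleaned in the fixed order replicate filter (detected in ≥ 4 of 5
replicates of some treatment group) → blank filter (sample/blank mean ratio
> 3) → sample filter (detected in > half of non-blank samples) →
missForest-style random-forest imputation, with probabilistic quotient
normalization (PQN) available for dilution correction.

**PEDS.** For each combination, PCA on the cleaned profiles of the four
groups (ctrl, drug1, drug2, comb) yields group centroids `p` and variance
proportions `γ`; synergy is the γ-weighted distance of the combination from
control relative to the additive expectation:

    PEDS = sqrt(Σᵢ γᵢ (p_comb,i − p_ctrl,i)²) /
           ( ½ · sqrt(Σᵢ γᵢ (p_drug1,i + p_drug2,i − 2 p_ctrl,i)²) )

PEDS = 1 at exact additivity of displacements; PEDS > 1 is synergistic.

**Tracer MFA.** Isotopologue intensities are corrected for natural isotope
abundance (non-negative least squares against a binomial correction
matrix), giving mass isotopomer distribution vectors (MDVs). An atom-mapped
network model (a packaged 53-reaction / 34-metabolite central-carbon
curation with glucose uptake pinned at 100) simulates steady-state MDVs via
elementary-metabolite-unit (EMU) decomposition; a Metropolis–Hastings
random walk in the free-flux space samples the posterior under the
Gaussian-error likelihood `exp(−RSS/2)`, where RSS sums squared
SD-standardized differences between measured and simulated isotope
fractions. Per-reaction fluxes are compared between conditions as
`log10(v/v_CS)` (citrate synthase reference) using Cohen's d with the
0.2 / 0.5 / 0.8 magnitude thresholds.

**Synthetic data.** `gen_plate()`, `gen_feature_table()` and
`gen_tracer_dataset()` emit every input the pipeline consumes from declared
ground truth (planted interactions, combination rule `d_comb =
α(d1+d2)/2`, known fluxes), so each stage — and the whole chain — is
testable without any download.

## Worked example

```r
library(synerflux)

## 1. primary screen: audit the reported Bliss indices by estimating the
##    partner viability from the other screen rows (leave-one-out)
rec <- reconstruct_bliss(condition = "hypoxia")
head(rec[, c("drug_name", "v_drug", "v_combo", "reported_bliss",
             "reconstructed_bliss")], 4)
#>          drug_name v_drug v_combo reported_bliss reconstructed_bliss
#> 1       Paclitaxel  0.420   0.303          0.075              0.0745
#> 2            AC220  1.101   0.855          0.134              0.1346
#> 3      Vincristine  0.324   0.216          0.074              0.0752
#> 4 Flavopiridol HCl  0.722   0.728         -0.079             -0.0791

## 2. PEDS on a synthetic secondary screen with a planted super-additive
##    combination (alpha = 2)
gen <- gen_feature_table(omics_spec(n_features = 40, alpha = 2,
                                    noise_sd = 0.1), seed = 1)
ft <- clean_features(gen$table, seed = 1)
peds(fit_pca(preprocess_profiles(ft, offset = 0)))
#> PEDS = 1.9796 (synergistic; 19 components)

## 3. tracer MFA: recover known fluxes on a branched toy network
model <- toy_model("branched")
truth <- interior_flux(model)
gt <- gen_tracer_dataset(model, truth$v, tracer_spec("GLC_x", 1:2, 1),
                         targets = c("PYR", "LAC", "OAA"), sd = 0.005,
                         seed = 1)
fit <- mfa_fit(model, gt$data, schedule = desk_schedule(), seed = 1)
fit
#> Flux posterior fit: 10000 retained samples (4 chains), median RSS 3.672
s <- summary(fit); s$truth <- truth$v
s[s$reaction %in% c("EMP", "OXP", "PC", "LDH"), ]
#>   reaction mean     sd   q2.5 q97.5 truth
#> 2      EMP 37.4  0.385 36.687  38.2  37.1
#> 3      OXP 62.6  0.385 61.813  63.3  62.9
#> 7      LDH 53.5 30.887  3.689 115.6  66.8
#> 9       PC 26.3 17.169  0.994  59.3  30.6
```

Reading the example: the glycolysis/oxidative-branch split (EMP vs OXP) is
sharply identified by the labeling data (posterior SD ~0.4 flux units),
while the lactate-export split (LDH) is weakly identified — its wide
credible interval still covers the truth. `flux_ratios()` +
`compare_flux_ratios()` then turn two such fits into a per-reaction
Cohen's-d table.

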