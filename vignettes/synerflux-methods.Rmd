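---
title: "Methods: synergy screening, PEDS, and tracer flux analysis"
author: "synerflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synergy screening, PEDS, and tracer flux analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synerflux)
```

This vignette documents the models implemented by synerflux, the choices
made where the methodology was genuinely open, and what the synthetic-data
tests do and do not establish about real data.

## 1. Primary screen: Bliss scoring

The screen model is an ATP-bioluminescence readout proportional to viable
cell number. Per treatment group, replicate signals (typically four) are
first passed through Dixon's Q test — the small-sample outlier test
comparing the gap of the most extreme value to the data range against
tabulated critical values — and then averaged; relative viability is the
group mean over the control-group mean.

Choices worth stating explicitly:

* **Dixon's Q at 95% confidence, two-sided, single pass.** The test is
  tabulated for 3–10 replicates; only the most extreme value is ever
  removed, which makes the filter idempotent in practice. 90% and 99%
  tables are packaged too; 95% is the conventional default for replicate
  QC and the one we adopt absent stronger guidance.
* **Viabilities are not capped at 1.** The packaged OCI-AML3 screen summary
  is only internally consistent under uncapped viabilities: a single
  partner viability `v̂` reproduces all 21 printed Bliss indices (within
  ±0.006, see the regression test) only when drug-alone viabilities above
  1 (e.g. AC220, 1.101) enter the product `v_drug · v̂` unclipped.
* **Bliss index on the viability scale**: `BI = v_drug · v_partner −
  v_combo`; `BI > 0` synergistic (strict), `BI ≥ 0.1` strong synergism
  (inclusive).
* **Hit criteria read conjunctively across arms.** "With and without the
  partner" is enforced in both arms for the stromal-sparing clause and for
  the leukemia-kill clause; the leukemia clause is satisfied if *any*
  leukemia line qualifies, the stromal clause only if *all* stromal lines
  do. The per-condition hit sets are combined by set union.
* Replicate SDs are reported alongside viabilities but not propagated into
  the index — the index is a point summary; uncertainty enters the pipeline
  downstream (PEDS replication, flux posteriors).

`partner_viability_ls()` implements the audit used in the worked example:
given rows `(v_drug, v_combo, BI)` sharing one partner, least squares gives
`v̂ = Σ v_drug (BI + v_combo) / Σ v_drug²`.

## 2. DIMS cleaning

Direct-infusion MS trades chromatographic depth for throughput; the
cleaning cascade is what makes its feature tables statistically usable.
The order is fixed — replicate filter, blank filter, sample filter,
imputation — because each step's contract assumes the previous one.

* **Annotation** is by mass accuracy only, inclusive at exactly 5 ppm, with
  `[M+H]+`/`[M−H]−` as default adducts (extensible). Isobaric database
  entries are all retained and flagged ambiguous rather than resolved —
  DIMS cannot distinguish them without tandem MS, which is out of scope.
* **"Detected" means non-missing.** Zeros are treated as measured values;
  this keeps the filters well defined when an instrument exports true
  zeros.
* **Replicate filter**: kept if detected in ≥ 4 of 5 replicates of at least
  one treatment group (ctrl/drug1/drug2/comb); undersized groups are
  skipped with a warning rather than silently passing.
* **Blank filter**: strict mean-signal/mean-blank > 3; zero or all-missing
  blank signal keeps the feature (no evidence of contamination).
* **Sample filter**: strictly more than half of the non-blank samples; QC
  samples count as samples, blanks never do.
* **Imputation** is an iterative random-forest scheme: initialize missing
  cells with feature means, then per feature (in order of increasing
  missingness) fit a 100-tree regression forest on the other features and
  re-predict the missing cells, iterating until the relative change in the
  imputed values rises (stagnation) or 10 rounds. Observed cells are never
  altered; the seed fixes the forests, making the output reproducible; the
  hyperparameters are recorded in the attached imputation report.
* **PQN** divides each sample by the median of its feature-wise quotients
  against a reference spectrum (feature-wise median of QC samples, or of
  all non-blank samples). PQN estimates *relative* dilution: factors are
  identified up to the scale of the reference, so a constructed-dilution
  fixture recovers the planted factors exactly when the median planted
  dilution is 1. Within-sample ratios are preserved exactly.

## 3. PEDS

PCA is fitted per drug combination on its own four groups only (no
cross-combination pooling), on log-transformed, feature-centered profiles.
With group centroids `p` and variance proportions `γ`,

$$\mathrm{PEDS} = \frac{\sqrt{\sum_i \gamma_i (p_{comb,i}-p_{ctrl,i})^2}}
 {\tfrac12\sqrt{\sum_i \gamma_i (p_{drug1,i}+p_{drug2,i}-2p_{ctrl,i})^2}}$$

The rendering of this statistic admits two readings that differ in the
factor ½. We adopt the midpoint form above because it is dimensionally
symmetric, places PEDS = 1 exactly at additivity of the two single-drug
displacements (`d_comb = (d_1 + d_2)/2`), and matches the
Euclidean-distance naming; the variant without the ½ is available via
`peds(..., denominator = "sum")`. Other open choices: group scores are
**centroids** of replicate scores; **all** nonzero components are retained
by default (truncation at a cumulative-γ threshold is available); profiles
are centered but **not autoscaled** — with γ-weighting, autoscaling would
double-correct variance.

PEDS is invariant to relabeling drug1 ↔ drug2 and to scaling all
displacements by a common factor; both are property-tested, as is recovery
of a planted combination rule `d_comb = α(d_1+d_2)/2` for α ∈ {0.5, 1, 2}
as replicate noise vanishes.

## 4. Tracer arithmetic

Natural-abundance correction solves `raw = M x` for the tracer-only
isotopologue amounts, where column *j* of `M` is the nominal-mass shift
distribution of a molecule carrying *j* tracer atoms: binomial 13C/15N/2H
terms and multinomial O/S terms (+1 and +2 isotopes), with standard IUPAC
abundances (13C 0.0107, 15N 0.00364, 2H 0.000115, 17O 0.00038, 18O 0.00205,
33S 0.0075, 34S 0.0425), all overridable.

Conventions: the package works with **nominal-mass MDVs** — 13C and 15N
shifts are not resolved apart, matching DIMS practice and M+n reporting —
and for a dual 13C/15N tracer the *j* labeled atoms are attributed to
carbon first, then nitrogen, when deciding how many atoms remain available
for natural abundance. The solve is **non-negative least squares**
(unconstrained inversion produces negative fractions on noisy data);
corrected vectors are renormalized to sum to 1, and SDs are propagated
linearly through the triangular inverse. A condition-number guard (10⁸)
rejects degenerate matrices.

## 5. Flux model and EMU simulation

The packaged network (`default_model()`) is a curated, synthetic
53-reaction / 34-metabolite central-carbon model — glycolysis, a lumped
oxidative plus full non-oxidative pentose phosphate pathway, oxidative and
reductive TCA (explicit reverse reactions for the exchange-relevant steps),
glutaminolysis and transaminations — with atom maps in lowercase-letter
notation, succinate/fumarate symmetry encoded as 0.5/0.5 mapping variants,
no intracellular compartments, and glucose uptake pinned at 100 flux
units. It is assembled for this package, not a published reconstruction,
and the model JSON is a first-class user input: any letter-balanced
network loads through the same `load_model()` path.

Steady-state labeling is simulated by EMU decomposition: starting from the
requested metabolites, the network is decomposed backwards into the
minimal set of metabolite fragments whose mass distributions matter;
fragments of equal size form linear balance systems (coefficients linear
in the fluxes), and condensation reactions become convolutions of smaller,
already-solved fragments. The cascade structure is built once in R and
solved in compiled code, since it is the per-proposal hot path of the
sampler.

Numerical details: fluxes are parametrized as `v = v₀ + Nθ` over an
orthonormal basis `N` of the null space of the stoichiometry augmented
with the uptake pin, so steady state and the uptake value hold to machine
precision for every proposal; bound checks use a relative tolerance of
10⁻⁷ (fluxes pinned at a bound sit on it only up to rounding); pools whose
consuming reactions all carry zero flux are pinned to unlabeled — exact,
because every outgoing contribution of such a pool is weighted by that
same zero flux.

The test suite validates the simulator against an independent brute-force
isotopomer solver (full 2ⁿ state distributions iterated to a fixed point)
on five packaged toy networks covering pass-through, condensation,
branching with CO₂ re-fixation, symmetric scrambling, and a condensation
cycle. The fixed-point oracle is exponential in fragment size and its
iteration diverges on networks with strong bilinear exchange loops (the
transketolase/transaldolase cycle of the full model), so the full model is
instead validated structurally: closed-form glycolysis labeling
([0.5, 0, 0.5] pyruvate from 1,2-13C₂-glucose), MDV normalization across
random admissible fluxes, and the reductive-carboxylation direction of the
citrate M+5/(M+4+M+5) readout under 13C₅-glutamine.

## 6. Posterior sampling and effect sizes

The likelihood is the standard Gaussian-error reading of a residual sum of
squares: `L(v) ∝ exp(−RSS(v)/2)` with `RSS = Σ ((sim − meas)/sd)²` over all
measured isotope fractions; a configurable SD floor (default 10⁻³)
prevents zero-SD blowups. Sampling is a random-walk Metropolis–Hastings in
the free-flux coordinates: isotropic Gaussian proposals, rejection outside
bounds, acceptance `min(1, exp(−ΔRSS/2))`. The proposal scale adapts every
500 steps during burn-in toward ~30% acceptance and is frozen afterwards,
so the retained samples come from a fixed kernel. Chains start from a
bounds-feasible flux refined by a short quasi-Newton descent on the RSS;
per-chain seeds are the master seed plus the chain index, making runs
bit-reproducible.

Schedules: `full_schedule()` is 8 chains × 5,000,000 steps, 2,500,000
burn-in, thinning 1,000 — 2,500 retained per chain, 20,000 total.
`desk_schedule()` (4 × 50,000, thinning 10, 10,000 retained) is the
package default used throughout the tests and examples; it is the size at
which the toy-network experiments below are well converged.

Condition comparisons use per-reaction `log10(v/v_CS)` samples (citrate
synthase reference; nonpositive fluxes floored at 10⁻⁶ × uptake and
flagged; an error is raised if the reference itself is ≤ the floor in more
than 1% of samples) and Cohen's d with n−1-weighted pooled SD; |d| ≥ 0.2 /
0.5 / 0.8 label small/medium/large (inclusive), and d < −0.8 marks large
decreases.

**Parameter recovery.** The recovery experiment uses the branched toy
network — chosen because all its fluxes are identified or bounded by the
measured labeling, making interval coverage a meaningful check — with the
true flux at the polytope's analytic center (`interior_flux()`), tracer
data at SD 0.005, and the desk schedule over 10 seeds; ≥ 90% of free
fluxes must fall inside their central 95% posterior intervals. On the full
53-reaction model the same machinery runs, but exchange-flux directions
are weakly identified from single-tracer data and random-walk chains
traverse those flat valleys slowly; posterior intervals for exchange
fluxes at desk scale should be read as lower bounds on uncertainty. This
is a property of model-times-data identifiability, not of the sampler's
correctness.

## 7. Synthetic generators: scope of the evidence

The generators emulate the statistical structure of each input: lognormal
multiplicative noise for luminescence and feature intensities
(non-negative, CV-parametrized), group displacement vectors with the
combination rule `d_comb = α(d1+d2)/2` in log space, planted
blank-dominated and low-replicate features for filter tests, and MDVs from
known fluxes with zero-truncated, renormalized Gaussian noise. Missingness
is injected at a capped rate (at most one cell per feature and group) so
that planted-removal tests remain exact. Ground truth is always emitted
next to the data.

They deliberately do **not** simulate raw spectra, chromatography,
ionization suppression, batch drift, or heavy-tailed contamination. Green
tests therefore establish that the implementations compute their defined
quantities correctly and recover planted effects under the declared noise
model — not that the pipeline is robust to every artifact of a real
instrument run.

## 8. Known limitations

* The packaged flux model is a stand-in curation; results on real data
  should use a model file reviewed for the biological system at hand.
* Exchange fluxes of the full model are weakly identified from
  single-tracer MDVs (see §6); multi-tracer designs help and are supported
  by `measured_mdv_set()` taking several experiments.
* Natural-abundance correction assumes nominal-mass (unit-resolution)
  isotopologues; resolved fine structure would need an element-resolved
  correction.
* No IC50 curve fitting, Loewe/HSA models, plate spatial correction,
  tandem-MS identity confirmation, or compartmentalized/dynamic MFA.
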