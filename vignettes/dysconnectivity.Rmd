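---
title: "Normative dysconnectivity indices: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative dysconnectivity indices: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In disorders characterised by dysconnectivity — schizophrenia spectrum
disorders foremost — the question is rarely whether a *group* differs from
controls, but how far an *individual's* functional connectome deviates
from a healthy norm, and whether an intervention moves it back. `dysconn`
implements a normative-deviation pipeline for exactly this setting:

1. build a per-connection reference distribution of Fisher-z functional
   connectivity from a healthy cohort;
2. count, for each patient, region and session, the connections that
   deviate beyond a threshold (the dysconnectivity count, DCC) and
   aggregate them into hemisphere-normalised indices (the dysconnectivity
   index, DCI), whole-brain or restricted to networks and region pairs;
3. test longitudinal change with random-intercept linear mixed models
   across a battery of DCI outcomes, FDR-corrected, with Tukey post hoc
   contrasts expressed as Cohen's d;
4. relate regional change to clinical change scores by region-wise
   regression; and
5. relate the spatial pattern of change to parcel-level gene expression
   through spatial-autocorrelation-preserving surrogate maps and
   pre-ranked cell-type gene-set enrichment.

Every stage is exercisable end to end on synthetic data with known ground
truth; no imaging data, atlas download or donor expression data is needed.

# The deviation model

For hemisphere $h$ and connection $c$, the reference cohort provides
$\hat\mu_{hc}$ and $\hat\sigma_{hc}$, the across-subject mean and SD of
the Fisher-z connectivity $z_{hc}$. A connection of a new subject is
*dysconnected* when

$$|z_{hc} - \hat\mu_{hc}| > k_{\mathrm{eff}}\,\hat\sigma_{hc},$$

two-sided, with nominal threshold $k = 2$ by default. The DCC of a region
is the number of flagged connections incident to it (within hemisphere;
hemispheres are processed separately end to end, and cross-hemisphere
connections are never formed). The whole-brain DCI is the hemisphere's
summed DCC divided by the hemisphere's region count; a *specific* DCI
restricts the flag set to connections between two region sets $A$ and $B$
(a network when $A = B$, a seed pair otherwise) and normalises by
$|A \cup B|$.

## Finite-reference calibration of the threshold

With an infinite reference cohort, a healthy subject would flag a fraction
$2\Phi(-k) \approx 0.0455$ of connections at $k = 2$. With $n$ reference
subjects, both $\hat\mu$ and $\hat\sigma$ are estimates, and the naive
$k$-SD rule flags

$$2\left(1 - F_{t,n-1}\!\left(k/\sqrt{1 + 1/n}\right)\right)$$

— about $0.055$ at $n = 40$, a 22% excess that is pure estimation
artefact. `fit_reference_norm(calibrate = TRUE)` (the default) therefore
stores

$$k_{\mathrm{eff}} = \sqrt{1 + 1/n}\; F^{-1}_{t,n-1}(\Phi(k)),$$

which restores the nominal $2\Phi(-k)$ flag rate for held-out subjects
drawn from the reference population, exactly under Gaussian deviations,
and converges to $k$ as $n \to \infty$ (at $n = 40$,
$k_{\mathrm{eff}} \approx 2.09$). `calibrate = FALSE` restores the naive
rule. The deviation rule itself, the two-sidedness, and $k$ are
configurable and recorded in the norm object; the exact threshold used by
the original clinical work is not public, so $k = 2$ two-sided is a
documented default, not a fidelity claim.

## Change maps

Longitudinal change is expressed per region by standardising the DCC
across all participants (both sessions pooled, the default) and
subtracting: standardised baseline minus standardised follow-up, so that
**positive change = reduction in dysconnectivity**. The source
description of this step is ambiguous about the normalisation statistic
and the subtraction order (its literal order contradicts its stated sign
interpretation); the implementation follows the stated interpretation,
offers per-session standardisation as an option, and stores the
convention in the map's metadata.

# The longitudinal model

Each DCI outcome is modelled as

$$\mathrm{DCI}_{ijk} = \beta_0 + \sum_n \beta_n X_{ijk,n} + \gamma_i +
\varepsilon_{ijk}$$

for subject $i$, session $j \in \{\text{baseline}, \text{follow-up}\}$
and hemisphere $k \in \{L, R\}$, with fixed effects session, age, sex,
chlorpromazine-equivalent dose, number of achieved exercise sessions,
group and hemisphere, and a per-participant random intercept $\gamma_i$.
Estimation is REML (lme4), session p-values use Satterthwaite degrees of
freedom (lmerTest). The battery fits thirteen outcomes — whole brain,
eight networks (visual, somatomotor, limbic, frontoparietal,
default-mode, dorsal attention, salience, subcortical), and four seed
scopes (thalamus–middle-frontal, thalamus–somatomotor,
hippocampal-formation–prefrontal, within hippocampal formation) — and
corrects the thirteen session p-values by Benjamini–Hochberg FDR.
Covariates without variation are dropped from the design automatically; a
constant response short-circuits to a zero effect with zero variances.

The post hoc session contrast (follow-up minus baseline, Tukey-adjusted
via emmeans, degenerate for two levels) is standardised to Cohen's d by
the model-based total SD $\sqrt{\hat\sigma^2_\gamma +
\hat\sigma^2_\varepsilon}$ — the source does not state its standardiser,
and this model-based choice is the only one implemented; it is recorded in
the result object. A DCI that falls over the intervention yields $d < 0$.
The 95% CI maps the contrast's t interval onto the d scale and therefore
ignores the sampling error of the standardiser itself; simulation (see the
acceptance suite) puts its coverage near 0.95 for desk-scale designs with
a moderate random-intercept share.

Clinical relevance is assessed descriptively: per region, OLS of the
clinical change score (GAF, PANSS, cognition composite; all encoded so
that positive = improvement) on the region's DCC change, controlling for
age, sex and CPZ equivalents, with beta maps thresholded at an
*unadjusted* p < 0.05 — deliberately hypothesis-generating, mirroring the
source's explicitly liberal choice; an FDR-thresholded variant is a flag
away.

# Imaging transcriptomics

The session-effect map (per-region repeated-measures model of the DCC,
sign-flipped so positive = reduction) is parcellated by averaging regions
within parcels. Spearman correlations between the parcellated map and
each gene's expression profile get spatial p-values from
variogram-matched surrogates: each surrogate permutes the map, smooths
the permutation with exponential distance kernels over a ladder of
candidate scales (plus the unsmoothed permutation itself), keeps the
scale whose empirical variogram — ten equal-count distance bins — best
matches the original's in least squares, and rank-remaps the result onto
the original value multiset. The surrogate therefore preserves the value
distribution *exactly* and the spatial autocorrelation *approximately*;
the design goal is that preservation property, not bit-compatibility
with any published toolbox (the full published scheme additionally
regresses smoothed permutations onto the target with free amplitude
parameters). Euclidean distances between parcel centroids stand in for
geodesic distances — a documented limitation. The two-sided spatial
p-value uses the add-one convention $p = (1 + \#\{|\rho_{\mathrm{surr}}|
\ge |\rho|\})/(n_{\mathrm{surr}} + 1)$ and can never be zero.

Cell-type enrichment is pre-ranked GSEA on the per-gene correlation
vector: the weighted Kolmogorov–Smirnov running sum with weight exponent
1 (hits advance by $|\rho|$, misses retreat by $1/(N - m)$), null ES from
gene-label permutations (sample permutation being impossible for a single
ranked vector), NES as ES over the mean absolute same-sign null ES, and a
signed-NES permutation FDR. Both tail fractions of the FDR ratio use
add-one smoothing: with a strongly coupled gene set at the top of the
ranking, the null ES distribution becomes heavily sign-asymmetric and the
rare-sign side may contain only a handful of permutation draws, which
would otherwise collapse to an over-confident q = 0.
Benjamini–Hochberg over nominal p-values is available as an alternative.
Positive NES marks sets whose expression is higher where dysconnectivity
fell.

# The synthetic-data generator

The generator is first-class, tested code; it defines the study
conditions under which every property is verified.

**Cohorts.** Two hemispheres of 60 regions each (desk-scale default),
12 network/region-group labels with deliberately *unequal* region shares
— default-mode largest (10/60), sensory networks next (8/60), focal
region groups smallest (2/60) — reflecting the strongly unequal cortical
footprint of resting-state networks. The population connectivity of a
hemisphere is a block correlation matrix (within-network r = 0.35,
between 0.10). Each subject deviates from it by
$\mathrm{cov2cor}((I + E)\,\Sigma\,(I + E)^{\!\top})$ with Gaussian $E$,
scaled (with a fixed-point correction for the diagonal renormalisation)
so the per-connection Fisher-z deviation SD is `subject_sd` (default
0.1). This construction guarantees a valid correlation matrix for every
subject — independent per-connection deviations of realistic size cannot
stay positive definite at this dimension — at the cost of weak
dependence between a subject's deviations. $E$ is drawn once per subject
(a stable trait across sessions) and shared between hemispheres,
emulating the dominantly homotopic organisation of individual
connectivity deviations; this also makes the longitudinal model's single
per-participant random intercept correctly specified. Frames are drawn
i.i.d. multivariate Gaussian (no temporal autocorrelation), keeping the
connectivity oracle closed form; series pass through the cleaning
pipeline unchanged in expectation because correlations are invariant to
its operations.

**Planted effects.** A planted effect shifts the Fisher-z of a target
connection set by `baseline_shift` at baseline and by
`baseline_shift * (1 - attenuation)` at follow-up, mapped back through
tanh so correlations stay valid. A network target means the network's
within-network pairs by default; an `"incident"` scope (every connection
touching the network) exists but is geometrically feasible only for
small shifts — a few regions cannot each correlate strongly with many
mutually weak ones, and infeasible targets trigger the logged
eigenvalue-clipping repair. The planted magnitudes are free parameters
of the generator, not estimates of any study's effect sizes.

**Clinical scores and expression.** Clinical change scores are weighted
sums of each subject's *realised* regional deviation change in a target
network plus noise (positive = improvement for all three scales).
Parcel-by-gene expression couples one annotated cell-type set (default:
oligodendrocytes, `Oli`, among ten single-nucleus-style sets of 150
genes each) to a target map with strength `coupling` (default 0.5) on
top of unit-SD noise; all other genes are pure noise.

## What the generator does not emulate

No haemodynamic forward model, no temporal autocorrelation by default,
no head motion, no scanner or site effects, no spatially heterogeneous
reference variance, no overlap between cell-type gene sets, and
correlation-geometry-level realism only (no anatomical connectome
structure). Passing tests therefore demonstrate that the *method* is
calibrated and recovers planted truth under a clean generative model —
not that any particular clinical dataset would yield the same effect
sizes.

# Numerical choices

* Correlations are clipped to $\pm(1 - 10^{-6})$ before `atanh`, keeping
  z finite without materially changing any realistic value.
* Cleaning order: drop first 5 frames → per-region linear detrend →
  zero-phase order-2 Butterworth band-pass (0.01–0.08 Hz) →
  standardisation last.
* Framewise displacement uses the backward-difference formulation with
  rotations scaled to arc length on a 50 mm sphere.
* Reference SDs below `sd_floor` ($10^{-6}$) are floored, keeping the
  deviation rule defined for degenerate reference sets.
* Non-positive-definite target covariances are repaired by eigenvalue
  clipping at $10^{-8}$ followed by rescaling to unit diagonal; every
  repair is recorded in the study log.
* Ties in the surrogate rank-remapping are broken by first occurrence,
  which keeps the value multiset exact.
* Change-map regions with zero pooled SD yield zero change rather than
  NaN.

# Problem sizes used by the tests and the acceptance script

The shipped checks run at desk scale, chosen to exercise the full
pipeline in minutes on one core: cohorts of 40 reference and 12 patient
subjects, 60 regions per hemisphere, 300 timepoints; 100-replicate
calibration loops for the mixed-model and clinical-map nulls; 100
parcels × 2000 genes × 1000 permutations (50 seeded repetitions) for the
enrichment recovery; 200–500 surrogates for the spatial nulls. The
reference-cohort machinery is size-agnostic (a 200-subject norm — the
scale of the original healthy reference — fits without modification).

# Known limitations

* The deviation threshold and its two-sidedness follow a documented
  default, not a published value; results depend on $k$ and the norm
  records it.
* The Cohen's d confidence interval ignores standardiser uncertainty.
* The surrogate engine matches a single kernel scale per surrogate;
  maps whose autocorrelation mixes scales are matched only coarsely, and
  spatial p-values are approximately, not exactly, calibrated.
* The nuisance-regression step of fully real pipelines is out of scope:
  the pipeline starts from cleaned region-by-time series.
* Cross-hemisphere connections are never analysed, by design.
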