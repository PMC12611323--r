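---
title: "Methods: building and evaluating a common-dolphin epigenetic clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and evaluating a common-dolphin epigenetic clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delphiclock)
```

## The problem

Age determination in free-ranging odontocetes is hard: external ageing cues
are minimal, and the reference method — counting dentinal growth layer
groups in extracted teeth — is invasive, mostly post-mortem, and loses
reliability in old animals whose teeth are worn or show accessory lines.
DNA methylation drifts predictably with age at a subset of conserved CpG
sites, so a penalized regression on methylation fractions ("beta values",
methylated/total signal per CpG in [0,1]) can act as an *epigenetic clock*.
This package implements such a clock for the common dolphin end to end:
quality control, age transformation, elastic-net fitting with leave-one-out
cross-validation (LOOCV), a hybrid maturity-gated model, sex
classification, and the evaluation suite, plus a synthetic-data generator
that makes the whole pipeline testable.

## The age transformation

Epigenetic ageing is faster before sexual maturity. We therefore fit clocks
not on chronological age but on a log-linear transform anchored on the age
at sexual maturity *m* (ASM) and gestation length *g*:

$$T(a) = \begin{cases}\log\dfrac{a+g}{m+g} & a < m\\[4pt]
\dfrac{a-m}{m+g} & a \ge m\end{cases}$$

logarithmic (compressing) before maturity, linear after, continuous and
once-differentiable at the knot (both one-sided derivatives equal
$1/(m+g)$), and strictly increasing on $a > -g$. The gestation offset makes
birth ($a = 0$) a regular interior point, so neonates are representable.
The inverse is $T^{-1}(y) = (m+g)e^{y} - g$ for $y<0$ and $y(m+g)+m$
otherwise; the gestation correction lives *inside* this inverse (the $-g$
term), and no second additive correction is applied anywhere else, so
predictions are gestation-adjusted exactly once. `llin2()` exposes the
branch point `asm` as an argument: the standard clock uses the pooled
anchor, the hybrid model each sample's sex-specific anchor.

Default life history (overridable for other species, all in years):

| parameter | default | role |
|---|---|---|
| `asm_female` | 7.5 | female maturity anchor (hybrid model) |
| `asm_male` | 8.8 | male maturity anchor (hybrid model) |
| `asm_pooled` | 8.15 | anchor of the standard clock (mean of the two) |
| `gestation` | 1.05 | offset making age 0 regular |
| `max_lifespan` | 60 | data-validation bound on dental age |

## Quality control

Three screens, mirroring standard methylation-array practice:

1. **Probe failure.** A measurement fails when its detection p-value is
   strictly above 0.05 (background-level signal).
2. **Fraction outliers.** Samples with strictly more than 1% failed probes
   are excluded. Both comparisons are deliberately strict (`>`), so a
   sample at exactly the threshold survives.
3. **Multivariate outliers.** Betas are centred per CpG (not scaled, not
   otherwise normalised), samples are projected onto the top principal
   components (enough to explain 90% of variance, capped at 5), and each
   sample's Euclidean distance to the sample centroid is computed; samples
   strictly above mean + 2 SD of those distances are excluded.

The third screen folds the usual PCA-plus-hierarchical-clustering visual
inspection into a single order-invariant, reproducible criterion; the 2-SD
rule is retained, and the criterion (components, SD multiplier) is
pluggable. One caveat worth stating: which samples it flags depends on what
dominates the variance. On synthetic data, where age drift is the largest
variance component and no technical artifacts are simulated, it tends to
flag age-extreme animals; on real arrays, technical variance (batch,
degradation) usually dwarfs biology and the flagged samples are genuine
technical outliers. Manual exclusions (e.g. animals with inconsistent
life-history records) are passed explicitly and recorded with their own
reason code. `apply_qc()` is idempotent.

## Clock fitting and cross-validation

**Elastic net.** `fit_clock()` regresses $T(\text{age})$ on betas with
penalty $\lambda[(1-\alpha)\|\beta\|_2^2/2 + \alpha\|\beta\|_1]$ via
glmnet. Features are standardized internally by the solver and
coefficients reported on the beta scale. λ is chosen by seeded internal
10-fold cross-validation under the minimum-mean-CV-error rule (not the
1-SE rule — the default of the fitting ecosystem this follows). Predicted
transformed ages are inverted to years before any error metric is
computed.

**α selection.** `select_alpha()` scans α over 0, 0.1, …, 1 on 20 seeded
random 2/3 splits, scoring held-out MSE *on the transformed scale* (the
fitting scale; scoring in years would overweight old-age errors), and picks
the α with the lowest median MSE. Ties break toward the larger α, i.e. the
sparser model. α is selected once per subset and then held fixed during
LOOCV; the mild optimism this induces (the selection saw all samples) is a
known property of the workflow this reproduces.

**LOOCV.** `loocv_predict()` refits the full clock (including a fresh
internal λ search) on every size-$n-1$ subset. Each fold's randomness is
seeded from the *left-out sample's id*, not its position, so results are
invariant to sample order and an independent loop that materializes each
training set and calls `fit_clock()` with
`derive_seed(seed, paste0("loo:", id))` reproduces the pipeline exactly —
that equivalence is asserted in the tests rather than assumed.

**Degenerate inputs.** All-constant features produce an explicit
intercept-only model (intercept = mean transformed age, λ = ∞) rather than
a solver error; missing betas abort rather than being imputed silently.

**A numerical choice that matters.** glmnet by default truncates its λ path
once the deviance explained saturates (`fdev`/`devmax` stopping). On
near-noise-free data that truncation leaves a visibly shrunken model —
predictions biased several tenths of a year — so the package disables it
around every CV fit and lets the path run to the smallest λ. On noisy data
this costs a little time and changes nothing.

## Subsets and evaluation

Three nested analysis subsets: *relaxed* (all QC-passing samples), *strict*
(relaxed minus samples whose dental age is only a minimum estimate), and
*restricted* (relaxed minus samples with relaxed-LOOCV absolute error of 6
years or more — strictly-less-than-6 survives). Note an intentional
asymmetry: the restricted filter uses `< 6` while the error *counts* in the
report use `> 6`, so a sample with an error of exactly 6 is dropped from
restricted yet not counted among the ">6 years" errors.

`evaluate_predictions()` reports n, median absolute error (the headline
"MAE"; the mean is reported separately), Pearson *r*, and an OLS of
predicted age (response) on dental age (predictor) with slope, intercept
and R²; slopes below 1 are the signature of regression to the mean —
over-ageing the young, under-ageing the old — which penalized regression
produces mechanically when signal is weak. With pure-noise features the
LOO prediction-versus-age slope is approximately 0 (each prediction is
essentially the training mean), a property the tests assert at n = 80.

Covariate checks: a tie-corrected Kruskal–Wallis test of absolute error
across decomposition-condition categories (taken as they occur in the
data); and for storage duration, a Spearman correlation plus OLS of error
on storage with and without chronological age as covariate
(Shapiro–Wilk on residuals). The age-adjusted model matters because error
grows with age and archive composition often makes storage time track age;
the tests construct exactly that confound and verify the adjustment
removes the spurious storage effect. The all-ties Kruskal–Wallis case
(every error equal) is defined as H = 0 explicitly, since the tie
correction is 0/0 numerically.

## The hybrid model

Clocks underestimate old animals. The hybrid model counters this with
three components sharing one feature matrix: a random-forest classifier
(1000 trees) of physical maturity (≥ 18 y females, ≥ 20 y males, both
inclusive), an elastic net trained on everyone, and an elastic net trained
on mature animals only. Both nets regress $T$(age) anchored on the
sample's sex-specific ASM, with α and λ chosen jointly by seeded 5-fold
internal CV. A sample's prediction is the convex combination
$(1-p)\,\hat a_{\text{all}} + p\,\hat a_{\text{mature}}$ with $p$ the
forest's maturity probability, so predictions are always bounded by the two
component clocks, and forcing $p \in \{0, 1\}$ recovers each component
exactly (tested). Model-level evaluation uses k-fold CV (default 5)
*stratified by maturity label* — a choice the reference workflow leaves
open, made here
because unstratified folds can easily leave a training fold with no mature
animals when only a dozen exist. The mature-only net requires a configured
minimum of mature samples (default 10) and aborts otherwise rather than
silently degrading.

## Sex classification

A binomial elastic net on betas (male = 1, α = 0.4 by default, λ by seeded
internal CV, betas standardized as in the age clocks — the reference
workflow is silent on this and we follow the age-clock convention). A
sample is called male only when P(male) strictly exceeds 0.5; an exact tie
is female. Default evaluation is resubstitution, mirroring the reference
workflow (which applies no cross-validation to the sex model); for honest
generalization estimates use a
held-out split, as the tests do.

## The synthetic-data generator

`simulation_spec()` / `generate_dataset()` emulate the study conditions the
pipeline assumes: 84 samples before QC; ages 0–34 y drawn from a
Beta(1, 1.8) density rescaled to the range, so most animals are 0–20 y with
a minority of physically mature adults (roughly a fifth, matching the kind
of stranding-archive age structure the analysis has to cope with); a 47:37
female:male ratio; a 2,000-probe array standing in for the 37k-site
mammalian array, with 40 age-informative CpGs whose betas follow
$\mathrm{clamp}(b_j + s_j\,T(\text{age}) + \varepsilon,\,0,\,1)$ with
slopes 0.04–0.12 (random sign), 10 sex-differential CpGs offset ±0.3 in
males (large enough for complete separation, the synthetic analogue of
perfect sex calling), Gaussian beta noise (SD 0.02), and detection
p-values failing independently per cell at rate 0.002. Minimum-age flags go
to the oldest animals, where growth-layer counting actually fails. The two
oldest (flagged) animals sit at the age extreme, so the PCA outlier screen
can remove them on synthetic data (see the QC caveat above) — in that case
the strict subset coincides with the relaxed one; this is a property of the
simplified variance structure, not of the pipeline.

What the generator does *not* emulate — and therefore what green tests do
not certify about real data: batch and chip effects, probe
cross-hybridization, logit-scale (rather than clamped-linear) dynamics,
nonlinear or saturating age trajectories, correlated CpG modules, and
technical outlier samples. Passing the suite shows the machinery is
correct and calibrated in a regime where truth is known, not that any real
archive will yield a given MAE. Clamping keeps the model interpretable; a
logit-normal option would be the natural extension.

## Determinism and problem sizes

Every stochastic step draws from a seed derived as
`derive_seed(top_seed, key)` — a 31-bit polynomial hash of a stage- or
sample-specific key — so adding a stage never perturbs another stage's
stream, LOOCV is order-invariant, and identical configuration plus seed
reproduces every artifact byte for byte (asserted in the pipeline tests).
The test and acceptance workloads use n = 80–84 samples × 2,000 CpGs for
the signal-recovery and pipeline checks, 500 CpGs for the pure-noise
regression-to-the-mean check, and hand-sized fixtures (≤ 30 samples) for
the exact oracle-equivalence checks; these sizes are the package's chosen
balance between covering the estimator's behaviour and keeping the suite
quick to run.

## Known limitations

- The multivariate QC criterion flags whatever dominates variance; on data
  without technical artifacts that is biology (see above).
- α is selected before LOOCV on the same samples (mild optimism, inherited
  from the reference workflow).
- The mature-only clock is only as good as the handful of mature animals
  available; the minimum-sample guard refuses, it does not rescue.
- Resubstitution sex accuracy overstates generalization; use a split.
- Beta values are consumed as given: no normalization, batch correction or
  probe filtering is attempted upstream.
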