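---
title: "Models and methods behind neurocostar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neurocostar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocostar)
```

neurocostar implements the analysis chain of image-based ex vivo drug
screening in glioblastoma: pharmacoscopy (PCY) scoring of marker-gated
cell populations, a layered drug–target connectivity network
("constellation"), a cross-validated L1-penalized logistic model that
learns a minimal connectivity signature predictive of drug efficacy
(COSTAR), single-cell expressing-fraction specificity scores, and
calcium-trace analysis.  Every stage can be exercised on synthetic data
with planted ground truth; this vignette documents the models, the
parameters that matter, and the numerical and design choices made.

## PCY scoring

A well table carries one row per segmented cell with boolean marker
gates.  Populations are defined by boolean expressions over the gates:
glioblastoma cells are (Nestin+ or S100B+) and CD45−, immune cells are
CD45+ and Nestin−/S100B−, and triple-negative cells are "other".  Cells
matching no definition (e.g. Nestin+CD45+) are left unassigned but stay
in the all-cells denominator, because the denominator is every
DAPI+ nucleus.

Per well, the target-population fraction is `count / total`; per drug,
fractions are the *unweighted mean* over that drug's replicate wells,
which makes the estimate robust to well-size variation.  The PCY score
is the relative reduction against vehicle control,

$$\mathrm{PCY} = 1 - \mathrm{TP_{DRUG}} / \mathrm{TP_{DMSO}},$$

so 1 is the strongest on-target response, 0 means no effect, and
negative values mean the drug hits the non-target populations harder.
A zero DMSO fraction leaves the score undefined (missing), never
infinite.

Replicate significance uses a two-sample t-test on per-well target
fractions, Welch-corrected; the compared quantity is a design choice —
the source material names the test but not its units — and per-well
fractions are the natural replicate-level observable.  The one-tailed
alternative is a reduction under drug.  Families of p-values (all drugs
× concentrations within one patient sample) are adjusted with Holm when
the family holds fewer than 20 values and Benjamini–Hochberg otherwise.
Sample-level on-target hits require score > 0 and q < 0.05; a
cohort-level "top drug" requires a mean score across patients > 0.03.

Marker gating, when raw intensities are supplied, fits one threshold
per plate and channel.  The default is a two-component Gaussian mixture
on log10 intensity with the threshold at the posterior crossover;
fixed thresholds and a background-quantile rule are available.  The
mixture needs at least 500 cells per plate; a zero-variance channel is
an error naming the channel.

## The constellation

Bioactivity records map compounds to genes.  Primary target genes
(PTGs) are those with an inhibitory-constant (KI) endpoint; extended
primary target genes (ePTGs) include any bioactivity annotation, so
PTG ⊆ ePTG per drug.  Secondary target genes (STGs) are genes linked to
an ePTG by a protein–protein interaction with score ≥ 0.6 (inclusive;
the STRING 0–999 dialect is rescaled on ingest; duplicate pairs keep
the maximum score; self-loops are dropped).  A gene may act as both
ePTG and STG — the layers are roles, not disjoint sets.

The feature matrix counts *distinct ePTG paths*:
`X[d, g] = |{e ∈ ePTG(d) : g ∈ STG(e)}|`, with a binary view available.
"Integrated connectivity" is not given a formula in the source
material; the path count is the default because it preserves the
convergence-of-evidence idea (several independent primary targets
pointing at the same secondary target).  All-zero STG columns are
dropped, column order is lexicographic, and unannotated drugs keep an
all-zero row and a flag.

## The COSTAR model

Hit status across the labelled drugs is modelled by logistic regression
with an L1 penalty on the STG features:

$$\min_{\beta_0,\beta}\ \frac1n\sum_i\left[\log(1+e^{\eta_i}) - y_i\eta_i\right]
 + \lambda\lVert\beta\rVert_1,\qquad \eta_i=\beta_0+x_i^\top\beta,$$

with the intercept unpenalized and columns centered and scaled before
penalization (coefficients are reported on the original connectivity
scale).  The optimizer is cyclic coordinate descent on the IRLS
quadratic approximation with active-set sweeps, implemented in C++.
The contract is the KKT stationarity condition, not the algorithm:
every fit satisfies `|g_j| ≤ λ` on inactive coordinates and
`g_j = −sign(β_j)λ` on active ones within tolerance, and
`kkt_residual()` certifies it.

The penalty grid is geometric: 60 values from
`λ_max = max_j |x̃_j^\top(y-\bar y)|/n` down to `10^{-4}λ_max`.  λ is
chosen by 20-fold cross-validation at the strict minimum of mean
held-out binomial deviance (no one-standard-error rule).  Folds are
stratified by class: with ~30 positives among 127 drugs, unstratified
20-fold splits can produce positive-free folds, which the held-out
deviance cannot score.  The fold seed is recorded in the model.

Numerical choices in the optimizer:

* probabilities are clamped to `[10^{-5}, 1-10^{-5}]` inside IRLS, the
  standard guard against diverging working responses on separable data;
* the soft-threshold comparison carries a relative epsilon of
  `10^{-12}`, so the boundary case λ = λ_max yields exact zeros rather
  than `10^{-16}` junk;
* convergence is declared when the first full coordinate sweep of a
  fresh IRLS approximation moves no coefficient by more than `tol`;
* cross-validation fits tolerate iteration-capped non-convergence at
  extreme penalties silently (a capped fit perturbs one held-out
  deviance value at a penalty that will not be selected); training
  warns only when the *selected* lambda's fit is capped, and direct
  calls to the fitter error.

Predicted hit probabilities ("COSTAR scores") are
`sigmoid(β_0 + x·β)`; ranks break ties by compound id.  Subscores
`S[d,g] = β_g X[d,g]` decompose the logit exactly:
`Σ_g S[d,g] + β_0 = logit(score_d)`.  ePTG contributions aggregate the
selected-STG coefficients attached to each ePTG and normalise by the
largest absolute aggregate, a declared convention mapping contributions
into [−1, 1] with sign toward hit/non-hit.  Classification diagnostics
use threshold 0.5 (configurable); ROC curves move tied scores as one
block and AUC is the trapezoid area, which equals the midrank
(Mann–Whitney) statistic.

## Specificity scores

A gene's expression call in a cell is either any nonzero count (the
definition under which the specificity scores are stated, and the
default) or `log2(count+1) > τ` with τ = 3 (so count > 7), the
convention of the marker-panel analyses; τ = 5 fits datasets with
deeper coverage.  Neural specificity is the difference of pooled
expressing fractions, neural minus immune, pooling cells across
patients; it spans −1 to +1 and shrinks toward 0 for weakly detected
genes.  Patient specificity first forms, per patient, the
composition-independent quantity
`Fraction_expressing = fraction_immune + fraction_neural` (range
[0, 2]; summing the class-wise fractions removes the dependence on each
patient's immune/neural mix), then takes the *unscaled* median absolute
deviation across patients — no 1.4826 consistency factor, since the
score is a descriptive spread on a bounded quantity, and the MAD of
values in [0, 2] is at most 1, matching the stated 0–1 range.  Patients
count for a gene only when they contribute strictly more than 50
positive cells; the eligibility flag gates inclusion only and never
alters fraction values.  Cell lineage labels are inputs; deriving them
(clustering, signature scoring) is out of scope.

## Calcium traces

Plate-level kinetics: the fold change is the mean signal over the
400–600 s response window divided by the mean over the 200–300 s
baseline window.  Single-cell ratiometric (Fura-2) preprocessing
subtracts the mean background-ROI intensity per frame and channel,
computes a background floor as the lower 1st percentile of corrected
intensities across cells within the first 30 s (across ROIs, as
specified, not per ROI), excludes ROIs with strictly more than five
sub-floor frames, blanks the drug-addition frame (perfusion artefact),
and forms the 340/380 ratio.  ΔF/F0 uses the full pre-drug span as the
default baseline.  The drug-addition frame is either supplied or
detected as the largest one-frame jump of the across-ROI median trace
within a 120–150 s search window; an explicit time always wins.

Peak detection finds strict local maxima (plateaus collapse to their
first frame) and filters them by topographic prominence and a minimum
separation of 3 frames.  The default prominence threshold is
`k × MAD(diff(trace))/√2` with k = 8.  Two deliberate deviations from
the obvious construction are worth recording.  First, estimating noise
as the MAD of the *detrended trace* is self-defeating for exactly the
traces one wants to detect: a strong oscillator's own amplitude inflates
the estimate above its own prominence.  The MAD of first differences is
a standard noise estimator that slow oscillations barely leak into.
Second, k = 4 on that noise scale over-calls flat traces: among the
~230 local maxima of a pure-noise window, the largest few have
prominence comparable to the window's range (≈5.5σ), so two false peaks
— enough for an oscillatory call — are near-certain.  k = 8 sits between
that range statistic and the 2×amplitude prominence of a true oscillator
at signal-to-noise ratio ≥ 5, where the classification is specified to
reach balanced accuracy ≥ 0.95.  A window is called oscillatory at ≥ 2
detected peaks (the stated "more than one or two" is ambiguous; 2 is
used for both windows and is configurable per window).

## Synthetic data: what is emulated, what is not

Each generator takes one seed and derives per-entity substreams, so
outputs are reproducible regardless of generation order.

**Plates.**  Wells receive Poisson cell counts; drug effects act as
per-population survival multipliers on expected counts before a
multinomial redraw — modelling *relative* reduction, which is what the
fraction-based PCY readout measures.  The closed-form expected score,
`1 − [s_t f_t / Σ_p s_p f_p]/f_t`, is returned as ground truth;
Monte-Carlo estimates converge to it as cells grow.  Replicate
structure follows the screening layout (4 wells per drug, 16 DMSO
wells).  Raw images, segmentation and intensity thresholding are not
simulated.

**Networks.**  The default configuration mirrors the screening study's
shape: 127 drugs, ~30 hits, 1,000 candidate STGs, 20 planted.  Drugs
annotate 1–50 ePTGs from a 3,000-gene pool under a truncated power law
(exponent 2).  Labels follow
`P(hit) = sigmoid(a·k + b)` where k is the realized path count into the
planted set; the defaults a = 50, b = −25 saturate, making any planted
connectivity a near-certain hit (the "strong effect" regime).  The
planted wiring is *label-first*: 30 designated drugs are each wired to
the planted STGs through privately annotated ePTGs, every designated
drug at least once and every planted STG to 2 designated drugs.  This
design is deliberate.  Under independent wiring, 30 any-connection hits
spread over 20 planted STGs leave each STG ~1.7 connected hits, so
~18% of planted STGs touch no hit at all and are unrecoverable in
principle; under a shared hub, planted columns become so correlated that
L1 selection keeps only a subset.  Label-first wiring guarantees
coverage while keeping columns near-orthogonal, which is what makes the
prescribed recovery experiment (selected-feature recall ≥ 0.6, training
accuracy ≥ 0.9 in ≥ 80% of seeds) a test of the learner rather than of
luck.  Background edges at probability 0.001 with Uniform(0, 1) scores
(so the 0.6 cut keeps ~40%) contribute 100–170 realized distractor STG
columns and occasional accidental planted paths (~4 extra hits).

**Expression.**  Five gene classes (neural-specific, immune-specific,
pan, patient-variable, silent; specific classes are minorities, 10%
each) with target expressing probabilities per class.  The
expressed/unexpressed indicator is planted exactly: expressed cells draw
counts of 8 + NB(mean, dispersion), unexpressed cells 0, so expressing
fractions are Bernoulli with exactly the target probability under both
the nonzero and the τ = 3 definitions.  This controls the planted truth
but makes the count distribution bimodal rather than a realistic
zero-inflated NB — adequate for testing fraction-based scores, which
never look at magnitudes, but not a model of real scRNA-seq depth
effects, doublets or ambient RNA.

**Traces.**  Oscillators are `baseline + A sin(2πt/T + φ)` plus noise;
all ROIs gain a step after the drug frame; frames arrive every 2 s.
Dual-channel mode emits 340/380 pairs whose ratio equals the latent
signal up to noise, with five background ROI pairs and a deterministic
per-ROI brightness gradient (dye loading varies across cells; the ratio
cancels it).  The gradient matters for the exclusion rule: with
identical ROIs the cohort's 1st-percentile floor falls inside every
ROI's own noise cloud and the rule excludes everything, which is not how
it behaves on real recordings where dim cells sit near background and
bright cells far above it.  Waves, photobleaching and focus drift are
not simulated.

## Problem sizes and runtime

The test suite runs the full recovery experiments at the sizes above:
25 seeds for signature recovery (about 2 s each), a 227-drug network
split 127/100 for the held-out screen, 50 expression simulations of
5 patients × 400 cells for the specificity decile check, and 200 ROIs
for oscillation recovery.  These sizes were chosen to give the binomial
pass-rate criteria comfortable margins while keeping a full run on one
CPU in a few minutes; the acceptance script uses the same conditions
with slightly fewer repetitions.

## Known limitations

* The penalized fit treats class imbalance without reweighting (a plain
  binomial LASSO), as in the modelled analysis.
* The λ grid anchor λ_max is computed once on the full data; CV folds
  reuse it, so fold-level λ_max may exceed the grid top (the null model
  simply persists over the first grid points in that fold).
* `eptg_contributions()` normalisation and the 0.5 classification
  threshold are declared conventions where the modelled analysis states
  none.
* Elastic-net/ridge variants and live database queries are out of
  scope, as is reproducing the original network (it requires a specific
  bioactivity snapshot and interaction-database release).
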