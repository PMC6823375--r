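---
title: "Models and methods behind ezstim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ezstim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ezstim` implements the analysis core of a sham-controlled brain-stimulation
study design with two arms: choice-reaction-time (CRT) behaviour modelled
with the EZ-diffusion estimator and bootstrap inference, and resting-state
fMRI quantified by ALFF, regional homogeneity, and seed-based functional
connectivity with permutation cluster inference. Both arms ship with a
synthetic-data generator so every stage is testable end to end without any
external download. This vignette explains the models, the defaults and why
they are what they are, the numerical choices, and what the synthetic
validation does and does not establish.

## The behavioral model

Each trial's initiation time (go signal to home-button release) is treated
as the first passage of a Wiener diffusion: evidence $x(t)$ starts at
$z = a/2$, accumulates with drift $v$ and diffusion coefficient $s$
(fixed at 1, the conventional scale), and a response is produced when $x$
reaches $a$ (correct) or $0$ (error), after which the non-decision time
$T_{er}$ is added. The EZ estimator maps the pooled moments — accuracy
$P_c$, and the mean (MRT) and unbiased variance (VRT) of correct-trial
initiation times in seconds — to parameters in closed form. With
$L = \log\{P_c/(1-P_c)\}$:

$$v = \mathrm{sign}(P_c - \tfrac12)\, s\,
  \left\{ \frac{L\,(P_c^2 L - P_c L + P_c - \tfrac12)}{\mathrm{VRT}} \right\}^{1/4},
  \qquad a = \frac{s^2 L}{v},$$

$$\mathrm{MDT} = \frac{a}{2v}\,
  \frac{1 - e^{-va/s^2}}{1 + e^{-va/s^2}},
  \qquad T_{er} = \mathrm{MRT} - \mathrm{MDT}.$$

The estimator assumes an unbiased starting point and no across-trial
parameter variability; it is undefined at or below chance ($P_c \le 0.5$,
a hard error here) and for $\mathrm{VRT} = 0$. Perfect accuracy is
edge-corrected to $P_c = 1 - 1/(2n)$, the standard log-odds rule. The
package also provides the exact inverse (`ez_forward`), which makes the
estimator testable to machine precision: `ez_fit(ez_forward(θ)) = θ` is
property-tested over a thousand random admissible draws.

### Filtering and pooling

Before estimation, initiation times above 1000 ms are eliminated entirely
(they enter neither the accuracy denominator nor the moments — a choice the
package makes explicit, since either convention is defensible) and times
below 150 ms are kept but counted as errors. Because per-subject error
counts are tiny in this class of task, trials are pooled across subjects
into one population distribution per task and stimulation group; inference
then targets population-level parameter differences, not individual
cognition.

### Bootstrap inference

Confidence intervals resample (initiation time, correctness) pairs with
replacement *within* a condition, refit EZ on each of $B$ resamples, and
take the 2.5/97.5 percentiles. Hypothesis tests resample pairs of datasets
from the *merged* pools of both conditions, preserving the two sample
sizes, and report the proportion of resampled pairs whose absolute
parameter difference exceeds the observed one, floored at $1/B$ and
Bonferroni-multiplied by 3 (the number of tasks). The resampling unit is
the trial, consistent with the pooled-population framing. Resamples on
which the estimator is undefined are re-drawn (with an audit count) so $B$
is exact; more than 10% failures aborts as pathological.

Two calibration facts worth knowing. First, the between-condition test is
accurately calibrated: over 200 null replicates at the study's pooled scale
($n = 1500$, $B = 2000$) the rejection rate at $\alpha = 0.05$ sits inside
the exact binomial band. Second, the percentile CI is only first-order
accurate: measured coverage in the same configuration is about 93%, a
known property of percentile intervals rather than an implementation
defect; the tests assert coverage in a band that admits this shortfall.
BCa or studentized intervals would shrink it but are out of scope.

### The trial generator

`generate_trials` simulates the factorial design: per group 20/22 subjects
(configurable), three tasks of 75 trials balanced over five ISIs
(200–3200 ms; a sixth "0" level appears in some descriptions of such
designs, but five levels are what make $15 \times 5 = 75$ consistent, so
five is the default), movement times log-normal (median ≈ 180 ms,
$\sigma = 0.18$ — movement time is not modelled scientifically, it only
makes reaction-time columns realistic), anticipations (2%, uniform
50–149 ms, always errors) and lapses (4%, uniform 1000–2000 ms). With
these rates a 20-vs-21-subject configuration pools 1400–1530 trials per
cell after filtering, the scale the inference stage is designed for.
The per-group diffusion defaults encode the condition effects this study
design is built to detect — a raised boundary under real stimulation in
the fully-cued task ($a$ 1.05 vs 0.92), a slowed drift in the
uncued-compatible task ($v$ 3.74 vs 4.25), and faster drift with longer
non-decision time in the uncued-incompatible task — on top of the usual
task-difficulty gradient, placing estimates in realistic ranges
($a$ ≈ 0.9–1.1, $v$ ≈ 3–4.3, $T_{er}$ ≈ 330–370 ms). A single master
seed expands into per-subject substreams
(`seed + 104729 × subject index`), so any subject's data are invariant to
cohort size and generation order.

### Simulator accuracy

First passages are drawn by Euler–Maruyama with $dt = 0.5$ ms (maximum
10 s, non-absorbed paths re-drawn and counted). Discrete-time crossing
detection misses intra-step excursions, which acts like widening each
boundary by $\beta s \sqrt{dt}$ with $\beta = 0.5826$ — the standard
continuity correction. At the default step this predicts the simulator's
small biases (≈ +0.6 pp on $P(\text{upper})$, ≈ +3% on recovered $a$, a
few ms on MDT) and the test suite verifies the simulator *against the
corrected closed forms* rather than pretending the bias is zero.
Recovery from $n = 1500$ pools averaged over 20 seeds stays within 5%
($a$, $v$) and well under 10 ms ($T_{er}$); at $dt = 0.25$ ms and
$n = 10^5$ all three parameters recover within 2%.

## The resting-state pipeline

The pipeline starts where registration ends: inputs are a 4D series, a
6-parameter motion trace, and tissue/region label volumes. The fixed
order is: drop the first 5 volumes → QC flags → demean/linear detrend →
16-regressor nuisance removal → 0.009–0.08 Hz band-pass → 8 mm FWHM
Gaussian smoothing → metrics. Noisy volumes are *never deleted from the
series*; their flags are applied only when metrics and correlations are
estimated.

**Scrubbing.** Framewise displacement uses the Power convention (sum of
absolute translation differences plus 50 mm × absolute rotation
differences) with a conservative 0.3 mm cutoff; the intensity-based DVARS
(RMS over grey matter of the temporal difference) and spatial SD use
adaptive Tukey fences (75th percentile + 1.5 × IQR, linear-interpolation
quantiles, strict inequality). A session with more than 35% flagged
volumes is excluded. The FD formula and quantile convention are package
decisions — the analysis description this follows names the metrics and
cutoffs but not the formulas.

**Nuisance regression.** White-matter mean, CSF mean, six motion
parameters, and the eight backward-difference derivatives; all z-scored
on clean volumes only, the fit estimated on clean volumes and residuals
formed everywhere (the defensible reading when flagged volumes must stay
in the series). A rank-deficient design errors out with the collinear
columns named.

**Band-pass.** Second-order Butterworth, applied forward and backward
(zero phase, squaring the magnitude response) with odd-reflection padding
of up to 150 samples so the slow low-cut pole settles; the implementation
is a compiled per-voxel recursion validated against the analytic
$|H(f)|^2$ response. Within the 245-volume scans, edge transients remain
a sub-percent effect away from the first/last ~50 volumes, which is where
the tests measure.

**Metrics.** ALFF is the clean-volume variance of the band-passed series
(log-transformed for group statistics, where ratios become differences).
ReHo is Kendall's W over each voxel's 3×3×3 neighbourhood (shrinking at
borders) with the full tie correction, so identical tied series give
exactly $W = 1$ and independent series $E[W] = 1/27$. Seed connectivity
is the Pearson correlation of each voxel with the seed's mean clean-volume
time course, Fisher-z transformed with $|r|$ clipped at $1 - 10^{-7}$;
zero-variance voxels map to $z = 0$ and are counted.

**Inference.** The crossover Time × Stimulation interaction is the paired
t test on per-subject $\Delta_{real} - \Delta_{sham}$ (post − pre
differences), scalar for ROI summaries and voxelwise for maps. Cluster
inference thresholds $|t|$ at the two-sided cluster-forming level (default
$p < 0.01$), groups voxels by 26-connectivity inside an inclusion mask of
significantly positive baseline connectivity, and corrects by the
permutation null of the maximum cluster extent under subject sign-flips —
exact under exchangeability, and chosen over parametric random-field
correction deliberately: it is self-contained, assumption-light, and its
family-wise error control is verified on null simulations in the suite.

### The scan generator and what validation shows

`generate_session` builds sessions on a small native-space grid (default
16×16×12 voxels at 3 mm, 250 volumes, TR 2.4 s — the volume count and TR
of the emulated acquisition; the grid is deliberately minimal since
registration and atlases are out of scope, and label volumes stand in for
them). Signal per voxel: AR(1) noise (coefficient 0.3), a random-phase
low-frequency sinusoid (0.01–0.06 Hz, amplitude 1), shared band-limited
latents giving each seed coherent activity and the right seed a baseline
loading (0.4) on a 60-voxel distant cluster, WM/CSF confound time courses
with a 0.3 leak into grey matter, and motion spikes (4 per session,
0.4–1 mm) that also shift global intensity so FD and DVARS flag the same
volumes. Two plantable effects, both applied only to real/post sessions:
the right-seed series scaled to 1.5× variance, and the cluster's latent
loading incremented by 0.4.

On 10 cohorts of 19 subjects the full pipeline detects the planted ALFF
interaction and recovers ≥ 50% of the planted cluster at corrected
$p < 0.05$ in effectively every batch, while null cohorts stay at nominal
false-positive rates. That establishes that the pipeline's plumbing,
flag handling, and inference are correct and adequately powered for
effects of this size and coherence — it does not establish performance on
real BOLD data, whose spatial autocorrelation, physiological noise,
vascular structure and registration errors the generator intentionally
omits.

## The magnet model

The axial field of the axially magnetised cylinder (radius 22.5 mm,
length 30 mm) is the closed form
$B(z) = \tfrac{B_r}{2}\bigl[(z+L)/\sqrt{(z+L)^2+R^2} - z/\sqrt{z^2+R^2}\bigr]$,
with the analytic derivative for the gradient. The remanence is not part
of the published device description; 1.35 T (nominal N45) is the default
and checks against the reference field values carry a 2% tolerance, the
typical remanence spread of that grade. With the defaults the pole-face
field is exactly 540 mT and the 2–3 cm depth profile spans ≈ 167 to
92 mT, a mean gradient of ≈ 7500 mT/m.

## Problem sizes and reproducibility

The suite and the acceptance script parameterise simulations at the
scales the inference is designed for: pooled behavioral cells of
~1500 trials, $B = 2000$ desk-scale bootstraps (100000 for
replication-grade runs), 200-replicate calibration loops, and 10 fMRI
cohorts of 19 subjects × 4 sessions on the default grid. Every random
draw flows from explicit integer seeds; session and subject substreams
are derived arithmetically so results are independent of generation
order. Known limitations: no hierarchical (subject-level) resampling, no
across-trial parameter variability or starting-point bias in the
behavioral model, percentile (not BCa) intervals, and a spatially
unrealistic scan generator — each a deliberate scope decision recorded
above.
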