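---
title: "Inverting rice leaf nitrogen deficiency from reflectance differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverting rice leaf nitrogen deficiency from reflectance differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Nitrogen drives rice growth, but a leaf N concentration on its own does not
tell a grower whether a plot is deficient: deficiency is relative to what a
well-fertilized crop looks like at the same moment. `nitrospec` implements a
difference-based calibration. A "standard field" is defined as the
treatment with the highest grain yield; its mean leaf spectrum
$\bar R_{std}(\lambda)$ and mean leaf N content $\bar N_{std}$ become the
reference. Every other sample is represented by the signed differences

$$\Delta R_i(\lambda) = R_i(\lambda) - \bar R_{std}(\lambda), \qquad
  \Delta N_i = N_i - \bar N_{std},$$

and the inversion models map $\Delta R$ to $\Delta N$ (mg/g; negative
values mean a deficit). Differences are kept signed throughout — taking
absolute values would collapse surplus and deficit onto each other.

The workflow is: simulate (or load) a leaf sample table on the fixed
401–1000 nm grid (600 bands at 1 nm) → select the standard treatment by
max yield → difference → split 73/27 into training and validation →
reduce the 600-band differences by one of four routes → fit one of three
regressors → report $R^2$ and RMSE on both splits.

## The synthetic data generator

No public accession exists for the original field data, so the generator in
`sim_config()`/`generate_samples()` defines the study conditions every
downstream stage is tested on:

* **Design.** Four N rates (0/50/100/150 kg/ha), four plots each, 22 leaf
  samples per plot (three growth stages of repeated sampling). Leaf N is
  drawn per treatment from normals with means (1.8, 2.6, 3.3, 3.8) mg/g and
  SD 0.45, clipped to [1, 5] mg/g; only pooled moments of the original
  campaign are published (mean ≈ 2.9, SD ≈ 0.93 mg/g), and these defaults
  approximate them while keeping the treatment means ordered with N rate.
* **Yields.** A quadratic response fitted to the published per-treatment
  yields; its vertex sits near 94 kg/ha, so the 100 kg/ha treatment is the
  grid maximum and the printed ordering
  (100 > 50 > 150 > 0 kg/ha) is preserved.
* **Optics.** A stylized Gaussian-feature leaf model, not a
  radiative-transfer code: low visible reflectance, a green peak at 550 nm
  whose height decays exponentially with the chlorophyll proxy
  (Beer–Lambert-type saturation, so the spectrum–N link is deliberately
  nonlinear), a red absorption trough at 672 nm, a red edge whose
  inflection shifts ~16 nm to the red across the chlorophyll range, and a
  NIR plateau near 0.5 that rises slightly with N. The chlorophyll proxy
  equals the scaled N content plus Gaussian noise (`chl_noise_sd`, default
  0.12 on the 0–1 chlorophyll scale); this imperfect coupling sets a
  realistic ceiling on attainable inversion accuracy — with a
  deterministic link every model scores $R^2 \approx 1$ and the comparison
  between methods becomes meaningless.
* **Nuisance.** Per-sample N-unrelated structure: a small global
  brightness offset plus eight random Gaussian bumps (centers 420–980 nm,
  widths 15–50 nm, amplitude SD `structure_sd` = 0.025), plus i.i.d. band
  noise (SD 0.008). The bump scale matters: local (15–50 nm) structure
  leaves the coarse wavelet profile coefficients mutually diverse, whereas
  spectrum-wide modes would collapse them onto a single brightness factor,
  which is not what smooth leaf difference spectra look like.

What the generator does **not** emulate: plot-level random effects (no
within/between-plot variance decomposition is published), growth-stage
structure, canopy geometry, water-band absorption features, and instrument
artifacts. Passing tests therefore demonstrate that the pipeline recovers
the structure this generator encodes — not that it would achieve any
particular accuracy on field spectra.

## Wavelet multiscale decomposition (DWMD)

The decimated discrete wavelet transform is implemented in the package
(three orthogonal families: 20-tap order-10 Daubechies, 30-tap order-5
coiflet, 16-tap order-8 symlet; standard published filter coefficients).
Each analysis step uses half-point symmetric boundary extension and keeps
the even-indexed outputs, giving $a_j = \lfloor (a_{j-1} + L - 1)/2 \rfloor$
approximation coefficients at depth $j$ from $a_0 = 600$. This boundary
convention is the one that reproduces the published coefficient-count table
for all three families at all twelve depths. Reconstruction inverts each
step exactly (machine precision), so nothing is lost by the representation.

Two numerical notes:

* The symmetric extension is redundant at the boundaries, so the
  coefficient set slightly over-counts signal energy. `dwt_decompose()`
  also offers `boundary = "periodic"`, the orthogonal variant (circular
  convolution, $a_j = a_{j-1}/2$) under which energy is conserved exactly;
  the energy-conservation test uses it at depths where all lengths stay
  even. The symmetric default is what the feature extraction uses.
* At depth 10 every coefficient of a 600-band signal feels the boundary;
  this is inherent to compressing 600 bands to 15 coefficients and is
  shared by any implementation of this transform.

The mother wavelet and depth are chosen from a selection report
(count, compression ratio $100\,a_j/600$, and the Pearson correlation of the
approximation-only reconstruction with the signal, computed on the mean
training difference spectrum — the mean is deterministic, and per-sample
correlations would add noise without changing the ranking). The rule:
among (family, level) cells whose count has stabilized (unchanged from the
previous level, or level ≥ 10), take the lowest count; break ties by the
higher correlation, then the shallower level. On simulated difference
spectra this selects the symlet at level 10 (15 coefficients, 2.5 %
compression ratio), and those 15 coefficients are the DWMD feature set.

## Band selection: SPA, IRIV, PCA

**SPA.** The successive projections algorithm grows chains of bands, each
new band maximizing its norm after projection orthogonal to the previously
selected one; an instrumented counter verifies the textbook operation count
$(N-1)(J-N/2)$. The start band is not part of the method's definition, so
chains are grown from every candidate start; each (start, length) prefix is
scored by 10-fold cross-validated RMSE of an ordinary least-squares model,
and the winner is pruned by backward elimination with a 1 % relative
RMSECV tolerance (the pruning criterion is not published; 1 % removes only
bands that are essentially free to drop).

**IRIV.** The 600-band grid tiles into 30 intervals of 20 bands
(interval $k$ spans $401+20(k-1)$ to $400+20k$ nm). A synergy-interval PLS
screen evaluates all $\binom{30}{4} = 27{,}405$ four-interval combinations
by 10-fold cross-validated PLS RMSE and keeps the best 80-band joint
region. Iterative retention then draws, per round, a 50-row random binary
inclusion matrix (inclusion probability 0.5; the method's reported
definition leaves these parameters open), scores every row-combination by
RMSECV, and classifies each band by the difference of mean RMSECV between
models without and with it: positive differences are kept (strongly
informative if the two-sided Mann–Whitney U test gives P < 0.05, weakly
otherwise), non-positive ones dropped. After stabilization (≤ 5 rounds) a
backward-elimination pass removes bands whose removal lowers RMSECV, and
finally groups of mutually correlated bands (|r| > 0.9, transitively) are
collapsed to the member most correlated with $\Delta N$. Whether the U
test should be one- or two-sided is unstated; two-sided is used.

**PCA.** Five principal components, fitted on the training split only;
validation scores use the training center and loadings (fitting on all
samples would leak the validation set into the features).

## Inversion models

**PLSR.** A SIMPLS kernel for a univariate response, returning the whole
coefficient path from one decomposition; the latent-variable count is
chosen by 10-fold cross-validated RMSE over 1..min(15, rank). The kernel is
cross-checked in the test suite against an independent PLS implementation
(mixOmics) to 1e-8. A dedicated kernel is used because IRIV and the
interval screen evaluate on the order of $10^5$ small PLS models under
cross-validation.

**ELM.** A single hidden layer of logistic sigmoids; input weights and
hidden biases are drawn uniformly from $[-1, 1]$ under the given seed and
never trained; output weights solve the least-squares problem on the
hidden activations by the Moore–Penrose pseudo-inverse (singular values
below $10^{-12}$ of the largest are truncated, which regularizes
degenerate activation matrices; the output map is the identity, so no
iterative network trainer is involved — the solution is closed-form).
Inputs are centered and *whitened* by the training principal axes before
entering the hidden layer. This conditioning choice matters: wavelet
approximation coefficients are strongly collinear (two dominant variance
factors), and random projections of unwhitened inputs only ever excite
those factors, hiding the low-variance directions that carry the N signal.
Whitening makes the random hidden layer equally sensitive to every feature
direction; directions with relative SD below $10^{-6}$ are dropped.

**GA-ELM.** A real-coded genetic algorithm chooses the ELM's random layer.
Chromosome length is $l = s_1 s_2 + s_2 s_3 + s_2 + s_3$ (input weights,
output weights, hidden biases, output bias — the output blocks ride along
for completeness and are overwritten by the least-squares solve). An
individual's error $E$ is the training RMSE of its induced ELM and its
fitness $f = 1/(1+E)$. Each generation: the above-average-fitness half is
retained as the breeding subpopulation (the subpopulation mechanism is
only loosely specified in the method's description; retaining the
above-average half is the minimal faithful reading),
parents are drawn fitness-proportionally ($p_i = f_i/\sum f$), arithmetic
crossover and Gaussian mutation fire with adaptive rates
$p = k\,(f_{max} - f)/(f_{max} - \bar f)$ for at-or-above-average
individuals and $p = k$ below average ($k_c = k_m = 0.5$), and the best
individual is carried over unchanged, making the best fitness
non-decreasing. Defaults: population 30, 100 generations, mutation
perturbs 10 % of genes with SD 0.1, genes clipped to $[-1,1]$; none of
these are part of the method's reported definition, and they are sized so
a fit takes ~1–3 s at the package's problem sizes. Using the training
RMSE as $E$ is itself an interpretation (only an unspecified network
output error enters the fitness); it
carries an overfitting risk that is visible in practice — GA-ELM's
training $R^2$ always exceeds its validation $R^2$ — and is the reason
hidden layers should be sized to the training set (the test suite uses
$s_2 = 12$ when only 110 training samples are available, and the default
$s_2 = 20$ at $n \approx 190$).

## Evaluation protocol

`run_grid()` crosses the four reductions with the three regressors on one
simulated campaign: data are generated once, the reference and split are
computed once, features are built once per reduction (so every model in a
column consumes byte-identical inputs), and each cell reports
$R^2 = 1 - SSE/SST$ and RMSE (mg/g) on both splits. Cell failures are
recorded and the run continues. The 189/70-style split uses
`round(n · fraction)` with fraction 189/259; the split rule itself is not
published, so a uniform random split without stratification is used. (The
campaign's validation-set size is reported inconsistently, 79 vs 70
samples; 70 is consistent with the totals and is adopted.)

## Problem sizes and what the tests compute

The test suite runs entirely on generated data: the default campaign
(352 samples, 264 differences), planted-band recovery problems
(60 candidate bands for SPA, 40 for IRIV, 20 seeds each), a reduced
16-interval screen for the interval-recovery check, the reference
nonlinear problem (n = 259, 5 features, noise 0.2 mg/g) for the
three-regressor comparison over 11 seeds, and 11 simulated campaigns for
the wavelet-vs-PCA comparison under GA-ELM. These sizes were chosen so the
whole suite completes in a few minutes while keeping every comparison at
the sample sizes the campaign actually had (189/70-scale splits).

## Known limitations

* The standard reference pools all growth stages into a single spectrum
  and N content; whether the original analysis kept one reference per
  stage is not stated. Users with staged data should build references per
  stage and difference within stage.
* The generator's nuisance model is low-dimensional and smooth; real
  instrument noise, water bands and canopy effects are absent, so absolute
  accuracies from this package's simulations do not transfer to field
  data.
* SPA scans every start band by default, which is $O(J)$ chains of
  $O(JN)$ projections each; on the full 600-band grid the reference
  analysis scripts thin the start positions (every 5th band) with no
  observed change in the selected set.
* The published iteration arithmetic for IRIV (80 → 44 → 36 variables via
  "elimination in reverse") is internally inconsistent; the package
  implements iterate-then-backward-eliminate, which matches the order the
  numbers suggest.
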