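---
title: "Amplitude-envelope connectivity: model, simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplitude-envelope connectivity: model, simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aecnet)
```

## The scientific problem

Task MEG studies of social cognition compare the functional connectivity of
two groups of children — for instance very-preterm-born versus full-term-born
— while they watch short animations that evoke mental-state attribution.
Connectivity is measured in source space as the *amplitude envelope
correlation* (AEC): band-limited cortical signals are reconstructed at atlas
nodes, their slow amplitude modulations are extracted with the Hilbert
transform, and the Pearson correlation of every node pair's envelopes indexes
coupling. Group differences are assessed per frequency band (theta 4–7,
alpha 8–12, beta 13–29, gamma 30–55 Hz) and per post-stimulus time window
(0–5, 5–10, 10–15 s), with each window's AEC expressed as a fractional change
from the −5–0 s pre-stimulus baseline, and inference performed with the
Network-Based Statistic (NBS). Because the subject-level recordings behind
such studies are rarely deposited, `aecnet` pairs the full analysis chain with
a synthetic generator that plants known coupling structure, so every stage has
a testable ground truth.

## The generative model

Each node's signal is a band-limited Gaussian carrier multiplied by a slow
positive modulator,

\[ x_i(t) = s \, m_i(t)\, c_i(t), \qquad m_i(t) = \exp(\sigma z_i(t)), \]

where \(c_i\) is noise shaped to the analysis band's FIR magnitude response
(unit variance), \(z_i\) is standardized Gaussian noise low-passed below 1 Hz
(default cutoff 0.7 Hz), and \(s\) is an overall scale in fT. Envelope
coupling is planted by sharing a slow factor: all nodes of one connected
component of the planted graph load on a common \(g(t)\),

\[ z_i = a\, g + \sqrt{1 - a^2}\, u_i . \]

For a lognormal modulator riding on a Rayleigh carrier envelope the envelope
correlation implied by a loading \(a = \sqrt{\alpha}\) is analytic,

\[ r(\alpha) = \frac{(\pi/4)\,\bigl(e^{\sigma^2 \alpha} - 1\bigr)}
                   {e^{\sigma^2} - \pi/4}, \]

and `coupling_to_loading()` inverts it, so coupling targets are calibrated in
closed form rather than by lookup. With \(\sigma^2 = 1\) the attainable range
is \(r \in [0, 0.70)\); requests beyond the cap are rejected. Tests confirm
the realized correlations are unbiased to well within ±0.1 of the target over
60 s of signal.

Two deliberate simplifications of this construction matter for
interpretation:

* **Component-wise sharing.** Nodes inside one connected planted component
  share a *single* factor, so all pairs within the component couple, not only
  the listed edges. For node-disjoint planted edges this reduces exactly to
  pairwise sharing. A pairwise-exact factor model cannot reach strong coupling
  on connected graphs — the per-node sum of loadings would exceed one, i.e.
  the implied correlation matrix stops being positive semi-definite — and a
  coherently co-modulating subnetwork is also the more realistic target for
  NBS recovery.
* **Time-varying loading.** The loading switches from its baseline value to
  the task value at stimulus onset (and stays at baseline throughout Physical
  trials), giving the baseline window a well-defined reference coupling.

Leakage is emulated by a zero-lag unit-diagonal mixing matrix applied after
generation (`mixing_strength` scales a sparse random symmetric pattern, about
two partners per node); artefacts — brief >2500 fT spikes and scripted rigid
fiducial excursions — are injected after mixing so rejection operates on
realistic data. The default carrier scale (20 fT) keeps clean trials' peaks
around 1000–1500 fT: an occasional clean trial crossing 2500 fT (~1–2%)
is accepted as realistic rather than tuned away.

What the generator does *not* emulate: 1/f spectral background, anatomy-based
lead fields (the toy forward model is a random unit-norm-column gain matrix),
ocular or cardiac components, and non-rigid head deformation. Passing tests
therefore demonstrate correctness of the algorithms under the stated
statistical structure, not robustness to every property of real recordings.

## Preprocessing rules

* Continuous data are mean-centred, band-passed 1–150 Hz with a 4th-order
  Butterworth applied forward–backward (zero phase, preserving envelope
  timing; phase handling is our choice, as amplitude-envelope analysis must
  not skew envelope latencies), and line noise at 60/120 Hz is removed with a
  DFT notch that zeroes bins within ±0.5 Hz.
* Epochs span the half-open window [−5, 17) s around onset — 13,200 samples
  at 600 Hz — so no boundary sample is shared between windows.
* A trial is rejected when its absolute signal *exceeds* 2500 fT (a sample at
  exactly the threshold is kept), or when the rigid-body displacement of the
  fiducial triangle from the per-coordinate median head position exceeds
  10 mm. The rigid fit is a least-squares rotation-plus-translation (Kabsch);
  the displacement is the largest distance any fiducial is moved by the
  fitted transform. Amplitude rejection takes precedence in reporting; a
  trial failing both rules is counted once.
* ICA-based artefact removal, which requires visual component selection, is
  out of scope; the amplitude criterion stands alone.

## Beamforming

Node time series come from a linearly constrained minimum variance (LCMV)
beamformer with diagonal loading of 5% of the mean sensor power
(`Cr = C + 0.05 tr(C)/n I` — the common convention where only "5%
regularization" is stated). Weights satisfy the unit-gain constraint
`w l = 1` exactly — an invariant the suite checks on every run. For
free-orientation lead fields the dominant orientation is the principal
eigenvector of the 3×3 source-power matrix \((L^\top C_r^{-1} L)^{-1}\),
sign-fixed so its largest component is positive (eigenvectors are otherwise
sign-ambiguous, and determinism requires a rule; envelopes are sign-blind).
The neural activity index divides each weight vector by its norm so
unit-variance sensor noise maps to unit source variance. The covariance
window is all kept samples, baseline and task together.

## Connectivity pipeline

The order is fixed and tested: band-pass FIR → symmetric orthogonalization →
Hilbert envelope → windowed Pearson correlation → fractional-change
baselining.

* **FIR band filters** are Hamming-windowed, odd-length (type I), sized so
  the transition band is at most half the lower band edge, giving ≥40 dB of
  stopband attenuation one octave outside the band; group delay is
  compensated exactly.
* **Symmetric orthogonalization** finds the closest (Frobenius) set of
  mutually orthogonal node series — no privileged seed node — by alternating
  a Procrustes rotation (SVD polar factor) with per-node rescaling. Series
  are mean-centred first, which makes "orthogonal" equal "zero Pearson
  correlation" exactly. Convergence: relative residual change below 1e-10 or
  residual below 1e-12 of the input norm, at most 100 iterations;
  rank-deficient input is an error because the leakage correction is then
  undefined. It is applied per trial over the full epoch so baseline and task
  share one correction.
* **AEC granularity.** The static Pearson correlation of envelopes within
  each 5-s window is computed per trial and aggregated across trials by
  Fisher-z mean; envelopes stay at full sampling rate. We read the study
  design's three fixed windows as static windowed correlations rather than a
  sliding estimator.
* **Baselining** is the entrywise fractional change
  \((\mathrm{task}-\mathrm{base})/\max(|\mathrm{base}|, \epsilon)\) with the
  baseline's sign preserved and \(\epsilon = 10^{-3}\); guarded entries are
  flagged in a companion mask. A caution the synthetic work makes explicit:
  when the true baseline coupling of an edge is zero its estimate is pure
  noise, and the ratio amplifies it. Group comparisons remain valid (the
  noise is exchangeable between groups) but per-edge sensitivity drops;
  simulations that probe detection power therefore either plant a nonzero
  baseline coupling (the end-to-end demonstration uses 0.3) or measure
  recovery on the raw task-window matrices.

## Network-Based Statistic

Edgewise two-sample t statistics (pooled variance by default — the toolbox
convention; Welch optional, and the demographic utilities default to Welch
because printed degrees of freedom in study summary tables follow
Welch–Satterthwaite) are thresholded at τ per contrast direction, keeping
edges with t *at or above* τ. Connected components of the surviving graph are
the candidate networks; their extent (edge count) is the cluster statistic.
Group labels are permuted — uniformly, with replacement, the observed
labelling accounted for by the +1 convention — and the maximal extent of each
permutation forms the null, giving each observed component the
family-wise-error-corrected p-value \((1 + \#\{M_\pi \ge s\})/(1 + P)\), with
the floor \(1/(P+1)\). τ defaults to 2.7, the midpoint of the 2.5–3.0 range
used in the study this design follows; P defaults to 5000. Covariates are not
supported in the permutation scheme. Under label exchange the two contrast
directions swap exactly for the observed statistics; the sampled permutation
nulls agree in distribution (complement subsets are drawn, so draw-by-draw
identity is not expected and not asserted).

## Brain–behaviour models

Node strength is the sum of a subject's connectivity values over the
component edges incident to each node; the subject's mean network strength
averages strength over the component's node set only (nodes with at least one
incident edge). Mean strength is modelled by a Gaussian-identity GLM on
group, error count and their interaction — the study names only "generalized
linear models"; strength is continuous, so Gaussian-identity is our explicit
choice, with raw counts as predictors. Benjamini–Hochberg correction is
applied across (network, band) models per error type.

One sizing fact discovered while validating the behavioural generator: when
counts are produced by rounding a linear function of strength, the
reverse-regression interaction t is bounded near \(\sqrt{n}/2\) regardless of
slope and noise settings, so at 30 subjects per group detection power at
α = 0.05 cannot reliably exceed ~75%. The generator's power check therefore
runs at 60 subjects per group, where the design ceiling clears comfortably;
the GLM's own power check (strength generated from counts, the model's native
direction) is run at 30 per group and is essentially fully powered.

## Problem sizes and numerical settings used in validation

Simulation-based checks run at reduced sizes chosen to exercise the same
statistical structure: 150 Hz sampling, 20–30 nodes, 4–20 trials, 500
permutations (scaled from 5000; the permutation p floor scales accordingly),
50 planted-recovery replicates and 100–200 null replicates. Full-scale
defaults (90 nodes, 600 Hz, 22 trials, 5000 permutations) remain the
package's defaults throughout. All stochastic stages take explicit integer
seeds and record them in their outputs; the pipeline is a pure function of
(configuration, seed), and rerunning it reproduces byte-identical JSON
artifacts.

## Known limitations

* Envelope-coupling targets above ~0.70 are unattainable under the lognormal
  modulator with σ² = 1 (raise σ² to extend the cap slightly).
* Orthogonalization requires more samples than nodes per trial; with 90 nodes
  this needs epochs longer than 0.15 s at 600 Hz — never binding in practice,
  but hard rank deficiency (duplicated node series) is a fatal error by
  design.
* The toy forward model has fixed-orientation unit-norm random columns; lead
  field conditioning of real MEG arrays is not represented.
* Statistics recomputed from printed summary tables can disagree with values
  computed on the underlying raw data in the last printed digit; the
  demographic utilities reproduce the printed t statistics and degrees of
  freedom where the summaries determine them.
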