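---
title: "Binary-amplitude wavefront shaping through multimode fibres: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary-amplitude wavefront shaping through multimode fibres: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrefocus)
```

## The physical model

A multimode fibre scrambles a coherent input field into a speckle pattern.
For a fixed fibre conformation the scrambling is linear, so the map from the
N controllable input segments (groups of DMD micromirrors) to the M observed
output pixels is a complex transmission matrix \(T \in \mathbb{C}^{M \times
N}\): switching ON mirror \(n\) adds \(t_{mn}\) to the field at output pixel
\(m\). `fibrefocus` models the medium statistically, as is standard for
strongly mixing media: element phases are i.i.d. uniform on \((-\pi, \pi]\)
and amplitudes i.i.d. Rayleigh, restricted to \([0, 1]\) by resampling.

A DMD provides *binary amplitude* control only: each mirror is ON
(contributes its field, unit illumination amplitude) or OFF (contributes
nothing). A focusing algorithm must choose the ON set so that the retained
contributions interfere constructively at a chosen output pixel. Quality is
scored by the peak-to-background ratio (PBR): focus-pixel intensity over the
mean intensity of all other pixels (`pbr()`; the background definition is
configurable through `exclusion_radius`, with the default excluding only the
focus pixel, since nothing more specific is standard).

The simulation operating point mirrors a realistic endomicroscopy
configuration: \(N = 32 \times 32 = 1024\) input segments and
\(M = 64 \times 64 = 4096\) output pixels, focusing on the central pixel.

### Choice of the Rayleigh scale

The amplitude law "Rayleigh on \([0,1]\)" leaves its scale parameter open.
The package defaults to `rayleigh_scale = 0.3`, for which the truncation at
1 removes under 0.4% of the mass, so amplitudes are essentially exactly
Rayleigh — the circular-Gaussian medium model in which element intensities
are exponential. The scale matters more than it may appear: the PBR of a
phase-criterion mask is proportional to \(\mathbb{E}[A]^2 /
\mathbb{E}[A^2]\) of the amplitude law, so a strongly truncated choice
(large scale) would shift every reported PBR upward by up to ~13%. With 0.3
the simulated ensemble means reproduce the reference ground-truth PBRs at
both phase bounds to within a few percent, which is the empirical check that
settled the default.

## Theoretical PBR for binary amplitude modulation

Let \(\varphi\) be the half-width of the phase window: mirrors whose phase
(relative to a reference) lies within \(\pm\varphi\) are ON. Averaging over
the medium ensemble, with \(2\sigma^2\) the per-element mean intensity and
unit illumination \(A\),

\[ I_b = 2 N A^2 \sigma^2 \frac{\varphi}{\pi}, \qquad
   I_p = I_b + \frac{\pi}{2} N (N-1) A^2 \sigma^2
         \left(\frac{\sin\varphi}{\pi}\right)^2 , \]

implemented in `peak_and_background()`. The first expression is the mean
speckle background (each ON mirror contributes its mean intensity
incoherently); the second adds the coherent term from the \(N(N-1)\)
mirror pairs whose phasors are aligned within the window. These are the
ensemble-exact moments for the uniform-phase/Rayleigh model — the package
derives them from the model itself rather than transcribing intermediate
algebra from the literature, and validates them against a Monte-Carlo ensemble oracle
in the test suite. Their ratio gives, for large N, the familiar
approximation implemented by `theoretical_pbr()`:

\[ \mathrm{PBR}(N, \varphi) \approx \frac{N \sin^2 \varphi}{4 \varphi}. \]

Peak *intensity* is maximised by \(\varphi = \pi/2\) (keep every
constructive mirror), but the *PBR* is maximised where marginal mirrors stop
paying for the background they add: \(\tan\varphi = 2\varphi\), i.e.
\(\varphi^* = 0.371\pi\) (`optimal_phase_bound()`, solved by root finding to
1e-12). The PBR gain of \(\varphi^*\) over \(\pi/2\) is 13.8%.

Two caveats connect theory to simulation. First, the closed form uses a
*fixed* reference phase, whereas the simulated masks use the all-ON
reference phase \(\phi_R = \arg\sum_n t_{mn}\), which is estimated from the
same row it conditions on; this correlation inflates the simulated mean PBR
by roughly 8% over the closed form at \(N = 1024\). Second, single-medium
PBRs fluctuate with ~11% relative standard deviation at this size, which is
why the package reports ensemble means over replicate media.

## The four estimation algorithms

All four methods see only binary patterns and measured output intensities —
no interferometric reference arm — and they are compared on matched media
with their prescribed measurement budgets.

### RVITM (real-valued intensity transmission matrix), 2N probes

Displaying the complementary Hadamard pattern pairs \(H_1 = (H+1)/2\),
\(H_2 = (-H+1)/2\) (`hadamard_probes()`, Sylvester ordering; the
reconstruction is ordering-invariant) and differencing each pair's target
intensities projects out the real constants

\[ rvit_{mn} = A_{mn} A_R \cos(\theta_{mn} - \phi_R), \]

via a single Hadamard transform (`compute_rvitm()`). The differential form
of the reconstruction is algebraically equivalent on ideal data to the
single-reference form used in the literature (asserted in tests) and cancels
common-mode errors under noise. In noiseless simulation the identity is
exact to machine precision. Since \(rvit_{mn} > 0 \iff |\theta_{mn} -
\phi_R| < \pi/2\), keeping the positive values (P = 50%) reproduces the
classic peak-intensity mask; ranking mirrors by \(rvit_{mn}\) and keeping
only the top P% (`mask_top_p()`, round-half-up count, stable index
tie-break) trades peak intensity for background suppression. The sweep
(`p_sweep()`) locates the PBR optimum near P = 30%.

### Intensity-only phase retrieval, 6N probes

`retrieve_row()` estimates the complex row \(t_{m\cdot}\) from
\(y_k = |p_k \cdot t|^2\) under 6N random 50%-ON probes. The solver is an
alternating-projection (error-reduction) scheme: impose the measured
amplitudes on the predicted fields, refit the row by least squares
(precomputed Cholesky of the probe Gram matrix, so each iteration is two
real matrix products), and iterate — 200 iterations by default, beyond which
the estimate no longer changes materially at this probe budget. Reference
implementations of this pipeline use a variational-Bayes solver as a black
box; this package instead defines the retrieval *contract* (probe budget,
iteration budget, recovery quality, gauge conventions) and ships a
transparent solver that meets it.

Numerical choices worth knowing:

* **Initialisation.** Spectral start from the leading eigenvector of the
  intensity-weighted covariance of the centred probes, plus a small seeded
  complex perturbation. The perturbation matters: binary probes are real, so
  a purely real iterate can never leave the real subspace.
* **Gauges.** Intensity data determine the row only up to a global phase —
  and, because the probe vectors are real, up to complex conjugation. Both
  gauges are harmless for focusing: the mask criterion
  \(|\arg \hat t_{mn} - \hat\phi_R| < \varphi\) with the all-ON reference
  \(\hat\phi_R = \arg\sum_n \hat t_{mn}\) (`mask_from_phase()`, mode
  `"all-on"`, the default, chosen for comparability with the ground-truth
  masks) is invariant under both. The quality metric
  (`row_recovery_quality()`) therefore scores the better of the direct and
  conjugated matches.
* **Restarts.** If the final fit residual exceeds a relative tolerance the
  solve is repeated from seeded random starts (default 2 extras) and the
  best residual kept. Occasional stagnation at this measurement ratio is a
  known property of alternating projections; restarts recover it.

### Conditional probability algorithm (CPA), 6N probes

Probes whose target intensity exceeds the 80th percentile form the
"focusing" group (`split_focus_group()`); each mirror is scored by the
empirical \(P(\text{focusing} \mid \text{mirror ON})\)
(`conditional_probabilities()` — the count-ratio estimator that Bayes' rule
reduces to with empirical marginals; the alternative
\(P(\text{ON} \mid \text{focusing})\) ranks mirrors near-identically at
50%-ON probes); mirrors above the median probability are switched ON
(`mask_from_probabilities()`, strict inequality at both thresholds since no
tie policy is standard). The estimator is consistent but, at the 6N probe
budget and N = 1024, its per-mirror effect size is comparable to its
counting noise, so CPA masks are noticeably noisier than the other methods'
— visible as both a lower mean PBR and a much larger seed-to-seed spread in
the benchmark.

### Genetic algorithm

`ga_evolve()` runs a standard binary GA with the PBR itself as fitness:
population 20 at ~50% ON, rank-linear parent selection (weights
population-size down to 1; descriptions in the literature say only "larger
probabilities" for fitter parents), uniform crossover at rate 0.6, and
mutation either constant at 0.02 (the simulation setting) or on the decaying
schedule \(0.1 e^{-G/600} + 0.02\) (the experimental setting; both modes are
provided). The replacement scheme is rarely specified in the literature;
the package breeds population/2 offspring per generation, merges, and keeps
the best —
truncation selection with implicit elitism, the common design in binary
wavefront-shaping GAs. Under noisy fitness the retained individuals can be
re-evaluated each generation (`reevaluate = TRUE`), which deliberately
sacrifices the strict monotonicity of the recorded best.

Because the GA optimises the PBR directly it can exceed every
phase-criterion mask: it may switch ON a few mirrors with *negative*
\(rvit_{mn}\) that suppress background more than they cost focus intensity —
visible in `scatter_against_truth()` diagnostics.

## Reproducibility and problem sizes

Every stochastic stage draws from a named sub-stream derived from one base
seed (`derive_seed()`), so media, probes, noise and the GA are independently
reproducible, and noise injection never perturbs an enclosing stream.

The test suite exercises the full reference operating point (N = 1024,
M = 4096, ten replicate media) for the oracle, RVITM, phase-retrieval and
CPA pipelines. The GA's reference 30000-generation budget at full size is a
multi-hour computation; the suite instead runs the scaled-down configuration
N = 256, M = 1024 with 3000 generations, where the GA's characteristic
behaviour (beating the P = 50 RVITM mask, monotone elite fitness) is
already established; final masks containing negative-rvit mirrors appear in
a minority of runs at this budget, versus routinely at the full one. The
full budget remains available through `bench_config(ga_generations =
30000)`.

The noise model adds zero-mean Gaussian noise to each intensity frame with
standard deviation `mean(frame)/snr`, clipped at zero; experimental reports
rarely define their SNR more precisely, and referencing the noise to the
mean of the full camera frame is the convention this choice mirrors — for
that reason a noisy measurement always propagates the whole output frame
even when only the target row is consumed. Across SNR 33.3 down to 3.33
every method's mean PBR (over ten replicate media) stays within 10% of its
noiseless value, because the focus intensities that drive all four
algorithms sit far above the per-frame noise floor. One sensitivity is
worth knowing: the RVITM characterisation signal scales with the realized
reference amplitude \(A_R\), and \(A_R^2\) is exponentially distributed
over media, so the rare medium whose all-ON field interferes nearly
destructively at the target loses its RVITM focus under strong noise —
small ensembles can be dominated by one such medium.

## What the generator does and does not emulate

The synthetic medium is a dense i.i.d. random matrix: it captures modal
mixing, speckle statistics, and everything the compared algorithms are
sensitive to, and it is the model under which the theoretical PBR is
derived. It does *not* model mode-count limits, correlations between fibre
modes, bending or temperature drift, non-uniform illumination, or camera
saturation — so passing tests validate the algorithms and their ranking
under the stated statistical model, not the absolute PBRs of any particular
physical fibre (experimentally reported PBRs are several-fold lower than
simulated ones). The containers (`write_tm()`, `write_measurement_set()`)
and the replay callback (`replay_measure()`) let the same characterisation
code run on measured pattern/intensity stacks instead.

## Known limitations

* The phase-retrieval solver is contract-level: it meets the recovery
  quality and budget of the reference pipeline but is not the same
  algorithm, so per-seed estimates (not the ensemble behaviour) may differ
  from a variational-Bayes implementation.
* The CPA's reference single-medium PBR sits about one per-seed standard
  deviation above this package's ensemble mean at the same budget; with the
  reference thresholds and probe count the ensemble mean is materially lower
  (see the benchmark), and the package reports the ensemble behaviour.
* Background definition, target choice, and thresholds are exposed as
  configuration; defaults follow the reference settings where stated.
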