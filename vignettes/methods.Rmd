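---
title: "Tuning a bioinspired retinal spike encoder: model, objectives and optimiser comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tuning a bioinspired retinal spike encoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinatune)
```

## The problem

Retinal prosthetics and encoding studies need compact models that transform a
visual stimulus into spike trains resembling those of a real retinal ganglion
cell (RGC). `retinatune` implements such a model — a two-stage *bioinspired
retinal model* — together with everything required to fit its free parameters
to reference recordings: stimulus generators, spike-train objective
functions, five multi-objective metaheuristics, an exact hypervolume
indicator, and the nonparametric statistics used to decide which optimiser
does the job best. Because no public recording accompanies the problem, the
package also ships a synthetic reference generator that emulates the
recording protocol (repeated trials of moving bars in eight directions and
full-field flashes).

## The model

**Stage 1 (spatial filtering).** Per frame, a weighted sum of centre-surround
filters is evaluated at the modelled cell's centre pixel:

$$S_1 = W_1\,\mathrm{DoG}\!\left(\tfrac{R+B}{2},\,G\right)
      + W_2\,\mathrm{DoG}\!\left(\tfrac{R+G}{2},\,B\right)
      + W_3\,\mathrm{LoG}(I),$$

where DoG is a difference of normalised Gaussians (centre width
$\sigma_1$, surround width $\sigma_2$) and LoG is a zero-sum
Laplacian-of-Gaussian ("Mexican hat"). Grayscale input uses $R=G=B=I$, which
reduces the sum to $(W_1+W_2)\,\mathrm{DoG}(I,I) + W_3\,\mathrm{LoG}(I)$.
Channel sums such as "R+B" are realised as channel means so intensities stay
in $[0,1]$. Borders are handled by edge replication. The fixed parameters
default to $\sigma_1 = 1$, $\sigma_2 = 2$, $\mu_1 = \mu_2 = 0$,
$W = (0.25, 0.25, 0.5)$; the source work states such values were fixed but
never prints them, so these defaults are this package's own choice of a
conventional centre-surround configuration.

**Stage 2 (spike encoding).** A noisy leaky integrate-and-fire (NLIF) unit
integrates the activation. Each frame is processed `persistence_time` (pt)
times at sub-step $dt = T_\text{frame}/pt$:

$$V \leftarrow V - \frac{V}{l}\frac{dt}{dt_0} + g\,I_\text{eff}\,dt
  + \sigma\,\xi\sqrt{dt}, \qquad
I_\text{eff} = (1 - \text{fmf})\,S_1[n] + \text{fmf}\cdot pt\,(S_1[n]-S_1[n-1]),$$

with $dt_0 = 1$ ms, $\xi \sim \mathcal N(0,1)$. When $V$ reaches the
threshold $t$ a spike is emitted, $V$ resets to 0 and stays there for the
refractory period. The frequency-modulation factor fmf mixes sustained and
transient drive; the source work describes only its role ("modulates the
shape of the transient response"), so this mixing form is a documented
modelling choice, not inferred intent. The same caveat applies to the exact
discretisation and the $\sqrt{dt}$ noise scaling (standard Euler–Maruyama).

**Tuned genes.** Six parameters are optimised, each within a fixed range:
kernel size $K \in [3,13]$ (integer; even values use the next odd kernel
size, since discrete Gaussian kernels need a centre pixel), leakage
$\in [10,15]$, threshold $\in [225,275]$, persistence time $\in [3,7]$
(integer), refractory period $\in [1,10]$ ms, fmf $\in [0.25,0.40]$.

**Drive gain.** The threshold lives in arbitrary units never anchored to the
stimulus. `calibrate_input_gain()` fixes the gain once per stimulus set so
the peak steady-state potential ($V^* = g\,S_1\,l\,dt_0$, evaluated with the
nominal $K = 9$, $l = 12.5$) is 1.5 times a mid-range threshold of 250. The
gain is chromosome-independent, so tuning cannot cheat by inflating it.

## Stimuli

`make_bar_stimulus()` renders a white bar of physical width (default
250 µm ≈ 10 px at 26 µm/px, the 4 mm / 154 px mapping) sweeping across a
black field, one full traversal per second, in any of eight directions at
45° steps; bars enter from off-screen and exit fully, giving a dark baseline
each cycle (a non-wrapping sweep — the protocol leaves this open).
Rasterisation is binary (no anti-aliasing) and uses exact direction cosines,
so frames are bit-reproducible and the 180° sweep is the exact mirror of the
0° sweep. `make_flash_stimulus()` produces the 700 ms flash / 2300 ms
darkness classification cycles. Because stage 1 is purely spatial with
matched zero-sum/normalised kernels, a full-field flash produces zero drive
at an interior cell: flash rasters mostly carry noise-driven spikes and the
degenerate-histogram rule below keeps their objectives well defined.

## Objectives

Candidate and reference rasters are compared with four minimised objectives:

* **PSTH-KLD** — Kullback–Leibler divergence (natural log, reference first)
  between trial-summed, Gaussian-smoothed, normalised peristimulus time
  histograms (bin 10 ms, smoothing σ 20 ms), averaged over stimuli.
* **ISIH-KLD** — the same divergence between interspike-interval histograms
  (bin 5 ms, clipped at 500 ms).
* **FRAD** — absolute firing-rate difference on rates pooled over all
  stimuli and trials, in Hz.
* **RFAD** — absolute receptive-field-size difference in µm², from a
  spike-triggered average of the bar stimuli at 50 ms latency, thresholded
  at half peak, taking the connected region containing the peak.

None of these settings is printed in the source work; the defaults above are
conventional for RGC analysis and are exposed in `metric_config()`. Empty
histograms (a dead candidate) are replaced by the uniform mass, which keeps
the divergences finite while maximally penalising structure mismatch. With
ε-smoothing (ε = 10⁻⁶) the divergence of byte-identical rasters is exactly
zero, so a candidate equal to its reference scores (0, 0, 0, 0).

## Optimisers

All five metaheuristics share the published protocol settings: population
40, 100 generations, crossover probability 0.40, mutation probability 0.05,
archive size equal to population size. Variation is simulated binary
crossover (η = 15) with polynomial mutation (η = 20) — the publication fixes
only the probabilities — with integer genes rounded then clipped.

* **NSGA-II**: tournament on (front rank, crowding), combined 2N truncation.
* **SPEA2**: strength/raw fitness with k-NN density (k = √(N+archive)),
  fixed-size archive, nearest-neighbour truncation protecting the
  objective-wise extremes, mating from the archive only.
* **NSGA-III**: Das–Dennis reference points (p = 6 divisions, 84 points for
  4 objectives), niching on perpendicular distances of ideal/spread
  normalised objectives. The canonical extreme-point intercept
  normalisation is simplified to per-objective spread over the admitted
  fronts, which is robust at the small population sizes used here.
* **MOPSO**: Clerc constriction (φ₁ = φ₂ = 2.05, χ ≈ 0.72984), leaders
  drawn from the external archive by crowding-biased binary tournament,
  positions clipped with velocity zeroing, personal-best ties broken by a
  fair coin.
* **DE**: DE/rand/1/bin with F = 1 (as published) and CR = 0.9 (unstated in
  the source; the common default), three-way dominance replacement, pool
  truncation by rank and crowding.

Every algorithm seeds all randomness from one integer, never evaluates an
out-of-bounds chromosome, and records a snapshot per generation, so runs are
exactly reproducible.

## Hypervolume and statistics

`hypervolume()` computes the exact Lebesgue measure of the dominated region
by the WFG-style recursive dimension sweep — adequate for 4-objective fronts
of a few hundred points — with a Monte-Carlo estimator kept in the tests as
an independent oracle. The study-wide reference point is the componentwise
maximum over all compared fronts times 1.1 (+0.1 for zero components); the
source work never states its reference point, so this rule is a documented
choice, fixed once per comparison.

The comparison protocol (`compare_algorithms()`) is Kruskal–Wallis and
Friedman omnibus tests, pairwise Mann–Whitney U (normal approximation,
tie-corrected variance, no continuity correction — the variant whose
complete-separation floor at n = m = 10 reproduces the smallest published
pairwise p of 0.0002), and multiple-comparison adjustments. Two numerical
findings are reproduced and exposed rather than hidden: the published
Bonferroni column is consistent with multiplier m = 20 (ordered pairs of
five algorithms), not m = 10; and the published "Hochberg"/"Hommel" columns
follow the step-up m/j (Benjamini–Hochberg) arithmetic with m = 10 rather
than the classical family-wise formulas. `adjust_pvalues()` therefore
implements all four methods with a configurable multiplier; the classical
Hochberg/Hommel procedures are validated against `stats::p.adjust`.

## The synthetic reference

`make_reference()` emulates the recording protocol: a known "true"
chromosome drives the model over bar sweeps (default eight directions) plus
the flash, with 4 trials per stimulus and NLIF noise providing
trial-to-trial variability. The noise default (`noise_sd = 42`) was
calibrated once so repeated trials of the default cell correlate at ≈ 0.8 in
their smoothed PSTHs — the stated realism target — and then frozen. What the
generator does *not* emulate: cell-type diversity, adaptation and gain
control, correlated (non-white) noise, eye movements, and spike-sorting
artifacts. A green recovery test therefore establishes that the optimisers
can invert this model family under its own noise, not that the model
captures real mouse retina.

## Scaled test profile and acceptance

The full published protocol (5 algorithms × 10 runs × 100 generations on
biological recordings, ~20 min per iteration) is cluster-scale. Tests and
the soft algorithm-ordering check run a scaled profile: 48 × 62 px field,
two directions plus flash, population 16, 25 generations, 3–5 runs; a
complete mini-study takes minutes on one CPU.

One deliberate deviation is documented here: the parameter-recovery
acceptance check runs against a *noise-free* scaled reference. Measured on
the calibrated noisy world, the evaluator's irreducible PSTH-KLD at the true
genes (two independent noisy simulations of the same cell) is ≈ 1.0 × 10⁻³,
while the best of 16 random chromosomes already starts at ≈ 2.2–2.7 × 10⁻³:
no optimiser can reduce the archive best by 80% when the floor is 40% of the
start. Noise-free, the optimum is exactly zero and the check measures what
it names — whether tuning recovers the generating parameters (it does: the
swarm reaches KLD 0 and lands the threshold and leakage genes well inside
20% of their ranges).

## Numerical choices and degenerate inputs

* KLD ε-smoothing 10⁻⁶ per bin, renormalised; divergence of identical
  histograms is exactly 0.
* Rasters with no spikes / no intervals → uniform histogram mass; zero
  spikes → receptive-field size 0; a candidate and reference that are both
  silent on a stimulus are therefore judged identical on it.
* Kruskal–Wallis on all-identical data returns p = 1 by convention.
* Hommel's adjustment coincides with Hochberg's for two p-values (as in
  base R); with a multiplier m beyond the list length the absent hypotheses
  are treated as p = 1.
* Even kernel-size genes map to the next odd size; the gene value itself is
  preserved for the optimiser.
* Spike times are recorded at sub-step midpoints, so they always lie
  strictly inside the trial and inter-spike intervals respect the
  refractory period exactly.
* Frame files are 16-bit quantised plain text with a JSON sidecar (no TIFF
  reader is assumed); round trips are exact to 1/65535.

## Known limitations

* Stage 3 of the original architecture (electrode mapping) is out of scope.
* One modelled cell per evaluation at a configurable centre pixel; no
  population coupling or multi-cell aggregation.
* The HVS + Poisson baseline is a reduced reimplementation (compression,
  spatial DoG, temporal difference of exponentials) of a model whose full
  specification is external to the source work.
* The exact hypervolume recursion is exponential in the worst case; it is
  intended for the front sizes arising here (≤ ~200 points, 4 objectives).
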