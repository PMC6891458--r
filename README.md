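# retinatune

Multi-objective tuning of a bioinspired retinal spike encoder.

## What this is for

Researchers building retinal encoding models (e.g. for visual prosthetics)
need to fit a spiking model of a retinal ganglion cell (RGC) to reference
recordings and to know *which optimiser* to trust for that fit. `retinatune`
provides the full pipeline in R:

* a two-stage retinal model — centre-surround spatial filtering
  (difference-of-Gaussians / Laplacian-of-Gaussian) followed by a noisy
  leaky integrate-and-fire (NLIF) spike encoder — controlled by a 6-gene
  chromosome (kernel size, leakage, threshold, persistence time, refractory
  period, frequency-modulation factor), each gene bounded;
* the standard stimulus battery: 250 µm white bars sweeping a black field at
  1 Hz in eight directions, and 700 ms flashes followed by 2300 ms darkness;
* four minimised spike-train objectives: PSTH and ISI-histogram
  Kullback–Leibler divergences, absolute firing-rate difference (FRAD) and
  absolute receptive-field-size difference (RFAD, via spike-triggered
  averaging);
* five population-based multi-objective metaheuristics — NSGA-II, SPEA2,
  NSGA-III, MOPSO and DE/rand/1/bin — over the mixed-integer chromosome;
* an exact 4-D hypervolume indicator and per-generation trajectories;
* the nonparametric comparison protocol: Kruskal–Wallis, Friedman, pairwise
  Mann–Whitney U, and Bonferroni / Hochberg / Hommel / step-up m/j p-value
  adjustments;
* a synthetic reference generator (a known "true" chromosome plus calibrated
  encoder noise) standing in for biological recordings, and a baseline
  human-visual-system filter + Poisson spiker (HVSP) for comparison.

The core quantities, in the field's notation: stage 1 computes
`S1 = W1·DoG(mean(R,B), G) + W2·DoG(mean(R,G), B) + W3·LoG(I)` per frame at
the cell centre; stage 2 integrates
`V ← V − (V/l)(dt/dt0) + g·Ieff·dt + σ·ξ·√dt` with
`Ieff = (1−fmf)·S1[n] + fmf·pt·(S1[n]−S1[n−1])`, spiking at threshold with
reset and refractory hold. Optimisers minimise the objective vector
`(PSTH-KLD, ISIH-KLD, FRAD, RFAD)`; fronts are scored by hypervolume against
a shared reference point and compared across 10 runs with nonparametric
tests. See `vignettes/methods.Rmd` for assumptions and design choices.

## Worked example

```r
library(retinatune)

# a synthetic reference cell: known chromosome, 2 bar directions + flash
spec <- reference_spec(n_directions = 2, height_px = 48, width_px = 62,
                       noise_sd = 0, master_seed = 7)
ref  <- make_reference(spec)
ev   <- make_evaluator(ref)

# tune with MOPSO at the scaled profile
cfg <- algo_config(population_size = 16, generations = 25)
res <- run_algorithm("mopso", ev, cfg, seed = 5)
res
#> opt_result: mopso, seed 5, 25 generations, 416 evaluations, front size 20

# best front member by PSTH divergence vs the generating truth
i <- which.min(res$front_obj[, 1])
round(res$front_genes[i, ], 3)
#> [1]   9.000  13.319 251.280   5.000   3.160   0.300
chromosome_to_genes(spec$true_chromosome)
#> [1]   9.0  12.5 250.0   5.0   3.0   0.3
```

The tuned genes land on the generating values: kernel size and persistence
time exactly, threshold within 1.3 of 250, leakage within 0.9 of 12.5, and
the best PSTH divergence reaches 0 (noise-free reference). A full
multi-algorithm study is one call:

```r
study <- run_experiment(scaled_profile(runs = 3), out_dir = "study")
report(study)          # per-algorithm HV box-plot data + MOPSO median check
study$report           # Kruskal-Wallis, Friedman, pairwise Mann-Whitney + adjustments
```

The published-table arithmetic is directly reproducible:

```r
adjust_pvalues(c(0.0963, 0.0015), "bonferroni", m = 20)
#> [1] 1.00 0.03
round(mann_whitney_u(1:10, 11:20)$p_value, 4)
#> [1] 2e-04
```

## Command line

An entry point is installed under `exec/`:

```sh
retinatune gen-stimulus --kind bar --direction 90 --out bar90
retinatune make-reference --out ref --seed 1
retinatune tune --algorithm mopso --reference ref --seed 3 --out run3
retinatune hv --front run3/front.csv --ref auto
retinatune stats --table hv.csv --adjust bonferroni:20,hochberg,hommel,step_up_bh
```

## Layout

* `R/` — stimulus generation, retinal model, HVSP baseline, spike metrics,
  optimisers, hypervolume, statistics, experiment runner.
* `tests/testthat/` — unit and property tests with independent brute-force
  oracles, plus `test-acceptance.R` (the acceptance criteria).
* `scripts/acceptance.R` — the acceptance report.
* `vignettes/methods.Rmd` — the model, its assumptions, numerical choices
  and known limitations.
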