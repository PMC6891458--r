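Package: retinatune
Title: Multi-Objective Tuning of a Bioinspired Retinal Spike Encoder
Version: 0.1.0
Authors@R: person("retinatune", "maintainers", email = "maintainers@retinatune.dev", role = c("aut", "cre"))
Description: A tunable bioinspired retinal model (centre-surround DoG/LoG
    spatial filtering followed by noisy leaky integrate-and-fire spike
    encoding) together with the machinery needed to fit its parameters to
    reference spike recordings: moving-bar and flash stimulus generators,
    four spike-train objective functions (PSTH and ISI-histogram
    Kullback-Leibler divergences, firing-rate and receptive-field-size
    absolute differences), five population-based multi-objective
    metaheuristics (NSGA-II, SPEA2, NSGA-III, MOPSO, DE), an exact
    hypervolume indicator, and the nonparametric statistical protocol
    (Kruskal-Wallis, Friedman, pairwise Mann-Whitney U with
    multiple-comparison adjustments) used to compare the optimisers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
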