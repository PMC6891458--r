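#' Raster CSV I/O
#'
#' Rasters are exchanged as plain CSV with columns `cell_id`, `trial`,
#' `spike_time_ms`; the trial count and duration are carried in the header
#' comment-free companion columns `n_trials` and `duration_ms` of a one-line
#' JSON sidecar written next to the CSV (`<path>.meta.json`), so empty trials
#' survive the round trip.
#'
#' @param r a [spike_raster()].
#' @param path CSV file path.
#' @return `read_raster_csv` returns a [spike_raster()].
#' @export
write_raster_csv <- function(r, path) {
  rows <- do.call(rbind, lapply(seq_along(r$trials), function(i) {
    t <- r$trials[[i]]$spike_times_ms
    if (!length(t)) return(NULL)
    data.frame(cell_id = r$cell_id, trial = i, spike_time_ms = t)
  }))
  if (is.null(rows))
    rows <- data.frame(cell_id = character(0), trial = integer(0),
                       spike_time_ms = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE)
  jsonlite::write_json(list(cell_id = r$cell_id, stimulus_id = r$stimulus_id,
                            n_trials = length(r$trials),
                            duration_ms = r$duration_ms),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  trials <- lapply(seq_len(meta$n_trials), function(i) {
    spike_train(sort(df$spike_time_ms[df$trial == i]), meta$duration_ms)
  })
  spike_raster(trials, cell_id = meta$cell_id, stimulus_id = meta$stimulus_id)
}

#' Synthetic reference specification
#'
#' Describes the synthetic stand-in for a recorded ganglion cell: a known
#' "true" chromosome driving the retinal model over the standard stimulus
#' battery (bar sweeps in `n_directions` directions plus a repeated
#' full-field flash), with integrate-and-fire noise providing trial-to-trial
#' variability over `trials` repeats.
#'
#' @param true_chromosome the generating [chromosome()].
#' @param fixed a [stage1_params()].
#' @param noise_sd noise amplitude (default 42, calibrated once so repeated
#'   trials of the default cell correlate at roughly 0.8 in their smoothed
#'   PSTHs).
#' @param trials trials per stimulus (default 4).
#' @param n_directions bar directions in 45-degree steps starting at 0
#'   (default 8).
#' @param flash_repeats repeats of the 700/2300 ms flash cycle (default 1).
#' @param height_px,width_px,frame_rate_hz,pixel_scale_um stimulus geometry.
#' @param bar_width_um bar width (default 250).
#' @param master_seed integer seed for all reference randomness.
#' @return list of class `reference_spec`.
#' @export
reference_spec <- function(true_chromosome = chromosome(),
                           fixed = stage1_params(),
                           noise_sd = 42, trials = 4, n_directions = 8,
                           flash_repeats = 1, height_px = 120, width_px = 154,
                           frame_rate_hz = 60, pixel_scale_um = 26,
                           bar_width_um = 250, master_seed = 1L) {
  if (trials < 1) stop("trials must be >= 1", call. = FALSE)
  structure(list(true_chromosome = true_chromosome, fixed = fixed,
                 noise_sd = noise_sd, trials = as.integer(trials),
                 n_directions = as.integer(n_directions),
                 flash_repeats = as.integer(flash_repeats),
                 height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 frame_rate_hz = frame_rate_hz,
                 pixel_scale_um = pixel_scale_um,
                 bar_width_um = bar_width_um,
                 master_seed = as.integer(master_seed)),
            class = "reference_spec")
}

# Build the stimulus battery of a reference spec: named bar sweeps + flash.
reference_stimuli <- function(spec) {
  dirs <- (seq_len(spec$n_directions) - 1L) * 45L
  stims <- list()
  for (d in dirs) {
    stims[[sprintf("bar_%03d", d)]] <- make_bar_stimulus(
      spec$height_px, spec$width_px, spec$bar_width_um, d,
      sweep_freq_hz = 1, frame_rate_hz = spec$frame_rate_hz,
      n_sweeps = 1, pixel_scale_um = spec$pixel_scale_um)
  }
  stims$flash <- make_flash_stimulus(700, 2300, spec$flash_repeats,
                                     spec$height_px, spec$width_px,
                                     spec$frame_rate_hz, spec$pixel_scale_um)
  stims
}

#' Generate a synthetic reference dataset
#'
#' Builds the stimulus battery, calibrates the drive gain on it, simulates
#' the true-chromosome rasters per stimulus, and (optionally) writes
#' everything to disk: rasters as CSV, stimuli in the plain-text frame
#' format, and a JSON manifest recording the true chromosome, gain, noise
#' level and seeds. Byte-identical for identical master seeds.
#'
#' @param spec a [reference_spec()].
#' @param out_dir output directory, or NULL to keep everything in memory.
#' @return list of class `reference_set` with `stimuli`, `rasters`,
#'   `input_gain`, `center` and `spec`.
#' @export
make_reference <- function(spec, out_dir = NULL) {
  stims <- reference_stimuli(spec)
  center <- c(ceiling(spec$height_px / 2), ceiling(spec$width_px / 2))
  gain <- calibrate_input_gain(stims, spec$fixed, center)
  rasters <- list()
  for (i in seq_along(stims)) {
    nm <- names(stims)[i]
    rasters[[nm]] <- simulate_cell(
      spec$true_chromosome, spec$fixed, stims[[nm]], center = center,
      n_trials = spec$trials, noise_sd = spec$noise_sd, input_gain = gain,
      seed = derive_seed(spec$master_seed, i))
    rasters[[nm]]$stimulus_id <- nm
  }
  ref <- structure(list(stimuli = stims, rasters = rasters, input_gain = gain,
                        center = center, spec = spec),
                   class = "reference_set")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(stims)) {
      save_frames(stims[[nm]], file.path(out_dir, nm))
      write_raster_csv(rasters[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    manifest <- list(
      true_chromosome = unclass(spec$true_chromosome),
      stage1 = unclass(spec$fixed),
      noise_sd = spec$noise_sd, trials = spec$trials,
      input_gain = gain, center = center,
      stimuli = names(stims), master_seed = spec$master_seed,
      seeds = stats::setNames(
        lapply(seq_along(stims), function(i) derive_seed(spec$master_seed, i)),
        names(stims)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  ref
}

#' Build the tuning evaluator
#'
#' Returns the deterministic function mapping a gene vector to the
#' four-objective vector: the candidate chromosome is simulated over every
#' reference stimulus with the reference's gain, trial count and noise
#' level (under a fixed simulation seed so the evaluator is a pure function
#' of the genes) and compared with the reference rasters.
#'
#' @param ref a `reference_set` from [make_reference()].
#' @param cfg a [metric_config()]; defaults to one holding the reference's
#'   bar stimuli for the receptive-field objective.
#' @param sim_seed fixed simulation seed for candidate trials.
#' @param noise_sd candidate simulation noise; defaults to the reference's.
#' @return function(genes) -> named numeric length 4.
#' @export
make_evaluator <- function(ref, cfg = NULL, sim_seed = 99L, noise_sd = NULL) {
  if (is.null(cfg)) {
    bars <- ref$stimuli[grep("^bar_", names(ref$stimuli))]
    cfg <- metric_config(stimuli = bars)
  }
  if (is.null(noise_sd)) noise_sd <- ref$spec$noise_sd
  force(ref); force(sim_seed)
  function(genes) {
    cand_chrom <- genes_to_chromosome(genes)
    cand <- list()
    for (i in seq_along(ref$stimuli)) {
      nm <- names(ref$stimuli)[i]
      cand[[nm]] <- simulate_cell(
        cand_chrom, ref$spec$fixed, ref$stimuli[[nm]], center = ref$center,
        n_trials = ref$spec$trials, noise_sd = noise_sd,
        input_gain = ref$input_gain, seed = derive_seed(sim_seed, i))
    }
    objective_vector(ref$rasters, cand, cfg)
  }
}

#' Experiment configuration
#'
#' @param algorithms algorithms to compare.
#' @param runs independent runs per algorithm (default 10).
#' @param algo an [algo_config()].
#' @param reference a [reference_spec()].
#' @param master_seed seed from which all run seeds derive.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(algorithms = c("nsga2", "spea2", "nsga3",
                                             "mopso", "de"),
                              runs = 10, algo = algo_config(),
                              reference = reference_spec(),
                              master_seed = 1L) {
  if (runs < 1) stop("runs must be >= 1", call. = FALSE)
  structure(list(algorithms = algorithms, runs = as.integer(runs),
                 algo = algo, reference = reference,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' Scaled test profile
#'
#' The desk-scale version of the full tuning protocol, sized so a complete
#' mini-study runs on one CPU in minutes: a 48 x 62 px field, two bar
#' directions plus the flash, population 16, 25 generations, 3 runs per
#' algorithm.
#'
#' @inheritParams experiment_config
#' @return an `experiment_config`.
#' @export
scaled_profile <- function(algorithms = c("nsga2", "spea2", "nsga3", "mopso",
                                          "de"),
                           runs = 3,
                           algo = algo_config(population_size = 16,
                                              generations = 25),
                           reference = reference_spec(n_directions = 2,
                                                      height_px = 48,
                                                      width_px = 62),
                           master_seed = 1L) {
  experiment_config(algorithms = algorithms, runs = runs, algo = algo,
                    reference = reference, master_seed = master_seed)
}

#' Run a comparison study
#'
#' For every algorithm and run: tunes the model against the reference with a
#' derived seed, then computes hypervolume trajectories against one
#' study-wide reference point chosen over all final fronts, assembles the
#' runs-by-algorithms hypervolume table (final and max per run), and applies
#' the statistical protocol. If `out_dir` is given, all artifacts (manifest,
#' HV table CSV, per-run front CSVs, trajectory CSVs, stat report JSON) are
#' written there. A failed run is recorded and the study continues.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir optional output directory.
#' @return list of class `study` with `results` (nested algorithm -> run),
#'   `hv_ref`, `hv_table` (data.frame run, algorithm, hv_final, hv_max),
#'   `report` (a `stat_report` on final HV), and `errors`.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  ref <- make_reference(cfg$reference,
                        out_dir = if (is.null(out_dir)) NULL else
                          file.path(out_dir, "reference"))
  evaluator <- make_evaluator(ref)
  results <- list()
  errors <- list()
  for (alg in cfg$algorithms) {
    results[[alg]] <- vector("list", cfg$runs)
    for (r in seq_len(cfg$runs)) {
      seed <- derive_seed(cfg$master_seed, match(alg, cfg$algorithms), r)
      res <- tryCatch(run_algorithm(alg, evaluator, cfg$algo, seed),
                      error = function(e) e)
      if (inherits(res, "error")) {
        errors[[paste(alg, r, sep = "_")]] <- conditionMessage(res)
      } else {
        results[[alg]][[r]] <- res
      }
    }
  }
  fronts <- list()
  for (alg in names(results)) for (res in results[[alg]])
    if (!is.null(res)) fronts[[length(fronts) + 1L]] <- res$front_obj
  hv_ref <- choose_reference_point(fronts)
  rows <- NULL
  for (alg in names(results)) {
    for (r in seq_along(results[[alg]])) {
      res <- results[[alg]][[r]]
      if (is.null(res)) next
      traj <- hv_trajectory(res, hv_ref)
      res$hv_trajectory <- traj
      results[[alg]][[r]] <- res
      rows <- rbind(rows, data.frame(
        run = r, algorithm = alg, hv_final = traj[length(traj)],
        hv_max = max(traj), n_eval = res$n_eval, seed = res$seed))
    }
  }
  final_mat <- hv_table_to_matrix(data.frame(run = rows$run,
                                             algorithm = rows$algorithm,
                                             hv = rows$hv_final))
  report <- compare_algorithms(final_mat)
  study <- structure(list(config = cfg, hv_ref = hv_ref, results = results,
                          hv_table = rows, report = report, errors = errors),
                     class = "study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rows, file.path(out_dir, "hv_table.csv"),
                     row.names = FALSE)
    for (alg in names(results)) for (r in seq_along(results[[alg]])) {
      res <- results[[alg]][[r]]
      if (is.null(res)) next
      fr <- cbind(as.data.frame(res$front_genes),
                  as.data.frame(res$front_obj))
      names(fr) <- c(chromosome_bounds()$gene,
                     c("psth_kld", "isih_kld", "frad_hz", "rfad_um2"))
      utils::write.csv(fr, file.path(out_dir, sprintf("front_%s_run%d.csv",
                                                      alg, r)),
                       row.names = FALSE)
      utils::write.csv(data.frame(generation = seq_along(res$hv_trajectory) - 1L,
                                  hv = res$hv_trajectory),
                       file.path(out_dir, sprintf("hv_%s_run%d.csv", alg, r)),
                       row.names = FALSE)
    }
    jsonlite::write_json(list(
      algorithms = cfg$algorithms, runs = cfg$runs,
      master_seed = cfg$master_seed, hv_ref = hv_ref,
      errors = errors,
      omnibus = study$report$omnibus), file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(study$report$pairwise, file.path(out_dir, "pairwise.csv"),
                     row.names = FALSE)
  }
  study
}

#' Summarise a study
#'
#' Box-plot data of final and max hypervolume per algorithm, averaged
#' per-generation hypervolume curves, and the soft qualitative check that
#' the particle-swarm optimiser attains the highest median final
#' hypervolume (logged, not asserted: a mirror of the published conclusion
#' at reduced scale).
#'
#' @param study a `study` from [run_experiment()].
#' @return list of class `study_report` with `boxplot` (one row per
#'   algorithm), `hv_curves` (generation x algorithm matrix of mean HV),
#'   and `mopso_best_median` (logical or NA).
#' @export
report <- function(study) {
  tab <- study$hv_table
  algos <- unique(tab$algorithm)
  bp <- do.call(rbind, lapply(algos, function(a) {
    f <- tab$hv_final[tab$algorithm == a]
    mx <- tab$hv_max[tab$algorithm == a]
    data.frame(algorithm = a, final_min = min(f),
               final_median = stats::median(f), final_max = max(f),
               max_median = stats::median(mx))
  }))
  gens <- length(study$results[[1]][[1]]$hv_trajectory)
  curves <- sapply(algos, function(a) {
    trajs <- sapply(study$results[[a]], function(r) r$hv_trajectory)
    rowMeans(trajs)
  })
  mopso_best <- if ("mopso" %in% algos) {
    med <- bp$final_median[bp$algorithm == "mopso"]
    all(med >= bp$final_median)
  } else NA
  structure(list(boxplot = bp, hv_curves = curves,
                 mopso_best_median = mopso_best),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  print(x$boxplot)
  if (!is.na(x$mopso_best_median))
    cat(sprintf("check: MOPSO attains the best median final HV: %s\n",
                x$mopso_best_median))
  invisible(x)
}
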