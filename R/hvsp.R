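#' Human-visual-system filter + Poisson spiking (baseline model)
#'
#' A deliberately simple comparison baseline: luminance compression, a
#' spatial difference-of-Gaussians band-pass sampled at the cell centre, a
#' temporal difference of two exponential low-passes, half-wave
#' rectification, and a gain to firing rate in Hz. Spikes are then drawn from
#' an inhomogeneous Poisson process, which by construction lacks the
#' refractory and bursting structure of the integrate-and-fire encoder.
#'
#' @param stim a [frame_sequence()] (grayscale).
#' @param adaptation_halfpoint intensity at which compression reaches half
#'   saturation (`x / (x + h)`), positive.
#' @param sigma_c,sigma_s centre/surround widths in px, `sigma_c < sigma_s`.
#' @param tau_fast_ms,tau_slow_ms time constants of the fast and slow
#'   exponential low-passes; their difference forms the temporal band-pass.
#' @param center `(row, col)` sample point; NULL for the frame midpoint.
#' @param gain_hz firing rate per unit band-pass output.
#' @return object of class `rate_sequence`: list with nonnegative `rates_hz`
#'   (one per frame) and `frame_rate_hz`.
#' @export
hvs_filter <- function(stim, adaptation_halfpoint = 0.5, sigma_c = 1,
                       sigma_s = 3, tau_fast_ms = 20, tau_slow_ms = 100,
                       center = NULL, gain_hz = 200) {
  stopifnot_scalar_pos(adaptation_halfpoint, "adaptation_halfpoint")
  stopifnot_scalar_pos(sigma_c, "sigma_c")
  stopifnot_scalar_pos(sigma_s, "sigma_s")
  stopifnot_scalar_pos(tau_fast_ms, "tau_fast_ms")
  stopifnot_scalar_pos(tau_slow_ms, "tau_slow_ms")
  stopifnot_scalar_pos(gain_hz, "gain_hz")
  d <- dim(stim$frames)
  if (length(d) != 3L) stop("hvs_filter expects grayscale frames", call. = FALSE)
  if (is.null(center)) center <- c(ceiling(d[2] / 2), ceiling(d[3] / 2))

  k <- 2L * ceiling(3 * sigma_s) + 1L
  kern <- gaussian_kernel(sigma_c, 0, k) - gaussian_kernel(sigma_s, 0, k)
  compressed <- stim$frames / (stim$frames + adaptation_halfpoint)
  spatial <- as.numeric(frame_patches(compressed, as.integer(center), k) %*%
                          as.vector(kern))

  fp <- 1000 / stim$frame_rate_hz
  af <- fp / (tau_fast_ms + fp)
  as_ <- fp / (tau_slow_ms + fp)
  yf <- 0; ys <- 0
  rates <- numeric(d[1])
  for (i in seq_len(d[1])) {
    yf <- yf + af * (spatial[i] - yf)
    ys <- ys + as_ * (spatial[i] - ys)
    rates[i] <- max(0, yf - ys) * gain_hz
  }
  structure(list(rates_hz = rates, frame_rate_hz = stim$frame_rate_hz),
            class = "rate_sequence")
}

#' Poisson spike generation from a rate sequence
#'
#' Per frame, the spike count is Poisson with mean `rate * frame_period` and
#' spike times are uniform within the frame. Identical seeds give identical
#' rasters.
#'
#' @param r a `rate_sequence` from [hvs_filter()].
#' @param n_trials repeated trials.
#' @param seed integer seed.
#' @return a [spike_raster()].
#' @export
poisson_spikes <- function(r, n_trials = 4, seed = 1L) {
  fp <- 1000 / r$frame_rate_hz
  n <- length(r$rates_hz)
  dur <- n * fp
  mu <- r$rates_hz * fp / 1000
  with_seed(seed, {
    trials <- lapply(seq_len(n_trials), function(tr) {
      counts <- stats::rpois(n, mu)
      times <- numeric(0)
      nz <- which(counts > 0)
      for (i in nz) {
        times <- c(times, (i - 1) * fp + stats::runif(counts[i]) * fp)
      }
      times <- sort(times)
      # a uniform draw can tie or hit the boundary; nudge within the frame
      if (length(times) > 1L) {
        eq <- which(diff(times) <= 0)
        while (length(eq)) {
          times[eq + 1L] <- times[eq] + 1e-9
          eq <- which(diff(times) <= 0)
        }
      }
      times <- times[times < dur]
      spike_train(times, dur)
    })
    spike_raster(trials, cell_id = "hvsp")
  })
}
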