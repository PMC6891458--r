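#' Peristimulus time histogram
#'
#' Bins spike times, sums over trials, smooths with a discrete Gaussian and
#' normalises to a probability mass. A raster with no spikes yields the
#' uniform mass, the degenerate-input rule that keeps downstream divergences
#' finite while maximally penalising a dead candidate against a structured
#' reference.
#'
#' @param r a [spike_raster()].
#' @param bin_ms bin width (default 10 ms).
#' @param smooth_sigma_ms Gaussian smoothing width in ms (default 20; 0
#'   disables smoothing).
#' @return object of class `spike_histogram`: list with `bin_edges_ms` and
#'   normalised `masses`.
#' @export
psth <- function(r, bin_ms = 10, smooth_sigma_ms = 20) {
  stopifnot_scalar_pos(bin_ms, "bin_ms")
  edges <- seq(0, r$duration_ms + bin_ms - 1e-9, by = bin_ms)
  if (edges[length(edges)] < r$duration_ms) edges <- c(edges, r$duration_ms)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  for (tr in r$trials) {
    if (length(tr$spike_times_ms)) {
      i <- pmin(nb, floor(tr$spike_times_ms / bin_ms) + 1L)
      tab <- tabulate(i, nbins = nb)
      counts <- counts + tab
    }
  }
  if (smooth_sigma_ms > 0) counts <- gauss_smooth(counts, smooth_sigma_ms / bin_ms)
  normalise_hist(counts, edges)
}

# 1-D Gaussian smoothing (truncated discrete kernel, total mass preserved).
gauss_smooth <- function(x, sigma_bins) {
  h <- max(1L, ceiling(3 * sigma_bins))
  kern <- exp(-((-h):h)^2 / (2 * sigma_bins^2))
  kern <- kern / sum(kern)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    out[i] <- sum(x[j] * kern[j - i + h + 1L])
  }
  if (sum(out) > 0) out <- out * sum(x) / sum(out)
  out
}

normalise_hist <- function(masses, edges) {
  tot <- sum(masses)
  m <- if (tot <= 0) rep(1 / length(masses), length(masses)) else masses / tot
  structure(list(bin_edges_ms = edges, masses = m), class = "spike_histogram")
}

#' Interspike-interval histogram
#'
#' Histogram of within-trial consecutive spike-time differences, clamped at
#' `max_isi_ms`, normalised to a probability mass. Rasters with fewer than
#' two spikes in every trial yield the uniform mass (degenerate rule).
#'
#' @param r a [spike_raster()].
#' @param bin_ms bin width (default 5 ms).
#' @param max_isi_ms upper clip (default 500 ms).
#' @return a `spike_histogram`.
#' @export
isih <- function(r, bin_ms = 5, max_isi_ms = 500) {
  stopifnot_scalar_pos(bin_ms, "bin_ms")
  edges <- seq(0, max_isi_ms, by = bin_ms)
  if (edges[length(edges)] < max_isi_ms) edges <- c(edges, max_isi_ms)
  nb <- length(edges) - 1L
  isis <- unlist(lapply(r$trials, function(t) diff(t$spike_times_ms)))
  counts <- numeric(nb)
  if (length(isis)) {
    isis <- pmin(isis, max_isi_ms - 1e-9)
    counts <- tabulate(pmin(nb, floor(isis / bin_ms) + 1L), nbins = nb)
  }
  normalise_hist(counts, edges)
}

#' Kullback-Leibler divergence between histograms
#'
#' `sum p_i log(p_i / q_i)` (natural log) after epsilon-smoothing both masses
#' and renormalising, so the divergence is finite for empty bins.
#'
#' @param p,q `spike_histogram`s over identical bins (`p` the reference).
#' @param epsilon smoothing mass added per bin before renormalisation.
#' @return nonnegative scalar.
#' @export
kld <- function(p, q, epsilon = 1e-6) {
  if (length(p$masses) != length(q$masses) ||
      max(abs(p$bin_edges_ms - q$bin_edges_ms)) > 1e-9)
    stop("histograms must share identical binning", call. = FALSE)
  ps <- (p$masses + epsilon) / sum(p$masses + epsilon)
  qs <- (q$masses + epsilon) / sum(q$masses + epsilon)
  sum(ps * log(ps / qs))
}

#' Firing rate and its absolute difference
#'
#' `firing_rate` is the mean spike count per trial divided by the trial
#' duration, in Hz; `frad` is the absolute difference between two rates or
#' rasters.
#'
#' @param r a [spike_raster()].
#' @return rate in Hz.
#' @export
firing_rate <- function(r) {
  n <- vapply(r$trials, function(t) length(t$spike_times_ms), integer(1))
  mean(n) / (r$duration_ms / 1000)
}

#' @rdname firing_rate
#' @param a,b rates in Hz or [spike_raster()]s.
#' @export
frad <- function(a, b) {
  ra <- if (inherits(a, "spike_raster")) firing_rate(a) else a
  rb <- if (inherits(b, "spike_raster")) firing_rate(b) else b
  abs(ra - rb)
}

#' Receptive-field size by reverse correlation
#'
#' Spike-triggered average (STA) of the stimulus frames at a fixed latency,
#' pooled over all provided sweep directions; the STA is thresholded at a
#' fraction of its peak and the connected region containing the peak (4-
#' neighbour connectivity) is reported as an area in square micrometres. A
#' cell with no spikes has size 0.
#'
#' @param rasters named list of [spike_raster()]s, one per direction.
#' @param stims named list of [frame_sequence()]s with matching names.
#' @param latency_ms lag between stimulus frame and spike (default 50 ms).
#' @param threshold_frac fraction of the STA peak defining the field
#'   (default 0.5).
#' @return area in square micrometres.
#' @export
receptive_field_size <- function(rasters, stims, latency_ms = 50,
                                 threshold_frac = 0.5) {
  if (!setequal(names(rasters), names(stims)) || is.null(names(rasters)))
    stop("rasters and stimuli must be named lists over the same directions",
         call. = FALSE)
  sta <- NULL
  count <- 0
  scale_um <- NULL
  for (nm in names(rasters)) {
    st <- stims[[nm]]
    fp <- 1000 / st$frame_rate_hz
    nf <- n_frames(st)
    if (is.null(scale_um)) scale_um <- st$pixel_scale_um
    if (is.null(sta)) sta <- matrix(0, dim(st$frames)[2], dim(st$frames)[3])
    for (tr in rasters[[nm]]$trials) {
      fi <- floor((tr$spike_times_ms - latency_ms) / fp) + 1L
      fi <- fi[fi >= 1L & fi <= nf]
      for (f in fi) {
        sta <- sta + st$frames[f, , ]
        count <- count + 1
      }
    }
  }
  if (count == 0) return(0)
  sta <- sta / count
  peak <- max(sta)
  if (peak <= 0) return(0)
  mask <- sta >= threshold_frac * peak
  pk <- which(sta == peak, arr.ind = TRUE)[1, ]
  npx <- flood_fill_count(mask, pk[1], pk[2])
  npx * scale_um^2
}

# Size of the 4-connected TRUE component containing (r0, c0).
flood_fill_count <- function(mask, r0, c0) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  stack <- list(c(r0, c0))
  n <- 0L
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    r <- p[1]; cc <- p[2]
    if (r < 1L || r > h || cc < 1L || cc > w || seen[r, cc] || !mask[r, cc])
      next
    seen[r, cc] <- TRUE
    n <- n + 1L
    stack <- c(stack, list(c(r - 1L, cc), c(r + 1L, cc),
                           c(r, cc - 1L), c(r, cc + 1L)))
  }
  n
}

#' The four-objective vector
#'
#' Compares a candidate set of rasters against a reference set recorded (or
#' simulated) under the same stimuli. PSTH and ISI-histogram KL divergences
#' are averaged over stimuli with the reference as the first argument;
#' the firing-rate difference is computed on rates pooled over all stimuli
#' and trials; the receptive-field difference uses reverse correlation over
#' the bar-sweep stimuli.
#'
#' @param reference,candidate named lists of [spike_raster()]s over the same
#'   stimulus ids.
#' @param cfg a [metric_config()].
#' @return named numeric `c(psth_kld, isih_kld, frad_hz, rfad_um2)`, all
#'   nonnegative, all minimised.
#' @export
objective_vector <- function(reference, candidate, cfg) {
  if (!setequal(names(reference), names(candidate)) || is.null(names(reference)))
    stop("reference and candidate must cover the same stimulus ids",
         call. = FALSE)
  nms <- names(reference)
  pk <- ik <- 0
  tot_ref <- tot_cand <- 0   # pooled spikes
  tt <- 0                    # pooled trial-time, s
  for (nm in nms) {
    rr <- reference[[nm]]; cc <- candidate[[nm]]
    pk <- pk + kld(psth(rr, cfg$psth_bin_ms, cfg$psth_sigma_ms),
                   psth(cc, cfg$psth_bin_ms, cfg$psth_sigma_ms), cfg$epsilon)
    ik <- ik + kld(isih(rr, cfg$isih_bin_ms, cfg$isih_max_ms),
                   isih(cc, cfg$isih_bin_ms, cfg$isih_max_ms), cfg$epsilon)
    tot_ref <- tot_ref + sum(vapply(rr$trials,
                                    function(t) length(t$spike_times_ms), integer(1))) /
      length(rr$trials)
    tot_cand <- tot_cand + sum(vapply(cc$trials,
                                      function(t) length(t$spike_times_ms), integer(1))) /
      length(cc$trials)
    tt <- tt + rr$duration_ms / 1000
  }
  f <- abs(tot_ref - tot_cand) / tt
  rf <- 0
  if (!is.null(cfg$stimuli)) {
    bar_ids <- intersect(nms, names(cfg$stimuli))
    if (length(bar_ids)) {
      sz_ref <- receptive_field_size(reference[bar_ids], cfg$stimuli[bar_ids],
                                     cfg$latency_ms, cfg$threshold_frac)
      sz_cand <- receptive_field_size(candidate[bar_ids], cfg$stimuli[bar_ids],
                                      cfg$latency_ms, cfg$threshold_frac)
      rf <- abs(sz_ref - sz_cand)
    }
  }
  c(psth_kld = pk / length(nms), isih_kld = ik / length(nms),
    frad_hz = f, rfad_um2 = rf)
}

#' Metric configuration
#'
#' Histogram and receptive-field settings used by [objective_vector()]. The
#' defaults (10 ms PSTH bins smoothed with a 20 ms Gaussian, 5 ms ISI bins up
#' to 500 ms, epsilon 1e-6, 50 ms STA latency, half-peak field threshold)
#' are conventional for retinal ganglion cell analysis.
#'
#' @param psth_bin_ms,psth_sigma_ms PSTH bin width and smoothing sigma.
#' @param isih_bin_ms,isih_max_ms ISI histogram bin width and clip.
#' @param epsilon KLD smoothing mass.
#' @param latency_ms,threshold_frac receptive-field estimation settings.
#' @param stimuli named list of [frame_sequence()]s used for the STA (bar
#'   sweeps); stimulus ids absent from this list are excluded from the
#'   receptive-field objective.
#' @return a list of class `metric_config`.
#' @export
metric_config <- function(psth_bin_ms = 10, psth_sigma_ms = 20,
                          isih_bin_ms = 5, isih_max_ms = 500,
                          epsilon = 1e-6, latency_ms = 50,
                          threshold_frac = 0.5, stimuli = NULL) {
  structure(list(psth_bin_ms = psth_bin_ms, psth_sigma_ms = psth_sigma_ms,
                 isih_bin_ms = isih_bin_ms, isih_max_ms = isih_max_ms,
                 epsilon = epsilon, latency_ms = latency_ms,
                 threshold_frac = threshold_frac, stimuli = stimuli),
            class = "metric_config")
}

#' Pearson correlation of two rate traces
#'
#' @param a,b equal-length numeric traces, each non-constant, length >= 2.
#' @return correlation in `[-1, 1]`.
#' @export
pcc <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("traces must have equal length >= 2", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for constant traces", call. = FALSE)
  stats::cor(a, b)
}
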