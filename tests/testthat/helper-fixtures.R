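# Shared builders for small test objects. Everything is generated in code;
# sizes are kept tiny so the whole suite runs in minutes.

tiny_reference_spec <- function(noise_sd = 0, seed = 7L, trials = 2) {
  reference_spec(n_directions = 2, height_px = 24, width_px = 32,
                 noise_sd = noise_sd, trials = trials, master_seed = seed)
}

# raster from a list of spike-time vectors
raster_from_times <- function(times_list, duration_ms) {
  spike_raster(lapply(times_list, spike_train, duration_ms = duration_ms))
}

# brute-force O(n^2 M) nondominated sorting oracle: repeatedly strip the
# nondominated members
brute_force_fronts <- function(obj) {
  left <- seq_len(nrow(obj))
  fronts <- list()
  while (length(left)) {
    nd <- left[vapply(left, function(i) {
      !any(vapply(left, function(j) {
        j != i && all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ])
      }, logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1L]] <- nd
    left <- setdiff(left, nd)
  }
  fronts
}

# independent crowding-distance oracle, straight from the NSGA-II definition
brute_force_crowding <- function(obj) {
  n <- nrow(obj)
  d <- numeric(n)
  for (m in seq_len(ncol(obj))) {
    o <- order(obj[, m])
    d[o[1]] <- d[o[n]] <- Inf
    rng <- obj[o[n], m] - obj[o[1], m]
    if (rng > 0 && n > 2) {
      for (q in 2:(n - 1)) {
        d[o[q]] <- d[o[q]] + (obj[o[q + 1], m] - obj[o[q - 1], m]) / rng
      }
    }
  }
  d
}

# Monte-Carlo hypervolume estimate in the box [lower, ref]
mc_hypervolume <- function(pts, ref, lower, n_samples) {
  d <- length(ref)
  u <- matrix(runif(n_samples * d), ncol = d)
  u <- sweep(sweep(u, 2, ref - lower, "*"), 2, lower, "+")
  dominated <- rep(FALSE, n_samples)
  for (i in seq_len(nrow(pts))) {
    hit <- rep(TRUE, n_samples)
    for (m in seq_len(d)) hit <- hit & (u[, m] >= pts[i, m])
    dominated <- dominated | hit
  }
  frac <- mean(dominated)
  vol <- prod(ref - lower)
  list(estimate = frac * vol,
       se = sqrt(frac * (1 - frac) / n_samples) * vol)
}
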