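#' Fixed stage-1 filter parameters
#'
#' The first stage of the retinal model is a weighted sum of centre-surround
#' spatial filters: two difference-of-Gaussians (DoG) terms over
#' colour-opponent channel pairs and one Laplacian-of-Gaussian (LoG) term
#' over luminance. These parameters are held fixed during tuning; only the
#' shared kernel size is exposed as a gene of the chromosome.
#'
#' @param sigma1,sigma2 centre and surround Gaussian widths in pixels
#'   (`sigma1 < sigma2` gives the usual Mexican-hat antagonism).
#' @param mu1,mu2 kernel-centre offsets in pixels (default 0).
#' @param k1,k2 odd kernel sizes in pixels.
#' @param W length-3 weights of the three filter terms.
#' @return an object of class `stage1_params`.
#' @export
stage1_params <- function(sigma1 = 1.0, sigma2 = 2.0, mu1 = 0, mu2 = 0,
                          k1 = 7L, k2 = 7L, W = c(0.25, 0.25, 0.5)) {
  stopifnot_scalar_pos(sigma1, "sigma1")
  stopifnot_scalar_pos(sigma2, "sigma2")
  if (length(W) != 3L || any(!is.finite(W)))
    stop("W must be three finite weights", call. = FALSE)
  k1 <- as.integer(k1); k2 <- as.integer(k2)
  if (k1 %% 2L == 0L || k2 %% 2L == 0L || k1 < 3L || k2 < 3L)
    stop("kernel sizes must be odd and >= 3", call. = FALSE)
  structure(list(sigma1 = sigma1, sigma2 = sigma2, mu1 = mu1, mu2 = mu2,
                 k1 = k1, k2 = k2, W = as.numeric(W)),
            class = "stage1_params")
}

#' The tuned chromosome of the retinal model
#'
#' Six genes control the model: the stage-1 kernel size `K`, and the five
#' spike-encoder parameters (leak constant, firing threshold, persistence
#' time in sub-steps per frame, refractory period in ms, and the
#' frequency-modulation factor mixing sustained and transient drive). Each
#' gene is restricted to a fixed range; `K` and `persistence_time` are
#' integers.
#'
#' @param K kernel size gene, integer in `[3, 13]`.
#' @param leakage leak constant, in `[10, 15]` (membrane time constant in ms
#'   under the 1 ms reference step).
#' @param threshold firing threshold in membrane-potential units, `[225, 275]`.
#' @param persistence_time integer sub-steps per stimulus frame, `[3, 7]`.
#' @param refractory_period ms, `[1, 10]`.
#' @param fmf frequency-modulation factor, `[0.25, 0.40]`.
#' @return an object of class `chromosome`.
#' @export
chromosome <- function(K = 9L, leakage = 12.5, threshold = 250,
                       persistence_time = 5L, refractory_period = 3,
                       fmf = 0.3) {
  c <- structure(list(K = as.integer(round(K)), leakage = leakage,
                      threshold = threshold,
                      persistence_time = as.integer(round(persistence_time)),
                      refractory_period = refractory_period, fmf = fmf),
                 class = "chromosome")
  b <- chromosome_bounds()
  v <- as.numeric(unlist(c[b$gene]))
  if (any(v < b$lower - 1e-9) || any(v > b$upper + 1e-9))
    stop("chromosome gene outside its allowed range", call. = FALSE)
  c
}

#' Gene bounds of the chromosome
#'
#' @return data.frame with columns `gene`, `lower`, `upper`, `integer`.
#' @export
chromosome_bounds <- function() {
  data.frame(
    gene = c("K", "leakage", "threshold", "persistence_time",
             "refractory_period", "fmf"),
    lower = c(3, 10.0, 225.0, 3, 1.0, 0.25),
    upper = c(13, 15.0, 275.0, 7, 10.0, 0.40),
    integer = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' @export
print.chromosome <- function(x, ...) {
  cat(sprintf(
    "chromosome: K=%d leakage=%.3f threshold=%.2f pt=%d rp=%.2f fmf=%.3f\n",
    x$K, x$leakage, x$threshold, x$persistence_time, x$refractory_period,
    x$fmf))
  invisible(x)
}

#' Convert between chromosomes and plain gene vectors
#'
#' The optimisers work on numeric vectors in the fixed gene order of
#' [chromosome_bounds()]; these helpers translate to and from the
#' [chromosome()] object (clipping and integer-rounding on the way in).
#'
#' @param c a [chromosome()].
#' @param g numeric vector of length 6.
#' @return `chromosome_to_genes`: numeric length 6; `genes_to_chromosome`: a
#'   [chromosome()].
#' @export
chromosome_to_genes <- function(c) {
  c(c$K, c$leakage, c$threshold, c$persistence_time, c$refractory_period,
    c$fmf)
}

#' @rdname chromosome_to_genes
#' @export
genes_to_chromosome <- function(g) {
  g <- clip_genes(g)
  chromosome(K = g[1], leakage = g[2], threshold = g[3],
             persistence_time = g[4], refractory_period = g[5], fmf = g[6])
}

# Project a raw gene vector into the feasible box; integer genes are rounded
# first so rounding can never push a gene outside its range.
clip_genes <- function(g) {
  b <- chromosome_bounds()
  g <- as.numeric(g)
  g[b$integer] <- round(g[b$integer])
  clamp(g, b$lower, b$upper)
}

#' Random and clipped chromosomes
#'
#' `random_chromosome` samples each gene uniformly within its range (integer
#' genes uniform on the integer range) using the current RNG stream;
#' `clip_chromosome` projects any out-of-range gene to the nearest bound and
#' rounds integer genes.
#'
#' @param c a [chromosome()] or a plain list with the six gene fields.
#' @return a [chromosome()].
#' @export
random_chromosome <- function() {
  b <- chromosome_bounds()
  g <- numeric(6)
  for (i in seq_len(6)) {
    g[i] <- if (b$integer[i]) {
      sample(b$lower[i]:b$upper[i], 1L)
    } else {
      runif(1, b$lower[i], b$upper[i])
    }
  }
  genes_to_chromosome(g)
}

#' @rdname random_chromosome
#' @export
clip_chromosome <- function(c) {
  genes_to_chromosome(clip_genes(
    c(c$K, c$leakage, c$threshold, c$persistence_time, c$refractory_period,
      c$fmf)))
}

# ---- spatial filters -------------------------------------------------------

#' Normalised Gaussian kernel
#'
#' `k x k` kernel sampled from an isotropic Gaussian whose centre is shifted
#' by `mu` pixels in both axes, normalised to sum to one.
#'
#' @param sigma Gaussian width in pixels, positive.
#' @param mu centre offset in pixels.
#' @param k odd kernel size.
#' @return `k x k` numeric matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma, mu = 0, k = 7L) {
  stopifnot_scalar_pos(sigma, "sigma")
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 1L) stop("k must be odd and positive", call. = FALSE)
  h <- (k - 1L) / 2L
  off <- (-h):h
  g2 <- outer(off - mu, off - mu, function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
  g2 / sum(g2)
}

# Zero-sum Laplacian-of-Gaussian kernel (negative centre, positive annulus).
log_kernel <- function(sigma, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 1L) stop("k must be odd and positive", call. = FALSE)
  h <- (k - 1L) / 2L
  off <- (-h):h
  m <- outer(off, off, function(y, x) {
    r2 <- x^2 + y^2
    (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  })
  # The "Mexican hat": excitatory centre, inhibitory surround.
  m <- -m
  m - mean(m)
}

# 2-D convolution with edge replication, implemented by accumulating shifted
# copies of the image (kernels here are small, <= 13 x 13).
conv2_replicate <- function(img, kernel) {
  h <- nrow(img); w <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  ch <- (kh - 1L) / 2L; cw <- (kw - 1L) / 2L
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) {
    di <- i - 1L - ch
    ri <- clamp(seq_len(h) + di, 1L, h)
    for (j in seq_len(kw)) {
      kv <- kernel[i, j]
      if (kv == 0) next
      dj <- j - 1L - cw
      cj <- clamp(seq_len(w) + dj, 1L, w)
      out <- out + kv * img[ri, cj, drop = FALSE]
    }
  }
  out
}

#' Difference-of-Gaussians filtering
#'
#' Convolves the centre image with the narrow Gaussian and the surround image
#' with the wide Gaussian and subtracts, modelling centre-surround
#' antagonism between two (possibly different) input channels. Borders are
#' handled by edge replication.
#'
#' @param center_img,surround_img numeric matrices of identical shape.
#' @param p a [stage1_params()].
#' @return numeric matrix of the same shape.
#' @export
dog_filter <- function(center_img, surround_img, p) {
  if (!identical(dim(center_img), dim(surround_img)))
    stop("centre and surround images must have the same shape", call. = FALSE)
  kc <- gaussian_kernel(p$sigma1, p$mu1, p$k1)
  ks <- gaussian_kernel(p$sigma2, p$mu2, p$k2)
  conv2_replicate(center_img, kc) - conv2_replicate(surround_img, ks)
}

#' Laplacian-of-Gaussian filtering
#'
#' Convolution with a zero-sum discrete LoG kernel of width `sigma1` and size
#' `k1`, capturing the "Mexican hat" luminance response.
#'
#' @inheritParams dog_filter
#' @param intensity_img numeric matrix.
#' @return numeric matrix of the same shape.
#' @export
log_filter <- function(intensity_img, p) {
  conv2_replicate(intensity_img, log_kernel(p$sigma1, p$k1))
}

# ---- stage 1 ---------------------------------------------------------------

# Effective (odd) kernel size for a K gene; Table-1 K may be even.
effective_ksize <- function(K) {
  K <- as.integer(K)
  if (K %% 2L == 0L) K + 1L else K
}

# Gather the k x k edge-replicated patch around `center` for every frame:
# returns an n_frames x k^2 matrix, so the centre-pixel response to any
# kernel is a single matrix-vector product.
frame_patches <- function(frames, center, k) {
  d <- dim(frames)
  h <- d[2]; w <- d[3]
  half <- (k - 1L) / 2L
  ri <- clamp(center[1] + (-half):half, 1L, h)
  ci <- clamp(center[2] + (-half):half, 1L, w)
  # column-major over (row, col) to match as.vector(kernel)
  idx <- as.matrix(expand.grid(r = ri, c = ci))
  out <- matrix(0, d[1], k * k)
  for (j in seq_len(nrow(idx))) out[, j] <- frames[, idx[j, 1], idx[j, 2]]
  out
}

#' Stage-1 activation at the modelled cell's centre
#'
#' Applies the weighted filter bank per frame and samples the result at the
#' cell's centre pixel:
#' `S1 = W1 * DoG(mean(R,B), G) + W2 * DoG(mean(R,G), B) + W3 * LoG(I)`.
#' Grayscale input uses `R = G = B = I`, which reduces to
#' `(W1 + W2) * DoG(I, I) + W3 * LoG(I)`.
#'
#' @param stim a [frame_sequence()].
#' @param p a [stage1_params()].
#' @param center integer `(row, col)` of the modelled cell, inside the frame.
#' @return object of class `activation_sequence`: list with `values` (one per
#'   frame) and `frame_rate_hz`.
#' @export
stage1 <- function(stim, p, center) {
  d <- dim(stim$frames)
  center <- as.integer(center)
  if (length(center) != 2L || center[1] < 1L || center[1] > d[2] ||
      center[2] < 1L || center[2] > d[3])
    stop("center must be a (row, col) pair inside the frame", call. = FALSE)
  kc <- gaussian_kernel(p$sigma1, p$mu1, p$k1)
  ks <- gaussian_kernel(p$sigma2, p$mu2, p$k2)
  kl <- log_kernel(p$sigma1, p$k1)
  kmax <- max(p$k1, p$k2)
  pad <- function(kern) {               # embed into common kmax x kmax
    if (nrow(kern) == kmax) return(kern)
    out <- matrix(0, kmax, kmax)
    off <- (kmax - nrow(kern)) / 2
    out[off + seq_len(nrow(kern)), off + seq_len(ncol(kern))] <- kern
    out
  }
  kc <- pad(kc); ks <- pad(ks); kl <- pad(kl)
  W <- p$W
  if (length(d) == 3L) {
    patches <- frame_patches(stim$frames, center, kmax)
    comb <- (W[1] + W[2]) * (as.vector(kc) - as.vector(ks)) + W[3] * as.vector(kl)
    vals <- as.numeric(patches %*% comb)
  } else {
    pr <- frame_patches(stim$frames[, , , 1], center, kmax)
    pg <- frame_patches(stim$frames[, , , 2], center, kmax)
    pb <- frame_patches(stim$frames[, , , 3], center, kmax)
    vc <- as.vector(kc); vs <- as.vector(ks); vl <- as.vector(kl)
    s_rb_g <- ((pr + pb) / 2) %*% vc - pg %*% vs
    s_rg_b <- ((pr + pg) / 2) %*% vc - pb %*% vs
    s_i <- ((pr + pg + pb) / 3) %*% vl
    vals <- as.numeric(W[1] * s_rb_g + W[2] * s_rg_b + W[3] * s_i)
  }
  structure(list(values = vals, frame_rate_hz = stim$frame_rate_hz),
            class = "activation_sequence")
}

# ---- stage 2: noisy leaky integrate-and-fire -------------------------------

#' Spike trains and rasters
#'
#' A `spike_train` is a strictly increasing sequence of spike times in ms
#' within `[0, duration_ms)`; a `spike_raster` bundles repeated trials of the
#' same cell under the same stimulus.
#'
#' @param spike_times_ms numeric, strictly increasing, `0 <= t < duration_ms`.
#' @param duration_ms trial duration.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(spike_times_ms, duration_ms) {
  t <- as.numeric(spike_times_ms)
  if (length(t) && (is.unsorted(t, strictly = TRUE) || t[1] < 0 ||
                    t[length(t)] >= duration_ms))
    stop("spike times must be strictly increasing in [0, duration_ms)",
         call. = FALSE)
  structure(list(spike_times_ms = t, duration_ms = duration_ms),
            class = "spike_train")
}

#' @rdname spike_train
#' @param trials list of `spike_train`s sharing one duration.
#' @param cell_id,stimulus_id identifiers.
#' @export
spike_raster <- function(trials, cell_id = "cell", stimulus_id = "stim") {
  if (!length(trials)) stop("a raster needs at least one trial", call. = FALSE)
  dur <- vapply(trials, function(t) t$duration_ms, numeric(1))
  if (max(dur) - min(dur) > 1e-9)
    stop("all trials must share duration_ms", call. = FALSE)
  structure(list(cell_id = cell_id, stimulus_id = stimulus_id,
                 trials = trials, duration_ms = dur[1]),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  n <- vapply(x$trials, function(t) length(t$spike_times_ms), integer(1))
  cat(sprintf("spike_raster '%s' on '%s': %d trials, %.4g ms, %.1f spikes/trial\n",
              x$cell_id, x$stimulus_id, length(x$trials), x$duration_ms, mean(n)))
  invisible(x)
}

#' Noisy leaky integrate-and-fire encoding
#'
#' Encodes a stage-1 activation sequence into a spike train. Each stimulus
#' frame is processed `persistence_time` times at sub-step
#' `dt = frame_period / persistence_time`; per sub-step the membrane
#' potential evolves as
#' \deqn{V \leftarrow V - (V/l)(dt/dt_0) + g\,I\,dt + \sigma\,\xi\,\sqrt{dt}}
#' with reference step `dt0 = 1` ms, leak `l`, input gain `g`, standard
#' normal noise `xi`, and effective drive mixing sustained and transient
#' components: `I = (1 - fmf) * S1[n] + fmf * pt * (S1[n] - S1[n-1])`. When
#' `V` reaches the threshold a spike is emitted, `V` resets to 0 and is held
#' there for the refractory period.
#'
#' @param s1 an `activation_sequence` from [stage1()].
#' @param c a [chromosome()].
#' @param input_gain positive drive scale (see [calibrate_input_gain()]).
#' @param noise_sd noise amplitude per sqrt(ms); 0 gives a deterministic
#'   train.
#' @param seed integer seed; identical seeds give identical trains.
#' @return a [spike_train()].
#' @export
nlif_encode <- function(s1, c, input_gain = 1, noise_sd = 0, seed = 1L) {
  stopifnot_scalar_pos(input_gain, "input_gain")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  with_seed(seed, {
    fp <- 1000 / s1$frame_rate_hz
    pt <- c$persistence_time
    dt <- fp / pt
    leak_f <- dt / c$leakage            # dt0 = 1 ms reference
    n <- length(s1$values)
    nsub <- n * pt
    # per-substep quantities, precomputed (the spike/reset logic is the only
    # part that has to stay sequential)
    s_now <- s1$values
    drive <- (1 - c$fmf) * s_now + c$fmf * pt * (s_now - c(0, s_now[-n]))
    inp <- rep(input_gain * drive * dt, each = pt)
    if (noise_sd > 0) inp <- inp + noise_sd * sqrt(dt) * rnorm(nsub)
    t_mid <- ((seq_len(nsub) - 0.5)) * dt
    v <- 0
    refract_until <- -Inf
    spikes <- numeric(0)
    thr <- c$threshold
    rp <- c$refractory_period
    for (i in seq_len(nsub)) {
      if (t_mid[i] < refract_until) next  # held at reset
      v <- v - v * leak_f + inp[i]
      if (v >= thr) {
        spikes <- c(spikes, t_mid[i])
        v <- 0
        refract_until <- t_mid[i] + rp
      }
    }
    spike_train(spikes, n * fp)
  })
}

#' Simulate one modelled cell
#'
#' Runs stage 1 once with `k1 = k2` set from the chromosome's `K` gene (even
#' `K` uses `K + 1`, the nearest odd size), then encodes `n_trials`
#' repetitions with per-trial derived seeds.
#'
#' @param c a [chromosome()].
#' @param fixed a [stage1_params()]; its kernel sizes are overridden by `K`.
#' @param stim a [frame_sequence()].
#' @param center `(row, col)` cell centre; default the frame midpoint.
#' @param n_trials repeated trials.
#' @param noise_sd,input_gain,seed passed to [nlif_encode()].
#' @return a [spike_raster()].
#' @export
simulate_cell <- function(c, fixed, stim, center = NULL, n_trials = 4,
                          noise_sd = 0, input_gain = 1, seed = 1L) {
  d <- dim(stim$frames)
  if (is.null(center)) center <- c(ceiling(d[2] / 2), ceiling(d[3] / 2))
  k <- effective_ksize(c$K)
  p <- stage1_params(sigma1 = fixed$sigma1, sigma2 = fixed$sigma2,
                     mu1 = fixed$mu1, mu2 = fixed$mu2, k1 = k, k2 = k,
                     W = fixed$W)
  s1 <- stage1(stim, p, center)
  trials <- lapply(seq_len(n_trials), function(i) {
    nlif_encode(s1, c, input_gain = input_gain, noise_sd = noise_sd,
                seed = derive_seed(seed, i))
  })
  spike_raster(trials)
}

#' Calibrate the drive gain
#'
#' The firing threshold of the chromosome lives in arbitrary units that the
#' model never anchors to the stimulus; the gain is therefore chosen once per
#' stimulus set so that the asymptotic membrane potential under the peak
#' noise-free stage-1 drive is `target_ratio` times a nominal mid-range
#' threshold (steady state `V* = g * S1 * l * dt0`). The nominal kernel size
#' and leak are fixed (K = 9, l = 12.5) so the gain does not depend on the
#' candidate being evaluated.
#'
#' @param stims list of [frame_sequence()]s.
#' @param fixed a [stage1_params()].
#' @param center `(row, col)` or NULL for the frame midpoint.
#' @param target_ratio peak steady-state potential over threshold (default 1.5).
#' @return positive scalar gain.
#' @export
calibrate_input_gain <- function(stims, fixed, center = NULL,
                                 target_ratio = 1.5) {
  k <- effective_ksize(9L)
  p <- stage1_params(sigma1 = fixed$sigma1, sigma2 = fixed$sigma2,
                     mu1 = fixed$mu1, mu2 = fixed$mu2, k1 = k, k2 = k,
                     W = fixed$W)
  peak <- 0
  for (s in stims) {
    d <- dim(s$frames)
    ctr <- if (is.null(center)) c(ceiling(d[2] / 2), ceiling(d[3] / 2)) else center
    peak <- max(peak, max(abs(stage1(s, p, ctr)$values)))
  }
  if (peak == 0) stop("stimulus set produces no stage-1 drive", call. = FALSE)
  target_ratio * 250 / (12.5 * peak)
}
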