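test_that("gaussian_kernel is normalised, symmetric and flat in the wide limit", {
  for (sig in c(0.5, 1, 3)) for (k in c(3L, 7L, 13L)) {
    kern <- gaussian_kernel(sig, 0, k)
    expect_lt(abs(sum(kern) - 1), 1e-12)
    expect_equal(kern, t(kern))                       # mu = 0: 90-deg symmetry
    expect_equal(kern, kern[k:1, k:1])
  }
  flat <- gaussian_kernel(100, 0, 3)
  expect_true(all(abs(flat - 1 / 9) < 1e-4))
  expect_error(gaussian_kernel(1, 0, 4), "odd")
})

test_that("dog_filter cancels constants, is linear, and has centre-surround sign", {
  p <- stage1_params(sigma1 = 0.8, sigma2 = 2, k1 = 5L, k2 = 9L)
  const <- matrix(0.37, 15, 15)
  out <- dog_filter(const, const, p)
  expect_lt(max(abs(out[5:11, 5:11])), 1e-12)         # interior only

  img <- matrix(0, 15, 15); img[8, 8] <- 1
  out <- dog_filter(img, img, p)
  expect_gt(out[8, 8], 0)                             # positive at the pixel
  expect_lt(min(out[6:10, 6:10]), 0)                  # negative annulus nearby

  a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
  expect_equal(dog_filter(2 * a, 2 * b, p), 2 * dog_filter(a, b, p))
  expect_error(dog_filter(a, matrix(0, 4, 4), p), "same shape")
})

test_that("log_filter is zero-sum, linear, with opposed centre and surround", {
  p <- stage1_params(sigma1 = 1, k1 = 7L)
  const <- matrix(1, 13, 13)
  out <- log_filter(const, p)
  expect_lt(max(abs(out[4:10, 4:10])), 1e-12)
  kern <- retinatune:::log_kernel(1, 7L)
  expect_lt(abs(sum(kern)), 1e-12)
  expect_true(sign(kern[4, 4]) != sign(kern[1, 1]))   # centre vs far corner
  img <- matrix(runif(169), 13, 13)
  expect_equal(log_filter(3 * img, p), 3 * log_filter(img, p))
})

test_that("stage1 matches a brute-force convolution oracle on a toy image", {
  set.seed(41)
  img <- matrix(runif(25), 5, 5)
  frames <- array(0, dim = c(1, 5, 5)); frames[1, , ] <- img
  stim <- frame_sequence(frames, 60, 26)
  p <- stage1_params(sigma1 = 0.5, sigma2 = 1, k1 = 3L, k2 = 3L, W = c(1, 1, 1))

  # oracle: direct replicated-border convolution at the centre pixel
  conv_at <- function(img, kern, r0, c0) {
    k <- nrow(kern); h <- (k - 1) / 2
    acc <- 0
    for (i in -h:h) for (j in -h:h) {
      ri <- min(max(r0 + i, 1), nrow(img))
      ci <- min(max(c0 + j, 1), ncol(img))
      acc <- acc + kern[i + h + 1, j + h + 1] * img[ri, ci]
    }
    acc
  }
  kc <- gaussian_kernel(0.5, 0, 3L)
  ks <- gaussian_kernel(1, 0, 3L)
  kl <- retinatune:::log_kernel(0.5, 3L)
  expected <- 2 * (conv_at(img, kc, 3, 3) - conv_at(img, ks, 3, 3)) +
    conv_at(img, kl, 3, 3)
  got <- stage1(stim, p, c(3, 3))$values
  expect_equal(got, expected, tolerance = 1e-12)

  # grayscale identity: (W1+W2) dog + W3 log at centre via the full filters
  full <- (p$W[1] + p$W[2]) * dog_filter(img, img, p)[3, 3] +
    p$W[3] * log_filter(img, p)[3, 3]
  expect_equal(got, full, tolerance = 1e-12)
  expect_error(stage1(stim, p, c(9, 9)), "inside")
})

test_that("stage1 of an all-black stimulus is zero, and is linear in the input", {
  black <- frame_sequence(array(0, dim = c(4, 10, 12)), 60, 26)
  p <- stage1_params()
  expect_true(all(stage1(black, p, c(5, 6))$values == 0))

  set.seed(5)
  arr <- array(runif(4 * 10 * 12), dim = c(4, 10, 12))
  s1 <- stage1(frame_sequence(arr, 60, 26), p, c(5, 6))$values
  s2 <- stage1(frame_sequence(arr / 2, 60, 26), p, c(5, 6))$values
  expect_equal(s1, 2 * s2, tolerance = 1e-12)
})

test_that("nlif_encode honours the refractory contract and zero-input silence", {
  fr <- 60
  s1 <- structure(list(values = rep(0, 30), frame_rate_hz = fr),
                  class = "activation_sequence")
  ch <- chromosome()
  expect_length(nlif_encode(s1, ch, 1, 0, 1)$spike_times_ms, 0)

  s1$values <- rep(100, 120)
  for (seed in 1:5) {
    tr <- nlif_encode(s1, ch, input_gain = 1, noise_sd = 50, seed = seed)
    if (length(tr$spike_times_ms) > 1)
      expect_gte(min(diff(tr$spike_times_ms)), ch$refractory_period)
    expect_lt(max(tr$spike_times_ms), tr$duration_ms)
  }
  # reproducibility
  a <- nlif_encode(s1, ch, 1, 30, 11)
  b <- nlif_encode(s1, ch, 1, 30, 11)
  expect_identical(a, b)
})

test_that("noise-free ISI matches the deterministic membrane recurrence", {
  fr <- 100
  n <- 200
  drive_level <- 40
  s1 <- structure(list(values = rep(drive_level, n), frame_rate_hz = fr),
                  class = "activation_sequence")
  ch <- chromosome(K = 9, leakage = 12, threshold = 260, persistence_time = 4,
                   refractory_period = 5, fmf = 0.3)
  tr <- nlif_encode(s1, ch, input_gain = 1, noise_sd = 0, seed = 1)
  isis <- diff(tr$spike_times_ms)[-1]   # first interval still carries the
  expect_gt(length(isis), 3)            # onset transient of the fmf term

  # oracle: iterate v <- v - v dt/l + g I dt from 0 until threshold; the
  # steady-state drive is (1 - fmf) * S1 once the transient term vanishes.
  # rp is an exact multiple of dt here, so integration resumes exactly rp
  # after a spike and the ISI is rp + (steps - 1) dt.
  dt <- (1000 / fr) / ch$persistence_time
  inp <- 1 * (1 - ch$fmf) * drive_level * dt
  v <- 0; steps <- 0
  repeat {
    v <- v - v * dt / ch$leakage + inp
    steps <- steps + 1
    if (v >= ch$threshold) break
  }
  expect_equal(unique(round(isis, 6)),
               round(ch$refractory_period + (steps - 1) * dt, 6))
})

test_that("raising the threshold never increases the noise-free spike count", {
  stim <- make_bar_stimulus(24, 32, 250, 0, 1, 60, 1)
  fixed <- stage1_params()
  counts <- sapply(c(225, 240, 255, 275), function(thr) {
    ch <- chromosome(threshold = thr)
    r <- simulate_cell(ch, fixed, stim, n_trials = 1, noise_sd = 0,
                       input_gain = 40, seed = 1)
    length(r$trials[[1]]$spike_times_ms)
  })
  expect_gt(counts[1], 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("simulate_cell returns reproducible rasters with equal-duration trials", {
  stim <- make_bar_stimulus(24, 32, 250, 90, 1, 60, 1)
  ch <- chromosome()
  r1 <- simulate_cell(ch, stage1_params(), stim, n_trials = 4, noise_sd = 30,
                      input_gain = 40, seed = 3)
  r2 <- simulate_cell(ch, stage1_params(), stim, n_trials = 4, noise_sd = 30,
                      input_gain = 40, seed = 3)
  expect_length(r1$trials, 4)
  expect_identical(r1, r2)
  durs <- vapply(r1$trials, function(t) t$duration_ms, numeric(1))
  expect_true(all(durs == durs[1]))

  r0 <- simulate_cell(ch, stage1_params(), stim, n_trials = 3, noise_sd = 0,
                      input_gain = 40, seed = 3)
  expect_identical(r0$trials[[1]], r0$trials[[2]])
  expect_identical(r0$trials[[2]], r0$trials[[3]])
})

test_that("random_chromosome respects the gene table and clipping projects", {
  b <- chromosome_bounds()
  set.seed(9)
  for (i in 1:1000) {
    g <- retinatune:::chromosome_to_genes(random_chromosome())
    expect_true(all(g >= b$lower & g <= b$upper))
  }
  expect_equal(clip_chromosome(list(K = 20, leakage = 12, threshold = 250,
                                    persistence_time = 5,
                                    refractory_period = 3, fmf = 0.3))$K, 13)
  expect_equal(clip_chromosome(list(K = 9, leakage = 12, threshold = 250,
                                    persistence_time = 5,
                                    refractory_period = 3, fmf = 0.1))$fmf,
               0.25)
})
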