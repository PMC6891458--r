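test_that("dominance and nondominated sorting have their defining properties", {
  expect_true(dominates(c(1, 1, 1, 1), c(2, 2, 2, 2)))
  expect_false(dominates(c(1, 1), c(1, 1)))
  expect_false(dominates(c(1, 3, 1, 1), c(2, 2, 2, 2)))
  expect_false(dominates(c(2, 2, 2, 2), c(1, 3, 1, 1)))

  nd <- matrix(c(0, 2, 1, 1, 2, 0), ncol = 2, byrow = TRUE)
  expect_length(fast_nondominated_sort(nd), 1L)

  chain <- matrix(c(1, 1, 2, 2, 3, 3), ncol = 2, byrow = TRUE)
  expect_equal(fast_nondominated_sort(chain), list(1L, 2L, 3L))
})

test_that("sorting and crowding agree with brute-force oracles on random inputs", {
  set.seed(100)
  for (case in 1:100) {
    n <- sample(4:60, 1)
    obj <- matrix(runif(n * 4), ncol = 4)
    fronts <- fast_nondominated_sort(obj)
    oracle <- brute_force_fronts(obj)
    expect_equal(lapply(fronts, sort), lapply(oracle, sort))
    f1 <- obj[fronts[[1]], , drop = FALSE]
    expect_equal(crowding_distance(f1), brute_force_crowding(f1))
  }
})

test_that("crowding distance hand case and boundary conventions", {
  two <- matrix(c(0, 1, 1, 0), ncol = 2, byrow = TRUE)
  expect_equal(crowding_distance(two), c(Inf, Inf))
  three <- matrix(c(0, 2, 1, 1, 2, 0), ncol = 2, byrow = TRUE)
  d <- crowding_distance(three)
  expect_equal(d[2], 2)
  expect_equal(d[c(1, 3)], c(Inf, Inf))
  perm <- c(3, 1, 2)
  expect_equal(crowding_distance(three[perm, ]), d[perm])
})

test_that("variation operators respect bounds and SBX is mean-preserving", {
  set.seed(7)
  b <- chromosome_bounds()
  p1 <- retinatune:::chromosome_to_genes(random_chromosome())
  p2 <- retinatune:::chromosome_to_genes(random_chromosome())

  ch <- sbx_crossover(p1, p2, prob = 0)
  expect_equal(ch[[1]], retinatune:::clip_genes(p1))
  expect_equal(ch[[2]], retinatune:::clip_genes(p2))
  expect_equal(polynomial_mutation(p1, prob = 0), retinatune:::clip_genes(p1))

  # bounds over many children, and mean preservation on the real genes for
  # parents comfortably inside the box
  pa <- c(8, 12, 245, 5, 5, 0.32)
  pb <- c(6, 13, 255, 4, 6, 0.34)
  kid_sum <- numeric(6)
  in_bounds <- TRUE
  for (i in 1:5000) {
    kids <- sbx_crossover(pa, pb, prob = 1)
    k1 <- polynomial_mutation(kids[[1]], 0.05)
    k2 <- polynomial_mutation(kids[[2]], 0.05)
    in_bounds <- in_bounds && all(k1 >= b$lower & k1 <= b$upper) &&
      all(k2 >= b$lower & k2 <= b$upper)
    kid_sum <- kid_sum + kids[[1]] + kids[[2]]
  }
  expect_true(in_bounds)
  kid_mean <- kid_sum / 10000
  real <- !b$integer
  bias <- abs(kid_mean - (pa + pb) / 2)[real] / (b$upper - b$lower)[real]
  expect_true(all(bias < 0.01))
})

# deterministic 2-gene stub problem: minimise (x^2, (x-2)^2) where x is a
# rescaling of the leakage gene to [0, 4]; true Pareto set is x in [0, 2]
stub_evaluator <- function(genes) {
  x <- (genes[2] - 10) / 5 * 4
  c(x^2, (x - 2)^2, 0, 0)
}

test_that("nsga2_generation preserves size and elitism, and solves the stub", {
  set.seed(21)
  cfg <- algo_config(population_size = 20, generations = 20)
  res <- run_algorithm("nsga2", stub_evaluator, cfg, seed = 2)
  expect_equal(nrow(res$snapshots[[5]]$genes), 20)

  # elitism: generation g+1 front not dominated wholesale by generation g
  f_prev <- res$snapshots[[10]]$front_obj
  f_next <- res$snapshots[[11]]$front_obj
  wholesale <- all(apply(f_next, 1, function(u)
    any(apply(f_prev, 1, function(v) dominates(v, u)))))
  expect_false(wholesale)

  # front coverage of the true Pareto set x in [0, 2]
  xs <- sort((res$front_genes[, 2] - 10) / 5 * 4)
  expect_lt(xs[1], 0.15)
  expect_gt(xs[length(xs)], 1.85)
  expect_lt(max(diff(c(0, xs, 2))), 0.3)
})

test_that("spea2 keeps a fixed, mutually nondominated archive with F < 1", {
  set.seed(3)
  cfg <- algo_config(population_size = 12, generations = 8, archive_size = 8)
  res <- run_algorithm("spea2", stub_evaluator, cfg, seed = 4)
  for (g in 3:9) {
    arch <- res$snapshots[[g]]$archive_obj
    expect_equal(nrow(arch), 8)
  }

  # strength fitness: nondominated members have R = 0 hence F < 1
  obj <- matrix(runif(80), ncol = 4)
  fit <- retinatune:::spea2_fitness(obj, k = 4)
  nd <- retinatune:::nondominated_idx(obj)
  expect_true(all(fit[nd] < 1))
  expect_true(all(fit[setdiff(1:20, nd)] >= 1))

  # archive mutual nondominance when candidates fit
  cfg2 <- algo_config(population_size = 12, generations = 5, archive_size = 40)
  res2 <- run_algorithm("spea2", stub_evaluator, cfg2, seed = 5)
  arch <- res2$snapshots[[6]]$archive_obj
  nd2 <- retinatune:::nondominated_idx(arch)
  # all nondominated members present imply padding only with dominated ones;
  # the nondominated subset itself must be mutually nondominated
  expect_equal(sort(retinatune:::nondominated_idx(arch[nd2, , drop = FALSE])),
               seq_along(nd2))
})

test_that("nsga3 reference points form the Das-Dennis lattice", {
  rp <- nsga3_reference_points(4, 6)
  expect_equal(nrow(rp), choose(9, 3))   # 84
  expect_true(all(abs(rowSums(rp) - 1) < 1e-12))
  expect_equal(nsga3_reference_points(2, 1),
               matrix(c(0, 1, 1, 0), ncol = 2, byrow = TRUE),
               ignore_attr = TRUE)
  res <- run_algorithm("nsga3", stub_evaluator,
                       algo_config(population_size = 12, generations = 10,
                                   nsga3_divisions = 6), seed = 3)
  expect_equal(nrow(res$snapshots[[11]]$genes), 12)
})

test_that("mopso uses the constriction factor and keeps a clean archive", {
  expect_equal(constriction_factor(2.05, 2.05), 0.72984, tolerance = 1e-5)
  expect_error(constriction_factor(1, 1), "> 4")

  cfg <- algo_config(population_size = 10, generations = 10)
  res <- run_algorithm("mopso", stub_evaluator, cfg, seed = 6)
  b <- chromosome_bounds()
  for (g in c(1, 5, 11)) {
    snap <- res$snapshots[[g]]
    arch <- snap$archive_obj
    expect_equal(sort(retinatune:::nondominated_idx(arch)), seq_len(nrow(arch)))
    expect_true(all(t(snap$genes) >= b$lower & t(snap$genes) <= b$upper))
  }
})

test_that("de generation follows DE/rand/1/bin contracts", {
  set.seed(11)
  genes <- t(replicate(8, retinatune:::chromosome_to_genes(random_chromosome())))
  obj <- t(apply(genes, 1, stub_evaluator))
  pop <- list(genes = genes, obj = obj)

  cfg <- algo_config(population_size = 8, F = 0, CR = 1)
  out <- de_generation(pop, stub_evaluator, cfg)
  expect_equal(nrow(out$genes), 8)
  # with F=0, CR=1 every trial is a copy of an existing member
  for (i in seq_len(8)) {
    match_any <- any(apply(genes, 1, function(g) all(abs(g - out$genes[i, ]) < 1e-12)))
    expect_true(match_any)
  }

  # binomial crossover with CR=0 inherits exactly one mutant gene
  target <- c(5, 11, 230, 4, 2, 0.28)
  mutant <- c(9, 14, 270, 6, 8, 0.38)
  for (i in 1:50) {
    tr <- retinatune:::de_trial(target, mutant, CR = 0)
    expect_equal(sum(tr != target), 1L)
  }
  expect_error(de_generation(list(genes = genes[1:3, ], obj = obj[1:3, ]),
                             stub_evaluator, cfg), "at least 4")
})

test_that("run_algorithm is reproducible with the contracted snapshot count", {
  cfg <- algo_config(population_size = 8, generations = 6)
  for (alg in c("nsga2", "spea2", "nsga3", "mopso", "de")) {
    r1 <- run_algorithm(alg, stub_evaluator, cfg, seed = 9)
    r2 <- run_algorithm(alg, stub_evaluator, cfg, seed = 9)
    expect_identical(r1, r2)
    expect_length(r1$snapshots, 7L)
    # final front mutually nondominated
    fo <- r1$front_obj
    expect_equal(sort(retinatune:::nondominated_idx(fo)), seq_len(nrow(fo)))
  }
  expect_error(run_algorithm("annealing", stub_evaluator, cfg, 1), "arg")

  # archive-based algorithms only accumulate: final HV >= initial HV
  ref <- c(20, 20, 1, 1)
  for (alg in c("spea2", "mopso")) {
    r <- run_algorithm(alg, stub_evaluator, cfg, seed = 10)
    traj <- hv_trajectory(r, ref)
    expect_gte(traj[length(traj)], traj[1])
  }
})

test_that("all algorithms keep every evaluated chromosome within bounds", {
  b <- chromosome_bounds()
  seen_bad <- FALSE
  checking_eval <- function(genes) {
    if (any(genes < b$lower - 1e-9) || any(genes > b$upper + 1e-9))
      seen_bad <<- TRUE
    stub_evaluator(genes)
  }
  cfg <- algo_config(population_size = 8, generations = 5)
  for (alg in c("nsga2", "spea2", "nsga3", "mopso", "de")) {
    run_algorithm(alg, checking_eval, cfg, seed = 12)
  }
  expect_false(seen_bad)
})
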