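#' Optimiser configuration
#'
#' Shared settings for the five population-based metaheuristics. Defaults
#' follow the published tuning protocol: population 40, 100 generations,
#' crossover probability 0.40, mutation probability 0.05, PSO acceleration
#' coefficients phi1 = phi2 = 2.05 (the canonical constriction setting), DE
#' scale factor F = 1, and archive size equal to the population size.
#'
#' @param population_size at least 4.
#' @param generations generation count.
#' @param crossover_prob,mutation_prob variation probabilities in `[0, 1]`.
#' @param eta_crossover,eta_mutation SBX / polynomial-mutation distribution
#'   indices.
#' @param phi1,phi2 PSO acceleration coefficients.
#' @param F,CR DE scale factor and crossover rate.
#' @param archive_size external archive capacity (SPEA2, MOPSO).
#' @param nsga3_divisions Das-Dennis simplex divisions per objective.
#' @return a list of class `algo_config`.
#' @export
algo_config <- function(population_size = 40, generations = 100,
                        crossover_prob = 0.40, mutation_prob = 0.05,
                        eta_crossover = 15, eta_mutation = 20,
                        phi1 = 2.05, phi2 = 2.05, F = 1, CR = 0.9,
                        archive_size = population_size,
                        nsga3_divisions = 6) {
  if (population_size < 4) stop("population_size must be >= 4", call. = FALSE)
  if (archive_size < 1) stop("archive_size must be >= 1", call. = FALSE)
  for (p in c(crossover_prob, mutation_prob))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 eta_crossover = eta_crossover, eta_mutation = eta_mutation,
                 phi1 = phi1, phi2 = phi2, F = F, CR = CR,
                 archive_size = as.integer(archive_size),
                 nsga3_divisions = as.integer(nsga3_divisions)),
            class = "algo_config")
}

#' Pareto dominance (minimisation)
#'
#' @param u,v objective vectors of equal length.
#' @return TRUE iff `u` is no worse in every component and strictly better in
#'   at least one.
#' @export
dominates <- function(u, v) {
  all(u <= v) && any(u < v)
}

#' Fast nondominated sorting
#'
#' Partitions a population into Pareto fronts: front 1 holds the
#' nondominated members, front 2 those nondominated once front 1 is removed,
#' and so on.
#'
#' @param obj numeric matrix, one row per individual, one column per
#'   objective (minimised).
#' @return list of integer vectors of row indices, in front order.
#' @export
fast_nondominated_sort <- function(obj) {
  if (anyNA(obj)) stop("all objectives must be set before sorting", call. = FALSE)
  n <- nrow(obj)
  if (n == 0L) return(list())
  dom_count <- integer(n)
  dominated_by <- vector("list", n)
  for (i in seq_len(n)) {
    ui <- obj[i, ]
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(ui, obj[j, ])) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (dominates(obj[j, ], ui)) {
        dom_count[i] <- dom_count[i] + 1L
      }
    }
  }
  fronts <- list()
  current <- which(dom_count == 0L)
  while (length(current)) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated_by[[i]]) {
        dom_count[j] <- dom_count[j] - 1L
        if (dom_count[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- sort(nxt)
  }
  fronts
}

# Row indices of the nondominated members of `obj`.
nondominated_idx <- function(obj) {
  if (nrow(obj) == 0L) return(integer(0))
  fast_nondominated_sort(obj)[[1]]
}

#' Crowding distance of a front
#'
#' Per objective, front members are sorted, boundary members receive
#' infinity, and interior members accumulate the normalised gap between
#' their neighbours.
#'
#' @param obj objective matrix of one front (rows = members).
#' @return numeric distances, one per row.
#' @export
crowding_distance <- function(obj) {
  n <- nrow(obj)
  if (n == 0L) return(numeric(0))
  d <- numeric(n)
  for (m in seq_len(ncol(obj))) {
    o <- order(obj[, m])
    rng <- obj[o[n], m] - obj[o[1], m]
    d[o[1]] <- Inf
    d[o[n]] <- Inf
    if (n > 2L && rng > 0) {
      for (i in 2:(n - 1L)) {
        d[o[i]] <- d[o[i]] + (obj[o[i + 1L], m] - obj[o[i - 1L], m]) / rng
      }
    }
  }
  d
}

# (rank, crowding) keys for a whole population; smaller rank better, larger
# crowding better.
rank_and_crowding <- function(obj) {
  fronts <- fast_nondominated_sort(obj)
  rank <- integer(nrow(obj))
  crowd <- numeric(nrow(obj))
  for (fi in seq_along(fronts)) {
    idx <- fronts[[fi]]
    rank[idx] <- fi
    crowd[idx] <- crowding_distance(obj[idx, , drop = FALSE])
  }
  list(rank = rank, crowd = crowd, fronts = fronts)
}

# Truncate indices 1..nrow(obj) to n by (front rank, crowding distance).
truncate_by_rank_crowding <- function(obj, n) {
  rc <- rank_and_crowding(obj)
  ord <- order(rc$rank, -rc$crowd)
  sort(ord[seq_len(n)])
}

# ---- variation operators ---------------------------------------------------

#' Simulated binary crossover and polynomial mutation
#'
#' Standard real-coded variation over the chromosome's bounded genes.
#' `sbx_crossover` applies SBX gene-wise with the given pair probability;
#' `polynomial_mutation` perturbs each gene with the given per-gene
#' probability. Integer genes are rounded then clipped, so children always
#' satisfy the gene bounds.
#'
#' @param p1,p2 gene vectors (length 6).
#' @param c gene vector to mutate.
#' @param prob pair probability (crossover) / per-gene probability (mutation).
#' @param eta distribution index.
#' @return `sbx_crossover`: list of two children; `polynomial_mutation`: one
#'   gene vector.
#' @export
sbx_crossover <- function(p1, p2, prob = 0.4, eta = 15) {
  b <- chromosome_bounds()
  c1 <- p1; c2 <- p2
  if (runif(1) < prob) {
    for (g in seq_along(p1)) {
      if (runif(1) > 0.5 || abs(p1[g] - p2[g]) < 1e-14) next
      u <- runif(1)
      beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1)) else
        (1 / (2 * (1 - u)))^(1 / (eta + 1))
      c1[g] <- 0.5 * ((1 + beta) * p1[g] + (1 - beta) * p2[g])
      c2[g] <- 0.5 * ((1 - beta) * p1[g] + (1 + beta) * p2[g])
    }
  }
  list(clip_genes(c1), clip_genes(c2))
}

#' @rdname sbx_crossover
#' @export
polynomial_mutation <- function(c, prob = 0.05, eta = 20) {
  b <- chromosome_bounds()
  for (g in seq_along(c)) {
    if (runif(1) >= prob) next
    lo <- b$lower[g]; hi <- b$upper[g]
    u <- runif(1)
    delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1 else
      1 - (2 * (1 - u))^(1 / (eta + 1))
    c[g] <- c[g] + delta * (hi - lo)
  }
  clip_genes(c)
}

# Binary tournament by (rank asc, crowding desc); returns an index.
tournament_rc <- function(rank, crowd) {
  n <- length(rank)
  a <- sample.int(n, 1L); bb <- sample.int(n, 1L)
  if (rank[a] < rank[bb]) return(a)
  if (rank[bb] < rank[a]) return(bb)
  if (crowd[a] > crowd[bb]) a else bb
}

make_offspring_rc <- function(genes, rank, crowd, cfg) {
  n <- nrow(genes)
  off <- matrix(0, n, ncol(genes))
  i <- 1L
  while (i <= n) {
    pa <- genes[tournament_rc(rank, crowd), ]
    pb <- genes[tournament_rc(rank, crowd), ]
    ch <- sbx_crossover(pa, pb, cfg$crossover_prob, cfg$eta_crossover)
    off[i, ] <- polynomial_mutation(ch[[1]], cfg$mutation_prob, cfg$eta_mutation)
    if (i + 1L <= n)
      off[i + 1L, ] <- polynomial_mutation(ch[[2]], cfg$mutation_prob,
                                           cfg$eta_mutation)
    i <- i + 2L
  }
  off
}

evaluate_genes <- function(genes, evaluator) {
  t(apply(genes, 1L, evaluator))
}

# ---- NSGA-II ---------------------------------------------------------------

#' One NSGA-II generation
#'
#' Binary-tournament mating on (front rank, crowding distance), SBX +
#' polynomial mutation, evaluation of the offspring, and truncation of the
#' combined parent + offspring set back to the population size by rank then
#' crowding (the usual elitist "delete the worst 50%" step).
#'
#' @param pop list with `genes` (n x 6) and `obj` (n x 4) matrices.
#' @param evaluator function mapping a gene vector to a 4-objective vector.
#' @param cfg an [algo_config()].
#' @return updated `pop` list.
#' @export
nsga2_generation <- function(pop, evaluator, cfg) {
  rc <- rank_and_crowding(pop$obj)
  off <- make_offspring_rc(pop$genes, rc$rank, rc$crowd, cfg)
  off_obj <- evaluate_genes(off, evaluator)
  genes <- rbind(pop$genes, off)
  obj <- rbind(pop$obj, off_obj)
  keep <- truncate_by_rank_crowding(obj, cfg$population_size)
  list(genes = genes[keep, , drop = FALSE], obj = obj[keep, , drop = FALSE])
}

# ---- SPEA2 -----------------------------------------------------------------

spea2_fitness <- function(obj, k) {
  n <- nrow(obj)
  S <- integer(n)
  dom <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && dominates(obj[i, ], obj[j, ])) dom[i, j] <- TRUE
    }
  }
  S <- rowSums(dom)
  R <- vapply(seq_len(n), function(i) sum(S[dom[, i]]), numeric(1))
  dist <- as.matrix(stats::dist(obj))
  D <- vapply(seq_len(n), function(i) {
    dk <- sort(dist[i, -i])[min(k, n - 1L)]
    1 / (dk + 2)
  }, numeric(1))
  R + D
}

# Iterative nearest-neighbour archive truncation; objective-wise extremes
# (the minimum per objective) are protected.
spea2_truncate <- function(obj, target) {
  keep <- seq_len(nrow(obj))
  while (length(keep) > target) {
    o <- obj[keep, , drop = FALSE]
    protected <- unique(vapply(seq_len(ncol(o)), function(m) which.min(o[, m]),
                               integer(1)))
    dist <- as.matrix(stats::dist(o))
    diag(dist) <- Inf
    cand <- setdiff(seq_along(keep), protected)
    if (!length(cand)) cand <- seq_along(keep)
    # remove the member with lexicographically smallest sorted distance vector
    best <- cand[1]
    best_key <- sort(dist[best, ])
    for (i in cand[-1]) {
      ki <- sort(dist[i, ])
      cmp <- ki - best_key
      nz <- which(abs(cmp) > 1e-15)
      if (length(nz) && cmp[nz[1]] < 0) {
        best <- i; best_key <- ki
      }
    }
    keep <- keep[-best]
  }
  keep
}

#' One SPEA2 generation
#'
#' Strength/raw-fitness assignment with k-nearest-neighbour density over the
#' union of population and archive, archive update to a fixed capacity
#' (nondominated members, truncated by iterative nearest-neighbour removal
#' that retains boundary points, or padded with the best dominated members),
#' and mating restricted to the archive.
#'
#' @param pop,archive lists with `genes`/`obj` matrices (archive may be empty).
#' @inheritParams nsga2_generation
#' @return list with updated `pop` and `archive`.
#' @export
spea2_generation <- function(pop, archive, evaluator, cfg) {
  genes <- rbind(pop$genes, archive$genes)
  obj <- rbind(pop$obj, archive$obj)
  k <- max(1L, round(sqrt(cfg$population_size + cfg$archive_size)))
  fit <- spea2_fitness(obj, k)
  nd <- which(fit < 1)
  if (length(nd) > cfg$archive_size) {
    keep <- nd[spea2_truncate(obj[nd, , drop = FALSE], cfg$archive_size)]
  } else if (length(nd) < cfg$archive_size) {
    dom <- setdiff(seq_len(nrow(obj)), nd)
    pad <- dom[order(fit[dom])][seq_len(min(length(dom),
                                            cfg$archive_size - length(nd)))]
    keep <- c(nd, pad)
  } else keep <- nd
  arch <- list(genes = genes[keep, , drop = FALSE],
               obj = obj[keep, , drop = FALSE])
  afit <- fit[keep]
  n <- cfg$population_size
  na <- length(keep)
  off <- matrix(0, n, ncol(genes))
  i <- 1L
  tour <- function() {
    a <- sample.int(na, 1L); bb <- sample.int(na, 1L)
    if (afit[a] <= afit[bb]) a else bb
  }
  while (i <= n) {
    pa <- arch$genes[tour(), ]
    pb <- arch$genes[tour(), ]
    ch <- sbx_crossover(pa, pb, cfg$crossover_prob, cfg$eta_crossover)
    off[i, ] <- polynomial_mutation(ch[[1]], cfg$mutation_prob, cfg$eta_mutation)
    if (i + 1L <= n)
      off[i + 1L, ] <- polynomial_mutation(ch[[2]], cfg$mutation_prob,
                                           cfg$eta_mutation)
    i <- i + 2L
  }
  list(pop = list(genes = off, obj = evaluate_genes(off, evaluator)),
       archive = arch)
}

# ---- NSGA-III --------------------------------------------------------------

#' Das-Dennis structured reference points
#'
#' All points on the unit simplex whose coordinates are multiples of `1/p`;
#' there are `choose(M + p - 1, p)` of them.
#'
#' @param M number of objectives.
#' @param p number of divisions per objective.
#' @return matrix with `M` columns, rows summing to 1.
#' @export
nsga3_reference_points <- function(M, p) {
  if (p < 1) stop("p must be >= 1", call. = FALSE)
  rec <- function(left, dims) {
    if (dims == 1L) return(matrix(left, ncol = 1))
    out <- NULL
    for (i in 0:left) {
      sub <- rec(left - i, dims - 1L)
      out <- rbind(out, cbind(i, sub))
    }
    out
  }
  rec(p, M) / p
}

# Perpendicular distance from normalised point z to the line through origin
# and reference direction w.
perp_distance <- function(z, w) {
  nw <- sqrt(sum(w^2))
  proj <- sum(z * w) / nw
  sqrt(max(0, sum(z^2) - proj^2))
}

#' One NSGA-III generation
#'
#' Offspring by tournament on front rank, then environmental selection by
#' nondominated sorting and reference-point niching: objectives are
#' normalised by the ideal point and the observed per-objective spread,
#' members are associated with the nearest reference line, and the last
#' front is admitted by repeatedly filling the least-occupied niche (ties
#' broken randomly under the run's RNG stream).
#'
#' @inheritParams nsga2_generation
#' @param ref_points matrix from [nsga3_reference_points()].
#' @export
nsga3_generation <- function(pop, evaluator, cfg, ref_points) {
  rc <- rank_and_crowding(pop$obj)
  off <- make_offspring_rc(pop$genes, rc$rank, rc$crowd, cfg)
  off_obj <- evaluate_genes(off, evaluator)
  genes <- rbind(pop$genes, off)
  obj <- rbind(pop$obj, off_obj)
  n <- cfg$population_size
  fronts <- fast_nondominated_sort(obj)
  chosen <- integer(0)
  fi <- 1L
  while (length(chosen) + length(fronts[[fi]]) <= n) {
    chosen <- c(chosen, fronts[[fi]])
    fi <- fi + 1L
    if (fi > length(fronts)) break
  }
  if (length(chosen) < n && fi <= length(fronts)) {
    last <- fronts[[fi]]
    pool <- c(chosen, last)
    ideal <- apply(obj[pool, , drop = FALSE], 2, min)
    span <- apply(obj[pool, , drop = FALSE], 2, max) - ideal
    span[span <= 0] <- 1
    normed <- sweep(sweep(obj[pool, , drop = FALSE], 2, ideal), 2, span, "/")
    assoc <- integer(length(pool))
    pdist <- numeric(length(pool))
    for (i in seq_along(pool)) {
      ds <- apply(ref_points, 1, function(w) perp_distance(normed[i, ], w))
      assoc[i] <- which.min(ds)
      pdist[i] <- min(ds)
    }
    names(assoc) <- names(pdist) <- NULL
    in_chosen <- seq_along(chosen)
    niche_count <- tabulate(assoc[in_chosen], nbins = nrow(ref_points))
    remaining <- setdiff(seq_along(pool), in_chosen)
    while (length(chosen) < n) {
      active <- unique(assoc[remaining])
      jmin <- active[niche_count[active] == min(niche_count[active])]
      j <- if (length(jmin) > 1L) jmin[sample.int(length(jmin), 1L)] else jmin
      members <- remaining[assoc[remaining] == j]
      pick <- if (niche_count[j] == 0L) {
        members[which.min(pdist[members])]
      } else {
        members[sample.int(length(members), 1L)]
      }
      chosen <- c(chosen, pool[pick])
      niche_count[j] <- niche_count[j] + 1L
      remaining <- setdiff(remaining, pick)
    }
  }
  chosen <- sort(chosen)
  list(genes = genes[chosen, , drop = FALSE], obj = obj[chosen, , drop = FALSE])
}

# ---- MOPSO -----------------------------------------------------------------

#' Clerc-Kennedy constriction coefficient
#'
#' `chi = 2 / |2 - phi - sqrt(phi^2 - 4 phi)|` with `phi = phi1 + phi2`;
#' for the canonical `phi1 = phi2 = 2.05` this is about 0.72984.
#'
#' @param phi1,phi2 acceleration coefficients with `phi1 + phi2 > 4`.
#' @return the constriction factor.
#' @export
constriction_factor <- function(phi1 = 2.05, phi2 = 2.05) {
  phi <- phi1 + phi2
  if (phi <= 4) stop("constriction requires phi1 + phi2 > 4", call. = FALSE)
  2 / abs(2 - phi - sqrt(phi^2 - 4 * phi))
}

# Update the external archive with candidate rows; capacity enforced by
# crowding-distance truncation.
archive_update <- function(archive, genes, obj, capacity) {
  g <- rbind(archive$genes, genes)
  o <- rbind(archive$obj, obj)
  # drop exact duplicates so the archive cannot silt up with clones
  dup <- duplicated(cbind(g, o))
  g <- g[!dup, , drop = FALSE]; o <- o[!dup, , drop = FALSE]
  nd <- nondominated_idx(o)
  g <- g[nd, , drop = FALSE]; o <- o[nd, , drop = FALSE]
  if (nrow(o) > capacity) {
    cd <- crowding_distance(o)
    keep <- order(cd, decreasing = TRUE)[seq_len(capacity)]
    g <- g[keep, , drop = FALSE]; o <- o[keep, , drop = FALSE]
  }
  list(genes = g, obj = o)
}

#' One MOPSO generation
#'
#' Constriction-factor velocity update towards each particle's personal best
#' and a leader drawn from the external archive by crowding-biased binary
#' tournament; positions are clipped to the gene bounds (velocity zeroed on
#' the clipped genes); personal bests are replaced on dominance and kept or
#' swapped by a fair coin on mutual nondominance; the archive accumulates
#' the nondominated visited solutions under crowding-distance truncation.
#'
#' @param swarm list with `genes`, `obj`, `vel`, `pbest_genes`, `pbest_obj`.
#' @param archive list with `genes`/`obj`.
#' @inheritParams nsga2_generation
#' @export
mopso_generation <- function(swarm, archive, evaluator, cfg) {
  n <- nrow(swarm$genes)
  chi <- constriction_factor(cfg$phi1, cfg$phi2)
  b <- chromosome_bounds()
  na <- nrow(archive$obj)
  acd <- if (na > 0) crowding_distance(archive$obj) else numeric(0)
  pick_leader <- function() {
    if (na == 1L) return(1L)
    a <- sample.int(na, 1L); bb <- sample.int(na, 1L)
    if (acd[a] >= acd[bb]) a else bb
  }
  for (i in seq_len(n)) {
    leader <- archive$genes[pick_leader(), ]
    r1 <- runif(ncol(swarm$genes)); r2 <- runif(ncol(swarm$genes))
    v <- chi * (swarm$vel[i, ] +
                  cfg$phi1 * r1 * (swarm$pbest_genes[i, ] - swarm$genes[i, ]) +
                  cfg$phi2 * r2 * (leader - swarm$genes[i, ]))
    x <- swarm$genes[i, ] + v
    clipped <- x < b$lower | x > b$upper
    v[clipped] <- 0
    x <- clip_genes(x)
    swarm$vel[i, ] <- v
    swarm$genes[i, ] <- x
  }
  swarm$obj <- evaluate_genes(swarm$genes, evaluator)
  for (i in seq_len(n)) {
    if (dominates(swarm$obj[i, ], swarm$pbest_obj[i, ])) {
      swarm$pbest_genes[i, ] <- swarm$genes[i, ]
      swarm$pbest_obj[i, ] <- swarm$obj[i, ]
    } else if (!dominates(swarm$pbest_obj[i, ], swarm$obj[i, ])) {
      if (runif(1) < 0.5) {
        swarm$pbest_genes[i, ] <- swarm$genes[i, ]
        swarm$pbest_obj[i, ] <- swarm$obj[i, ]
      }
    }
  }
  archive <- archive_update(archive, swarm$genes, swarm$obj, cfg$archive_size)
  list(swarm = swarm, archive = archive)
}

# ---- DE --------------------------------------------------------------------

# Binomial crossover of target and mutant: each gene comes from the mutant
# with probability CR, and one randomly chosen gene is always the mutant's.
de_trial <- function(target, mutant, CR) {
  jrand <- sample.int(length(target), 1L)
  cross <- runif(length(target)) < CR
  cross[jrand] <- TRUE
  clip_genes(ifelse(cross, mutant, target))
}

#' One DE/rand/1/bin generation
#'
#' For each target, a mutant `x_r1 + F (x_r2 - x_r3)` over three distinct
#' other members, binomial crossover with rate `CR` and one guaranteed
#' mutant gene, bound clipping, and the three-way replacement rule: a trial
#' that dominates its target replaces it; one dominated by its target is
#' discarded; mutually nondominated trials are appended and the pool is
#' truncated back to the population size by nondominated rank and crowding.
#'
#' @inheritParams nsga2_generation
#' @export
de_generation <- function(pop, evaluator, cfg) {
  n <- nrow(pop$genes)
  if (n < 4L) stop("DE requires a population of at least 4", call. = FALSE)
  genes <- pop$genes; obj <- pop$obj
  extra_g <- NULL; extra_o <- NULL
  for (i in seq_len(n)) {
    r <- sample(setdiff(seq_len(n), i), 3L)
    mutant <- pop$genes[r[1], ] + cfg$F * (pop$genes[r[2], ] - pop$genes[r[3], ])
    trial <- de_trial(pop$genes[i, ], mutant, cfg$CR)
    tobj <- evaluator(trial)
    if (dominates(tobj, pop$obj[i, ])) {
      genes[i, ] <- trial; obj[i, ] <- tobj
    } else if (dominates(pop$obj[i, ], tobj)) {
      # discarded
    } else {
      extra_g <- rbind(extra_g, trial); extra_o <- rbind(extra_o, tobj)
    }
  }
  if (!is.null(extra_g)) {
    genes <- rbind(genes, extra_g); obj <- rbind(obj, extra_o)
    keep <- truncate_by_rank_crowding(obj, n)
    genes <- genes[keep, , drop = FALSE]; obj <- obj[keep, , drop = FALSE]
  }
  list(genes = genes, obj = obj)
}

# ---- driver ----------------------------------------------------------------

#' Run one metaheuristic
#'
#' Seeds the RNG, initialises the population uniformly within the gene
#' bounds, iterates the requested algorithm for `cfg$generations`
#' generations, records a snapshot after initialisation and after every
#' generation, and extracts the final nondominated front (from the archive
#' union for archive-based algorithms). Deterministic given `(name, cfg,
#' seed)` and a deterministic evaluator.
#'
#' @param name one of `"nsga2"`, `"spea2"`, `"nsga3"`, `"mopso"`, `"de"`.
#' @param evaluator function: gene vector -> numeric objective vector.
#' @param cfg an [algo_config()].
#' @param seed integer seed.
#' @return object of class `opt_result`: list with `algorithm`, `seed`,
#'   `config`, `n_eval`, `snapshots` (length generations + 1, each holding
#'   `genes`, `obj` and the generation's nondominated `front_genes` /
#'   `front_obj`), and the final `front_genes` / `front_obj`.
#' @export
run_algorithm <- function(name, evaluator, cfg, seed = 1L) {
  name <- match.arg(name, c("nsga2", "spea2", "nsga3", "mopso", "de"))
  n_eval <- 0L
  ev <- function(g) {
    n_eval <<- n_eval + 1L
    v <- evaluator(g)
    if (any(!is.finite(v))) stop("evaluator returned non-finite objectives",
                                 call. = FALSE)
    v
  }
  with_seed(seed, {
    n <- cfg$population_size
    genes <- t(vapply(seq_len(n),
                      function(i) chromosome_to_genes(random_chromosome()),
                      numeric(6)))
    obj <- evaluate_genes(genes, ev)
    pop <- list(genes = genes, obj = obj)
    archive <- list(genes = genes[0, , drop = FALSE],
                    obj = obj[0, , drop = FALSE])
    swarm <- NULL
    ref_points <- NULL
    if (name == "mopso") {
      swarm <- list(genes = genes, obj = obj,
                    vel = matrix(0, n, ncol(genes)),
                    pbest_genes = genes, pbest_obj = obj)
      archive <- archive_update(archive, genes, obj, cfg$archive_size)
    } else if (name == "spea2") {
      upd <- spea2_seed_archive(pop, cfg)
      archive <- upd
    } else if (name == "nsga3") {
      ref_points <- nsga3_reference_points(ncol(obj), cfg$nsga3_divisions)
    }
    snapshot <- function(pop, archive) {
      g <- rbind(pop$genes, archive$genes)
      o <- rbind(pop$obj, archive$obj)
      nd <- nondominated_idx(o)
      list(genes = pop$genes, obj = pop$obj,
           archive_genes = archive$genes, archive_obj = archive$obj,
           front_genes = g[nd, , drop = FALSE],
           front_obj = o[nd, , drop = FALSE])
    }
    snaps <- vector("list", cfg$generations + 1L)
    snaps[[1L]] <- if (name == "mopso") snapshot(swarm, archive) else
      snapshot(pop, archive)
    for (g in seq_len(cfg$generations)) {
      if (name == "nsga2") {
        pop <- nsga2_generation(pop, ev, cfg)
      } else if (name == "spea2") {
        upd <- spea2_generation(pop, archive, ev, cfg)
        pop <- upd$pop; archive <- upd$archive
      } else if (name == "nsga3") {
        pop <- nsga3_generation(pop, ev, cfg, ref_points)
      } else if (name == "mopso") {
        upd <- mopso_generation(swarm, archive, ev, cfg)
        swarm <- upd$swarm; archive <- upd$archive
      } else {
        pop <- de_generation(pop, ev, cfg)
      }
      snaps[[g + 1L]] <- if (name == "mopso") snapshot(swarm, archive) else
        snapshot(pop, archive)
    }
    fin <- snaps[[cfg$generations + 1L]]
    structure(list(algorithm = name, seed = as.integer(seed), config = cfg,
                   n_eval = n_eval, snapshots = snaps,
                   front_genes = fin$front_genes, front_obj = fin$front_obj),
              class = "opt_result")
  })
}

# Initial SPEA2 archive: nondominated members of the seed population,
# truncated/padded to capacity.
spea2_seed_archive <- function(pop, cfg) {
  k <- max(1L, round(sqrt(cfg$population_size + cfg$archive_size)))
  fit <- spea2_fitness(pop$obj, k)
  nd <- which(fit < 1)
  if (length(nd) > cfg$archive_size) {
    keep <- nd[spea2_truncate(pop$obj[nd, , drop = FALSE], cfg$archive_size)]
  } else if (length(nd) < cfg$archive_size) {
    dom <- setdiff(seq_len(nrow(pop$obj)), nd)
    pad <- dom[order(fit[dom])][seq_len(min(length(dom),
                                            cfg$archive_size - length(nd)))]
    keep <- c(nd, pad)
  } else keep <- nd
  list(genes = pop$genes[keep, , drop = FALSE],
       obj = pop$obj[keep, , drop = FALSE])
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("opt_result: %s, seed %d, %d generations, %d evaluations, front size %d\n",
              x$algorithm, x$seed, length(x$snapshots) - 1L, x$n_eval,
              nrow(x$front_obj)))
  invisible(x)
}
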