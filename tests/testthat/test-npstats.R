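test_that("kruskal_wallis reproduces the hand-ranked case and rank invariance", {
  out <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(out$statistic, 12 / 42 * (6^2 / 3 + 15^2 / 3) - 3 * 7,
               tolerance = 1e-12)
  expect_equal(round(out$statistic, 4), 3.8571)

  # invariant under strictly increasing transforms
  out2 <- kruskal_wallis(list(exp(c(1, 2, 3)), exp(c(4, 5, 6))))
  expect_equal(out$statistic, out2$statistic)

  # interleaved identical groups: H near 0
  out3 <- kruskal_wallis(list(c(1, 3, 5, 7), c(2, 4, 6, 8)))
  expect_lt(out3$statistic, 0.8)

  expect_equal(kruskal_wallis(list(rep(2, 4), rep(2, 4)))$p_value, 1)

  # oracle: base R implementation on random data with ties
  set.seed(14)
  for (i in 1:20) {
    g <- list(sample(1:8, 7, TRUE), sample(1:8, 9, TRUE), sample(1:8, 6, TRUE))
    ours <- kruskal_wallis(g)
    ref <- stats::kruskal.test(g)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("friedman matches its formula, conventions and the base-R oracle", {
  # perfect agreement across 10 blocks of 3 treatments: chi2 = n(k-1) = 20
  m <- matrix(rep(c(1, 2, 3), each = 10), ncol = 3)
  expect_equal(friedman(m)$statistic, 20)
  expect_equal(friedman(matrix(5, 4, 3))$statistic, 0)
  perm <- sample(nrow(m))
  expect_equal(friedman(m[perm, ])$statistic, friedman(m)$statistic)

  set.seed(15)
  for (i in 1:20) {
    mm <- matrix(rnorm(40), ncol = 4)   # no ties a.s.
    ours <- friedman(mm)
    ref <- stats::friedman.test(mm)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("mann_whitney_u reproduces the published floor and its identities", {
  x <- 1:10; y <- 11:20
  out <- mann_whitney_u(x, y)
  expect_equal(out$p_value, 2 * pnorm(-50 / sqrt(175)), tolerance = 1e-12)
  expect_equal(round(out$p_value, 4), 2e-04)

  expect_equal(mann_whitney_u(x, y)$U + mann_whitney_u(y, x)$U, 100)
  set.seed(16)
  a <- rnorm(8); b <- rnorm(12)
  expect_equal(mann_whitney_u(a, b)$p_value, mann_whitney_u(b, a)$p_value)

  # oracle: base R normal approximation (continuity-corrected variant)
  for (i in 1:20) {
    a <- sample(1:15, 9, TRUE); b <- sample(1:15, 11, TRUE)
    ours <- mann_whitney_u(a, b, continuity = TRUE)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = TRUE))
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("adjust_pvalues reproduces the published table arithmetic", {
  # full unadjusted pairwise column of the comparison study
  p_all <- c(0.0963, 0.0015, 0.0002, 0.0233, 0.0003, 0.0002, 0.4497,
             0.0002, 0.0002, 0.0002)
  bonf <- adjust_pvalues(p_all, "bonferroni", m = 20)
  expect_equal(round(bonf[1], 4), 1.0000)
  expect_equal(round(bonf[2], 4), 0.0300)

  bh <- adjust_pvalues(p_all, "step_up_bh", m = 10)
  expect_equal(round(bh[1], 4), 0.1070)   # 0.0963 * 10/9
  expect_equal(round(bh[2], 4), 0.0021)   # 0.0015 * 10/7
  expect_equal(round(bh[5], 4), 0.0005)   # 0.0003 * 10/6
  expect_equal(round(bh[3], 4), 0.0004)   # 0.0002 * 10/5
  expect_equal(round(bh[7], 4), 0.4497)

  # single p: all methods are the identity
  for (m in c("bonferroni", "hochberg", "hommel", "step_up_bh"))
    expect_equal(adjust_pvalues(0.037, m), 0.037)

  expect_error(adjust_pvalues(c(0.5, 1.2), "bonferroni"), "\\[0, 1\\]")
})

test_that("adjustment methods obey dominance ordering and match p.adjust", {
  set.seed(17)
  for (i in 1:30) {
    k <- sample(2:12, 1)
    p <- runif(k)
    bo <- adjust_pvalues(p, "bonferroni")
    ho <- adjust_pvalues(p, "hochberg")
    hm <- adjust_pvalues(p, "hommel")
    bh <- adjust_pvalues(p, "step_up_bh")
    expect_equal(bo, stats::p.adjust(p, "bonferroni"))
    expect_equal(ho, stats::p.adjust(p, "hochberg"))
    expect_equal(hm, stats::p.adjust(p, "hommel"))
    expect_equal(bh, stats::p.adjust(p, "BH"))
    # known dominance: hommel <= hochberg <= bonferroni
    expect_true(all(hm <= ho + 1e-12))
    expect_true(all(ho <= bo + 1e-12))
    # adjusted >= unadjusted, capped at 1
    for (a in list(bo, ho, hm, bh)) {
      expect_true(all(a >= p - 1e-12))
      expect_true(all(a <= 1))
    }
  }
  # bonferroni is idempotent on an already-capped list
  p <- c(1, 1, 1)
  expect_equal(adjust_pvalues(adjust_pvalues(p, "bonferroni"), "bonferroni"), p)
})

test_that("compare_algorithms runs the full protocol", {
  set.seed(18)
  m <- cbind(a = rnorm(10), b = rnorm(10), c = rnorm(10, 5),
             d = rnorm(10, 5), e = rnorm(10, 10))
  rep <- compare_algorithms(m, adjust_methods = c("bonferroni:20", "hochberg",
                                                  "hommel", "step_up_bh"))
  expect_equal(nrow(rep$pairwise), choose(5, 2))
  expect_s3_class(rep, "stat_report")
  expect_equal(nrow(rep$summary), 5)
  expect_true(all(c("min", "q1", "median", "q3", "max") %in% names(rep$summary)))

  # clearly separated pair
  i_ae <- which(rep$pairwise$a == "a" & rep$pairwise$b == "e")
  expect_lt(rep$pairwise$p[i_ae], 0.001)

  # identical columns: omnibus p = 1 convention and no significant pairs
  same <- matrix(2, 6, 3, dimnames = list(NULL, c("x", "y", "z")))
  rep2 <- compare_algorithms(same)
  expect_equal(rep2$omnibus$kruskal_wallis$p_value, 1)
  expect_false(any(rep2$pairwise$signif))

  # long-format input round trip
  df <- data.frame(run = rep(1:10, 5),
                   algorithm = rep(colnames(m), each = 10),
                   hv = as.vector(m))
  rep3 <- compare_algorithms(df)
  expect_equal(rep3$pairwise$p, rep$pairwise$p)
})
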