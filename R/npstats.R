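#' Kruskal-Wallis omnibus test
#'
#' Rank-based H statistic with tie correction; p-value from the chi-square
#' distribution with `k - 1` degrees of freedom. When every observation is
#' identical the test is uninformative and `p = 1` is returned by
#' convention.
#'
#' @param groups list of numeric samples (>= 2 groups, each nonempty).
#' @return list with `statistic` (H) and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(!vapply(groups, length, integer(1))))
    stop("need at least 2 nonempty groups", call. = FALSE)
  x <- unlist(groups)
  if (max(x) - min(x) == 0) {
    return(list(statistic = 0, p_value = 1))
  }
  n <- length(x)
  r <- rank(x)
  sizes <- vapply(groups, length, integer(1))
  idx <- rep(seq_along(groups), sizes)
  rs <- tapply(r, idx, sum)
  H <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- H / tie_corr
  k <- length(groups)
  list(statistic = H, p_value = stats::pchisq(H, k - 1, lower.tail = FALSE))
}

#' Friedman test on a runs-by-algorithms matrix
#'
#' Within-block (row) average ranks with ties averaged;
#' `chi2 = 12 n / (k (k + 1)) * sum((Rbar_j - (k + 1)/2)^2)`, p-value from
#' chi-square with `k - 1` degrees of freedom. Here blocks are independent
#' runs paired by run index, a nominal blocking.
#'
#' @param m numeric matrix, blocks (runs) in rows, treatments (algorithms)
#'   in columns; >= 2 of each.
#' @return list with `statistic` (chi-square) and `p_value`.
#' @export
friedman <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 blocks and >= 2 treatments", call. = FALSE)
  ranks <- t(apply(m, 1L, rank))
  rbar <- colMeans(ranks)
  chi2 <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  list(statistic = chi2,
       p_value = stats::pchisq(chi2, k - 1, lower.tail = FALSE))
}

#' Mann-Whitney U test (normal approximation)
#'
#' U statistic from tie-averaged ranks and a two-sided p-value from the
#' normal approximation with tie-corrected variance; the continuity
#' correction is off by default. For completely separated samples of size
#' 10 vs 10 this gives `p = 2 Phi(-50 / sqrt(175)) = 0.000157`.
#'
#' @param x,y numeric samples.
#' @param continuity apply the 0.5 continuity correction.
#' @return list with `U` (for `x`) and `p_value` (two-sided).
#' @export
mann_whitney_u <- function(x, y, continuity = FALSE) {
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both samples must be nonempty", call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nn <- n1 + n2
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1))
  z <- U - mu
  if (continuity) z <- z - sign(z) * 0.5
  z <- z / sqrt(sigma2)
  list(U = U, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Multiple-comparison p-value adjustment
#'
#' Adjusts a vector of p-values for multiplicity. `bonferroni` multiplies by
#' `m` and caps at 1; `hochberg` is the classical step-up procedure with
#' `(m - j + 1)` multipliers; `hommel` implements Hommel's (1988) algorithm;
#' `step_up_bh` is the step-up `m/j` arithmetic (the Benjamini-Hochberg
#' form), which with `m = 10` reproduces the published adjusted tables that
#' the classical family-wise formulas do not. The multiplier `m` defaults to
#' the list length but may be set larger (e.g. 20 for ordered pairs of five
#' algorithms).
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param method one of `"bonferroni"`, `"hochberg"`, `"hommel"`,
#'   `"step_up_bh"`.
#' @param m comparison multiplier; default `length(pvals)`.
#' @return adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(pvals,
                           method = c("bonferroni", "hochberg", "hommel",
                                      "step_up_bh"),
                           m = length(pvals)) {
  method <- match.arg(method)
  p <- as.numeric(pvals)
  if (any(p < 0 | p > 1 | is.na(p)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  k <- length(p)
  if (m < k) stop("multiplier m must be >= length(pvals)", call. = FALSE)
  if (k == 0L) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- switch(method,
    bonferroni = pmin(1, p * m),
    hochberg = {
      mult <- m - seq_len(k) + 1
      a <- rev(cummin(rev(ps * mult)))
      out <- numeric(k); out[o] <- pmin(1, a); out
    },
    step_up_bh = {
      mult <- m / seq_len(k)
      a <- rev(cummin(rev(ps * mult)))
      out <- numeric(k); out[o] <- pmin(1, a); out
    },
    hommel = {
      # Hommel (1988) closed testing shortcut over the sorted p-values,
      # generalised to an m >= k comparison family by treating the absent
      # hypotheses as having p = 1.
      if (m == k) {
        q <- hommel_adjust(ps)
      } else {
        q <- hommel_adjust(c(ps, rep(1, m - k)))[seq_len(k)]
      }
      out <- numeric(k); out[o] <- pmin(1, q); out
    })
  adj
}

# Hommel adjustment of sorted p-values (ascending); returns sorted adjusted.
# For n = 2 Hommel coincides with Hochberg (as in base R's p.adjust).
hommel_adjust <- function(ps) {
  n <- length(ps)
  if (n == 1L) return(ps)
  if (n == 2L) return(c(min(2 * ps[1], ps[2]), ps[2]))
  q <- pa <- rep(min(n * ps / seq_len(n)), n)
  for (mm in (n - 1):2) {
    i1 <- seq_len(n - mm + 1L)
    i2 <- (n - mm + 2L):n
    q1 <- min(mm * ps[i2] / (2:mm))
    q[i1] <- pmin(mm * ps[i1], q1)
    q[i2] <- q[n - mm + 1L]
    pa <- pmax(pa, q)
  }
  pmax(pa, ps)
}

#' Compare algorithms from a hypervolume table
#'
#' Runs the full nonparametric protocol on a runs-by-algorithms matrix of
#' hypervolume values: Kruskal-Wallis across algorithms, Friedman over
#' run-blocked ranks, all pairwise Mann-Whitney U tests, every requested
#' p-value adjustment, significance flags at `alpha`, and per-algorithm
#' box-plot summaries (min, Q1, median, Q3, max).
#'
#' @param table numeric matrix (runs x algorithms) with column names, or a
#'   data.frame of columns `run`, `algorithm`, `hv`.
#' @param alpha significance level (default 0.05).
#' @param adjust_methods character vector of methods for
#'   [adjust_pvalues()]; entries may carry an explicit multiplier as
#'   `"bonferroni:20"`.
#' @return object of class `stat_report`: list with `omnibus`, `pairwise`
#'   (data.frame of pair, U, p, adjusted columns, significance flags) and
#'   `summary` (box-plot statistics).
#' @export
compare_algorithms <- function(table, alpha = 0.05,
                               adjust_methods = c("bonferroni", "hochberg",
                                                  "hommel", "step_up_bh")) {
  if (is.data.frame(table) && all(c("run", "algorithm", "hv") %in% names(table))) {
    table <- hv_table_to_matrix(table)
  }
  m <- as.matrix(table)
  if (is.null(colnames(m))) colnames(m) <- paste0("algo", seq_len(ncol(m)))
  algos <- colnames(m)
  groups <- lapply(seq_len(ncol(m)), function(j) m[, j])
  kw <- kruskal_wallis(groups)
  fr <- friedman(m)
  pairs <- utils::combn(length(algos), 2)
  pw <- data.frame(
    a = algos[pairs[1, ]], b = algos[pairs[2, ]],
    U = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    mw <- mann_whitney_u(m[, pairs[1, i]], m[, pairs[2, i]])
    pw$U[i] <- mw$U
    pw$p[i] <- mw$p_value
  }
  for (spec_ in adjust_methods) {
    parts <- strsplit(spec_, ":", fixed = TRUE)[[1]]
    meth <- parts[1]
    mult <- if (length(parts) > 1L) as.numeric(parts[2]) else nrow(pw)
    col <- if (length(parts) > 1L) paste0(meth, "_", parts[2]) else meth
    pw[[col]] <- adjust_pvalues(pw$p, meth, m = mult)
    pw[[paste0(col, "_signif")]] <- pw[[col]] < alpha
  }
  pw$signif <- pw$p < alpha
  sm <- t(apply(m, 2, function(col) stats::quantile(col, c(0, 0.25, 0.5, 0.75, 1))))
  colnames(sm) <- c("min", "q1", "median", "q3", "max")
  structure(list(
    omnibus = list(kruskal_wallis = kw, friedman = fr),
    alpha = alpha, pairwise = pw,
    summary = data.frame(algorithm = algos, sm, row.names = NULL)),
    class = "stat_report")
}

hv_table_to_matrix <- function(df) {
  algos <- unique(df$algorithm)
  runs <- sort(unique(df$run))
  m <- matrix(NA_real_, length(runs), length(algos),
              dimnames = list(NULL, algos))
  for (i in seq_len(nrow(df))) {
    m[match(df$run[i], runs), match(df$algorithm[i], algos)] <- df$hv[i]
  }
  if (anyNA(m)) stop("hv table has missing run x algorithm entries", call. = FALSE)
  m
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("stat_report: KW H=%.4g (p=%.4g), Friedman chi2=%.4g (p=%.4g)\n",
              x$omnibus$kruskal_wallis$statistic, x$omnibus$kruskal_wallis$p_value,
              x$omnibus$friedman$statistic, x$omnibus$friedman$p_value))
  print(x$pairwise)
  invisible(x)
}
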