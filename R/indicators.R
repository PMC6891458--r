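#' Exact hypervolume of a minimisation front
#'
#' Lebesgue measure of the union of boxes `[point_i, ref]`, computed exactly
#' by the recursive dimension-sweep used by the WFG algorithm: each point's
#' exclusive contribution is its box volume minus the hypervolume of the
#' remaining points clipped into its box. Points that do not strictly fit
#' under the reference point are dropped with a warning; an empty set has
#' hypervolume 0 (with a warning).
#'
#' @param points numeric matrix, one row per objective vector (minimised), or
#'   a single vector.
#' @param ref reference point, componentwise >= every measured point.
#' @return nonnegative scalar.
#' @export
hypervolume <- function(points, ref) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  ref <- as.numeric(ref)
  if (ncol(points) != length(ref))
    stop("reference point dimension mismatch", call. = FALSE)
  if (nrow(points) == 0L) {
    warning("empty point set has hypervolume 0")
    return(0)
  }
  ok <- apply(points, 1L, function(p) all(p <= ref))
  if (!all(ok)) {
    warning(sum(!ok), " point(s) not dominated by the reference were dropped")
    points <- points[ok, , drop = FALSE]
    if (nrow(points) == 0L) return(0)
  }
  nd <- nondominated_idx(points)
  hv_wfg(points[nd, , drop = FALSE], ref)
}

hv_wfg <- function(pts, ref) {
  n <- nrow(pts)
  if (n == 0L) return(0)
  # sorting by the first objective (descending) keeps the limit sets small
  pts <- pts[order(pts[, 1], decreasing = TRUE), , drop = FALSE]
  total <- 0
  for (i in seq_len(n)) {
    p <- pts[i, ]
    box <- prod(ref - p)
    if (i < n) {
      lim <- sweep(pts[(i + 1):n, , drop = FALSE], 2, p, pmax)
      lim <- lim[nondominated_idx(lim), , drop = FALSE]
      box <- box - hv_wfg(lim, ref)
    }
    total <- total + box
  }
  total
}

#' Shared reference point for a comparison study
#'
#' The componentwise maximum over the union of all fronts being compared,
#' scaled by 1.1 (components whose maximum is 0 get +0.1 instead, so the
#' reference strictly dominates, in the minimisation sense is dominated by,
#' every member). Fixed once per study so per-run hypervolumes are
#' comparable.
#'
#' @param fronts list of objective matrices (or a single matrix).
#' @return numeric reference point.
#' @export
choose_reference_point <- function(fronts) {
  if (is.matrix(fronts)) fronts <- list(fronts)
  all_pts <- do.call(rbind, fronts)
  if (is.null(all_pts) || nrow(all_pts) == 0L)
    stop("cannot choose a reference point from an empty union", call. = FALSE)
  mx <- apply(all_pts, 2, max)
  ifelse(mx == 0, 0.1, mx * 1.1)
}

#' Per-generation hypervolume trajectory
#'
#' Hypervolume of each snapshot's nondominated front against one fixed
#' reference point. No monotonicity is imposed: algorithms without an
#' archive can lose hypervolume between generations.
#'
#' @param result an `opt_result` from [run_algorithm()].
#' @param ref reference point (e.g. from [choose_reference_point()]).
#' @return numeric vector of length `generations + 1`.
#' @export
hv_trajectory <- function(result, ref) {
  vapply(result$snapshots, function(s) {
    pts <- s$front_obj
    ok <- apply(pts, 1L, function(p) all(p <= ref))
    pts <- pts[ok, , drop = FALSE]
    if (nrow(pts) == 0L) return(0)
    hv_wfg(pts[nondominated_idx(pts), , drop = FALSE], ref)
  }, numeric(1))
}
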