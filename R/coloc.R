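#' DBSCAN clustering of localization coordinates
#'
#' Density-based clustering for single-molecule localization data. A point is
#' a core point when at least `min_points` points (itself included) lie
#' within `eps_nm`; clusters are the connected components of core points
#' under the eps-neighborhood relation, and each non-core point with a core
#' neighbor joins the cluster of its nearest core neighbor. Remaining points
#' are noise. Labels are canonical — clusters are numbered 1, 2, ... by
#' their smallest member index — so the partition does not depend on point
#' order.
#'
#' @param points Matrix or data.frame, one row per point, columns x and y in
#'   nm.
#' @param eps_nm Neighborhood radius in nm (default 200).
#' @param min_points Minimum neighborhood size for a core point, self
#'   included (default 3, i.e. a minimum cluster size of three points).
#' @return Integer vector of labels, 0 for noise, >= 1 for clusters.
#' @export
dbscan_cluster <- function(points, eps_nm = 200, min_points = 3) {
  if (eps_nm <= 0 || min_points < 1) stop("eps_nm > 0 and min_points >= 1 required",
                                          call. = FALSE)
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(p)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(p))
  nbr <- d <= eps_nm            # self included on the diagonal
  core <- rowSums(nbr) >= min_points
  labels <- integer(n)
  cl <- 0L
  # connected components over core points (BFS in ascending index order)
  for (i in which(core)) {
    if (labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      q <- queue[1]
      queue <- queue[-1]
      nb <- which(nbr[q, ] & core & labels == 0L)
      labels[nb] <- cl
      queue <- c(queue, nb)
    }
  }
  # border points join the cluster of their nearest core neighbor
  for (i in which(!core)) {
    cand <- which(nbr[i, ] & core)
    if (length(cand)) {
      labels[i] <- labels[cand[which.min(d[i, cand])]]
    }
  }
  # canonical numbering by smallest member index
  if (cl > 0L) {
    first <- vapply(seq_len(cl), function(k) min(which(labels == k)), integer(1))
    remap <- integer(cl)
    remap[order(first)] <- seq_len(cl)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
  }
  labels
}

# per-point density profiles over the radius ladder and their Spearman score
.doc_one_channel <- function(self_pts, other_pts, radii) {
  n <- nrow(self_pts)
  scores <- numeric(n)
  r2 <- radii^2
  inv_r2 <- 1 / r2
  step <- radii[2] - radii[1]
  nbin <- length(radii)
  for (i in seq_len(n)) {
    ds <- (self_pts[, 1] - self_pts[i, 1])^2 + (self_pts[, 2] - self_pts[i, 2])^2
    dc <- (other_pts[, 1] - self_pts[i, 1])^2 + (other_pts[, 2] - self_pts[i, 2])^2
    ds <- ds[ds > 0]            # exclude self (and exact duplicates)
    dc <- dc[dc > 0]
    cnt_s <- cumsum(tabulate(pmin(ceiling(sqrt(ds) / step), nbin + 1L), nbin + 1L))[1:nbin]
    cnt_c <- cumsum(tabulate(pmin(ceiling(sqrt(dc) / step), nbin + 1L), nbin + 1L))[1:nbin]
    # density gradient across the ladder: the step-to-step change in
    # neighbor density, which cancels trends shared by both channels
    # (global density, field-edge falloff)
    grad_s <- diff(c(0, cnt_s * inv_r2))
    grad_c <- diff(c(0, cnt_c * inv_r2))
    if (stats::sd(grad_s) == 0 || stats::sd(grad_c) == 0) {
      scores[i] <- 0
    } else {
      scores[i] <- stats::cor(grad_s, grad_c, method = "spearman")
    }
  }
  scores
}

#' Degree-of-colocalization (DoC) scores for two channels
#'
#' For every point, the local density of same-channel and cross-channel
#' neighbors is profiled over a ladder of radii (`step_nm` to `r_max_nm`,
#' density = cumulative neighbor count / r^2) and the two profiles are
#' compared by Spearman rank correlation, giving a score in \[-1, 1\]:
#' near +1 where the two channels share density structure, near 0 where they
#' are unrelated, negative where they are anti-correlated. Points with a
#' flat profile (no neighbors inside `r_max_nm`) score 0. The fraction of
#' points at or above `threshold` is reported as the colocalized fraction.
#'
#' @param channel_a,channel_b Matrices of point coordinates (nm), >= 10
#'   points each.
#' @param r_max_nm Largest profiling radius (default 2500 nm).
#' @param step_nm Radius step (default 10 nm).
#' @param threshold Colocalization score threshold (default 0.4).
#' @return A list of class `doc_result` with elements `a` and `b`, each a
#'   list of `scores` (per point) and `colocalized_fraction` (percent), plus
#'   the parameters used.
#' @export
doc_scores <- function(channel_a, channel_b, r_max_nm = 2500, step_nm = 10,
                       threshold = 0.4) {
  a <- as.matrix(channel_a)[, 1:2, drop = FALSE]
  b <- as.matrix(channel_b)[, 1:2, drop = FALSE]
  if (nrow(a) < 10 || nrow(b) < 10) {
    stop("each channel needs at least 10 points for DoC scoring", call. = FALSE)
  }
  radii <- seq(step_nm, r_max_nm, by = step_nm)
  sa <- .doc_one_channel(a, b, radii)
  sb <- .doc_one_channel(b, a, radii)
  structure(list(
    a = list(scores = sa, colocalized_fraction = coloc_fraction(sa, threshold)),
    b = list(scores = sb, colocalized_fraction = coloc_fraction(sb, threshold)),
    r_max_nm = r_max_nm, step_nm = step_nm, threshold = threshold
  ), class = "doc_result")
}

#' @export
print.doc_result <- function(x, ...) {
  cat(sprintf("DoC (Rmax %g nm, step %g nm, threshold %.2f)\n",
              x$r_max_nm, x$step_nm, x$threshold))
  cat(sprintf("  channel A: median score %.3f, %.1f%% colocalized (n = %d)\n",
              stats::median(x$a$scores), x$a$colocalized_fraction, length(x$a$scores)))
  cat(sprintf("  channel B: median score %.3f, %.1f%% colocalized (n = %d)\n",
              stats::median(x$b$scores), x$b$colocalized_fraction, length(x$b$scores)))
  invisible(x)
}

#' Fraction of colocalized points
#'
#' @param scores Numeric DoC scores (or a `doc_result` channel's `scores`).
#' @param threshold Score threshold (default 0.4).
#' @return Percentage (0-100) of points with score >= threshold.
#' @export
coloc_fraction <- function(scores, threshold = 0.4) {
  if (length(scores) == 0) stop("no scores", call. = FALSE)
  100 * mean(scores >= threshold)
}
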