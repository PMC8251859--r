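#' Detect 3D scale-space keypoints
#'
#' Difference-of-Gaussian blob detector with SIFT-style descriptors,
#' operating in physical mm (anisotropic voxels are handled by per-axis
#' kernel widths). Candidates are extrema of the DoG over their 3 x 3 x 3
#' spatial x 3-scale neighbourhood; low-contrast responses and edge-like
#' responses (Hessian eigenvalue ratio) are rejected. The descriptor
#' concatenates gradient-direction octant histograms over the 8 spatial
#' octants of a window around the point (64 bins), is clipped at 0.2 and
#' normalised to unit length. No rotation invariance is applied: the
#' detector is meant for small-deformation correspondence finding, where
#' orientation normalisation only adds noise.
#'
#' @param vol a [volume3d()].
#' @param params list of options: `sigma0_mm` base scale (default 1.6),
#'   `n_scales` number of Gaussian scales (default 6), `scale_step`
#'   (default `2^(1/2)`), `contrast_threshold` as a fraction of the volume
#'   dynamic range (default 0.02), `edge_ratio` maximum Hessian eigenvalue
#'   ratio (default 10), `descriptor_radius_factor` window radius in units
#'   of the detection scale (default 2).
#' @return A data.frame of class `keypoints3d`: world mm `ap, si, rl`,
#'   `scale_mm`, `response`, plus a `descriptor` matrix attribute (one row
#'   per keypoint, unit norm). Zero rows for featureless volumes.
#' @export
detect_keypoints <- function(vol, params = list()) {
  stopifnot(inherits(vol, "volume3d"))
  p <- utils::modifyList(list(sigma0_mm = 1.6, n_scales = 6L,
                              scale_step = sqrt(2),
                              contrast_threshold = 0.02,
                              edge_ratio = 10,
                              descriptor_radius_factor = 2), params)
  a <- vol$data
  drange <- diff(range(a))
  empty <- keypoint_frame(matrix(numeric(), 0, 3), numeric(), numeric(),
                          matrix(numeric(), 0, 64))
  if (drange == 0) return(empty)
  sigmas <- p$sigma0_mm * p$scale_step^(0:(p$n_scales - 1L))
  blurred <- lapply(sigmas, function(s) gauss_smooth3(a, s / vol$spacing))
  dogs <- lapply(seq_len(p$n_scales - 1L), function(i)
    blurred[[i + 1L]] - blurred[[i]])
  thr <- p$contrast_threshold * drange
  cand <- NULL
  for (si in 2:(length(dogs) - 1L)) {
    dg <- dogs[[si]]
    mx <- local_extreme3(dg, max = TRUE)
    mn <- local_extreme3(dg, max = FALSE)
    lo <- dogs[[si - 1L]]; hi <- dogs[[si + 1L]]
    is_max <- mx & dg > pmax(lo, hi) & dg > thr
    is_min <- mn & dg < pmin(lo, hi) & dg < -thr
    sel <- which(is_max | is_min)
    if (length(sel))
      cand <- rbind(cand, cbind(arrayInd(sel, dim(dg)), si, dg[sel]))
  }
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  # edge / line rejection via the DoG Hessian eigenvalue ratio
  keep <- logical(nrow(cand))
  for (q in seq_len(nrow(cand))) {
    H <- dog_hessian(dogs[[cand[q, 4]]], cand[q, 1:3], vol$spacing)
    if (is.null(H)) next
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    aev <- abs(ev)
    keep[q] <- min(aev) > 0 && max(aev) / min(aev) <= p$edge_ratio
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  pos <- sweep(sweep(cand[, 1:3, drop = FALSE] - 1, 2, vol$spacing, "*"),
               2, vol$origin, "+")
  scale_mm <- sigmas[cand[, 4]]
  desc <- keypoint_descriptors(blurred[[1]], vol, cand[, 1:3, drop = FALSE],
                               p$descriptor_radius_factor * scale_mm)
  ok <- rowSums(desc^2) > 0
  keypoint_frame(pos[ok, , drop = FALSE], scale_mm[ok], cand[ok, 5],
                 desc[ok, , drop = FALSE])
}

keypoint_frame <- function(pos, scale_mm, response, desc) {
  df <- data.frame(ap = pos[, 1], si = pos[, 2], rl = pos[, 3],
                   scale_mm = scale_mm, response = response)
  attr(df, "descriptor") <- desc
  class(df) <- c("keypoints3d", "data.frame")
  df
}

# strict local max/min over the 26-neighbourhood, vectorised by shifts
local_extreme3 <- function(a, max = TRUE) {
  d <- dim(a)
  res <- array(TRUE, d)
  cmp <- if (max) function(x, y) x > y else function(x, y) x < y
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sh <- shift3(a, c(dx, dy, dz))
    res <- res & cmp(a, sh)
  }
  # boundary voxels cannot be verified extrema
  res[c(1, d[1]), , ] <- FALSE
  res[, c(1, d[2]), ] <- FALSE
  res[, , c(1, d[3])] <- FALSE
  res
}

# shift with replicated edges
shift3 <- function(a, off) {
  d <- dim(a)
  ix <- lapply(1:3, function(ax) pmin(pmax(seq_len(d[ax]) + off[ax], 1L),
                                      d[ax]))
  a[ix[[1]], ix[[2]], ix[[3]]]
}

dog_hessian <- function(dg, v, spacing) {
  d <- dim(dg)
  if (any(v < 2L) || any(v > d - 1L)) return(NULL)
  i <- v[1]; j <- v[2]; k <- v[3]
  sp <- spacing
  c0 <- dg[i, j, k]
  H <- matrix(0, 3, 3)
  H[1, 1] <- (dg[i + 1, j, k] - 2 * c0 + dg[i - 1, j, k]) / sp[1]^2
  H[2, 2] <- (dg[i, j + 1, k] - 2 * c0 + dg[i, j - 1, k]) / sp[2]^2
  H[3, 3] <- (dg[i, j, k + 1] - 2 * c0 + dg[i, j, k - 1]) / sp[3]^2
  H[1, 2] <- H[2, 1] <- (dg[i + 1, j + 1, k] - dg[i + 1, j - 1, k] -
                           dg[i - 1, j + 1, k] + dg[i - 1, j - 1, k]) /
    (4 * sp[1] * sp[2])
  H[1, 3] <- H[3, 1] <- (dg[i + 1, j, k + 1] - dg[i + 1, j, k - 1] -
                           dg[i - 1, j, k + 1] + dg[i - 1, j, k - 1]) /
    (4 * sp[1] * sp[3])
  H[2, 3] <- H[3, 2] <- (dg[i, j + 1, k + 1] - dg[i, j + 1, k - 1] -
                           dg[i, j - 1, k + 1] + dg[i, j - 1, k - 1]) /
    (4 * sp[2] * sp[3])
  H
}

# 64-d descriptor: 8 spatial octants x 8 gradient-sign octants,
# |g|-weighted, Gaussian-windowed, clipped at 0.2 and renormalised
keypoint_descriptors <- function(base, vol, vox, radius_mm) {
  g <- image_gradient(base, vol$spacing)
  d <- dim(base)
  n <- nrow(vox)
  desc <- matrix(0, n, 64L)
  for (q in seq_len(n)) {
    r_vox <- pmax(1L, ceiling(radius_mm[q] / vol$spacing))
    lo <- pmax(vox[q, ] - r_vox, 1L)
    hi <- pmin(vox[q, ] + r_vox, d)
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    gx <- g[[1]][ii, jj, kk]; gy <- g[[2]][ii, jj, kk]
    gz <- g[[3]][ii, jj, kk]
    mag <- sqrt(gx^2 + gy^2 + gz^2)
    # relative mm offsets
    ox <- (ii - vox[q, 1]) * vol$spacing[1]
    oy <- (jj - vox[q, 2]) * vol$spacing[2]
    oz <- (kk - vox[q, 3]) * vol$spacing[3]
    OX <- array(ox, dim(gx))
    OY <- array(rep(oy, each = length(ii)), dim(gx))
    OZ <- array(rep(oz, each = length(ii) * length(jj)), dim(gx))
    wgt <- exp(-(OX^2 + OY^2 + OZ^2) / (2 * radius_mm[q]^2))
    s_oct <- 1L + (OX >= 0) + 2L * (OY >= 0) + 4L * (OZ >= 0)
    g_oct <- 1L + (gx >= 0) + 2L * (gy >= 0) + 4L * (gz >= 0)
    bin <- (s_oct - 1L) * 8L + g_oct
    h <- vapply(1:64, function(b) sum((mag * wgt)[bin == b]), 0)
    nrm <- sqrt(sum(h^2))
    if (nrm > 0) {
      h <- pmin(h / nrm, 0.2)
      h <- h / sqrt(sum(h^2))
    }
    desc[q, ] <- h
  }
  desc
}

#' Match keypoints between two volumes
#'
#' Nearest-neighbour descriptor matching with Lowe's ratio test
#' (best/second-best distance below `ratio_threshold`), a mutual-
#' consistency check, and an optional cap on the 3D distance between
#' matched positions (gross-outlier guard for registration-residual use).
#'
#' @param a,b `keypoints3d` objects from [detect_keypoints()].
#' @param ratio_threshold Lowe ratio (default 0.8).
#' @param max_dist_mm maximum allowed 3D distance between matched points.
#' @return A data.frame with the matched positions (`ap_a, si_a, rl_a,
#'   ap_b, si_b, rl_b`), descriptor distance `desc_dist` and 3D point
#'   distance `dist_mm`.
#' @export
match_keypoints <- function(a, b, ratio_threshold = 0.8, max_dist_mm = 20) {
  da <- attr(a, "descriptor"); db <- attr(b, "descriptor")
  empty <- data.frame(ap_a = numeric(), si_a = numeric(), rl_a = numeric(),
                      ap_b = numeric(), si_b = numeric(), rl_b = numeric(),
                      desc_dist = numeric(), dist_mm = numeric())
  if (is.null(da) || is.null(db) || nrow(a) == 0L || nrow(b) == 0L)
    return(empty)
  # squared descriptor distances (unit vectors): 2 - 2 a.b
  S <- da %*% t(db)
  D2 <- pmax(2 - 2 * S, 0)
  best_ab <- apply(D2, 1, which.min)
  best_ba <- apply(D2, 2, which.min)
  rows <- list()
  for (i in seq_len(nrow(a))) {
    j <- best_ab[i]
    if (best_ba[j] != i) next # mutual consistency
    d1 <- D2[i, j]
    d2 <- if (ncol(D2) > 1L) min(D2[i, -j]) else Inf
    if (is.finite(d2) && d2 > 0 && sqrt(d1) >= ratio_threshold * sqrt(d2))
      next
    if (!is.finite(d2) || d2 == 0) next # ambiguous: identical descriptors
    dist <- sqrt((a$ap[i] - b$ap[j])^2 + (a$si[i] - b$si[j])^2 +
                   (a$rl[i] - b$rl[j])^2)
    if (dist > max_dist_mm) next
    rows[[length(rows) + 1L]] <-
      data.frame(ap_a = a$ap[i], si_a = a$si[i], rl_a = a$rl[i],
                 ap_b = b$ap[j], si_b = b$si[j], rl_b = b$rl[j],
                 desc_dist = sqrt(d1), dist_mm = dist)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
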