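#' Scalar image volume on a regular, axis-aligned grid
#'
#' The basic imaging container of the package: a 3D numeric array together
#' with per-axis voxel spacing and a world origin, both in millimetres.
#' Array axes follow the anatomical order (AP, SI, RL): axis 1 runs
#' anterior-posterior, axis 2 inferior-superior, axis 3 right-left. World
#' coordinates are `origin + index * spacing` with 0-based voxel indices;
#' only axis-aligned geometry is supported (no oblique orientations).
#'
#' @param data numeric 3D array, indexed (i, j, k).
#' @param spacing numeric(3), voxel size in mm per axis; all > 0.
#' @param origin numeric(3), world position (mm) of voxel (0, 0, 0).
#' @param axis_labels character(3) anatomical labels of the array axes.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     axis_labels = c("AP", "SI", "RL")) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume3d: 'data' must be a 3D array, got dimensionality ",
         length(dim(data)))
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume3d: 'spacing' must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("volume3d: 'origin' must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 axis_labels = axis_labels),
            class = "volume3d")
}

#' Per-voxel 3D displacement field
#'
#' Displacements are stored as a 4D array (nx, ny, nz, 3) in millimetres
#' along world axes, on the same grid as the volume the field deforms.
#' Fields are backward-mapping (pull) package-wide: warping a moving image
#' by the field samples `moving(x + u(x))` at every fixed-grid voxel `x`.
#'
#' @param u numeric 4D array (nx, ny, nz, 3), displacement in mm.
#' @inheritParams volume3d
#' @return An object of class `vectorfield3d`.
#' @export
vectorfield3d <- function(u, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                          axis_labels = c("AP", "SI", "RL")) {
  if (!is.array(u) || length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("vectorfield3d: 'u' must be a 4D array with 3 components")
  if (any(!is.finite(u))) stop("vectorfield3d: displacements must be finite")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("vectorfield3d: 'spacing' must be 3 positive values (mm)")
  structure(list(u = u, spacing = spacing, origin = origin,
                 axis_labels = axis_labels),
            class = "vectorfield3d")
}

#' Zero displacement field on the grid of a volume
#' @param vol a `volume3d` (or `vectorfield3d`) supplying the grid.
#' @return A `vectorfield3d` of zeros.
#' @export
zero_field <- function(vol) {
  d <- grid_dim(vol)
  vectorfield3d(array(0, c(d, 3L)), spacing = vol$spacing, origin = vol$origin,
                axis_labels = vol$axis_labels)
}

grid_dim <- function(x) {
  if (inherits(x, "volume3d")) dim(x$data) else dim(x$u)[1:3]
}

#' Test whether two objects live on the same grid
#' @param a,b `volume3d` or `vectorfield3d` objects.
#' @param tol geometric tolerance in mm.
#' @return logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(grid_dim(a), grid_dim(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "operands") {
  if (!same_grid(a, b))
    stop("grid geometry mismatch between ", what,
         " (dims ", paste(grid_dim(a), collapse = "x"), " vs ",
         paste(grid_dim(b), collapse = "x"), ")")
  invisible(TRUE)
}

#' World coordinates of all voxel centres
#'
#' @param vol a `volume3d` or `vectorfield3d`.
#' @return A matrix (n_voxels x 3) of world mm coordinates in array order.
#' @export
grid_world_coords <- function(vol) {
  d <- grid_dim(vol)
  ax <- lapply(1:3, function(a) vol$origin[a] + (0:(d[a] - 1L)) * vol$spacing[a])
  cbind(rep(ax[[1]], times = d[2] * d[3]),
        rep(rep(ax[[2]], each = d[1]), times = d[3]),
        rep(ax[[3]], each = d[1] * d[2]))
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels (%s), spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3], paste(x$axis_labels, collapse = ","),
              paste(format(x$spacing, digits = 4), collapse = " x "),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.vectorfield3d <- function(x, ...) {
  d <- dim(x$u)
  m <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat(sprintf("<vectorfield3d> %d x %d x %d voxels, spacing %s mm, |u| max %.3g mm, mean %.3g mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x "),
              max(m), mean(m)))
  invisible(x)
}

# ---- interpolation primitives ------------------------------------------

# Trilinear interpolation of a 3D array at continuous 0-based voxel
# coordinates (n x 3). Out-of-domain coordinates clamp to the edge.
interp_trilinear <- function(arr, idx) {
  d <- dim(arr)
  x <- pmin(pmax(idx[, 1], 0), d[1] - 1L)
  y <- pmin(pmax(idx[, 2], 0), d[2] - 1L)
  z <- pmin(pmax(idx[, 3], 0), d[3] - 1L)
  i0 <- pmin(floor(x), d[1] - 1L); j0 <- pmin(floor(y), d[2] - 1L)
  k0 <- pmin(floor(z), d[3] - 1L)
  i1 <- pmin(i0 + 1, d[1] - 1L); j1 <- pmin(j0 + 1, d[2] - 1L)
  k1 <- pmin(k0 + 1, d[3] - 1L)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  n12 <- d[1] * d[2]
  lin <- function(i, j, k) arr[1L + i + d[1] * j + n12 * k]
  c000 <- lin(i0, j0, k0); c100 <- lin(i1, j0, k0)
  c010 <- lin(i0, j1, k0); c110 <- lin(i1, j1, k0)
  c001 <- lin(i0, j0, k1); c101 <- lin(i1, j0, k1)
  c011 <- lin(i0, j1, k1); c111 <- lin(i1, j1, k1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz
}

# Nearest-neighbour interpolation at continuous 0-based voxel coordinates.
interp_nearest <- function(arr, idx) {
  d <- dim(arr)
  i <- pmin(pmax(round(idx[, 1]), 0), d[1] - 1L)
  j <- pmin(pmax(round(idx[, 2]), 0), d[2] - 1L)
  k <- pmin(pmax(round(idx[, 3]), 0), d[3] - 1L)
  arr[1L + i + d[1] * j + d[1] * d[2] * k]
}

# world mm -> continuous 0-based voxel index
world_to_index <- function(p, vol) {
  sweep(sweep(p, 2, vol$origin, "-"), 2, vol$spacing, "/")
}

#' Sample a volume at arbitrary world positions
#' @param vol a `volume3d`.
#' @param p matrix (n x 3) of world mm positions.
#' @param interp `"linear"` or `"nearest"`; out-of-domain clamps to edge.
#' @return numeric vector of sampled intensities.
#' @export
sample_volume <- function(vol, p, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  idx <- world_to_index(p, vol)
  if (interp == "linear") interp_trilinear(vol$data, idx)
  else interp_nearest(vol$data, idx)
}

# Sample a vector field (all 3 components) at world positions; returns n x 3.
sample_field <- function(field, p, interp = "linear") {
  idx <- world_to_index(p, field)
  f <- if (interp == "linear") interp_trilinear else interp_nearest
  cbind(f(field$u[, , , 1], idx), f(field$u[, , , 2], idx),
        f(field$u[, , , 3], idx))
}

# ---- separable Gaussian smoothing --------------------------------------

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution along the first axis of a matrix with replicated edges.
conv_axis1 <- function(m, k) {
  if (length(k) == 1L) return(m)
  n <- nrow(m); r <- (length(k) - 1L) / 2L
  out <- matrix(0, n, ncol(m))
  for (t in seq_along(k)) {
    off <- t - 1L - r
    rows <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + k[t] * m[rows, , drop = FALSE]
  }
  out
}

# Separable Gaussian smoothing of a 3D array; sigma given in voxels per axis.
gauss_smooth3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (a in 1:3) {
    if (sigma_vox[a] <= 0 || d[a] < 2L) next
    k <- gauss_kernel(sigma_vox[a])
    perm <- c(a, setdiff(1:3, a))
    m <- aperm(arr, perm)
    dm <- dim(m)
    m <- conv_axis1(matrix(m, dm[1]), k)
    dim(m) <- dm
    arr <- aperm(m, order(perm))
  }
  arr
}

# Downsample a volume by integer factors (Gaussian pre-smoothing).
downsample_volume <- function(vol, factor) {
  factor <- as.integer(rep_len(factor, 3L))
  if (all(factor == 1L)) return(vol)
  sm <- gauss_smooth3(vol$data, 0.5 * (factor - 1L) + 1e-9)
  d <- dim(sm)
  ix <- lapply(1:3, function(a) seq(1L, d[a], by = factor[a]))
  volume3d(sm[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
           spacing = vol$spacing * factor, origin = vol$origin,
           axis_labels = vol$axis_labels)
}

# Resample each component of a coarse field onto the grid of `target`
# (trilinear); displacement values are in mm so no rescaling is needed.
upsample_field <- function(field, target) {
  p <- grid_world_coords(target)
  u <- sample_field(field, p)
  d <- grid_dim(target)
  vectorfield3d(array(u, c(d, 3L)), spacing = target$spacing,
                origin = target$origin, axis_labels = target$axis_labels)
}
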