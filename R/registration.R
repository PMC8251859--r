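#' Deformable registration parameters
#'
#' Controls the multiresolution free-form registration used to build the
#' motion model. At each pyramid level the displacement field is refined by
#' intensity-driven updates (mean-squared-difference forces by default) and
#' regularised by Gaussian smoothing at the scale of the control spacing,
#' which plays the role of a stiffness/bending penalty and keeps estimated
#' deformations fold-free. The control spacing doubles at each coarser
#' level.
#'
#' @param n_levels pyramid depth (>= 1).
#' @param control_spacing_mm regularisation/control scale at the finest
#'   level, in mm.
#' @param metric `"mse"` (mean squared intensity difference; same-modality
#'   default) or `"ncc"` (global normalised cross-correlation, implemented
#'   as MSE on z-normalised intensities).
#' @param max_iter iterations per level (recycled to `n_levels`, coarse to
#'   fine).
#' @param reg_weight regularisation weight in (0, 1]; scales the smoothing
#'   kernel width.
#' @param tol relative metric-improvement convergence tolerance per level.
#' @param step update step scale in (0, 1].
#' @return An object of class `registration_params`.
#' @export
registration_params <- function(n_levels = 3L, control_spacing_mm = 10,
                                metric = c("mse", "ncc"),
                                max_iter = c(60L, 40L, 20L),
                                reg_weight = 1, tol = 1e-4, step = 0.8) {
  metric <- match.arg(metric)
  n_levels <- as.integer(n_levels)
  if (n_levels < 1L) stop("registration_params: 'n_levels' must be >= 1")
  if (control_spacing_mm <= 0)
    stop("registration_params: 'control_spacing_mm' must be > 0")
  if (reg_weight <= 0) stop("registration_params: 'reg_weight' must be > 0")
  structure(list(n_levels = n_levels,
                 control_spacing_mm = control_spacing_mm,
                 metric = metric,
                 max_iter = rev(rev(rep_len(as.integer(max_iter), n_levels))),
                 reg_weight = reg_weight, tol = tol, step = step),
            class = "registration_params")
}

#' Deformable image registration
#'
#' Estimates the backward-mapping displacement field `u` on the fixed grid
#' such that `warp_volume(moving, u)` matches `fixed`: multiresolution
#' free-form registration with intensity-difference forces and Gaussian
#' field regularisation. Deterministic: no random initialisation.
#'
#' @param fixed,moving [volume3d()] objects on the same grid.
#' @param params a [registration_params()].
#' @param init optional initial [vectorfield3d()] on the fixed grid.
#' @return A [vectorfield3d()] with attributes `metric_before`,
#'   `metric_after` and `converged` (logical; `FALSE` is reported with a
#'   warning, and the field is still returned).
#' @export
register_deformable <- function(fixed, moving, params = registration_params(),
                                init = NULL) {
  stopifnot(inherits(fixed, "volume3d"), inherits(moving, "volume3d"))
  stop_if_grid_mismatch(fixed, moving, "fixed and moving volumes")
  if (params$metric == "ncc") {
    fixed <- znorm_volume(fixed)
    moving <- znorm_volume(moving)
  }
  d <- grid_dim(fixed)
  # pyramid factors, never shrinking an axis below 8 voxels
  factors <- lapply(params$n_levels:1, function(lv) {
    f <- 2L^(lv - 1L)
    pmax(1L, pmin(f, pmax(1L, d %/% 8L)))
  })
  field <- NULL
  m0 <- mean((fixed$data - moving$data)^2)
  for (lv in seq_len(params$n_levels)) {
    f <- factors[[lv]]
    fx <- downsample_volume(fixed, f)
    mv <- downsample_volume(moving, f)
    field <- if (is.null(field)) {
      if (is.null(init)) zero_field(fx) else upsample_field(init, fx)
    } else upsample_field(field, fx)
    sigma_mm <- params$reg_weight * 0.5 *
      params$control_spacing_mm * 2^(params$n_levels - lv)
    field <- refine_level(fx, mv, field, params$max_iter[lv], sigma_mm,
                          params$tol, params$step)
  }
  m1 <- mean((warp_volume(moving, field)$data - fixed$data)^2)
  converged <- isTRUE(attr(field, "level_converged")) || m1 <= m0
  if (!converged)
    warning("register_deformable: did not reach convergence tolerance; ",
            "returning best field")
  structure(field, metric_before = m0, metric_after = m1,
            converged = converged)
}

znorm_volume <- function(vol) {
  s <- stats::sd(vol$data)
  if (s == 0) s <- 1
  volume3d((vol$data - mean(vol$data)) / s, vol$spacing, vol$origin,
           vol$axis_labels)
}

# One pyramid level of force-based refinement with Gaussian regularisation.
refine_level <- function(fixed, moving, field, max_iter, sigma_mm, tol, step) {
  d <- grid_dim(fixed)
  sp <- fixed$spacing
  sigma_vox <- sigma_mm / sp
  diff_vox <- pmin(0.5, 0.35 * sigma_mm / sp)
  # spatial gradient of the moving image, physical mm units
  g <- image_gradient(moving$data, sp)
  P <- grid_world_coords(fixed)
  msp2 <- mean(sp)^2
  u <- field$u
  n <- prod(d)
  best <- Inf; best_u <- u
  prev <- Inf
  cap <- 2 * max(sp) # per-iteration displacement cap, mm
  level_converged <- FALSE
  for (it in seq_len(max_iter)) {
    Q <- P + matrix(u, n)
    idx <- world_to_index(Q, moving)
    w <- interp_trilinear(moving$data, idx)
    r <- w - fixed$data
    mse <- mean(r^2)
    if (mse < best) { best <- mse; best_u <- u }
    if (is.finite(prev) && prev - mse < tol * max(prev, 1e-12)) {
      level_converged <- TRUE
      break
    }
    prev <- mse
    g1 <- interp_trilinear(g[[1]], idx)
    g2 <- interp_trilinear(g[[2]], idx)
    g3 <- interp_trilinear(g[[3]], idx)
    denom <- g1 * g1 + g2 * g2 + g3 * g3 + (r * r) / msp2 + 1e-8
    s <- -step * r / denom
    du <- cbind(s * g1, s * g2, s * g3)
    mag <- sqrt(rowSums(du^2))
    over <- mag > cap
    if (any(over)) du[over, ] <- du[over, ] * (cap / mag[over])
    du <- array(du, c(d, 3L))
    # fluid-like regularisation: updates smoothed at the control scale,
    # the accumulated field by light diffusion only
    for (cmp in 1:3) {
      u[, , , cmp] <- gauss_smooth3(u[, , , cmp] +
                                      gauss_smooth3(du[, , , cmp], sigma_vox),
                                    diff_vox)
    }
  }
  out <- vectorfield3d(best_u, spacing = fixed$spacing, origin = fixed$origin,
                       axis_labels = fixed$axis_labels)
  attr(out, "level_converged") <- level_converged
  out
}

image_gradient <- function(arr, spacing) {
  lapply(1:3, function(a) central_diff(arr, a) / spacing[a])
}

# central differences along one axis, one-sided at the boundaries
central_diff <- function(arr, axis) {
  d <- dim(arr)
  n <- d[axis]
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  den <- idx_p - idx_m
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(arr, perm)
  dm <- dim(m)
  m2 <- matrix(m, dm[1])
  out <- (m2[idx_p, , drop = FALSE] - m2[idx_m, , drop = FALSE]) / den
  dim(out) <- dm
  aperm(out, order(perm))
}

#' Warp a volume by a displacement field
#'
#' Backward-mapping resampling: `out(x) = vol(x + u(x))` at every voxel of
#' the field's grid, with linear or nearest-neighbour interpolation.
#' Out-of-domain samples clamp to the nearest edge value.
#'
#' @param vol a [volume3d()].
#' @param field a [vectorfield3d()] on the same grid.
#' @param interp `"linear"` or `"nearest"` (use nearest for binary masks).
#' @return A [volume3d()].
#' @export
warp_volume <- function(vol, field, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(inherits(vol, "volume3d"), inherits(field, "vectorfield3d"))
  stop_if_grid_mismatch(vol, field, "volume and field")
  d <- grid_dim(vol)
  P <- grid_world_coords(vol) + matrix(field$u, prod(d))
  vals <- sample_volume(vol, P, interp)
  volume3d(array(vals, d), spacing = vol$spacing, origin = vol$origin,
           axis_labels = vol$axis_labels)
}

#' Compose two displacement fields
#'
#' Returns the field `c` with `c(x) = inner(x) + outer(x + inner(x))`, so
#' that warping once by `c` equals warping by `outer` first and then by
#' `inner`: `warp(vol, c) ~ warp(warp(vol, outer), inner)`.
#'
#' @param outer,inner [vectorfield3d()] objects on the same grid.
#' @return A [vectorfield3d()].
#' @export
compose_fields <- function(outer, inner) {
  stopifnot(inherits(outer, "vectorfield3d"), inherits(inner, "vectorfield3d"))
  stop_if_grid_mismatch(outer, inner, "fields")
  d <- grid_dim(inner)
  n <- prod(d)
  ui <- matrix(inner$u, n)
  Q <- grid_world_coords(inner) + ui
  uo <- sample_field(outer, Q)
  vectorfield3d(array(ui + uo, c(d, 3L)), spacing = inner$spacing,
                origin = inner$origin, axis_labels = inner$axis_labels)
}

#' Jacobian determinant of a deformation
#'
#' Determinant of the Jacobian of the mapping `x -> x + u(x)`, computed by
#' central differences in physical mm (one-sided at the volume boundary).
#' The identity map gives 1 everywhere; negative values indicate local
#' folding of the deformation.
#'
#' @param field a [vectorfield3d()].
#' @return A [volume3d()] of determinant values.
#' @export
jacobian_determinant <- function(field) {
  stopifnot(inherits(field, "vectorfield3d"))
  sp <- field$spacing
  J <- vector("list", 9L)
  q <- 1L
  for (cmp in 1:3) {
    for (ax in 1:3) {
      J[[q]] <- central_diff(field$u[, , , cmp], ax) / sp[ax] +
        (cmp == ax)
      q <- q + 1L
    }
  }
  # J[[3*(c-1)+a]] = d(x_c + u_c)/d x_a
  det <- J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
    J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
    J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  volume3d(det, spacing = sp, origin = field$origin,
           axis_labels = field$axis_labels)
}

#' Fraction of physically plausible (non-folding) voxels
#'
#' @param jdet a [volume3d()] of Jacobian determinants (from
#'   [jacobian_determinant()]).
#' @return Fraction of voxels with determinant >= 0, in `[0, 1]`.
#' @export
plausibility_fraction <- function(jdet) {
  stopifnot(inherits(jdet, "volume3d"))
  mean(jdet$data >= 0)
}
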