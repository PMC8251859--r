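test_that("warping follows the backward-mapping contract", {
  set.seed(2)
  a <- array(0, c(20, 20, 12))
  vol <- volume3d(a, spacing = c(1, 1, 1))
  P <- grid_world_coords(vol)
  vol$data[] <- 50 * exp(-rowSums(sweep(P, 2, c(10, 8, 6))^2) / 18) +
    20 * exp(-rowSums(sweep(P, 2, c(5, 12, 4))^2) / 8)
  # zero field: identity
  expect_identical(warp_volume(vol, zero_field(vol))$data, vol$data)
  # constant field on a shifted copy recovers the original (oracle: direct
  # integer reindexing builds the shifted copy)
  shifted <- vol
  shifted$data <- vol$data[, , c(6:12, rep(12, 5))] # content moved -5 in RL
  cst <- zero_field(vol); cst$u[, , , 3] <- -5
  rec <- warp_volume(shifted, cst)
  expect_equal(rec$data[, , 6:12], vol$data[, , 6:12], tolerance = 1e-12)
  # nearest interpolation keeps a binary mask binary
  mask <- vol; mask$data <- array(as.numeric(vol$data > 10), dim(a))
  sm <- zero_field(vol); sm$u[] <- 0.4
  wm <- warp_volume(mask, sm, interp = "nearest")
  expect_true(all(wm$data %in% c(0, 1)))
})

test_that("field composition matches its closed forms and sequential warps", {
  d <- c(14, 12, 10)
  zf <- vectorfield3d(array(0, c(d, 3)), spacing = c(1, 1, 1))
  u <- zf; u$u[, , , 1] <- 1; u$u[, , , 2] <- -1
  v <- zf; v$u[, , , 2] <- 1; v$u[, , , 3] <- 0.5
  expect_identical(compose_fields(u, zf)$u, u$u) # compose(u, 0) = u
  expect_identical(compose_fields(zf, v)$u, v$u) # compose(0, v) = v
  ab <- compose_fields(u, v)
  expect_equal(ab$u, u$u + v$u) # constants add
  # warp equivalence on a smooth random field
  set.seed(4)
  vol <- volume3d(array(0, d), spacing = c(1, 1, 1))
  P <- grid_world_coords(vol)
  vol$data[] <- 30 * exp(-rowSums(sweep(P, 2, c(7, 6, 5))^2) / 20)
  w2 <- warp_volume(warp_volume(vol, u), v)
  w1 <- warp_volume(vol, compose_fields(u, v))
  inner <- w1$data[3:12, 3:10, 3:8]
  expect_equal(inner, w2$data[3:12, 3:10, 3:8], tolerance = 1e-8)
})

test_that("Jacobian determinants match closed forms", {
  d <- c(12, 11, 9)
  zf <- vectorfield3d(array(0, c(d, 3)), spacing = c(1.33, 1.33, 5))
  expect_equal(jacobian_determinant(zf)$data, array(1, d))
  cst <- zf; cst$u[, , , 1] <- 4; cst$u[, , , 3] <- -2
  expect_equal(jacobian_determinant(cst)$data, array(1, d))
  # u = (alpha * x, 0, 0) -> det = 1 + alpha everywhere (linear field,
  # central differences are exact)
  P <- grid_world_coords(zf)
  lin <- zf; lin$u[, , , 1] <- array(0.1 * P[, 1], d)
  expect_equal(jacobian_determinant(lin)$data, array(1.1, d),
               tolerance = 1e-9)
  # random small affine field vs analytic det(I + A), interior voxels
  set.seed(9)
  A <- matrix(rnorm(9, sd = 0.05), 3)
  aff <- zf
  for (cmp in 1:3) aff$u[, , , cmp] <- array(P %*% A[cmp, ], d)
  jd <- jacobian_determinant(aff)$data
  expect_equal(jd[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)],
               array(det(diag(3) + A), d - 2), tolerance = 1e-6)
})

test_that("plausibility fraction counts folded voxels", {
  d <- c(10, 10, 10)
  zf <- vectorfield3d(array(0, c(d, 3)), spacing = c(1, 1, 1))
  expect_equal(plausibility_fraction(jacobian_determinant(zf)), 1.0)
  # a single spike folds exactly one voxel: du1/dx = -2 at its +x neighbour
  sp <- zf; sp$u[5, 5, 5, 1] <- 4
  jd <- jacobian_determinant(sp)
  expect_equal(sum(jd$data < 0), 1L)
  expect_equal(plausibility_fraction(jd), 0.999)
})

test_that("registration is exact on identity and recovers phantom deformation", {
  pair <- small_pair_clean()
  s1 <- pair$S1
  u0 <- register_deformable(s1$reference, s1$reference)
  expect_lt(mean(field_magnitude(u0)), 0.1 * min(s1$reference$spacing))
  k <- which.max(s1$truth$bin_scale$R1)
  u <- register_deformable(fixed = s1$fourD$R1[[k]], moving = s1$reference)
  expect_lte(attr(u, "metric_after"), attr(u, "metric_before"))
  tr <- phantom_truth_dvf(s1, "R1", k - 1L)
  err <- respmotion:::dvf_error_mm(u, tr)
  expect_lt(median(err), 2 * 1.33) # within two in-plane voxels
  # physically plausible deformation
  expect_gt(plausibility_fraction(jacobian_determinant(u)), 0.99)
  expect_error(register_deformable(s1$reference,
                                   volume3d(array(0, c(10, 10, 5)))),
               "geometry mismatch")
})

test_that("forward and backward registrations are approximately inverse", {
  pair <- small_pair_clean()
  s1 <- pair$S1
  k <- which.max(s1$truth$bin_scale$R1)
  ab <- register_deformable(s1$fourD$R1[[k]], s1$reference)
  ba <- register_deformable(s1$reference, s1$fourD$R1[[k]])
  resid <- compose_fields(ab, ba) # should be near identity
  # soft inverse-consistency: mean residual below one in-plane voxel
  expect_lt(mean(field_magnitude(resid)), 1.33)
})
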