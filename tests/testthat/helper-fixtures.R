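# Shared fixtures, built lazily and cached for the whole test run.
.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# Desk-scale phantom used by the unit tests: 48 x 48 x 13 voxels at the
# standard spacing, 4 bins, short cine.
small_cfg <- function(...) {
  args <- utils::modifyList(list(grid_shape = c(48, 48, 13), n_bins = 4,
                                 cine_duration_s = 15, seed = 7),
                            list(...))
  do.call(phantom_config, args)
}

small_pair <- function() fixture("small_pair", function()
  generate_session_pair(small_cfg()))

# noiseless variant for exactness-style checks
small_pair_clean <- function() fixture("small_pair_clean", function()
  generate_session_pair(small_cfg(noise_sd = 0)))

small_model <- function() fixture("small_model", function()
  motion_model(small_pair_clean()$S1$fourD$R1,
               sag_index = small_pair_clean()$S1$cine$sag_rl_index))

# mean-free textured 2D frame for tracking tests
textured_frame <- function(n = 48, seed = 1) {
  set.seed(seed)
  f <- matrix(0, n, n)
  for (q in 1:12) {
    cx <- runif(1, 8, n - 8); cy <- runif(1, 8, n - 8)
    sg <- runif(1, 1.5, 4)
    f <- f + runif(1, -40, 60) *
      exp(-(outer((1:n - cx)^2, (1:n - cy)^2, "+")) / (2 * sg^2))
  }
  f
}

# shift a matrix by integer pixels with edge replication
shift_frame <- function(f, dx, dy) {
  n <- dim(f)
  f[pmin(pmax(seq_len(n[1]) + dx, 1L), n[1]),
    pmin(pmax(seq_len(n[2]) + dy, 1L), n[2])]
}

# minimal cine-like container around a list of sagittal frames
as_cine <- function(frames, dt = 0.25, spacing = c(1, 1)) {
  list(frames = frames, t = (seq_along(frames) - 1) * dt,
       plane = rep("sagittal", length(frames)),
       sag_spacing = spacing, cor_spacing = spacing,
       sag_rl_index = 0L, cor_ap_index = 0L)
}

field_magnitude <- function(field) {
  sqrt(field$u[, , , 1]^2 + field$u[, , , 2]^2 + field$u[, , , 3]^2)
}

# voxels far from intensity edges: strong-gradient voxels dilated by a
# configurable radius (voxels per axis); widen by the motion extent when
# comparing warped volumes so edge interpolation error is excluded
away_from_edges <- function(vol, grad_thr = 1.0, dil_vox = c(2, 2, 1)) {
  g2 <- 0
  for (a in 1:3)
    g2 <- g2 + (respmotion:::central_diff(vol$data, a) / vol$spacing[a])^2
  hi <- array(sqrt(g2) > grad_thr, dim(vol$data))
  dil <- hi
  for (dx in -dil_vox[1]:dil_vox[1])
    for (dy in -dil_vox[2]:dil_vox[2])
      for (dz in -dil_vox[3]:dil_vox[3])
        dil <- dil | respmotion:::shift3(hi, c(dx, dy, dz))
  !dil
}
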