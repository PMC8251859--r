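test_that("breathing waveform is a normalised, periodic, exhale-weighted cycle", {
  tt <- seq(0, 4, by = 0.001)
  s <- breathing_waveform(tt, period = 4, exhale_fraction = 0.6)
  expect_equal(breathing_waveform(0, 4), 0)
  expect_equal(breathing_waveform(4, 4), 0)
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(max(s), 0.999999) # single maximum of 1 per cycle
  expect_equal(sum(diff(sign(diff(s))) < 0), 1L)
  # peak sits at elapsed fraction 1 - exhale_fraction
  expect_equal(tt[which.max(s)], 4 * (1 - 0.6), tolerance = 1e-2)
  # periodicity and continuity
  expect_equal(s, breathing_waveform(tt + 8, 4, 0.6))
  expect_lt(max(abs(diff(s))), 0.01)
  # exhale dwell dominates the inhale dwell
  expect_gt(mean(s < 0.2), mean(s > 0.8) + 0.1)
  expect_error(breathing_waveform(1, 0), "period")
  expect_error(breathing_waveform(1, -2), "period")
  expect_error(breathing_waveform(1, 4, exhale_fraction = 1.2), "exhale")
})

test_that("phantom config validates its invariants", {
  expect_error(phantom_config(n_bins = 1), "n_bins")
  expect_error(phantom_config(spacing_mm = c(1.33, 0, 5)), "spacing")
  expect_error(phantom_config(cycle_amp_sd = -0.1), "variability")
  expect_error(phantom_config(breath_period_s = 0), "period")
  expect_error(phantom_config(grid_shape = c(8, 8, 4)), "too small")
  cfg <- phantom_config()
  expect_identical(cfg$n_bins, 8L)
  expect_equal(cfg$spacing_mm, c(1.33, 1.33, 5.0))
  expect_equal(cfg$cine_dt_s, 0.230)
})

test_that("ground-truth deformation is a scaled envelope with the configured peak", {
  pair <- small_pair_clean()
  s1 <- pair$S1
  f0 <- true_dvf(s1, s = 0)
  expect_equal(max(abs(f0$u)), 0)
  f_half <- true_dvf(s1, s = 0.5)
  f_full <- true_dvf(s1, s = 1)
  expect_equal(f_half$u, 0.5 * f_full$u) # separability in the state scale
  # peak SI displacement equals si_amplitude at unit scale, AP is the
  # configured fraction of it, RL is zero
  expect_equal(max(abs(f_full$u[, , , 2])), pair$config$si_amplitude_mm)
  expect_equal(max(abs(f_full$u[, , , 1])),
               pair$config$ap_fraction * pair$config$si_amplitude_mm)
  expect_equal(max(abs(f_full$u[, , , 3])), 0)
  # compact support: zero on the volume boundary
  expect_equal(max(abs(f_full$u[1, , , ])), 0)
  expect_equal(max(abs(f_full$u[, dim(f_full$u)[2], , ])), 0)
})

test_that("session generation is deterministic and responds to its variability knobs", {
  cfg <- small_cfg()
  p1 <- generate_session_pair(cfg)
  p2 <- generate_session_pair(cfg)
  expect_identical(p1$S1$fourD$R1[[3]]$data, p2$S1$fourD$R1[[3]]$data)
  expect_identical(p1$S2$cine$frames, p2$S2$cine$frames)
  expect_identical(p1$S1$truth$bin_scale, p2$S1$truth$bin_scale)
  # no variability sources -> the two sessions' 4DMRIs coincide voxelwise
  cfg0 <- small_cfg(cycle_amp_sd = 0, cycle_period_sd_s = 0,
                    baseline_shift_mm = c(0, 0, 0), noise_sd = 0)
  q <- generate_session_pair(cfg0)
  for (k in seq_len(cfg0$n_bins))
    expect_equal(q$S1$fourD$R1[[k]]$data, q$S2$fourD$R1[[k]]$data)
  expect_equal(q$S1$fourD$R1[[2]]$data, q$S1$fourD$R2[[2]]$data)
})

test_that("inter-session baseline shift moves the tumour COM by the configured amount", {
  cfg <- small_cfg(baseline_shift_mm = c(0, 8, 0), noise_sd = 0)
  pair <- generate_session_pair(cfg)
  m1 <- respmotion:::as_mask_volume(pair$S1$truth$mask_ref, pair$S1$reference)
  m2 <- respmotion:::as_mask_volume(pair$S2$truth$mask_ref, pair$S2$reference)
  expect_equal(com_distance(m1, m2), 8, tolerance = 0.5 * 1.33 / 8)
  # direction: superior-inferior
  c1 <- respmotion:::mask_com(m1); c2 <- respmotion:::mask_com(m2)
  expect_equal(abs(c2[2] - c1[2]), 8, tolerance = 0.67)
  expect_lt(abs(c2[1] - c1[1]), 0.67)
  # the truth baseline field is the constant backward shift
  expect_equal(max(abs(pair$S2$truth$baseline$u[, , , 2] + 8)), 0)
})

test_that("per-cycle amplitude multipliers are positive with the configured spread", {
  cfg <- phantom_config(grid_shape = c(40, 40, 10), n_bins = 4,
                        cine_duration_s = 220, noise_sd = 0, seed = 21)
  pair <- generate_session_pair(cfg)
  cyc <- pair$S1$cine$cycles
  expect_gte(nrow(cyc), 50L)
  expect_true(all(cyc$amp > 0))
  expect_true(all(cyc$period_s > 0))
  expect_lt(abs(sd(cyc$amp) - cfg$cycle_amp_sd), 0.2 * cfg$cycle_amp_sd)
  expect_lt(abs(mean(cyc$amp) - 1), 0.05)
})

test_that("warping the reference by the truth DVF reproduces the generated bin", {
  pair <- small_pair_clean()
  s1 <- pair$S1
  dr <- diff(range(s1$reference$data))
  for (k in c(2L, which.max(s1$truth$bin_scale$R1))) {
    tdvf <- phantom_truth_dvf(s1, "R1", k - 1L)
    w <- warp_volume(s1$reference, tdvf)
    diffv <- abs(w$data - s1$fourD$R1[[k]]$data)
    # exclude voxels whose warped sample position is near an edge
    motion_vox <- ceiling(apply(abs(matrix(tdvf$u, ncol = 3)), 2,
                                max) / s1$reference$spacing)
    away <- away_from_edges(s1$reference,
                            dil_vox = c(2, 2, 1) + motion_vox)
    expect_gt(mean(away), 0.15) # the check covers a substantial region
    expect_lt(max(diffv[away]) / dr, 0.02)
    expect_lt(median(diffv) / dr, 0.005)
  }
})

test_that("cine series alternates planes, samples the continuous state and matches the reference at s = 0", {
  pair <- small_pair_clean()
  cine <- extract_cine_frames(pair$S1)
  cfg <- pair$config
  expect_length(cine$frames, floor(cfg$cine_duration_s / cfg$cine_dt_s))
  expect_identical(unique(cine$plane[c(TRUE, FALSE)]), "sagittal")
  expect_identical(unique(cine$plane[c(FALSE, TRUE)]), "coronal")
  expect_equal(diff(cine$t), rep(cfg$cine_dt_s, length(cine$t) - 1))
  # frame 0 is at t = 0, end-exhale: equals the reference slice exactly
  expect_equal(cine$state$s[1], 0)
  expect_equal(cine$frames[[1]],
               pair$S1$reference$data[, , cine$sag_rl_index + 1L])
})

test_that("a static phantom produces identical cine frames", {
  cfg <- small_cfg(si_amplitude_mm = 0, noise_sd = 0, cine_duration_s = 5)
  pair <- generate_session_pair(cfg)
  cine <- extract_cine_frames(pair$S1)
  sag <- cine$frames[cine$plane == "sagittal"]
  for (f in sag[-1]) expect_identical(f, sag[[1]])
})

test_that("phantom scenes carry enough texture features for keypoint detection", {
  pair <- small_pair()
  expect_gte(nrow(pair$scene$blobs), 30L)
  kp <- detect_keypoints(pair$S1$reference)
  expect_gte(nrow(kp), 15L)
})

test_that("a phantom study round-trips through its on-disk layout", {
  dir <- withr::local_tempdir()
  pair <- small_pair_clean()
  write_phantom(pair, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  v <- read_volume(file.path(dir, "S1", "R1_bin01.nii.gz"))
  expect_equal(v$data, pair$S1$fourD$R1[[2]]$data, tolerance = 1e-7)
  d <- read_dvf(file.path(dir, "S1", "truth_dvf_R1_bin01.nii.gz"))
  expect_equal(d$u, phantom_truth_dvf(pair$S1, "R1", 1L)$u, tolerance = 1e-6)
  lm <- read_landmarks(file.path(dir, "S2", "landmarks_truth.csv"))
  expect_true(all(lm$plane %in% c("sagittal", "coronal")))
  bl <- read_dvf(file.path(dir, "S2", "truth_baseline.nii.gz"))
  expect_equal(bl$u, pair$S2$truth$baseline$u, tolerance = 1e-6)
})
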