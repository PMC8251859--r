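test_that("median/IQR summaries follow the linear-interpolation quantile rule", {
  expect_equal(summarize_mm(c(1, 2, 3)), c(median = 2, iqr = 1))
  expect_equal(summarize_mm(5), c(median = 5, iqr = 0))
  # oracle: direct linear interpolation between order statistics
  x <- c(1, 1, 1, 100)
  xs <- sort(x)
  q_at <- function(p) {
    h <- p * (length(xs) - 1) + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }
  expect_equal(summarize_mm(x),
               c(median = q_at(0.5), iqr = q_at(0.75) - q_at(0.25)))
  expect_equal(unname(summarize_mm(x)["median"]), 1)
  expect_error(summarize_mm(numeric()), "samples")
  expect_error(summarize_mm(NA_real_), "samples")
})

sphere_mask <- function(centre, radius = 6, dims = c(30, 30, 12),
                        spacing = c(1.33, 1.33, 5)) {
  vol <- volume3d(array(0, dims), spacing = spacing)
  P <- grid_world_coords(vol)
  vol$data[] <- as.numeric(rowSums(sweep(P, 2, centre)^2) <= radius^2)
  vol
}

test_that("centre-of-mass distances behave like Euclidean metrics on masks", {
  a <- sphere_mask(c(18, 18, 30))
  expect_equal(com_distance(a, a), 0)
  b <- sphere_mask(c(18, 23, 30)) # 5 mm SI shift
  expect_equal(com_distance(a, b), 5, tolerance = 0.665 / 5)
  expect_equal(com_distance(a, b), com_distance(b, a))
  empty <- a; empty$data[] <- 0
  expect_error(com_distance(a, empty), "empty")
})

test_that("DIR validation reports near-zero residual for truth fields and motion-scale residual for zero fields", {
  pair <- small_pair_clean()
  s1 <- pair$S1
  k <- which.max(s1$truth$bin_scale$R1)
  truth <- phantom_truth_dvf(s1, "R1", k - 1L)
  cases <- list(
    list(name = "truth", fixed = s1$fourD$R1[[k]], moving = s1$reference,
         dvf = truth, truth_dvf = truth),
    list(name = "zero", fixed = s1$fourD$R1[[k]], moving = s1$reference,
         dvf = zero_field(s1$reference), truth_dvf = truth))
  rep <- dir_validation(cases)
  expect_identical(nrow(rep), 4L) # one row per case and method
  r_truth <- rep[rep$name == "truth" & rep$method == "keypoints", ]
  r_zero <- rep[rep$name == "zero" & rep$method == "keypoints", ]
  # perfect registration limit: residual below one in-plane voxel
  expect_lt(r_truth$median_mm, 1.33)
  # no registration: residual reflects the motion, well above the truth row
  expect_gt(r_zero$median_mm, 2 * r_truth$median_mm + 1)
  # truth-route rows: zero error for the truth field, motion scale for zero
  t_truth <- rep[rep$name == "truth" & rep$method == "truth", ]
  t_zero <- rep[rep$name == "zero" & rep$method == "truth", ]
  expect_equal(t_truth$median_mm, 0)
  expect_gt(t_zero$median_mm, 1)
})

test_that("3D validation in the perfect-model limit drives errors below one voxel", {
  pair <- small_pair_clean()
  s1 <- pair$S1
  model <- small_model()
  # replace the estimated library by the phantom ground truth
  truth_model <- model
  truth_model$library <- lapply(seq_along(model$library) - 1L, function(k)
    phantom_truth_dvf(s1, "R2", k))
  samples <- data.frame(phase = bin_phases_of_building(4), amplitude = 1)
  truth <- list(dvf = lapply(0:3, phantom_truth_dvf, session = s1,
                             acq = "R2"),
                masks = s1$truth$masks$R2)
  mask_ref <- respmotion:::as_mask_volume(s1$truth$mask_ref, s1$reference)
  rep <- validate_3d(truth_model, s1$fourD$R2, samples, mask_ref,
                     truth = truth)
  sm <- rep$summary
  expect_lt(sm$median_mm[sm$metric == "point_error"], 1.33)
  expect_lt(sm$median_mm[sm$metric == "com_error"], 1.33)
  expect_equal(sm$median_mm[sm$metric == "truth_error"], 0, tolerance = 1e-9)
  # report structure: one samples row per bin with Jacobian plausibility
  expect_identical(nrow(rep$samples), 4L)
  expect_true(all(rep$jacobian > 0.99))
})

test_that("zero-amplitude estimation reproduces the range of motion (no-model baseline)", {
  pair <- small_pair_clean()
  s1 <- pair$S1
  model <- small_model()
  samples <- data.frame(phase = bin_phases_of_building(4), amplitude = 0)
  truth <- list(dvf = lapply(0:3, phantom_truth_dvf, session = s1,
                             acq = "R2"),
                masks = s1$truth$masks$R2)
  mask_ref <- respmotion:::as_mask_volume(s1$truth$mask_ref, s1$reference)
  rep <- validate_3d(model, s1$fourD$R2, samples, mask_ref, truth = truth)
  sm <- rep$summary
  k_ei <- rep$end_inhale_bin + 1L
  com_ei <- rep$samples$com_mm[k_ei]
  rom_com <- sm$median_mm[sm$metric == "rom_com"]
  # without the model, the end-inhale error equals the motion to compensate
  expect_equal(com_ei, rom_com, tolerance = 0.672 / max(rom_com, 1))
  expect_gt(rep$samples$truth_median_mm[k_ei], 2)
})

test_that("2D validation tracks landmarks and reports the three cine metrics", {
  # without cycle-amplitude variability the cine motion must match the
  # motion described by the building 4DMRI
  pair <- fixture("pair_novar", function()
    generate_session_pair(small_cfg(cycle_amp_sd = 0,
                                    cycle_period_sd_s = 0, noise_sd = 0)))
  s1 <- pair$S1
  model <- small_model()
  cine <- extract_cine_frames(s1)
  sig <- extract_signal(cine)
  samples_all <- to_phase_amplitude(sig, model$building_peak_mm, 4,
                                    mean_period_s = 4)
  samples <- respmotion:::expand_samples_to_frames(samples_all, cine, 4)
  lm <- s1$landmarks$ref
  lms0 <- data.frame(id = lm$id, plane = lm$plane,
                     x_mm = ifelse(lm$plane == "sagittal", lm$ap, lm$si),
                     y_mm = ifelse(lm$plane == "sagittal", lm$si, lm$rl))
  # sagittal only: the small grid leaves just the dome-edge landmark on the
  # coronal plane, where template sliding along the edge dominates
  rep <- validate_2d(model, cine, lms0, s1$fourD$R1, samples,
                     planes = "sagittal")
  sm <- rep$summary
  expect_true(all(c("cine_error", "cine_motion", "fourD_motion") %in%
                    sm$metric))
  # no cycle variability: cine motion matches the 4DMRI motion within a
  # voxel
  cm <- sm$median_mm[sm$metric == "cine_motion"]
  fm <- sm$median_mm[sm$metric == "fourD_motion"]
  expect_lt(abs(cm - fm), 1.33)
  # estimation error stays below the described motion
  expect_lt(sm$median_mm[sm$metric == "cine_error"], cm)
  expect_true(all(rep$jacobian > 0.99))
})

test_that("a static cine yields zero cine-motion", {
  cfg <- small_cfg(si_amplitude_mm = 0, noise_sd = 0, cine_duration_s = 5)
  pair <- generate_session_pair(cfg)
  s1 <- pair$S1
  cine <- extract_cine_frames(s1)
  model <- small_model()
  samples <- data.frame(frame = seq_along(cine$frames) - 1L, t_s = cine$t,
                        phase = 0, amplitude = 0, valid = TRUE)
  lm <- s1$landmarks$ref
  lms0 <- data.frame(id = lm$id, plane = lm$plane,
                     x_mm = ifelse(lm$plane == "sagittal", lm$ap, lm$si),
                     y_mm = ifelse(lm$plane == "sagittal", lm$si, lm$rl))
  # building 4D of the same static phantom: bins all equal the reference
  rep <- validate_2d(model, cine, lms0, pair$S1$fourD$R1, samples)
  cm <- rep$samples$value_mm[rep$samples$metric == "cine_motion"]
  expect_true(all(cm == 0))
})
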