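test_that("model building yields a zero bin-0 field and a full library", {
  model <- small_model()
  n <- length(model$library)
  expect_identical(n, small_pair_clean()$config$n_bins)
  expect_equal(max(abs(model$library[[1]]$u)), 0)
  expect_identical(model$bin_phases, 0:(n - 1L))
  expect_gt(model$building_peak_mm, 0)
  expect_null(model$baseline)
  # library fields recover the phantom truth within two in-plane voxels
  s1 <- small_pair_clean()$S1
  for (k in 2:n) {
    err <- respmotion:::dvf_error_mm(model$library[[k]],
                                     phantom_truth_dvf(s1, "R1", k - 1L))
    expect_lt(median(err), 2 * 1.33)
  }
})

test_that("a motionless 4DMRI builds a near-identity library", {
  ref <- small_pair_clean()$S1$reference
  fourD <- replicate(3, ref, simplify = FALSE)
  expect_warning(model <- motion_model(fourD), "surrogate")
  for (k in 2:3)
    expect_lt(mean(field_magnitude(model$library[[k]])),
              0.1 * min(ref$spacing))
})

test_that("DVF estimation is exact at the library anchors and linear in amplitude", {
  model <- small_model()
  n <- length(model$library)
  # integer phase, amplitude 1: the stored field, exactly
  for (k in c(0, 2)) {
    est <- estimate_dvf(model, phase = k, amplitude = 1)
    expect_identical(est$u, model$library[[k + 1L]]$u)
  }
  # amplitude 0: zero field
  expect_equal(max(abs(estimate_dvf(model, 1.7, 0)$u)), 0)
  # half phase: voxelwise mean of the neighbours
  est <- estimate_dvf(model, 1.5, 1)
  expect_equal(est$u, 0.5 * (model$library[[2]]$u + model$library[[3]]$u))
  # amplitude linearity, exact
  e1 <- estimate_dvf(model, 2.3, 0.4)
  e2 <- estimate_dvf(model, 2.3, 0.8)
  expect_equal(e2$u, 2 * e1$u)
  # circular continuity across the wrap
  near_wrap <- estimate_dvf(model, n - 1e-7, 1)
  at0 <- estimate_dvf(model, 0, 1)
  expect_lt(max(abs(near_wrap$u - at0$u)), 1e-4)
  # clipping
  expect_warning(estimate_dvf(model, 1, 5), "clip")
})

test_that("interpolated DVF magnitudes stay within the neighbouring library fields", {
  model <- small_model()
  for (ph in c(0.25, 1.5, 2.75)) {
    k <- floor(ph)
    est <- field_magnitude(estimate_dvf(model, ph, 1))
    cap <- pmax(field_magnitude(model$library[[k + 1L]]),
                field_magnitude(model$library[[(k + 1L) %% length(model$library) + 1L]]))
    expect_true(all(est <= cap + 1e-9))
  }
})

test_that("volume estimation returns the active reference bit-identically at amplitude 0", {
  model <- small_model()
  est <- estimate_volume(model, 0.8, 0)
  expect_identical(est$data, model$reference$data)
  expect_equal(max(abs(attr(est, "dvf")$u)), 0)
  # with a baseline: the updated reference
  s2 <- small_pair_clean()$S2
  model_b <- update_baseline(model, s2$fourD$R1[[1]])
  est_b <- estimate_volume(model_b, 0.8, 0)
  expect_identical(est_b$data, model_b$updated_reference$data)
})

test_that("baseline update is an identity on the reference itself and replaces on re-run", {
  model <- small_model()
  m_id <- update_baseline(model, model$reference)
  expect_lt(mean(field_magnitude(m_id$baseline)),
            0.1 * min(model$reference$spacing))
  expect_equal(m_id$updated_reference$data, model$reference$data,
               tolerance = 0.02 * diff(range(model$reference$data)))
  # library untouched
  expect_identical(m_id$library, model$library)
  # phantom baseline shift is recovered
  pair <- fixture("pair_shift8", function()
    generate_session_pair(small_cfg(baseline_shift_mm = c(0, 8, 0),
                                    noise_sd = 0)))
  mod <- motion_model(pair$S1$fourD$R1,
                      sag_index = pair$S1$cine$sag_rl_index)
  mb <- update_baseline(mod, pair$S2$fourD$R1[[1]])
  object <- pair$S2$reference$data > 45 # liver and tumour
  err <- respmotion:::dvf_error_mm(mb$baseline, pair$S2$truth$baseline,
                                   region = object)
  expect_lt(median(err), 1.33)
  # calling twice replaces, not composes
  mb2 <- update_baseline(mb, pair$S2$fourD$R1[[1]])
  expect_equal(mb2$baseline$u, mb$baseline$u)
})

test_that("predict dispatches on type and vectorises over samples", {
  model <- small_model()
  d <- predict(model, phase = 1, amplitude = 1, type = "dvf")
  expect_s3_class(d, "vectorfield3d")
  expect_identical(d$u, model$library[[2]]$u)
  vols <- predict(model, phase = c(0, 1), amplitude = c(0, 1))
  expect_length(vols, 2L)
  expect_identical(vols[[1]]$data, model$reference$data)
})

test_that("motion models persist to a directory and restore equivalently", {
  dir <- withr::local_tempdir()
  model <- small_model()
  save_motion_model(model, dir)
  back <- load_motion_model(dir)
  expect_equal(back$reference$data, model$reference$data, tolerance = 1e-7)
  expect_equal(back$building_peak_mm, model$building_peak_mm)
  expect_length(back$library, length(model$library))
  expect_equal(estimate_dvf(back, 1.5, 0.7)$u,
               estimate_dvf(model, 1.5, 0.7)$u, tolerance = 1e-6)
})
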