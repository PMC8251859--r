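test_that("surrogate extraction returns zero displacement on static frames and exact integer shifts", {
  f0 <- textured_frame(48, seed = 11)
  cine <- as_cine(replicate(6, f0, simplify = FALSE))
  sig <- extract_signal(cine)
  expect_s3_class(sig, "surrogate_signal")
  expect_equal(sig$displacement_mm, rep(0, 6))
  expect_true(all(sig$valid))
  # frames displaced by known integer SI shifts -> recovered exactly
  # (oracle: the exhaustive NCC search itself)
  shifts <- c(0, 3, -2, 5, 1, 0)
  frames <- lapply(shifts, function(s) shift_frame(f0, 0, -s))
  sig2 <- extract_signal(as_cine(frames), params = list(subpixel = FALSE))
  expect_equal(sig2$displacement_mm, shifts)
})

test_that("surrogate extraction fails informatively when no frame matches", {
  set.seed(13)
  frames <- replicate(5, matrix(rnorm(48 * 48), 48), simplify = FALSE)
  expect_error(extract_signal(as_cine(frames),
                              params = list(score_threshold = 0.99)),
               "surrogate")
  expect_error(extract_signal(as_cine(list(textured_frame(48)))),
               "at least 2")
})

test_that("phase/amplitude conversion follows the trough and peak conventions", {
  # symmetric breathing trace, 3 cycles of period 4 s, peak 10 mm
  t <- seq(0, 12, by = 0.1)
  disp <- 10 * sin(pi * ((t / 4) %% 1))^2
  sig <- structure(data.frame(frame = seq_along(t) - 1L, t_s = t,
                              displacement_mm = disp, score = 1,
                              valid = TRUE),
                   class = c("surrogate_signal", "data.frame"))
  smp <- to_phase_amplitude(sig, building_peak_mm = 10, n_bins = 4,
                            mean_period_s = 4)
  # trough sample: amplitude 0, phase 0
  i_tr <- which(t == 4)
  expect_equal(smp$amplitude[i_tr], 0)
  expect_equal(smp$phase[i_tr], 0)
  # peak equal to the building peak: amplitude 1, mid-cycle phase
  i_pk <- which(t == 6)
  expect_equal(smp$amplitude[i_pk], 1, tolerance = 1e-6)
  expect_equal(smp$phase[i_pk], 2, tolerance = 0.05)
  # inhale and exhale samples of equal depth get distinct phases
  i_in <- which(t == 5); i_ex <- which(t == 7)
  expect_equal(smp$amplitude[i_in], smp$amplitude[i_ex], tolerance = 1e-6)
  expect_gt(abs(smp$phase[i_ex] - smp$phase[i_in]), 1)
  expect_error(to_phase_amplitude(sig, building_peak_mm = 0, n_bins = 4),
               "building_peak_mm")
  # fewer than one complete cycle
  mono <- sig[t <= 2, ]
  expect_error(to_phase_amplitude(mono, 10, 4), "cycle")
})

test_that("signal orientation makes inhale positive regardless of tracking sign", {
  t <- seq(0, 12, by = 0.1)
  disp <- 10 * sin(pi * ((t / 4) %% 1))^4 # exhale-dwelling trace
  expect_equal(orient_si(disp), disp)
  expect_equal(orient_si(-disp), disp)
})

test_that("surrogate tables round-trip through CSV", {
  dir <- withr::local_tempdir()
  smp <- data.frame(frame = 0:3, t_s = c(0, 0.23, 0.46, 0.69),
                    displacement_mm = c(0, 2.5, 6, 3.25),
                    phase = c(0, 1.2, 4, 6.5),
                    amplitude = c(0, 0.3, 1, 0.4),
                    valid = c(TRUE, TRUE, FALSE, TRUE))
  p <- file.path(dir, "samples.csv")
  write_surrogate(smp, p)
  expect_equal(read_surrogate(p), smp)
})

test_that("building bins carry integer phases", {
  expect_identical(bin_phases_of_building(8), 0:7)
  expect_identical(bin_phases_of_building(4), 0:3)
  expect_identical(bin_phases_of_building(8)[1], 0L)
  expect_error(bin_phases_of_building(1), "n_bins")
})

test_that("on phantom cine the surrogate amplitude tracks the true state monotonically", {
  pair <- small_pair_clean()
  s1 <- pair$S1
  cine <- extract_cine_frames(s1)
  # track a known high-contrast structure explicitly (the auto-ROI band is
  # meant for full-size frames)
  dia <- s1$landmarks$ref
  dia <- dia[dia$plane == "sagittal", ][1, ]
  sig <- extract_signal(cine, roi = list(x_mm = dia$ap, y_mm = dia$si))
  sag <- cine$plane == "sagittal"
  truth_scale <- cine$state$scale[sag]
  d <- orient_si(sig$displacement_mm)
  expect_gt(cor(d, truth_scale), 0.95)
  # displacement is linear in the true state scale up to tracking noise
  fit <- coef(lm(d ~ truth_scale))
  expect_lt(max(abs(d - (fit[1] + fit[2] * truth_scale))), 2 * 1.33)
  # phase recovery at bin-centre frames within half a bin
  smp <- to_phase_amplitude(sig, building_peak_mm = max(d), n_bins = 4,
                            mean_period_s = pair$config$breath_period_s)
  ok <- smp$valid
  dphi <- (smp$phase[ok] - cine$state$phase[sag][ok] + 2) %% 4 - 2
  expect_lt(median(abs(dphi)), 0.5)
})
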