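#' Configuration of the synthetic 4D abdominal breathing phantom
#'
#' The phantom emulates a two-session MRI motion study of an abdominal
#' lesion: per session, two respiratory-correlated 4DMRIs (R1, R2) of a
#' sagittal slab plus one interleaved sagittal/coronal 2D cine series.
#' Geometry defaults follow a 1.33 x 1.33 mm in-plane / 5 mm slice
#' acquisition of a 12.5 cm right-left slab binned into 8 breathing phases,
#' with cine frames every 230 ms. Array axes are (AP, SI, RL); all vector
#' parameters (e.g. `baseline_shift_mm`) use that component order.
#'
#' @param grid_shape integer(3), voxels per (AP, SI, RL) axis.
#' @param spacing_mm numeric(3), voxel size in mm.
#' @param n_bins breathing phase bins per 4DMRI (bin 0 = end-exhale).
#' @param cine_dt_s cine frame interval in seconds.
#' @param cine_duration_s cine acquisition length in seconds.
#' @param breath_period_s mean breathing cycle period in seconds.
#' @param exhale_fraction fraction of the cycle spent in the exhale half;
#'   free breathing dwells longer around end-exhale, so > 0.5 by default.
#' @param si_amplitude_mm peak superior-inferior diaphragm displacement at
#'   unit cycle amplitude.
#' @param ap_fraction anterior-posterior amplitude as a fraction of SI.
#' @param cycle_amp_sd SD of the per-cycle amplitude multiplier (mean 1,
#'   truncated positive).
#' @param cycle_period_sd_s SD of the per-cycle period in seconds.
#' @param baseline_shift_mm numeric(3), inter-session baseline displacement
#'   of the whole scene in mm, (AP, SI, RL) order.
#' @param noise_sd additive Gaussian intensity noise, as a fraction of the
#'   scene dynamic range.
#' @param local_change logical; add a session-2 local intensity/displacement
#'   change region (bowel-filling analogue).
#' @param seed RNG seed making the whole study reproducible.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(96, 96, 25),
                           spacing_mm = c(1.33, 1.33, 5.0),
                           n_bins = 8L,
                           cine_dt_s = 0.230,
                           cine_duration_s = 30,
                           breath_period_s = 4,
                           exhale_fraction = 0.6,
                           si_amplitude_mm = 12,
                           ap_fraction = 0.3,
                           cycle_amp_sd = 0.1,
                           cycle_period_sd_s = 0.3,
                           baseline_shift_mm = c(0, 3, 0),
                           noise_sd = 0.02,
                           local_change = FALSE,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("phantom_config: 'grid_shape' must be 3 integers >= 4")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("phantom_config: 'spacing_mm' must be 3 positive values")
  if (n_bins < 2L) stop("phantom_config: 'n_bins' must be >= 2")
  if (cine_dt_s <= 0 || cine_duration_s <= 0)
    stop("phantom_config: cine timing must be positive")
  if (breath_period_s <= 0) stop("phantom_config: 'breath_period_s' must be > 0")
  if (exhale_fraction <= 0 || exhale_fraction >= 1)
    stop("phantom_config: 'exhale_fraction' must be in (0, 1)")
  if (cycle_amp_sd < 0 || cycle_period_sd_s < 0)
    stop("phantom_config: cycle variability SDs must be >= 0")
  if (si_amplitude_mm < 0) stop("phantom_config: 'si_amplitude_mm' must be >= 0")
  if (length(baseline_shift_mm) != 3L)
    stop("phantom_config: 'baseline_shift_mm' must have 3 components")
  extent <- grid_shape * spacing_mm
  if (min(extent) < 40)
    stop("phantom_config: grid too small to contain the phantom organs ",
         "(needs >= 40 mm extent per axis, got ",
         paste(round(extent, 1), collapse = " x "), " mm)")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 n_bins = as.integer(n_bins), cine_dt_s = cine_dt_s,
                 cine_duration_s = cine_duration_s,
                 breath_period_s = breath_period_s,
                 exhale_fraction = exhale_fraction,
                 si_amplitude_mm = si_amplitude_mm,
                 ap_fraction = ap_fraction,
                 cycle_amp_sd = cycle_amp_sd,
                 cycle_period_sd_s = cycle_period_sd_s,
                 baseline_shift_mm = as.numeric(baseline_shift_mm),
                 noise_sd = noise_sd,
                 local_change = isTRUE(local_change),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Normalised free-breathing waveform
#'
#' Periodic waveform in `[0, 1]` with value 0 at the cycle start/end
#' (end-exhale) and a single maximum of 1 per cycle. The cycle is
#' time-warped so that the peak (end-inhale) sits at elapsed fraction
#' `1 - exhale_fraction`, and a `sin^4` profile flattens the curve near the
#' troughs, reproducing the end-exhale dwell of free breathing.
#'
#' @param t time in seconds (vectorised).
#' @param period cycle period in seconds, > 0 (scalar or per-sample).
#' @param exhale_fraction fraction of the cycle in the exhale half, in (0, 1).
#' @return Waveform values in `[0, 1]`.
#' @export
breathing_waveform <- function(t, period, exhale_fraction = 0.6) {
  if (!length(period) || any(!is.finite(period)) || any(period <= 0))
    stop("breathing_waveform: 'period' must be positive")
  if (exhale_fraction <= 0 || exhale_fraction >= 1)
    stop("breathing_waveform: 'exhale_fraction' must be in (0, 1)")
  tau <- (t / period) %% 1
  peak <- 1 - exhale_fraction
  u <- ifelse(tau <= peak, 0.5 * tau / peak,
              0.5 + 0.5 * (tau - peak) / (1 - peak))
  sin(pi * u)^4
}

# ---- scene geometry ----------------------------------------------------

# Raised-cosine window: 0 outside [lo, hi], cosine ramps of width rlo / rhi,
# 1 on the plateau. C1-continuous, compactly supported.
coswin <- function(x, lo, hi, rlo, rhi) {
  w <- numeric(length(x))
  up <- x >= lo & x < lo + rlo
  dn <- x > hi - rhi & x <= hi
  mid <- x >= lo + rlo & x <= hi - rhi
  w[mid] <- 1
  w[up] <- 0.5 - 0.5 * cos(pi * (x[up] - lo) / rlo)
  w[dn] <- 0.5 - 0.5 * cos(pi * (hi - x[dn]) / rhi)
  w
}

# logistic smooth step: ~0 for d << -w, ~1 for d >> w
sstep <- function(d, w = 1.2) 1 / (1 + exp(-4 * d / w))

# Analytic scene: liver slab under a curved diaphragm dome, lung above,
# spherical tumour, Gaussian-blob vessels for texture. Geometry is scaled
# to the volume extent so small test grids stay anatomically proportioned.
# Draws blob parameters from the current RNG stream.
make_scene <- function(config) {
  L <- config$grid_shape * config$spacing_mm
  apc <- 0.5 * L[1]; rlc <- 0.5 * L[3]
  # envelope windows: cosine ramps have peak slope (pi/2)/width, so widths
  # scale with the breathing amplitude to keep the ground-truth deformation
  # fold-free (|du/dx| < 1) with margin
  amp_mm <- max(config$si_amplitude_mm, 1)
  si_lo <- 0.03 * L[2]; si_hi <- 0.97 * L[2]
  si_rhi <- min(max(2.4 * amp_mm, 0.12 * L[2]), 0.45 * (si_hi - si_lo))
  z0 <- min(0.70 * L[2], si_hi - si_rhi - 1)
  si_rlo <- min(max(2.4 * amp_mm, 0.50 * L[2]), z0 - si_lo - 1)
  geom <- list(
    env_si = c(si_lo, si_hi, max(si_rlo, 1), max(si_rhi, 1)),
    env_ap = c(0.02 * L[1], 0.98 * L[1], 0.40 * L[1], 0.40 * L[1]),
    env_rl = c(0.02 * L[3], 0.98 * L[3], 0.35 * L[3], 0.35 * L[3]),
    L = L, apc = apc, rlc = rlc, z0 = z0,
    dome_drop = 0.18 * L[2],
    dome_rad_ap = 0.45 * L[1], dome_rad_rl = 0.45 * L[3],
    liver_th = 0.45 * L[2],
    liver_rad_ap = 0.44 * L[1], liver_rad_rl = 0.48 * L[3],
    tum_centre = c(apc + 0.06 * L[1], z0 - 0.28 * L[2], rlc),
    tum_radius = min(9, 0.09 * min(L[1], L[2])),
    I_lung = 10, I_tissue = 35, I_liver = 60, I_tum = 85,
    edge_w = 1.0)
  # vessel blobs inside the liver slab
  n_blob <- 34L
  bl_ap <- stats::runif(n_blob, apc - 0.38 * L[1], apc + 0.38 * L[1])
  bl_si <- stats::runif(n_blob, z0 - 0.40 * L[2], z0 - 0.06 * L[2])
  bl_rl <- stats::runif(n_blob, rlc - 0.40 * L[3], rlc + 0.40 * L[3])
  bl_sg <- stats::runif(n_blob, 2.2, 4.0)
  bl_am <- sample(c(-1, 1), n_blob, replace = TRUE) *
    stats::runif(n_blob, 16, 28)
  # keep blobs away from the tumour so it stays a clean sphere
  dtum <- sqrt((bl_ap - geom$tum_centre[1])^2 + (bl_si - geom$tum_centre[2])^2 +
               (bl_rl - geom$tum_centre[3])^2)
  keep <- dtum > geom$tum_radius + 3 * bl_sg
  # background texture blobs below the liver (bowel analogue)
  n_bg <- 10L
  bg_ap <- stats::runif(n_bg, 0.12 * L[1], 0.88 * L[1])
  bg_si <- stats::runif(n_bg, 0.05 * L[2], 0.22 * L[2])
  bg_rl <- stats::runif(n_bg, 0.15 * L[3], 0.85 * L[3])
  bg_sg <- stats::runif(n_bg, 3.0, 5.0)
  bg_am <- sample(c(-1, 1), n_bg, replace = TRUE) * stats::runif(n_bg, 8, 14)
  geom$blobs <- data.frame(
    ap = c(bl_ap[keep], bg_ap), si = c(bl_si[keep], bg_si),
    rl = c(bl_rl[keep], bg_rl), sigma = c(bl_sg[keep], bg_sg),
    amp = c(bl_am[keep], bg_am),
    vessel = rep(c(TRUE, FALSE), c(sum(keep), n_bg)))
  geom
}

# diaphragm dome height at (ap, rl)
dome_si <- function(scene, ap, rl) {
  scene$z0 - scene$dome_drop *
    (((ap - scene$apc) / scene$dome_rad_ap)^2 +
     ((rl - scene$rlc) / scene$dome_rad_rl)^2)
}

# scene intensity at world points P (n x 3), undeformed reference frame
scene_intensity <- function(scene, P) {
  ap <- P[, 1]; si <- P[, 2]; rl <- P[, 3]
  w <- scene$edge_w
  zd <- dome_si(scene, ap, rl)
  below <- sstep(zd - si, w)                       # below diaphragm
  lat <- 1 - (((ap - scene$apc) / scene$liver_rad_ap)^2 +
              ((rl - scene$rlc) / scene$liver_rad_rl)^2)
  liver <- below * sstep(si - (zd - scene$liver_th), w) *
    sstep(lat * 0.25 * min(scene$L[1], scene$L[3]), w)
  I <- scene$I_tissue + (scene$I_liver - scene$I_tissue) * liver
  lung <- 1 - below
  I <- I + (scene$I_lung - I) * lung
  # vessels / texture blobs (bounded support for speed)
  b <- scene$blobs
  for (q in seq_len(nrow(b))) {
    r3 <- 3 * b$sigma[q]
    sel <- which(abs(ap - b$ap[q]) < r3 & abs(si - b$si[q]) < r3 &
                 abs(rl - b$rl[q]) < r3)
    if (!length(sel)) next
    d2 <- (ap[sel] - b$ap[q])^2 + (si[sel] - b$si[q])^2 +
          (rl[sel] - b$rl[q])^2
    gain <- if (b$vessel[q]) liver[sel] else 1
    I[sel] <- I[sel] + b$amp[q] * gain * exp(-d2 / (2 * b$sigma[q]^2))
  }
  tumd <- sqrt((ap - scene$tum_centre[1])^2 + (si - scene$tum_centre[2])^2 +
               (rl - scene$tum_centre[3])^2)
  tum <- sstep(scene$tum_radius - tumd, w)
  I + (scene$I_tum - I) * tum
}

scene_tumour_ind <- function(scene, P) {
  tumd2 <- (P[, 1] - scene$tum_centre[1])^2 +
    (P[, 2] - scene$tum_centre[2])^2 + (P[, 3] - scene$tum_centre[3])^2
  tumd2 <= scene$tum_radius^2
}

# smooth compactly-supported breathing envelope, 1 at the diaphragm apex
scene_envelope <- function(scene, P) {
  a <- scene$env_ap; s <- scene$env_si; r <- scene$env_rl
  coswin(P[, 1], a[1], a[2], a[3], a[4]) *
    coswin(P[, 2], s[1], s[2], s[3], s[4]) *
    coswin(P[, 3], r[1], r[2], r[3], r[4])
}

# per-point breathing displacement (backward-mapping, mm) at unit scale
# (s * cycle_amp = 1); columns (AP, SI, RL)
unit_displacement <- function(scene, P, config) {
  m <- config$si_amplitude_mm * scene_envelope(scene, P)
  cbind(-config$ap_fraction * m, m, 0)
}

# session-2 baseline (backward) displacement at points P, and the local
# change indicator; anatomy shifts by +b so the backward field is -b
session2_baseline_disp <- function(scene, P, config) {
  n <- nrow(P)
  ub <- matrix(rep(-config$baseline_shift_mm, each = n), n)
  ind <- rep(0, n)
  if (config$local_change) {
    # bowel-filling analogue pressing on the inferior liver: local
    # displacement (8.4 mm peak) plus an intensity change that breaks
    # image correspondence, so DIR cannot fully compensate it
    L <- scene$L
    c0 <- c(0.42 * L[1], 0.30 * L[2], 0.5 * L[3])
    sg <- c(0.14 * L[1], 0.10 * L[2], 0.18 * L[3])
    g <- exp(-0.5 * (((P[, 1] - c0[1]) / sg[1])^2 +
                     ((P[, 2] - c0[2]) / sg[2])^2 +
                     ((P[, 3] - c0[3]) / sg[3])^2))
    bump_mm <- 8.4
    ub <- ub - bump_mm * cbind(0.4 * g, 0.9 * g, 0 * g)
    ind <- g
  }
  list(ub = ub, ind = ind)
}

# ---- state evaluation ---------------------------------------------------

# Evaluate the deformed scene of a session at world points P for breathing
# scale = s * cycle_amp. Returns intensity and the tumour indicator.
# Session 1: I(x) = scene(x + scale * e(x));
# Session 2: the scene is first baseline-shifted (backward field ub), the
# breathing envelope follows the shifted anatomy.
session_sample_state <- function(scene, config, session_id, P, scale) {
  if (session_id == 1L) {
    u <- scale * unit_displacement(scene, P, config)
    Q <- P + u
    list(intensity = scene_intensity(scene, Q),
         mask = scene_tumour_ind(scene, Q))
  } else {
    Pb <- sweep(P, 2, config$baseline_shift_mm, "-")
    u <- scale * unit_displacement(scene, Pb, config)
    Q <- P + u
    bl <- session2_baseline_disp(scene, Q, config)
    R <- Q + bl$ub
    I <- scene_intensity(scene, R)
    if (config$local_change) I <- I + 25 * bl$ind
    list(intensity = I, mask = scene_tumour_ind(scene, R))
  }
}

# ---- ground-truth deformation ------------------------------------------

#' Ground-truth breathing deformation field at a respiratory state
#'
#' Returns the backward-mapping field that carries the session's end-exhale
#' reference onto the breathing state with normalised waveform value `s` and
#' per-cycle amplitude multiplier `cycle_amp`: the displacement is the
#' smooth spatial envelope times `s * cycle_amp`, SI-dominant with an AP
#' component of `ap_fraction` times the SI one, compactly supported inside
#' the volume, and its peak SI magnitude at the diaphragm apex equals
#' `si_amplitude_mm * s * cycle_amp`.
#'
#' @param session a `phantom_session` (from [generate_session_pair()]), or
#'   `NULL` to evaluate for session 1 of a fresh scene.
#' @param s normalised waveform value in `[0, 1]`.
#' @param cycle_amp per-cycle amplitude multiplier.
#' @param config a [phantom_config()]; defaults to the session's.
#' @return A [vectorfield3d()] on the phantom grid.
#' @export
true_dvf <- function(session, s, cycle_amp = 1, config = session$config) {
  env <- session$truth$env_unit
  d <- dim(env$u)
  vectorfield3d(env$u * (s * cycle_amp), spacing = env$spacing,
                origin = env$origin, axis_labels = env$axis_labels)
}

#' Ground-truth DVF of a 4DMRI bin or cine frame
#'
#' @param session a `phantom_session`.
#' @param acq `"R1"` or `"R2"` for 4DMRI bins; `"cine"` for cine frames.
#' @param index 0-based bin index or 0-based cine frame index.
#' @return A [vectorfield3d()]; bin 0 is identically zero.
#' @export
phantom_truth_dvf <- function(session, acq = c("R1", "R2", "cine"), index) {
  acq <- match.arg(acq)
  scale <- if (acq == "cine") session$cine$state$scale[index + 1L]
  else session$truth$bin_scale[[acq]][index + 1L]
  true_dvf(session, s = scale, cycle_amp = 1)
}

# ---- session generation -------------------------------------------------

draw_cycles <- function(n, config) {
  amp <- pmax(stats::rnorm(n, 1, config$cycle_amp_sd), 0.05)
  per <- pmax(stats::rnorm(n, config$breath_period_s, config$cycle_period_sd_s),
              0.3 * config$breath_period_s)
  data.frame(cycle = seq_len(n), period_s = per, amp = amp,
             start_s = c(0, cumsum(per))[seq_len(n)])
}

# breathing state at arbitrary times given a cycle table
cycle_state <- function(t, cycles, config) {
  j <- findInterval(t, cycles$start_s)
  j <- pmin(pmax(j, 1L), nrow(cycles))
  tau <- (t - cycles$start_s[j]) / cycles$period_s[j]
  tau <- pmin(pmax(tau, 0), 1)
  s <- breathing_waveform(tau * cycles$period_s[j], cycles$period_s[j],
                          config$exhale_fraction)
  data.frame(t = t, cycle = j, tau = tau, s = s, cycle_amp = cycles$amp[j],
             phase = config$n_bins * tau, scale = s * cycles$amp[j])
}

# forward-map reference points through the breathing deformation:
# find x with x + u(x) = p  (fixed-point iteration; u is smooth and small)
forward_map_points <- function(scene, config, session_id, p, scale) {
  x <- p
  for (it in 1:8) {
    if (session_id == 1L) {
      u <- scale * unit_displacement(scene, x, config)
    } else {
      xb <- sweep(x, 2, config$baseline_shift_mm, "-")
      u <- scale * unit_displacement(scene, xb, config)
    }
    x <- p - u
  }
  x
}

make_volume <- function(vals, config) {
  volume3d(array(vals, config$grid_shape), spacing = config$spacing_mm,
           origin = c(0, 0, 0))
}

#' Generate the two-session phantom study
#'
#' Produces sessions S1 and S2, each holding two binned 4DMRIs (R1, R2), an
#' interleaved sagittal/coronal cine series, ground-truth deformations,
#' tumour masks and landmark trajectories. Session 2 is the same scene
#' displaced by `baseline_shift_mm` (optionally with a local
#' intensity/displacement change region). R1 and R2 within a session differ
#' by resampled cycle-amplitude variability; binned volumes sample the
#' continuous deformation at bin-centre phases. All randomness derives from
#' `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return An object of class `phantom_pair`: list with elements `S1`, `S2`
#'   (class `phantom_session`), `config` and `scene`.
#' @export
generate_session_pair <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  scene <- make_scene(config)
  P <- NULL # grid coords, built lazily below
  gridvol <- make_volume(0, config)
  P <- grid_world_coords(gridvol)
  drange <- NULL

  sessions <- vector("list", 2L)
  for (sid in 1:2) {
    # unit envelope field for this session (anatomy-following)
    Ps <- if (sid == 1L) P else sweep(P, 2, config$baseline_shift_mm, "-")
    Uu <- unit_displacement(scene, Ps, config)
    env_unit <- vectorfield3d(array(Uu, c(config$grid_shape, 3L)),
                              spacing = config$spacing_mm, origin = c(0, 0, 0))
    # reference (end-exhale, no noise yet)
    ref_samp <- session_sample_state(scene, config, sid, P, 0)
    if (is.null(drange)) drange <- diff(range(ref_samp$intensity))
    noise_sd_abs <- config$noise_sd * drange

    bin_s <- breathing_waveform(
      (0:(config$n_bins - 1L)) / config$n_bins * config$breath_period_s,
      config$breath_period_s, config$exhale_fraction)

    fourD <- list(); truth_scale <- list(); masks <- list()
    for (acq in c("R1", "R2")) {
      # retrospective binning averages several cycles: per-bin multipliers
      # are cycle-amplitude draws shrunk by the ~6 cycles mixed into a bin
      mult <- pmax(stats::rnorm(config$n_bins, 1,
                                config$cycle_amp_sd / sqrt(6)), 0.05)
      scl <- bin_s * mult
      scl[1] <- 0 # bin 0 is end-exhale by construction
      vols <- vector("list", config$n_bins)
      mks <- vector("list", config$n_bins)
      for (k in seq_len(config$n_bins)) {
        smp <- if (scl[k] == 0) ref_samp
        else session_sample_state(scene, config, sid, P, scl[k])
        v <- smp$intensity
        if (noise_sd_abs > 0)
          v <- v + stats::rnorm(length(v), 0, noise_sd_abs)
        vols[[k]] <- make_volume(v, config)
        mks[[k]] <- array(smp$mask, config$grid_shape)
      }
      fourD[[acq]] <- vols
      truth_scale[[acq]] <- scl
      masks[[acq]] <- mks
    }

    # cine series
    n_frames <- floor(config$cine_duration_s / config$cine_dt_s)
    cycles <- draw_cycles(
      ceiling(config$cine_duration_s /
                max(0.3 * config$breath_period_s,
                    config$breath_period_s - 3 * config$cycle_period_sd_s)) + 2L,
      config)
    t_frames <- (seq_len(n_frames) - 1L) * config$cine_dt_s
    state <- cycle_state(t_frames, cycles, config)
    state$plane <- ifelse(seq_len(n_frames) %% 2L == 1L, "sagittal", "coronal")

    tumc <- scene$tum_centre +
      if (sid == 2L) config$baseline_shift_mm else c(0, 0, 0)
    sag_rl <- round(tumc[3] / config$spacing_mm[3])
    sag_rl <- min(max(sag_rl, 0L), config$grid_shape[3] - 1L)
    cor_ap <- round(tumc[1] / config$spacing_mm[1])
    cor_ap <- min(max(cor_ap, 0L), config$grid_shape[1] - 1L)

    idx_sag <- which(rep(0:(config$grid_shape[3] - 1L),
                         each = prod(config$grid_shape[1:2])) == sag_rl)
    sag_P <- P[idx_sag, , drop = FALSE]
    idx_cor <- which(rep(rep(0:(config$grid_shape[1] - 1L),
                             times = config$grid_shape[2]),
                         times = config$grid_shape[3]) == cor_ap)
    cor_P <- P[idx_cor, , drop = FALSE]

    frames <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      pl <- state$plane[i]
      Pp <- if (pl == "sagittal") sag_P else cor_P
      smp <- session_sample_state(scene, config, sid, Pp, state$scale[i])
      v <- smp$intensity
      if (noise_sd_abs > 0) v <- v + stats::rnorm(length(v), 0, noise_sd_abs)
      frames[[i]] <- if (pl == "sagittal")
        matrix(v, config$grid_shape[1], config$grid_shape[2])
      else matrix(v, config$grid_shape[2], config$grid_shape[3])
    }

    lm <- phantom_landmarks(scene, config, sid, sag_rl, cor_ap)
    lm_truth <- NULL
    if (nrow(lm)) {
      rows <- vector("list", n_frames)
      for (i in seq_len(n_frames)) {
        pl <- state$plane[i]
        sub <- lm[lm$plane == pl, , drop = FALSE]
        if (!nrow(sub)) next
        fwd <- forward_map_points(scene, config, sid,
                                  as.matrix(sub[, c("ap", "si", "rl")]),
                                  state$scale[i])
        xy <- if (pl == "sagittal") fwd[, 1:2, drop = FALSE]
        else fwd[, 2:3, drop = FALSE]
        rows[[i]] <- data.frame(id = sub$id, plane = pl, frame = i - 1L,
                                x_mm = xy[, 1], y_mm = xy[, 2])
      }
      lm_truth <- do.call(rbind, rows)
    }

    baseline_truth <- NULL
    if (sid == 2L) {
      bl <- session2_baseline_disp(scene, P, config)
      baseline_truth <- vectorfield3d(array(bl$ub, c(config$grid_shape, 3L)),
                                      spacing = config$spacing_mm,
                                      origin = c(0, 0, 0))
    }

    ref_noisy <- ref_samp$intensity
    sessions[[sid]] <- structure(list(
      id = paste0("S", sid), config = config,
      reference = make_volume(ref_noisy, config),
      fourD = fourD,
      cine = list(frames = frames, t = t_frames, plane = state$plane,
                  state = state, cycles = cycles,
                  sag_rl_index = sag_rl, cor_ap_index = cor_ap,
                  sag_spacing = config$spacing_mm[1:2],
                  cor_spacing = config$spacing_mm[2:3]),
      truth = list(env_unit = env_unit, bin_scale = truth_scale,
                   masks = masks, mask_ref = array(ref_samp$mask,
                                                   config$grid_shape),
                   baseline = baseline_truth,
                   noise_sd_abs = noise_sd_abs),
      landmarks = list(ref = lm, truth = lm_truth)),
      class = "phantom_session")
  }
  structure(list(S1 = sessions[[1]], S2 = sessions[[2]],
                 config = config, scene = scene),
            class = "phantom_pair")
}

# Landmark definition on the session reference: diaphragm dome point,
# tumour centre and the two strongest vessel blobs near each cine plane.
phantom_landmarks <- function(scene, config, session_id, sag_rl, cor_ap) {
  b <- if (session_id == 2L) config$baseline_shift_mm else c(0, 0, 0)
  L <- scene$L
  sp <- config$spacing_mm
  sag_rl_mm <- sag_rl * sp[3]
  cor_ap_mm <- cor_ap * sp[1]
  rows <- list()
  # keep template + search window (8 + 14 mm) inside every tracked frame
  marg <- function(a) 22 + 2 * sp[a]
  add <- function(id, plane, p) {
    in_ap <- p[1] > marg(1) && p[1] < L[1] - marg(1)
    in_si <- p[2] > marg(2) && p[2] < L[2] - marg(2)
    in_rl <- p[3] > marg(3) && p[3] < L[3] - marg(3)
    ok <- if (plane == "sagittal") in_ap && in_si else
      in_si && in_rl
    if (ok) rows[[length(rows) + 1L]] <<-
        data.frame(id = id, plane = plane, ap = p[1], si = p[2], rl = p[3])
  }
  tum <- scene$tum_centre + b
  # a point just below the diaphragm dome, on each plane
  sag_d <- c(scene$apc + b[1],
             dome_si(scene, scene$apc, sag_rl_mm - b[3]) - 2.5 + b[2],
             sag_rl_mm)
  cor_d <- c(cor_ap_mm,
             dome_si(scene, cor_ap_mm - b[1], scene$rlc) - 2.5 + b[2],
             scene$rlc + b[3])
  add("diaphragm", "sagittal", sag_d)
  add("tumour", "sagittal", c(tum[1], tum[2], sag_rl_mm))
  add("diaphragm", "coronal", cor_d)
  add("tumour", "coronal", c(cor_ap_mm, tum[2], tum[3]))
  v <- scene$blobs[scene$blobs$vessel & abs(scene$blobs$amp) > 18 &
                     scene$blobs$sigma > 2.5, , drop = FALSE]
  if (nrow(v)) {
    # only blobs close enough to the plane to show in-plane contrast
    vs <- v[abs(v$rl + b[3] - sag_rl_mm) < 0.8 * v$sigma, , drop = FALSE]
    vs <- utils::head(vs[order(-abs(vs$amp)), , drop = FALSE], 2L)
    for (q in seq_len(nrow(vs)))
      add(paste0("vessel", q), "sagittal",
          c(vs$ap[q] + b[1], vs$si[q] + b[2], sag_rl_mm))
    vc <- v[abs(v$ap + b[1] - cor_ap_mm) < 0.8 * v$sigma, , drop = FALSE]
    vc <- utils::head(vc[order(-abs(vc$amp)), , drop = FALSE], 2L)
    for (q in seq_len(nrow(vc)))
      add(paste0("vessel", q), "coronal",
          c(cor_ap_mm, vc$si[q] + b[2], vc$rl[q] + b[3]))
  }
  if (!length(rows))
    return(data.frame(id = character(), plane = character(),
                      ap = numeric(), si = numeric(), rl = numeric()))
  do.call(rbind, rows)
}

#' Cine frame series of a phantom session
#'
#' Returns the interleaved sagittal/coronal 2D cine frames generated for a
#' session: frames alternate planes through the tumour centre of mass, each
#' sampled from the continuous deformation at its timestamp (not from the
#' phase bins), with timestamps spaced `cine_dt_s` apart.
#'
#' @param session a `phantom_session`.
#' @return A list with `frames` (list of 2D matrices), `t` (timestamps, s),
#'   `plane` (per-frame label), per-plane pixel spacings, the per-frame
#'   breathing `state` table, and the fixed plane indices.
#' @export
extract_cine_frames <- function(session) {
  stopifnot(inherits(session, "phantom_session"))
  session$cine
}

#' @export
print.phantom_session <- function(x, ...) {
  cat(sprintf("<phantom_session %s> grid %s, %d bins x 2 4DMRI, %d cine frames\n",
              x$id, paste(x$config$grid_shape, collapse = "x"),
              x$config$n_bins, length(x$cine$frames)))
  invisible(x)
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat("<phantom_pair> two-session synthetic breathing study\n")
  print(x$S1); print(x$S2)
  invisible(x)
}

#' Write a phantom study to disk
#'
#' Lays out the study as NIfTI volumes plus CSV/JSON sidecars: one
#' `.nii.gz` per 4DMRI bin, ground-truth DVFs as 3-component vector NIfTI
#' (mm, world axes), cine frames as one multi-frame NIfTI per plane with a
#' CSV of timestamps and plane labels, truth landmarks as CSV, tumour masks
#' as NIfTI, and a JSON manifest.
#'
#' @param pair a `phantom_pair`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(pair, dir) {
  stopifnot(inherits(pair, "phantom_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- pair$config
  manifest <- list(grid_shape = cfg$grid_shape, spacing_mm = cfg$spacing_mm,
                   n_bins = cfg$n_bins, seed = cfg$seed,
                   axis_order = c("AP", "SI", "RL"),
                   dvf_convention = "backward (pull): warped(x) = moving(x + u(x))",
                   sessions = c("S1", "S2"))
  for (sid in c("S1", "S2")) {
    s <- pair[[sid]]
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    for (acq in c("R1", "R2")) {
      for (k in seq_along(s$fourD[[acq]])) {
        write_volume(s$fourD[[acq]][[k]],
                     file.path(sdir, sprintf("%s_bin%02d.nii.gz", acq, k - 1L)))
        write_dvf(phantom_truth_dvf(s, acq, k - 1L),
                  file.path(sdir, sprintf("truth_dvf_%s_bin%02d.nii.gz",
                                          acq, k - 1L)))
      }
    }
    write_volume(volume3d(array(as.numeric(s$truth$mask_ref),
                                cfg$grid_shape),
                          spacing = cfg$spacing_mm),
                 file.path(sdir, "tumour_mask_ref.nii.gz"))
    # cine: one multi-frame NIfTI per plane
    for (pl in c("sagittal", "coronal")) {
      sel <- which(s$cine$plane == pl)
      if (!length(sel)) next
      fr <- s$cine$frames[sel]
      a <- array(unlist(fr), c(dim(fr[[1]]), 1L, length(fr)))
      sp2 <- if (pl == "sagittal") s$cine$sag_spacing else s$cine$cor_spacing
      write_nifti_geom(a, c(sp2, 1), c(0, 0, 0),
                       file.path(sdir, paste0("cine_", pl, ".nii.gz")))
    }
    utils::write.csv(
      data.frame(frame = seq_along(s$cine$t) - 1L, t_s = s$cine$t,
                 plane = s$cine$plane),
      file.path(sdir, "cine_frames.csv"), row.names = FALSE)
    if (!is.null(s$landmarks$truth))
      write_landmarks(s$landmarks$truth,
                      file.path(sdir, "landmarks_truth.csv"))
    if (!is.null(s$truth$baseline))
      write_dvf(s$truth$baseline, file.path(sdir, "truth_baseline.nii.gz"))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
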