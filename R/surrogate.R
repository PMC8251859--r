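#' Extract an image-based surrogate signal from cine frames
#'
#' Tracks a high-contrast structure (by default a diaphragm-analogue edge)
#' through the sagittal cine frames by normalised cross-correlation
#' template matching and returns its superior-inferior displacement
#' relative to the first frame. Frames whose match score falls below the
#' threshold are flagged invalid and excluded from downstream use.
#'
#' @param cine a cine series as returned by [extract_cine_frames()] (list
#'   with `frames`, `t`, `plane`, `sag_spacing`).
#' @param roi optional list with `x_mm`, `y_mm` (template centre on the
#'   first sagittal frame, in-plane mm); `NULL` picks the strongest SI
#'   intensity edge automatically.
#' @param params list of tracking options: `template_half`, `search_half`
#'   (px), `score_threshold`, `subpixel` (see [track_landmarks()]).
#' @return An object of class `surrogate_signal`: data.frame with columns
#'   `frame` (0-based index into the full interleaved series), `t_s`,
#'   `displacement_mm` (SI, relative to frame 0), `score`, `valid`;
#'   attribute `spacing_mm`.
#' @export
extract_signal <- function(cine, roi = NULL, params = list()) {
  p <- utils::modifyList(list(template_half = c(6L, 8L),
                              search_half = c(4L, 12L),
                              score_threshold = 0.5, subpixel = TRUE), params)
  sel <- which(cine$plane == "sagittal")
  if (length(sel) < 2L)
    stop("extract_signal: need at least 2 sagittal frames")
  frames <- cine$frames[sel]
  sp <- cine$sag_spacing
  if (is.null(roi)) roi <- default_surrogate_roi(frames[[1]], sp, p)
  lm0 <- data.frame(id = "surrogate", x_mm = roi$x_mm, y_mm = roi$y_mm)
  tr <- track_landmarks(frames, lm0, sp,
                        template_half = p$template_half,
                        search_half = p$search_half,
                        score_threshold = p$score_threshold,
                        subpixel = p$subpixel)
  if (!any(tr$valid[-1])) # frame 0 matches its own template trivially
    stop("extract_signal: failure in obtaining the image-based surrogate ",
         "signal (all frames below the match-score threshold)")
  out <- data.frame(frame = sel - 1L, t_s = cine$t[sel],
                    displacement_mm = tr$y_mm - tr$y_mm[1],
                    score = tr$score, valid = tr$valid)
  structure(out, spacing_mm = sp, roi = roi, class = c("surrogate_signal",
                                                       "data.frame"))
}

# Pick the ROI with the strongest SI gradient in the central AP band of the
# first sagittal frame, keeping the template + search window inside it.
default_surrogate_roi <- function(frame0, spacing, p) {
  d <- dim(frame0)
  gy <- frame0[, c(2:d[2], d[2])] - frame0[, c(1, 1:(d[2] - 1L))]
  mx <- p$template_half[1] + p$search_half[1] + 1L
  my <- p$template_half[2] + p$search_half[2] + 1L
  ap_band <- max(mx, round(d[1] * 0.30)):min(d[1] - mx, round(d[1] * 0.70))
  si_band <- my:(d[2] - my)
  sub <- abs(gy[ap_band, si_band])
  best <- arrayInd(which.max(sub), dim(sub))
  list(x_mm = (ap_band[best[1]] - 1L) * spacing[1],
       y_mm = (si_band[best[2]] - 1L) * spacing[2])
}

#' Convert a surrogate signal to phase/amplitude samples
#'
#' End-exhale troughs are detected as local minima with prominence at least
#' 20% of the signal peak-to-peak and separation at least half the mean
#' breathing period. Within each cycle the elapsed fraction maps linearly
#' to a circular phase in `[0, n_bins)` (so inhale and exhale samples of
#' equal depth get distinct phases), and the amplitude is the
#' trough-corrected displacement divided by `building_peak_mm` (clipped at
#' `amp_clip` to cap extrapolation of the DVF scaling).
#'
#' @param signal a `surrogate_signal` from [extract_signal()].
#' @param building_peak_mm peak surrogate displacement across the building
#'   4DMRI's bins (> 0); amplitude 1 means that depth.
#' @param n_bins number of phase bins of the motion model.
#' @param mean_period_s expected mean breathing period (trough separation
#'   floor); estimated from the signal when `NULL`.
#' @param amp_clip maximum amplitude (default 2).
#' @return A data.frame of class `surrogate_samples` with columns `frame`,
#'   `t_s`, `displacement_mm`, `phase` (in `[0, n_bins)`), `amplitude`
#'   (>= 0), `valid` (samples outside complete cycles or from invalid
#'   frames are flagged).
#' @export
to_phase_amplitude <- function(signal, building_peak_mm, n_bins,
                               mean_period_s = NULL, amp_clip = 2) {
  if (!is.finite(building_peak_mm) || building_peak_mm <= 0)
    stop("to_phase_amplitude: 'building_peak_mm' must be > 0")
  ok <- signal$valid
  t <- signal$t_s
  disp <- orient_si(signal$displacement_mm)
  troughs <- detect_troughs(t[ok], disp[ok], mean_period_s)
  if (length(troughs) < 2L)
    stop("to_phase_amplitude: fewer than one complete breathing cycle in ",
         "the surrogate signal")
  t_tr <- refine_trough_times(t[ok], disp[ok], troughs)
  d_tr <- disp[ok][troughs]
  # per-sample end-exhale baseline: linear interpolation between troughs
  base <- stats::approx(t_tr, d_tr, xout = t, rule = 2)$y
  amp <- pmax(disp - base, 0) / building_peak_mm
  clipped <- amp > amp_clip
  if (any(clipped & ok)) {
    warning("to_phase_amplitude: ", sum(clipped & ok),
            " sample(s) above the amplitude clip (", amp_clip, "); clipped")
    amp[clipped] <- amp_clip
  }
  cyc <- findInterval(t, t_tr)
  inside <- cyc >= 1L & cyc < length(t_tr)
  frac <- rep(NA_real_, length(t))
  j <- cyc[inside]
  frac[inside] <- (t[inside] - t_tr[j]) / (t_tr[j + 1L] - t_tr[j])
  phase <- (frac * n_bins) %% n_bins
  structure(data.frame(frame = signal$frame, t_s = t,
                       displacement_mm = disp, phase = phase,
                       amplitude = amp, valid = ok & inside),
            troughs_t = t_tr,
            class = c("surrogate_samples", "data.frame"))
}

# local minima with prominence >= 20% of peak-to-peak and minimum
# separation >= half the mean period
detect_troughs <- function(t, x, mean_period_s = NULL) {
  n <- length(x)
  if (n < 3L) return(integer())
  p2p <- diff(range(x))
  if (p2p == 0) return(integer())
  locmin <- which(x[2:(n - 1L)] <= x[1:(n - 2L)] &
                    x[2:(n - 1L)] <= x[3:n]) + 1L
  cand <- c(if (x[1] <= x[2]) 1L, locmin, if (x[n] <= x[n - 1L]) n)
  cand <- unique(sort(cand))
  # prominence: rise to the highest peak between consecutive candidates
  keep <- logical(length(cand))
  for (q in seq_along(cand)) {
    i <- cand[q]
    left_max <- if (q == 1L) max(x[1:i]) else max(x[cand[q - 1L]:i])
    right_max <- if (q == length(cand)) max(x[i:n]) else max(x[i:cand[q + 1L]])
    keep[q] <- min(left_max, right_max) - x[i] >= 0.2 * p2p
  }
  cand <- cand[keep]
  if (length(cand) < 2L) return(cand)
  if (is.null(mean_period_s))
    mean_period_s <- 2 * stats::median(diff(t[cand]))
  min_sep <- 0.5 * mean_period_s
  # greedy enforcement of the separation, keeping the deeper trough
  res <- cand[1]
  for (i in cand[-1]) {
    if (t[i] - t[res[length(res)]] >= min_sep) res <- c(res, i)
    else if (x[i] < x[res[length(res)]]) res[length(res)] <- i
  }
  res
}

# Refine trough times to sub-sample precision. Free breathing dwells at
# end-exhale, so the signal is flat around each trough and the argmin
# sample is arbitrary within the dwell; the centroid of the near-trough
# region is unbiased for a symmetric dwell.
refine_trough_times <- function(t, x, troughs) {
  p2p <- diff(range(x))
  if (p2p <= 0) return(t[troughs])
  half_period <- 0.5 * stats::median(diff(t[troughs]))
  vapply(troughs, function(i) {
    win <- which(abs(t - t[i]) <= 0.45 * half_period)
    w <- pmax(0, (x[i] + 0.1 * p2p) - x[win])
    if (sum(w) <= 0) t[i] else sum(w * t[win]) / sum(w)
  }, 0)
}

#' Orient a surrogate displacement series so inhale is positive
#'
#' The sign of a tracked SI displacement depends on which way the
#' structure moves through the image. Because free breathing dwells at
#' end-exhale, the series median sits near the end-exhale baseline and the
#' inhale excursion is the larger deviation from it: the series is flipped
#' when the negative excursion dominates.
#'
#' @param disp numeric displacement series in mm.
#' @return The series with inhale positive.
#' @export
orient_si <- function(disp) {
  med <- stats::median(disp, na.rm = TRUE)
  dev <- disp - med
  if (!any(is.finite(dev)) || all(dev == 0, na.rm = TRUE)) return(disp)
  if (abs(min(dev, na.rm = TRUE)) > abs(max(dev, na.rm = TRUE))) -disp
  else disp
}

#' Phase coordinates of the building 4DMRI bins
#'
#' Bins are equal phase increments over the breathing cycle with bin 0 at
#' end-exhale, so bin `k` carries phase `k`.
#'
#' @param n_bins number of bins.
#' @return Integer phases `0:(n_bins - 1)`.
#' @export
bin_phases_of_building <- function(n_bins) {
  if (n_bins < 2L) stop("bin_phases_of_building: 'n_bins' must be >= 2")
  0:(as.integer(n_bins) - 1L)
}

#' Write / read surrogate series as CSV
#'
#' Serialises a `surrogate_signal` or `surrogate_samples` table (columns
#' among `frame`, `t_s`, `displacement_mm`, `phase`, `amplitude`, `score`,
#' `valid`) to CSV and back; `read_surrogate` restores the plain table,
#' suitable for [estimate_dvf()] / [estimate_volume()] loops or the CLI
#' `estimate` subcommand.
#'
#' @param samples a surrogate table.
#' @param path CSV file path.
#' @return `path` invisibly (writer); a data.frame (reader).
#' @export
write_surrogate <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  if (!file.exists(path)) stop("read_surrogate: file not found: ", path)
  utils::read.csv(path)
}

#' Surrogate displacement of each 4DMRI bin
#'
#' Tracks the surrogate structure on the sagittal slice of every bin volume
#' (template from bin 0) and returns the SI displacement per bin, used to
#' normalise amplitudes (building 4DMRI) or to drive 3D testing
#' estimations.
#'
#' @param fourD list of [volume3d()] bins, bin 1 = end-exhale.
#' @param sag_index 0-based RL slice index of the sagittal plane.
#' @param roi optional ROI as in [extract_signal()].
#' @param params tracking options as in [extract_signal()].
#' @return numeric vector of per-bin SI displacements in mm (bin 1 = 0).
#' @export
surrogate_from_4d <- function(fourD, sag_index, roi = NULL, params = list()) {
  p <- utils::modifyList(list(template_half = c(6L, 8L),
                              search_half = c(4L, 12L),
                              score_threshold = 0.2, subpixel = TRUE), params)
  sp <- fourD[[1]]$spacing[1:2]
  frames <- lapply(fourD, function(v) v$data[, , sag_index + 1L])
  if (is.null(roi)) roi <- default_surrogate_roi(frames[[1]], sp, p)
  lm0 <- data.frame(id = "surrogate", x_mm = roi$x_mm, y_mm = roi$y_mm)
  tr <- track_landmarks(frames, lm0, sp,
                        template_half = p$template_half,
                        search_half = p$search_half,
                        score_threshold = p$score_threshold,
                        subpixel = p$subpixel)
  tr$y_mm - tr$y_mm[1]
}
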