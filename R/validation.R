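#' Median and interquartile range of a sample
#'
#' The reporting convention used throughout the package: median and
#' IQR = Q3 - Q1, with quartiles computed by linear interpolation between
#' order statistics (`stats::quantile` type 7), so summaries are
#' bit-reproducible across runs.
#'
#' @param x numeric vector of mm values (NAs dropped); must be non-empty.
#' @return Named numeric: `median`, `iqr`.
#' @export
summarize_mm <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("summarize_mm: no finite samples")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], iqr = q[3] - q[1])
}

#' Distance between centres of mass of two binary masks
#'
#' Intensity-unweighted voxel-centre centroids in world mm; Euclidean
#' distance between them. Symmetric in its arguments.
#'
#' @param mask_a,mask_b binary [volume3d()] objects (or logical arrays on
#'   the same grid wrapped in volumes); must be non-empty.
#' @return Distance in mm.
#' @export
com_distance <- function(mask_a, mask_b) {
  stop_if_grid_mismatch(mask_a, mask_b, "masks")
  sqrt(sum((mask_com(mask_a) - mask_com(mask_b))^2))
}

mask_com <- function(mask) {
  sel <- which(mask$data > 0.5)
  if (!length(sel)) stop("com_distance: empty mask")
  v <- arrayInd(sel, grid_dim(mask)) - 1L
  mask$origin + colMeans(v) * mask$spacing
}

# |u_est - u_truth| at a set of voxels (deforming region by default)
dvf_error_mm <- function(est, truth, region = NULL) {
  stop_if_grid_mismatch(est, truth, "estimated and truth fields")
  diff2 <- (est$u[, , , 1] - truth$u[, , , 1])^2 +
    (est$u[, , , 2] - truth$u[, , , 2])^2 +
    (est$u[, , , 3] - truth$u[, , , 3])^2
  if (is.null(region)) {
    mag <- truth$u[, , , 1]^2 + truth$u[, , , 2]^2 + truth$u[, , , 3]^2
    region <- mag > 0.25 # deforming region: |u_true| > 0.5 mm
    if (!any(region)) region <- rep(TRUE, length(mag))
  }
  sqrt(diff2[region])
}

#' Registration (DIR) error via automatically extracted points
#'
#' For each registration under test, keypoints are detected in the fixed
#' image and in the warped moving image, matched by descriptor, and the 3D
#' distance between matched positions is the residual registration error.
#' When a ground-truth field is supplied (phantom data), the voxelwise
#' error `|u - u_truth|` over the deforming region is reported alongside as
#' an oracle row.
#'
#' @param cases list of cases; each a list with `name`, `fixed`, `moving`
#'   ([volume3d()]), `dvf` ([vectorfield3d()]) and optional `truth_dvf`.
#' @param kp_params options for [detect_keypoints()].
#' @return A data.frame with one row per case and method: `name`, `method`
#'   (`"keypoints"` or `"truth"`), `n`, `median_mm`, `iqr_mm`,
#'   `low_confidence` (fewer than 10 matches).
#' @export
dir_validation <- function(cases, kp_params = list()) {
  rows <- list()
  for (cs in cases) {
    warped <- warp_volume(cs$moving, cs$dvf)
    ka <- detect_keypoints(cs$fixed, kp_params)
    kb <- detect_keypoints(warped, kp_params)
    m <- match_keypoints(ka, kb)
    if (nrow(m)) {
      s <- summarize_mm(m$dist_mm)
      rows[[length(rows) + 1L]] <-
        data.frame(name = cs$name, method = "keypoints", n = nrow(m),
                   median_mm = s["median"], iqr_mm = s["iqr"],
                   low_confidence = nrow(m) < 10L)
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(name = cs$name, method = "keypoints", n = 0L,
                   median_mm = NA_real_, iqr_mm = NA_real_,
                   low_confidence = TRUE)
    }
    if (!is.null(cs$truth_dvf)) {
      e <- dvf_error_mm(cs$dvf, cs$truth_dvf)
      s <- summarize_mm(e)
      rows[[length(rows) + 1L]] <-
        data.frame(name = cs$name, method = "truth", n = length(e),
                   median_mm = s["median"], iqr_mm = s["iqr"],
                   low_confidence = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' 3D model validation against a testing 4DMRI
#'
#' Estimates a 3D volume for every testing bin from its surrogate sample
#' and compares it with the ground-truth bin: keypoint match distances
#' (estimate vs truth volume), tumour centre-of-mass distance (reference
#' mask warped by the estimated DVF with nearest-neighbour interpolation vs
#' the truth bin mask), and, when truth DVFs are available, the voxelwise
#' correspondence error. Range-of-motion rows (end-inhale vs reference,
#' keypoints and COM) quantify the motion the model has to compensate.
#'
#' @param model a [motion_model()].
#' @param testing_fourD list of testing bin [volume3d()]s.
#' @param samples data.frame with one row per testing bin: `phase`,
#'   `amplitude`.
#' @param tumour_mask_ref reference binary [volume3d()] tumour mask (in
#'   the frame of the active reference).
#' @param truth optional list with `dvf` (list of truth [vectorfield3d()]
#'   per bin, relative to the testing reference) and `masks` (list of
#'   truth binary arrays per bin).
#' @param kp_params options for [detect_keypoints()].
#' @return A `validation_report` (list): `samples` (per-bin metric rows),
#'   `summary` (median/IQR per metric), `jacobian` (per-bin plausibility
#'   fractions), `estimated_dvfs` omitted to save memory.
#' @export
validate_3d <- function(model, testing_fourD, samples, tumour_mask_ref,
                        truth = NULL, kp_params = list()) {
  n_bins <- length(testing_fourD)
  stopifnot(nrow(samples) == n_bins)
  per_bin <- list()
  kp_err <- c(); com_err <- c(); tr_err <- c(); jfrac <- c()
  kp_truth <- detect_keypoints(testing_fourD[[1]], kp_params)
  end_inhale <- which.max(vapply(seq_len(n_bins) - 1L, function(k) {
    if (!is.null(truth)) max(abs(truth$dvf[[k + 1L]]$u)) else
      mean(abs(testing_fourD[[k + 1L]]$data - testing_fourD[[1]]$data))
  }, 0)) - 1L
  for (k in seq_len(n_bins)) {
    est <- estimate_volume(model, samples$phase[k], samples$amplitude[k])
    dvf <- attr(est, "dvf")
    jfrac[k] <- plausibility_fraction(jacobian_determinant(dvf))
    ke <- detect_keypoints(est, kp_params)
    kt <- detect_keypoints(testing_fourD[[k]], kp_params)
    m <- match_keypoints(ke, kt)
    kp_err_k <- if (nrow(m)) stats::median(m$dist_mm) else NA_real_
    kp_err <- c(kp_err, m$dist_mm)
    mask_est <- warp_volume(tumour_mask_ref, dvf, interp = "nearest")
    com_err_k <- if (!is.null(truth))
      com_distance(mask_est, as_mask_volume(truth$masks[[k]], tumour_mask_ref))
    else NA_real_
    com_err <- c(com_err, com_err_k)
    tr_err_k <- NA_real_
    if (!is.null(truth)) {
      e <- dvf_error_mm(dvf, truth$dvf[[k]])
      tr_err_k <- stats::median(e)
      tr_err <- c(tr_err, e)
    }
    per_bin[[k]] <- data.frame(bin = k - 1L, phase = samples$phase[k],
                               amplitude = samples$amplitude[k],
                               n_matches = nrow(m),
                               kp_median_mm = kp_err_k,
                               com_mm = com_err_k,
                               truth_median_mm = tr_err_k,
                               jacobian_plausibility = jfrac[k])
  }
  # range of motion: end-inhale vs reference
  k_ei <- end_inhale + 1L
  kei <- detect_keypoints(testing_fourD[[k_ei]], kp_params)
  m_rom <- match_keypoints(kp_truth, kei, max_dist_mm = Inf)
  rom_kp <- if (nrow(m_rom)) m_rom$dist_mm else NA_real_
  rom_com <- if (!is.null(truth))
    com_distance(as_mask_volume(truth$masks[[1]], tumour_mask_ref),
                 as_mask_volume(truth$masks[[k_ei]], tumour_mask_ref))
  else NA_real_
  summary <- rbind(
    metric_row("point_error", kp_err),
    metric_row("com_error", com_err),
    if (length(tr_err)) metric_row("truth_error", tr_err),
    metric_row("rom_points", rom_kp),
    metric_row("rom_com", rom_com))
  structure(list(samples = do.call(rbind, per_bin), summary = summary,
                 jacobian = jfrac, end_inhale_bin = end_inhale),
            class = "validation_report")
}

as_mask_volume <- function(mask_arr, like) {
  if (inherits(mask_arr, "volume3d")) return(mask_arr)
  volume3d(array(as.numeric(mask_arr), grid_dim(like)),
           spacing = like$spacing, origin = like$origin,
           axis_labels = like$axis_labels)
}

metric_row <- function(metric, x) {
  x <- x[is.finite(x)]
  if (!length(x))
    return(data.frame(metric = metric, n = 0L, median_mm = NA_real_,
                      iqr_mm = NA_real_))
  s <- summarize_mm(x)
  data.frame(metric = metric, n = length(x), median_mm = s["median"],
             iqr_mm = s["iqr"], row.names = NULL)
}

#' 2D model validation against a cine series
#'
#' For every cine frame with a valid surrogate sample, the model estimates
#' the 3D volume, the slice co-located with the frame's plane is extracted,
#' and the frame-0 landmark templates are tracked on both the cine frame
#' and the estimated slice. Three metrics follow the standard convention:
#' `cine_error` (in-plane distance between the two tracked positions),
#' `cine_motion` (per-landmark maximum displacement of the cine positions
#' from the end-exhale reference-slice positions) and `fourD_motion`
#' (per-landmark displacement range across the building 4DMRI bins'
#' slices). Frames with invalid tracking are excluded and counted.
#'
#' @param model a [motion_model()].
#' @param cine cine series (see [extract_cine_frames()]).
#' @param landmarks0 data.frame `id, plane, x_mm, y_mm`: landmark positions
#'   on the first frame of each plane.
#' @param building_fourD the building 4DMRI bins (for `fourD_motion`).
#' @param samples `surrogate_samples` covering the cine frames.
#' @param track_params options: `template_half_mm`, `search_half_mm` (window
#'   sizes in mm, converted per axis), `score_threshold`, `subpixel`.
#' @param planes planes to evaluate (default both).
#' @return A `validation_report` with per-(landmark, frame) samples and a
#'   pooled summary, plus per-frame Jacobian plausibility fractions.
#' @export
validate_2d <- function(model, cine, landmarks0, building_fourD, samples,
                        track_params = list(), planes = c("sagittal",
                                                          "coronal")) {
  tp <- utils::modifyList(list(template_half_mm = 8, search_half_mm = 14,
                               score_threshold = 0.4, subpixel = TRUE),
                          track_params)
  jfrac <- c(); res <- list(); n_excluded <- 0L
  for (pl in intersect(planes, unique(cine$plane))) {
    lms <- landmarks0[landmarks0$plane == pl, , drop = FALSE]
    if (!nrow(lms)) next
    sel <- which(cine$plane == pl)
    sel_valid <- sel[samples$valid[sel]]
    n_excluded <- n_excluded + length(sel) - length(sel_valid)
    if (!length(sel_valid)) next
    sp <- plane_spacing(cine, pl)
    # window sizes in mm -> px per (anisotropic) axis
    tp$template_half <- pmax(1L, round(tp$template_half_mm / sp))
    tp$search_half <- pmax(1L, round(tp$search_half_mm / sp))
    cine_frames <- cine$frames[sel]
    # track on the full plane series once (templates from frame 1)
    tr_cine <- track_landmarks(cine_frames, lms, sp,
                               template_half = tp$template_half,
                               search_half = tp$search_half,
                               score_threshold = tp$score_threshold,
                               subpixel = tp$subpixel)
    # estimated slices for the valid frames
    est_slices <- vector("list", length(sel_valid))
    for (q in seq_along(sel_valid)) {
      i <- sel_valid[q]
      est <- estimate_volume(model, samples$phase[i], samples$amplitude[i])
      jfrac <- c(jfrac, plausibility_fraction(
        jacobian_determinant(attr(est, "dvf"))))
      est_slices[[q]] <- extract_plane(est, cine, pl)
    }
    # seed estimated-slice tracking with the same frame-0 templates:
    # prepend the reference cine frame so templates match
    tr_est <- track_landmarks(c(cine_frames[1], est_slices), lms, sp,
                              template_half = tp$template_half,
                              search_half = tp$search_half,
                              score_threshold = tp$score_threshold,
                              subpixel = tp$subpixel)
    tr_est <- tr_est[tr_est$frame > 0L, , drop = FALSE]
    tr_est$frame_full <- sel_valid[tr_est$frame] - 1L
    # end-exhale / per-bin building-4D slice positions
    bins_slices <- lapply(building_fourD, extract_plane, cine = cine,
                          plane = pl)
    tr_bins <- track_landmarks(c(cine_frames[1], bins_slices), lms, sp,
                               template_half = tp$template_half,
                               search_half = tp$search_half,
                               score_threshold = tp$score_threshold,
                               subpixel = tp$subpixel)
    tr_bins <- tr_bins[tr_bins$frame > 0L, , drop = FALSE]
    for (li in seq_len(nrow(lms))) {
      id <- lms$id[li]
      tc <- tr_cine[tr_cine$id == id, , drop = FALSE]
      te <- tr_est[tr_est$id == id, , drop = FALSE]
      tb <- tr_bins[tr_bins$id == id & tr_bins$valid, , drop = FALSE]
      # cine-error on frames where both tracks are valid
      idx_full <- sel[tc$frame + 1L] - 1L
      tc$frame_full <- idx_full
      mrg <- merge(tc[tc$valid, c("frame_full", "x_mm", "y_mm")],
                   te[te$valid, c("frame_full", "x_mm", "y_mm")],
                   by = "frame_full", suffixes = c("_cine", "_est"))
      if (nrow(mrg)) {
        cine_err <- sqrt((mrg$x_mm_cine - mrg$x_mm_est)^2 +
                           (mrg$y_mm_cine - mrg$y_mm_est)^2)
        res[[length(res) + 1L]] <-
          data.frame(plane = pl, id = id, metric = "cine_error",
                     value_mm = cine_err)
      }
      # cine-motion: max displacement vs end-exhale reference slice
      ee <- tr_bins[tr_bins$id == id & tr_bins$frame == 1L, , drop = FALSE]
      if (nrow(ee) == 1L && ee$valid && any(tc$valid)) {
        dmove <- sqrt((tc$x_mm[tc$valid] - ee$x_mm)^2 +
                        (tc$y_mm[tc$valid] - ee$y_mm)^2)
        res[[length(res) + 1L]] <-
          data.frame(plane = pl, id = id, metric = "cine_motion",
                     value_mm = max(dmove))
      }
      # 4DMRI-motion: displacement range across building bins
      if (nrow(tb) >= 2L) {
        dx <- diff(range(tb$x_mm)); dy <- diff(range(tb$y_mm))
        res[[length(res) + 1L]] <-
          data.frame(plane = pl, id = id, metric = "fourD_motion",
                     value_mm = sqrt(dx^2 + dy^2))
      }
    }
  }
  samples_df <- if (length(res)) do.call(rbind, res) else
    data.frame(plane = character(), id = character(), metric = character(),
               value_mm = numeric())
  mets <- unique(samples_df$metric)
  summary <- do.call(rbind, lapply(mets, function(m)
    metric_row(m, samples_df$value_mm[samples_df$metric == m])))
  structure(list(samples = samples_df, summary = summary, jacobian = jfrac,
                 n_excluded_frames = n_excluded),
            class = "validation_report")
}

plane_spacing <- function(cine, plane) {
  if (plane == "sagittal") cine$sag_spacing else cine$cor_spacing
}

# extract the cine-co-located slice of a volume as a 2D matrix
extract_plane <- function(vol, cine, plane) {
  if (plane == "sagittal") vol$data[, , cine$sag_rl_index + 1L]
  else vol$data[cine$cor_ap_index + 1L, , ]
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(x$summary, row.names = FALSE)
  if (length(x$jacobian))
    cat(sprintf("  Jacobian plausibility: min %.4f over %d estimations\n",
                min(x$jacobian), length(x$jacobian)))
  invisible(x)
}
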