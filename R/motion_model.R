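#' Fit a global respiratory motion model to a 4DMRI
#'
#' Builds the model of a respiratory-correlated 4DMRI: bin 0 (end-exhale)
#' is the reference, and deformable registration of the reference onto
#' every other phase bin yields a library of backward-mapping deformation
#' vector fields, one per bin, with the bin-0 field identically zero. The
#' surrogate structure is tracked across the bins' sagittal slices to fix
#' the amplitude normalisation `building_peak_mm` (surrogate displacement
#' at the deepest library breath). Estimation for an arbitrary respiratory
#' state interpolates the library linearly on the circular phase
#' coordinate, scales the interpolated field by the amplitude, and warps
#' the (possibly baseline-updated) reference.
#'
#' @param fourD list of [volume3d()] phase bins; element 1 must be the
#'   end-exhale bin.
#' @param params a [registration_params()].
#' @param sag_index 0-based RL index of the sagittal plane used for
#'   surrogate tracking; defaults to the mid slab.
#' @param surrogate_roi optional ROI (see [extract_signal()]).
#' @param amp_clip maximum amplitude accepted at estimation time.
#' @param verbose print per-bin registration progress.
#' @return An object of class `motion_model` with elements `reference`,
#'   `library` (list of [vectorfield3d()]), `bin_phases`, `bin_surrogate_mm`,
#'   `building_peak_mm`, `baseline` and `updated_reference` (both `NULL`
#'   until [update_baseline()]), `params`.
#' @seealso [predict.motion_model()], [update_baseline()], [estimate_dvf()],
#'   [estimate_volume()]
#' @export
motion_model <- function(fourD, params = registration_params(),
                         sag_index = NULL, surrogate_roi = NULL,
                         amp_clip = 2, verbose = FALSE) {
  if (length(fourD) < 2L)
    stop("motion_model: need at least 2 phase bins")
  lapply(fourD, function(v) stopifnot(inherits(v, "volume3d")))
  n_bins <- length(fourD)
  reference <- fourD[[1]]
  for (k in 2:n_bins) stop_if_grid_mismatch(reference, fourD[[k]], "4DMRI bins")
  if (is.null(sag_index))
    sag_index <- (grid_dim(reference)[3] - 1L) %/% 2L
  library_ <- vector("list", n_bins)
  library_[[1]] <- zero_field(reference)
  for (k in 2:n_bins) {
    if (verbose) message("registering bin ", k - 1L, " / ", n_bins - 1L)
    library_[[k]] <- register_deformable(fixed = fourD[[k]],
                                         moving = reference, params = params)
  }
  surr <- orient_si(surrogate_from_4d(fourD, sag_index, roi = surrogate_roi))
  peak <- max(surr)
  if (!is.finite(peak) || peak <= 0) {
    warning("motion_model: no usable surrogate excursion across bins; ",
            "building_peak_mm set to NA (amplitudes must be supplied ",
            "externally)")
    peak <- NA_real_
  }
  structure(list(reference = reference, library = library_,
                 bin_phases = bin_phases_of_building(n_bins),
                 bin_surrogate_mm = surr, building_peak_mm = peak,
                 baseline = NULL, updated_reference = NULL,
                 sag_index = sag_index, amp_clip = amp_clip,
                 params = params),
            class = "motion_model")
}

#' @export
print.motion_model <- function(x, ...) {
  d <- grid_dim(x$reference)
  cat(sprintf("<motion_model> %d phase bins on a %d x %d x %d grid\n",
              length(x$library), d[1], d[2], d[3]))
  cat(sprintf("  building peak surrogate displacement: %.2f mm\n",
              x$building_peak_mm))
  cat(sprintf("  baseline update: %s\n",
              if (is.null(x$baseline)) "none" else "applied"))
  invisible(x)
}

#' @export
summary.motion_model <- function(object, ...) {
  mags <- vapply(object$library, function(f)
    max(sqrt(f$u[, , , 1]^2 + f$u[, , , 2]^2 + f$u[, , , 3]^2)), 0)
  out <- list(n_bins = length(object$library),
              max_displacement_mm = mags,
              bin_surrogate_mm = object$bin_surrogate_mm,
              building_peak_mm = object$building_peak_mm,
              baseline = !is.null(object$baseline))
  class(out) <- "summary.motion_model"
  out
}

#' @export
print.summary.motion_model <- function(x, ...) {
  cat("Global respiratory motion model\n")
  cat(sprintf("  bins: %d; building peak surrogate: %.2f mm; baseline: %s\n",
              x$n_bins, x$building_peak_mm,
              if (x$baseline) "updated" else "none"))
  cat("  per-bin max |DVF| (mm):",
      paste(sprintf("%.1f", x$max_displacement_mm), collapse = " "), "\n")
  invisible(x)
}

#' Update the model reference for inter-fraction baseline variation
#'
#' Registers the model's reference (moving) to the end-exhale volume of the
#' testing data set (fixed); the resulting baseline DVF warps the reference
#' once, and subsequent estimations warp this updated reference with the
#' respiratory DVF (two sequential warps; the respiratory library itself is
#' left in the original frame). Calling again replaces, not composes, the
#' baseline.
#'
#' @param model a [motion_model()].
#' @param testing_end_exhale end-exhale [volume3d()] of the testing data
#'   set, same grid as the model reference.
#' @param params registration parameters; defaults to the model's.
#' @return The model with `baseline` and `updated_reference` set.
#' @export
update_baseline <- function(model, testing_end_exhale, params = model$params) {
  stopifnot(inherits(model, "motion_model"),
            inherits(testing_end_exhale, "volume3d"))
  stop_if_grid_mismatch(model$reference, testing_end_exhale,
                        "model reference and testing end-exhale")
  baseline <- register_deformable(fixed = testing_end_exhale,
                                  moving = model$reference, params = params)
  model$baseline <- baseline
  model$updated_reference <- warp_volume(model$reference, baseline)
  model
}

#' Estimate the deformation for a surrogate sample
#'
#' Piecewise-linear interpolation of the DVF library on the circular phase
#' coordinate, scaled uniformly by the amplitude: with `k = floor(phase)`
#' and `w = phase - k`, the estimate is
#' `amplitude * ((1 - w) * library[k] + w * library[(k + 1) %% n_bins])`.
#' Integer phases return the stored library field exactly; amplitude 0
#' returns the zero field. Amplitudes above the model's clip limit are
#' clipped with a warning.
#'
#' @param model a [motion_model()].
#' @param phase circular phase in `[0, n_bins)`.
#' @param amplitude non-negative amplitude (1 = building-breath depth).
#' @return A [vectorfield3d()].
#' @export
estimate_dvf <- function(model, phase, amplitude) {
  stopifnot(inherits(model, "motion_model"))
  n <- length(model$library)
  if (!is.finite(phase) || !is.finite(amplitude))
    stop("estimate_dvf: phase and amplitude must be finite")
  if (amplitude < 0) stop("estimate_dvf: amplitude must be >= 0")
  if (amplitude > model$amp_clip) {
    warning("estimate_dvf: amplitude ", format(amplitude),
            " above clip limit ", model$amp_clip, "; clipped")
    amplitude <- model$amp_clip
  }
  phase <- phase %% n
  k <- floor(phase)
  w <- phase - k
  k0 <- as.integer(k) + 1L
  k1 <- (as.integer(k) + 1L) %% n + 1L
  f0 <- model$library[[k0]]
  u <- if (w == 0) amplitude * f0$u
  else amplitude * ((1 - w) * f0$u + w * model$library[[k1]]$u)
  vectorfield3d(u, spacing = f0$spacing, origin = f0$origin,
                axis_labels = f0$axis_labels)
}

#' Estimate the 3D volume for a surrogate sample
#'
#' Warps the active reference (the baseline-updated reference when a
#' baseline has been set, the building reference otherwise) by the
#' estimated DVF of [estimate_dvf()]. At amplitude 0 the active reference
#' is returned bit-identically (no resampling pass).
#'
#' @inheritParams estimate_dvf
#' @return A [volume3d()] with the estimated DVF attached as attribute
#'   `dvf` (for Jacobian plausibility analysis).
#' @export
estimate_volume <- function(model, phase, amplitude) {
  stopifnot(inherits(model, "motion_model"))
  ref <- if (!is.null(model$baseline)) model$updated_reference
  else model$reference
  if (amplitude == 0) {
    out <- ref
    attr(out, "dvf") <- zero_field(ref)
    return(out)
  }
  dvf <- estimate_dvf(model, phase, amplitude)
  out <- warp_volume(ref, dvf)
  attr(out, "dvf") <- dvf
  out
}

#' Predict method for motion models
#'
#' @param object a [motion_model()].
#' @param phase,amplitude surrogate sample(s); vectors are recycled to a
#'   common length.
#' @param type `"dvf"` or `"volume"`.
#' @param ... unused.
#' @return A single [vectorfield3d()]/[volume3d()] for scalar input, else a
#'   list of them.
#' @export
predict.motion_model <- function(object, phase, amplitude,
                                 type = c("volume", "dvf"), ...) {
  type <- match.arg(type)
  n <- max(length(phase), length(amplitude))
  phase <- rep_len(phase, n); amplitude <- rep_len(amplitude, n)
  f <- if (type == "dvf") function(p, a) estimate_dvf(object, p, a)
  else function(p, a) estimate_volume(object, p, a)
  if (n == 1L) f(phase, amplitude)
  else Map(f, phase, amplitude)
}

#' Persist / restore a motion model
#'
#' The model is laid out as a directory: reference volume and per-bin DVFs
#' as NIfTI, optional baseline DVF and updated reference, and a JSON
#' metadata file recording bin count, surrogate normalisation and the
#' geometry conventions.
#'
#' @param model a [motion_model()].
#' @param dir directory path.
#' @return `dir` (resp. the restored model), invisibly for the writer.
#' @export
save_motion_model <- function(model, dir) {
  stopifnot(inherits(model, "motion_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(model$reference, file.path(dir, "reference.nii.gz"))
  for (k in seq_along(model$library))
    write_dvf(model$library[[k]],
              file.path(dir, sprintf("dvf_bin%02d.nii.gz", k - 1L)))
  if (!is.null(model$baseline)) {
    write_dvf(model$baseline, file.path(dir, "baseline.nii.gz"))
    write_volume(model$updated_reference,
                 file.path(dir, "updated_reference.nii.gz"))
  }
  meta <- list(n_bins = length(model$library),
               building_peak_mm = model$building_peak_mm,
               bin_surrogate_mm = model$bin_surrogate_mm,
               sag_index = model$sag_index, amp_clip = model$amp_clip,
               dvf_convention = "backward (pull): warped(x) = moving(x + u(x))",
               axis_order = c("AP", "SI", "RL"))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_motion_model
#' @export
load_motion_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  reference <- read_volume(file.path(dir, "reference.nii.gz"))
  library_ <- lapply(seq_len(meta$n_bins) - 1L, function(k)
    read_dvf(file.path(dir, sprintf("dvf_bin%02d.nii.gz", k))))
  model <- structure(list(reference = reference, library = library_,
                          bin_phases = bin_phases_of_building(meta$n_bins),
                          bin_surrogate_mm = meta$bin_surrogate_mm,
                          building_peak_mm = meta$building_peak_mm,
                          baseline = NULL, updated_reference = NULL,
                          sag_index = meta$sag_index,
                          amp_clip = meta$amp_clip,
                          params = registration_params()),
                     class = "motion_model")
  bl <- file.path(dir, "baseline.nii.gz")
  if (file.exists(bl)) {
    model$baseline <- read_dvf(bl)
    model$updated_reference <- read_volume(file.path(dir,
                                                     "updated_reference.nii.gz"))
  }
  model
}
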