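#' The seven evaluation scenarios
#'
#' Returns the scenario table of the validation framework: 3D/2D,
#' intra-/inter-fraction. Intra-fraction scenarios build and test within
#' one session (no baseline update); inter-fraction scenarios build on
#' session 1 and test on session 2 with the baseline update enabled.
#'
#' @return A data.frame with columns `id`, `type` (2D/3D),
#'   `building_session`, `building_acq`, `testing_session`, `testing_acq`
#'   (`"R1"`, `"R2"` or `"cine"`), `baseline_update`.
#' @export
scenario_table <- function() {
  data.frame(
    id = c("3D-intra-S1", "3D-intra-S2", "2D-intra-S1", "2D-intra-S2",
           "3D-inter-R1", "3D-inter-R2", "2D-inter"),
    type = c("3D", "3D", "2D", "2D", "3D", "3D", "2D"),
    building_session = c("S1", "S2", "S1", "S2", "S1", "S1", "S1"),
    building_acq = "R1",
    testing_session = c("S1", "S2", "S1", "S2", "S2", "S2", "S2"),
    testing_acq = c("R2", "R2", "cine", "cine", "R1", "R2", "cine"),
    baseline_update = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

scenario_spec <- function(id) {
  tab <- scenario_table()
  row <- tab[tab$id == id, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown scenario id '", id, "'; valid ids: ",
         paste(tab$id, collapse = ", "))
  as.list(row)
}

# build (and cache) the model for a building session; models are keyed by
# session id since all scenarios build on R1
get_build_model <- function(pair, session_id, reg_params, cache = NULL,
                            verbose = FALSE) {
  if (!is.null(cache) && !is.null(cache[[session_id]]))
    return(cache[[session_id]])
  s <- pair[[session_id]]
  model <- motion_model(s$fourD$R1, params = reg_params,
                        sag_index = s$cine$sag_rl_index, verbose = verbose)
  if (!is.null(cache)) cache[[session_id]] <- model
  model
}

#' Run one validation scenario on a phantom study
#'
#' Builds the motion model on the scenario's building data set, applies the
#' baseline update for inter-fraction scenarios (registering the building
#' reference to the testing session's end-exhale volume), derives the
#' surrogate samples for the testing data (bin tracking for 4DMRI testing,
#' the cine surrogate signal for 2D testing), runs the 3D or 2D validation
#' and returns its report. A surrogate-extraction failure is recorded as a
#' skipped scenario rather than an error.
#'
#' @param id scenario id (see [scenario_table()]).
#' @param pair a `phantom_pair` from [generate_session_pair()].
#' @param reg_params a [registration_params()].
#' @param model_cache optional environment caching built models across
#'   scenarios (keyed `"S1"`, `"S2"`).
#' @param kp_params,track_params forwarded to the validation layers.
#' @param verbose print progress.
#' @return A `validation_report` with extra fields `scenario` and (when
#'   skipped) `skipped_reason`.
#' @export
run_scenario <- function(id, pair, reg_params = registration_params(),
                         model_cache = NULL, kp_params = list(),
                         track_params = list(), verbose = FALSE) {
  stopifnot(inherits(pair, "phantom_pair"))
  spec <- scenario_spec(id)
  model <- get_build_model(pair, spec$building_session, reg_params,
                           model_cache, verbose)
  build_s <- pair[[spec$building_session]]
  test_s <- pair[[spec$testing_session]]
  if (spec$baseline_update) {
    # testing end-exhale: bin 0 of the testing session's first 4DMRI
    key <- paste0("baseline_", spec$building_session, "_",
                  spec$testing_session)
    if (!is.null(model_cache) && !is.null(model_cache[[key]])) {
      model$baseline <- model_cache[[key]]
      model$updated_reference <- warp_volume(model$reference, model$baseline)
    } else {
      model <- update_baseline(model, test_s$fourD$R1[[1]], reg_params)
      if (!is.null(model_cache)) model_cache[[key]] <- model$baseline
    }
  } else {
    model$baseline <- NULL
    model$updated_reference <- NULL
  }
  n_bins <- length(model$library)
  report <- if (spec$type == "3D") {
    acq <- spec$testing_acq
    fourD_test <- test_s$fourD[[acq]]
    surr <- orient_si(surrogate_from_4d(fourD_test,
                                        test_s$cine$sag_rl_index))
    samples <- data.frame(phase = bin_phases_of_building(n_bins),
                          amplitude = pmax(surr, 0) / model$building_peak_mm)
    truth <- list(
      dvf = lapply(seq_len(n_bins) - 1L, function(k)
        phantom_truth_dvf(test_s, acq, k)),
      masks = test_s$truth$masks[[acq]])
    mask_ref <- model_frame_mask(model, build_s, test_s, spec)
    validate_3d(model, fourD_test, samples, mask_ref, truth = truth,
                kp_params = kp_params)
  } else {
    cine <- extract_cine_frames(test_s)
    samples_all <- tryCatch(
      to_phase_amplitude(extract_signal(cine), model$building_peak_mm,
                         n_bins,
                         mean_period_s = pair$config$breath_period_s),
      error = function(e) e)
    if (inherits(samples_all, "error")) {
      # mirror the clinical case of an unusable surrogate: record and skip
      rep <- structure(list(samples = NULL, summary = NULL,
                            jacobian = numeric(),
                            skipped_reason = conditionMessage(samples_all)),
                       class = "validation_report")
      rep$scenario <- id
      return(rep)
    }
    # expand to one row per cine frame (non-sagittal frames interpolated)
    samples <- expand_samples_to_frames(samples_all, cine, n_bins)
    lms0 <- test_s$landmarks$ref
    lms0 <- data.frame(id = lms0$id, plane = lms0$plane,
                       x_mm = ifelse(lms0$plane == "sagittal", lms0$ap,
                                     lms0$si),
                       y_mm = ifelse(lms0$plane == "sagittal", lms0$si,
                                     lms0$rl))
    validate_2d(model, cine, lms0, build_s$fourD$R1, samples,
                track_params = track_params)
  }
  report$scenario <- id
  report$baseline_update <- spec$baseline_update
  report
}

# the tumour mask in the frame of the active reference: the building
# session's reference mask; after a baseline update the mask is carried to
# the updated reference by the baseline DVF (nearest-neighbour)
model_frame_mask <- function(model, build_s, test_s, spec) {
  m <- as_mask_volume(build_s$truth$mask_ref, model$reference)
  if (spec$baseline_update)
    m <- warp_volume(m, model$baseline, interp = "nearest")
  m
}

# interpolate sagittal-surrogate samples onto every cine frame timestamp
expand_samples_to_frames <- function(samples, cine, n_bins) {
  n <- length(cine$frames)
  ok <- samples$valid
  out <- data.frame(frame = seq_len(n) - 1L, t_s = cine$t,
                    phase = NA_real_, amplitude = NA_real_, valid = FALSE)
  if (sum(ok) >= 2L) {
    t_ok <- samples$t_s[ok]
    amp <- stats::approx(t_ok, samples$amplitude[ok], xout = cine$t,
                         rule = 1)$y
    # circular phase: interpolate unwrapped cycle coordinate
    ph <- samples$phase[ok]
    wraps <- cumsum(c(0, diff(ph) < 0))
    unwrapped <- ph + wraps * n_bins
    phi <- stats::approx(t_ok, unwrapped, xout = cine$t, rule = 1)$y
    out$phase <- phi %% n_bins
    out$amplitude <- amp
    out$valid <- is.finite(out$phase) & is.finite(out$amplitude)
  }
  idx <- match(samples$frame, out$frame)
  out$phase[idx] <- samples$phase
  out$amplitude[idx] <- samples$amplitude
  out$valid[idx] <- samples$valid
  out$valid <- out$valid & is.finite(out$phase) & is.finite(out$amplitude)
  out
}

#' Run all seven scenarios and combine the reports
#'
#' @param pair a `phantom_pair`; generated from `config` when `NULL`.
#' @param config a [phantom_config()] (used when `pair` is `NULL`).
#' @param reg_params a [registration_params()].
#' @param kp_params,track_params forwarded to the validation layers.
#' @param verbose print progress.
#' @return A list of class `scenario_suite`: `reports` (named list of
#'   `validation_report`s), `combined` (one summary table with a scenario
#'   column), `jacobian_min` (minimum plausibility fraction over every
#'   estimation of every scenario).
#' @export
run_all_scenarios <- function(pair = NULL, config = phantom_config(),
                              reg_params = registration_params(),
                              kp_params = list(), track_params = list(),
                              verbose = FALSE) {
  if (is.null(pair)) pair <- generate_session_pair(config)
  cache <- new.env()
  ids <- scenario_table()$id
  reports <- list()
  for (id in ids) {
    if (verbose) message("scenario ", id)
    reports[[id]] <- run_scenario(id, pair, reg_params, model_cache = cache,
                                  kp_params = kp_params,
                                  track_params = track_params,
                                  verbose = verbose)
  }
  combined <- do.call(rbind, lapply(ids, function(id) {
    r <- reports[[id]]
    if (is.null(r$summary)) return(NULL)
    cbind(scenario = id, r$summary)
  }))
  jac <- unlist(lapply(reports, function(r) r$jacobian))
  dir_rep <- suite_dir_validation(pair, cache, kp_params)
  structure(list(reports = reports, combined = combined,
                 dir = dir_rep,
                 jacobian_min = if (length(jac)) min(jac) else NA_real_),
            class = "scenario_suite")
}

# DIR error evaluation: end-inhale library registrations of both sessions
# plus the inter-session baseline registration, against keypoints and
# phantom truth
suite_dir_validation <- function(pair, cache, kp_params = list()) {
  cases <- list()
  for (sid in c("S1", "S2")) {
    model <- cache[[sid]]
    if (is.null(model)) next
    s <- pair[[sid]]
    k_ei <- which.max(abs(s$truth$bin_scale$R1)) # end-inhale bin
    cases[[length(cases) + 1L]] <- list(
      name = paste0("4DMRI-", sid), fixed = s$fourD$R1[[k_ei]],
      moving = model$reference, dvf = model$library[[k_ei]],
      truth_dvf = phantom_truth_dvf(s, "R1", k_ei - 1L))
    }
  bl <- cache[["baseline_S1_S2"]]
  if (!is.null(bl) && !is.null(cache[["S1"]]))
    cases[[length(cases) + 1L]] <- list(
      name = "INTER", fixed = pair$S2$fourD$R1[[1]],
      moving = cache[["S1"]]$reference, dvf = bl,
      truth_dvf = pair$S2$truth$baseline)
  if (!length(cases)) return(NULL)
  dir_validation(cases, kp_params)
}

#' @export
print.scenario_suite <- function(x, ...) {
  cat("<scenario_suite> 7-scenario validation\n")
  print(x$combined, row.names = FALSE)
  if (!is.null(x$dir)) {
    cat("DIR validation:\n")
    print(x$dir, row.names = FALSE)
  }
  cat(sprintf("minimum Jacobian plausibility over all estimations: %.4f\n",
              x$jacobian_min))
  invisible(x)
}

#' Write scenario reports as CSV/JSON tables
#'
#' Produces one combined CSV in the column structure of the standard 3D
#' (estimation error / range of motion) and 2D (cine-error / cine-motion /
#' 4DMRI-motion) result tables, plus a JSON dump of every report summary.
#'
#' @param suite a `scenario_suite` from [run_all_scenarios()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_reports <- function(suite, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(suite$combined, file.path(dir, "combined_summary.csv"),
                   row.names = FALSE)
  if (!is.null(suite$dir))
    utils::write.csv(suite$dir, file.path(dir, "dir_validation.csv"),
                     row.names = FALSE)
  js <- lapply(suite$reports, function(r) {
    if (!is.null(r$skipped_reason))
      list(scenario = r$scenario, skipped = r$skipped_reason)
    else list(scenario = r$scenario, summary = r$summary,
              jacobian_min = if (length(r$jacobian)) min(r$jacobian) else NULL)
  })
  jsonlite::write_json(list(scenarios = js,
                            jacobian_min = suite$jacobian_min),
                       file.path(dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(dir)
}
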