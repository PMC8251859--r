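# 2D normalised cross-correlation template matching.
#
# Exhaustive search over all integer-pixel shifts inside the window, which
# makes the matcher its own gold standard for integer translations. Ties in
# the NCC score break toward the smallest displacement for determinism; an
# optional 3-point parabolic fit refines the peak to sub-pixel precision.

ncc_match <- function(frame, template, centre_px, search_half,
                      subpixel = TRUE) {
  th <- (dim(template) - 1L) %/% 2L
  nf <- dim(frame)
  tm <- template - mean(template)
  tden <- sqrt(sum(tm^2))
  scores <- matrix(-Inf, 2L * search_half[1] + 1L, 2L * search_half[2] + 1L)
  for (dx in -search_half[1]:search_half[1]) {
    cx <- centre_px[1] + dx
    if (cx - th[1] < 1L || cx + th[1] > nf[1]) next
    for (dy in -search_half[2]:search_half[2]) {
      cy <- centre_px[2] + dy
      if (cy - th[2] < 1L || cy + th[2] > nf[2]) next
      patch <- frame[(cx - th[1]):(cx + th[1]), (cy - th[2]):(cy + th[2])]
      pm <- patch - mean(patch)
      den <- tden * sqrt(sum(pm^2))
      scores[dx + search_half[1] + 1L, dy + search_half[2] + 1L] <-
        if (den > 0) sum(pm * tm) / den else 0
    }
  }
  # deterministic argmax: smallest displacement wins ties
  dxs <- (-search_half[1]):search_half[1]
  dys <- (-search_half[2]):search_half[2]
  d2 <- outer(dxs^2, dys^2, "+")
  eff <- scores - 1e-9 * d2
  best <- arrayInd(which.max(eff), dim(scores))
  bx <- best[1]; by <- best[2]
  shift <- c(dxs[bx], dys[by])
  score <- scores[bx, by]
  if (subpixel && score < 1 - 1e-9) { # an exact match needs no refinement
    for (ax in 1:2) {
      i <- best[ax]
      nmax <- dim(scores)[ax]
      if (i > 1L && i < nmax) {
        s0 <- if (ax == 1) scores[i - 1L, by] else scores[bx, i - 1L]
        s1 <- score
        s2 <- if (ax == 1) scores[i + 1L, by] else scores[bx, i + 1L]
        den <- s0 - 2 * s1 + s2
        if (is.finite(s0) && is.finite(s2) && den < 0) {
          delta <- 0.5 * (s0 - s2) / den
          if (abs(delta) <= 0.5) shift[ax] <- shift[ax] + delta
        }
      }
    }
  }
  list(shift_px = shift, score = score)
}

#' Track landmarks across 2D frames by template matching
#'
#' Each landmark's template is taken from the first frame and located in
#' every frame by exhaustive normalised cross-correlation within a bounded
#' search window (integer-pixel argmax, smallest displacement on ties,
#' optional parabolic sub-pixel refinement). Frames whose peak score falls
#' below `score_threshold` are flagged invalid.
#'
#' @param frames list of 2D matrices (one plane only).
#' @param landmarks0 data.frame with columns `id`, `x_mm`, `y_mm`: positions
#'   on frame 1 (world mm in-plane; axis 1 = matrix rows).
#' @param spacing_mm numeric(2) in-plane pixel spacing.
#' @param template_half integer(2) template half-size in px.
#' @param search_half integer(2) search window half-size in px.
#' @param score_threshold minimum NCC peak for a valid match.
#' @param subpixel logical, parabolic peak refinement.
#' @return A data.frame with one row per (landmark, frame): `id`, `frame`
#'   (0-based), `x_mm`, `y_mm`, `score`, `valid`.
#' @export
track_landmarks <- function(frames, landmarks0, spacing_mm,
                            template_half = c(7L, 7L),
                            search_half = c(10L, 10L),
                            score_threshold = 0.5, subpixel = TRUE) {
  stopifnot(length(frames) >= 1L)
  f0 <- frames[[1]]
  nf <- dim(f0)
  out <- vector("list", nrow(landmarks0))
  for (li in seq_len(nrow(landmarks0))) {
    cx <- round(landmarks0$x_mm[li] / spacing_mm[1]) + 1L
    cy <- round(landmarks0$y_mm[li] / spacing_mm[2]) + 1L
    if (cx - template_half[1] < 1L || cx + template_half[1] > nf[1] ||
        cy - template_half[2] < 1L || cy + template_half[2] > nf[2])
      stop("track_landmarks: template for landmark '", landmarks0$id[li],
           "' touches the image border")
    template <- f0[(cx - template_half[1]):(cx + template_half[1]),
                   (cy - template_half[2]):(cy + template_half[2])]
    rows <- data.frame(id = landmarks0$id[li],
                       frame = seq_along(frames) - 1L,
                       x_mm = NA_real_, y_mm = NA_real_,
                       score = NA_real_, valid = FALSE)
    for (fi in seq_along(frames)) {
      m <- ncc_match(frames[[fi]], template, c(cx, cy), search_half,
                     subpixel = subpixel)
      rows$x_mm[fi] <- landmarks0$x_mm[li] + m$shift_px[1] * spacing_mm[1]
      rows$y_mm[fi] <- landmarks0$y_mm[li] + m$shift_px[2] * spacing_mm[2]
      rows$score[fi] <- m$score
      rows$valid[fi] <- is.finite(m$score) && m$score >= score_threshold
    }
    out[[li]] <- rows
  }
  do.call(rbind, out)
}
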