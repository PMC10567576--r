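# Time-lapse analysis at nanopillars: per-pillar intensity traces,
# intensity-based grouping, and normalized temporal standard deviation.

#' Extract per-pillar intensity traces from a time-lapse
#'
#' The lattice is registered on frame 1 and assumed static; frame-to-frame
#' drift is checked by integer cross-correlation against frame 1 and the
#' extraction fails when it exceeds `max_drift` pixels.
#'
#' @param timelapse a `curv_timelapse` (see [render_timelapse()]) or a list
#'   of frames, each a named list of channel matrices.
#' @param windows a [tile_windows()] result (typically from frame 1).
#' @param rois pillar [derive_pillar_rois()] masks.
#' @param channel channel name to trace.
#' @param max_drift tolerated drift in pixels.
#' @return matrix `[n_pillars x n_frames]` of mean intensities over the
#'   pillar mask, row names = window ids.
#' @export
extract_traces <- function(timelapse, windows, rois, channel = "poi",
                           max_drift = 2) {
  frames <- if (inherits(timelapse, "curv_timelapse")) timelapse$frames else timelapse
  n_f <- length(frames)
  ref <- frames[[1]][[channel]]
  for (t in seq_len(n_f)) {
    d <- .xcorr_shift(ref, frames[[t]][[channel]])
    if (is.null(d)) {
      message("drift check inconclusive (no registrable structure); assuming static")
      break
    }
    if (max(abs(d)) > max_drift)
      stop("drift: frame ", t, " shifted by (", d[1], ", ", d[2], ") pixels")
  }
  tr <- vapply(seq_len(n_f), function(t)
    .window_mask_means(frames[[t]][[channel]], windows, rois$pillar_mask),
    numeric(sum(windows$in_cell)))
  tr <- matrix(tr, nrow = sum(windows$in_cell))
  rownames(tr) <- windows$id[windows$in_cell]
  tr
}

# Integer image shift (dx, dy) maximizing the circular cross-correlation,
# searched only within +/- radius (the images are lattice-periodic, so large
# shifts alias; small-drift detection is all that is needed). Returns NULL
# when the correlation peak is not significant against the plane-wide
# distribution, i.e. there is no registrable structure.
.xcorr_shift <- function(a, b, radius = 5L) {
  FA <- stats::fft(a - mean(a)); FB <- stats::fft(b - mean(b))
  cc <- Re(stats::fft(FA * Conj(FB), inverse = TRUE))
  sh <- c(0:radius, (-radius):(-1))
  win <- cc[sh %% nrow(a) + 1L, sh %% ncol(a) + 1L]
  pk <- arrayInd(which.max(win), dim(win))
  if ((max(win) - mean(cc)) < 5 * stats::sd(cc)) return(NULL)
  c(sh[pk[2]], sh[pk[1]])
}

#' Group pillars by integrin intensity
#'
#' `quartile_top25_bottom25` labels the top 25% `high_b5`, the bottom 25%
#' `low_b5` and the middle half `NA` (F-actin protocol);
#' `top25_bottom75` labels the top 25% `high_b5` and all others `low_b5`
#' (FCHo2 protocol). Quantile cuts use the nearest-rank method; ties
#' spanning a cut are resolved deterministically by pillar index (logged).
#'
#' @param intensities numeric vector of per-pillar intensities.
#' @param scheme grouping scheme.
#' @return factor with levels `high_b5`, `low_b5` (possibly `NA`s).
#' @export
group_by_intensity <- function(intensities,
                               scheme = c("top25_bottom75",
                                          "quartile_top25_bottom25")) {
  scheme <- match.arg(scheme)
  n <- length(intensities)
  if (n < 8L) stop("need at least 8 pillars to group")
  ord <- order(intensities, seq_len(n), decreasing = TRUE)  # index breaks ties
  if (anyDuplicated(intensities))
    message("ties resolved by pillar index")
  n_top <- ceiling(0.25 * n)  # nearest-rank quantile
  lab <- rep(NA_character_, n)
  lab[ord[seq_len(n_top)]] <- "high_b5"
  if (scheme == "top25_bottom75") {
    lab[ord[-seq_len(n_top)]] <- "low_b5"
  } else {
    lab[ord[(n - n_top + 1L):n]] <- "low_b5"
  }
  factor(lab, levels = c("high_b5", "low_b5"))
}

#' Normalized temporal standard deviation of pillar traces
#'
#' Each trace is divided by its value at frame 1 (so the normalized trace
#' starts at 1), then the sample standard deviation (n - 1 denominator) is
#' reported. Traces with a non-positive initial intensity are excluded.
#'
#' @param traces matrix `[n_pillars x n_frames]` from [extract_traces()].
#' @param normalize divide by the initial intensity first (`TRUE`, the
#'   FCHo2 protocol) or use raw intensities (`FALSE`, the LifeAct reading).
#' @return named numeric vector of per-pillar SDs (excluded traces dropped).
#' @export
temporal_sd <- function(traces, normalize = TRUE) {
  if (ncol(traces) < 2L) stop("need at least 2 frames")
  ok <- rep(TRUE, nrow(traces))
  if (normalize) {
    ok <- traces[, 1] > 0
    if (any(!ok)) message(sum(!ok), " trace(s) excluded: zero initial intensity")
    traces <- traces[ok, , drop = FALSE] / traces[ok, 1]
  } else {
    traces <- traces[ok, , drop = FALSE]
  }
  apply(traces, 1, stats::sd)
}
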