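# Ratiometric quantification: membrane-normalized end/side ratios on
# nanobars, pillar/membrane ratios on nanopillars, enriched-pillar
# classification, and rank correlation of a protein of interest with
# integrin enrichment.
#
# The membrane normalization is the load-bearing step: per-bar uneven
# membrane wrapping multiplies the integrin and membrane channels jointly,
# so dividing the integrin end/side ratio by the membrane end/side ratio of
# the same bar cancels the wrap factor exactly.

# Mean of `image` over `mask` (window coordinates) at each selected window.
.window_mask_means <- function(image, windows, mask, use = windows$in_cell) {
  h <- attr(windows, "half")
  side <- attr(windows, "side")
  m <- .fit_mask(mask, side)
  sel <- which(use)
  vapply(sel, function(k) {
    sub <- image[(windows$cy[k] - h):(windows$cy[k] + h),
                 (windows$cx[k] - h):(windows$cx[k] + h)]
    mean(sub[m])
  }, numeric(1))
}

#' Median background of the cell-free image region
#'
#' @param image intensity matrix.
#' @param cell_mask logical matrix marking the cell.
#' @return scalar background estimate (0 when no cell-free pixels exist).
#' @export
estimate_background <- function(image, cell_mask) {
  out <- image[!cell_mask]
  if (length(out) == 0L) return(0)
  stats::median(out)
}

#' Membrane-normalized end/side ratios on nanobars
#'
#' Per bar: `ratio_norm = (end/side of integrin) / (end/side of membrane)`;
#' the per-cell summary is the mean of `ratio_norm` over all bars of the
#' cell (one data point per cell). Bars whose side mean is not positive
#' after background subtraction are excluded and listed.
#'
#' @param integrin,membrane intensity matrices.
#' @param windows a [tile_windows()] result.
#' @param rois bar [derive_bar_rois()] masks.
#' @param cell_id identifier echoed into the per-cell row.
#' @param background length-2 numeric `c(integrin, membrane)` subtracted
#'   before ratioing (default 0: images already corrected).
#' @return object of class `end_side_result`: `per_bar` data frame,
#'   `per_cell` one-row data frame, and `excluded` window ids.
#' @export
end_side_ratios <- function(integrin, membrane, windows, rois, cell_id = 1L,
                            background = c(0, 0)) {
  if (!any(windows$in_cell)) stop("no in-cell windows")
  ids <- windows$id[windows$in_cell]
  e_i <- .window_mask_means(integrin, windows, rois$end_mask) - background[1]
  s_i <- .window_mask_means(integrin, windows, rois$side_mask) - background[1]
  e_m <- .window_mask_means(membrane, windows, rois$end_mask) - background[2]
  s_m <- .window_mask_means(membrane, windows, rois$side_mask) - background[2]
  ok <- s_i > 0 & s_m > 0 & e_m > 0
  if (any(!ok))
    message(sum(!ok), " bar(s) excluded: non-positive denominator after background subtraction")
  per_bar <- data.frame(window = ids, end_integrin = e_i, side_integrin = s_i,
                        end_membrane = e_m, side_membrane = s_m,
                        ratio_integrin = e_i / s_i, ratio_membrane = e_m / s_m)
  per_bar$ratio_norm <- per_bar$ratio_integrin / per_bar$ratio_membrane
  kept <- per_bar[ok, , drop = FALSE]
  if (nrow(kept) == 0L) stop("all bars excluded")
  per_cell <- data.frame(cell = cell_id, n_bars = nrow(kept),
                         mean_ratio_norm = mean(kept$ratio_norm))
  structure(list(per_bar = kept, per_cell = per_cell, excluded = ids[!ok]),
            class = "end_side_result")
}

#' Direct (non-normalized) end/side ratios of a single channel
#'
#' Used when no membrane marker is available; per-bar ratio is simply
#' end mean / side mean of the one channel.
#'
#' @inheritParams end_side_ratios
#' @param channel intensity matrix.
#' @param background scalar background subtracted first.
#' @return an `end_side_result` whose `ratio_norm` column is the direct
#'   ratio.
#' @export
direct_end_side <- function(channel, windows, rois, cell_id = 1L,
                            background = 0) {
  if (!any(windows$in_cell)) stop("no in-cell windows")
  ids <- windows$id[windows$in_cell]
  e <- .window_mask_means(channel, windows, rois$end_mask) - background
  s <- .window_mask_means(channel, windows, rois$side_mask) - background
  ok <- s > 0
  if (any(!ok)) message(sum(!ok), " bar(s) excluded: non-positive side mean")
  per_bar <- data.frame(window = ids, end = e, side = s, ratio_norm = e / s)
  kept <- per_bar[ok, , drop = FALSE]
  if (nrow(kept) == 0L) stop("all bars excluded")
  per_cell <- data.frame(cell = cell_id, n_bars = nrow(kept),
                         mean_ratio_norm = mean(kept$ratio_norm))
  structure(list(per_bar = kept, per_cell = per_cell, excluded = ids[!ok]),
            class = "end_side_result")
}

#' Group per-bar gradient results by bar diameter
#'
#' Bars of the same end-curvature diameter in one imaging field are averaged
#' into a single data point, mirroring the per-field reporting used for
#' gradient arrays.
#'
#' @param per_bar data frame with columns `ratio`, `diameter` and optionally
#'   `field` (default: one field).
#' @return data frame with one row per `(field, diameter)` and columns
#'   `n_bars`, `mean_ratio`; diameters with zero bars are omitted with a
#'   message.
#' @export
gradient_group <- function(per_bar) {
  if (is.null(per_bar$field)) per_bar$field <- 1L
  per_bar <- per_bar[is.finite(per_bar$ratio), , drop = FALSE]
  if (nrow(per_bar) == 0L) stop("no finite ratios to group")
  key <- interaction(per_bar$field, per_bar$diameter, drop = TRUE)
  agg <- do.call(rbind, lapply(split(per_bar, key), function(g)
    data.frame(field = g$field[1], diameter = g$diameter[1],
               n_bars = nrow(g), mean_ratio = mean(g$ratio))))
  rownames(agg) <- NULL
  agg[order(agg$field, agg$diameter), , drop = FALSE]
}

#' Normalized integrin/membrane ratios at nanopillars and flat annuli
#'
#' Per ROI (pillar disc and surrounding annulus of every in-cell window):
#' `ratio = mean(integrin)/mean(membrane)`; all ratios of the cell are
#' normalized by their grand mean, so the per-cell mean of `norm_ratio` is 1
#' by construction.
#'
#' @inheritParams end_side_ratios
#' @param rois pillar [derive_pillar_rois()] masks.
#' @param min_pillars minimum number of usable pillars (default 1; the
#'   published protocol uses >= 10 per cell).
#' @return object of class `pillar_ratio_result`: `per_roi` data frame
#'   (`window`, `type`, `ratio`, `norm_ratio`), `norm_constant`,
#'   `n_pillars`, `excluded`.
#' @export
pillar_ratios <- function(integrin, membrane, windows, rois, cell_id = 1L,
                          background = c(0, 0), min_pillars = 1L) {
  if (!any(windows$in_cell)) stop("no in-cell windows")
  ids <- windows$id[windows$in_cell]
  ip <- .window_mask_means(integrin, windows, rois$pillar_mask) - background[1]
  mp <- .window_mask_means(membrane, windows, rois$pillar_mask) - background[2]
  ia <- .window_mask_means(integrin, windows, rois$annulus_mask) - background[1]
  ma <- .window_mask_means(membrane, windows, rois$annulus_mask) - background[2]
  per_roi <- rbind(
    data.frame(window = ids, type = "pillar", num = ip, den = mp),
    data.frame(window = ids, type = "annulus", num = ia, den = ma))
  ok <- per_roi$den > 0
  if (any(!ok)) message(sum(!ok), " ROI(s) excluded: non-positive membrane mean")
  per_roi <- per_roi[ok, , drop = FALSE]
  per_roi$ratio <- per_roi$num / per_roi$den
  n_pillars <- sum(per_roi$type == "pillar")
  if (n_pillars < min_pillars) stop("fewer than ", min_pillars, " usable pillars")
  norm_constant <- mean(per_roi$ratio)
  per_roi$norm_ratio <- per_roi$ratio / norm_constant
  structure(list(per_roi = per_roi[, c("window", "type", "ratio", "norm_ratio")],
                 cell = cell_id, norm_constant = norm_constant,
                 n_pillars = n_pillars,
                 excluded = c(ids, ids)[!ok]),
            class = "pillar_ratio_result")
}

#' Classify pillars as integrin-enriched
#'
#' A pillar is enriched when its normalized pillar ratio exceeds the
#' threshold `T` (default 1.5, midway between the no-enrichment value 1.0
#' and the reported integrin beta-5 effect of ~1.9).
#'
#' @param x a [pillar_ratios()] result, or a numeric vector of normalized
#'   pillar ratios.
#' @param threshold enrichment cut-off `T`.
#' @return list with `enriched` (logical), `fraction` and `n`.
#' @export
classify_enriched <- function(x, threshold = 1.5) {
  v <- if (inherits(x, "pillar_ratio_result")) {
    x$per_roi$norm_ratio[x$per_roi$type == "pillar"]
  } else as.numeric(x)
  enriched <- v > threshold
  list(enriched = enriched, fraction = mean(enriched), n = length(v))
}

#' Spearman rank correlation (midrank ties)
#'
#' @param x,y numeric vectors of equal length.
#' @return rho in `[-1, 1]`, or `NA` when either input is constant.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    message("spearman_rho: constant input, rho undefined")
    return(NA_real_)
  }
  stats::cor(rank(x), rank(y))
}

#' Per-cell Spearman correlation of a protein of interest with enrichment
#'
#' Pairs, at each in-cell pillar, the mean POI intensity over the pillar
#' disc with the cell-normalized integrin/membrane ratio, and reports their
#' Spearman correlation.
#'
#' @inheritParams pillar_ratios
#' @param poi protein-of-interest intensity matrix.
#' @param background length-3 numeric `c(poi, integrin, membrane)`.
#' @return object of class `spearman_result`: `rho`, `n`.
#' @export
spearman_at_pillars <- function(poi, integrin, membrane, windows, rois,
                                background = c(0, 0, 0)) {
  if (sum(windows$in_cell) < 5L) stop("need at least 5 pillars")
  p <- .window_mask_means(poi, windows, rois$pillar_mask) - background[1]
  ip <- .window_mask_means(integrin, windows, rois$pillar_mask) - background[2]
  mp <- .window_mask_means(membrane, windows, rois$pillar_mask) - background[3]
  ok <- mp > 0
  r <- ip[ok] / mp[ok]
  r <- r / mean(r)
  rho <- spearman_rho(p[ok], r)
  structure(list(rho = rho, n = sum(ok)), class = "spearman_result")
}
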