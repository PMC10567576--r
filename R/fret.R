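# Ratiometric FRET tension analysis: moment-preserving auto-threshold of the
# donor channel, pillar-based classification of adhesions into curved vs
# focal, and cell-normalized acceptor/donor ratios per class.

#' Moment-preserving (Tsai) auto-threshold
#'
#' The image is min-max rescaled to integer levels 0..255 (the 256-bin
#' dialect of the common GUI implementation). The binary image that
#' preserves the first three gray-level moments of the histogram has a
#' below-threshold fraction `p0` with a closed form; the threshold is the
#' first level at which the cumulative histogram exceeds `p0`.
#'
#' @param image numeric matrix (or vector).
#' @return threshold in the original intensity units (pixels strictly above
#'   it are foreground), with attributes `level` (0..255 bin index) and
#'   `p0`.
#' @export
moments_threshold <- function(image) {
  v <- as.numeric(image)
  rng <- range(v)
  if (diff(rng) == 0) stop("degenerate histogram: constant image")
  lev <- round((v - rng[1]) / diff(rng) * 255)
  h <- tabulate(lev + 1L, 256L)
  p <- h / sum(h)
  i <- 0:255
  m1 <- sum(i * p); m2 <- sum(i^2 * p); m3 <- sum(i^3 * p)
  cd <- m2 - m1^2
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  z0 <- 0.5 * (-c1 - sqrt(c1^2 - 4 * c0))
  z1 <- 0.5 * (-c1 + sqrt(c1^2 - 4 * c0))
  p0 <- (z1 - m1) / (z1 - z0)
  cum <- cumsum(p)
  t_lev <- i[which(cum >= p0 - 1e-12)[1]]
  thr <- rng[1] + (t_lev + 0.5) * diff(rng) / 255
  structure(thr, level = t_lev, p0 = p0)
}

#' Segment adhesions from the donor channel and classify by pillar position
#'
#' All-adhesion mask = donor pixels above the Tsai threshold; the curved
#' mask is its intersection with the map of pillar discs (radius `r_in`
#' pixels around each lattice node); the remaining adhesion pixels are
#' focal (clathrin structures carry no talin sensor, so no further marker
#' is needed).
#'
#' @param donor donor-channel intensity matrix.
#' @param lattice a `nano_lattice` or [lattice_spec()] giving pillar
#'   positions.
#' @param r_in pillar ROI radius in pixels (default 9).
#' @return object of class `adhesion_mask_pair`: logical `curved_mask`,
#'   `focal_mask`, `all_mask`, `pillar_map`, and the donor `threshold` used.
#' @export
segment_and_classify <- function(donor, lattice, r_in = 9) {
  lat <- .as_nano_lattice(lattice)
  thr <- moments_threshold(donor)
  all_mask <- donor > as.numeric(thr)
  if (!any(all_mask)) stop("no adhesions above the donor threshold")
  dims <- dim(donor)
  nodes <- .lattice_node_grid(lat, dims, margin = 0)
  pillar_map <- matrix(FALSE, dims[1], dims[2])
  for (k in seq_len(nrow(nodes))) {
    xs <- max(1, floor(nodes$cx[k] - r_in)):min(dims[2], ceiling(nodes$cx[k] + r_in))
    ys <- max(1, floor(nodes$cy[k] - r_in)):min(dims[1], ceiling(nodes$cy[k] + r_in))
    d2 <- outer((ys - nodes$cy[k])^2, (xs - nodes$cx[k])^2, `+`)
    pillar_map[ys, xs] <- pillar_map[ys, xs] | (d2 <= r_in^2)
  }
  structure(list(curved_mask = all_mask & pillar_map,
                 focal_mask = all_mask & !pillar_map,
                 all_mask = all_mask, pillar_map = pillar_map,
                 threshold = as.numeric(thr)),
            class = "adhesion_mask_pair")
}

#' Normalized FRET ratios of curved and focal adhesions
#'
#' Acceptor/donor ratio per class, normalized by the cell-wide mean ratio
#' to minimize cell-to-cell variation. Pixels whose donor intensity falls
#' below `donor_floor` (default: background median + 3 SD, estimated from
#' non-adhesion pixels) are excluded from the ratios.
#'
#' @param acceptor,donor registered intensity matrices.
#' @param masks an [segment_and_classify()] result.
#' @param cell_mask optional logical matrix for the cell-wide reference
#'   (default: all pixels above the donor floor).
#' @param method `"mean_of_ratios"` (pixelwise, default) or
#'   `"ratio_of_means"`.
#' @param donor_floor optional numeric override of the donor floor.
#' @return object of class `fret_result`: `per_class` data frame (`class`,
#'   `n_px`, `ratio`, `norm_ratio`), `cell_ratio`, `donor_floor`.
#' @export
fret_ratios <- function(acceptor, donor, masks, cell_mask = NULL,
                        method = c("mean_of_ratios", "ratio_of_means"),
                        donor_floor = NULL) {
  method <- match.arg(method)
  if (is.null(donor_floor)) {
    bg <- donor[!masks$all_mask]
    donor_floor <- if (length(bg)) stats::median(bg) + 3 * stats::sd(bg) else 0
  }
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, nrow(donor), ncol(donor))
  ratio_over <- function(m) {
    m <- m & donor > donor_floor
    n <- sum(m)
    if (n == 0L) return(c(NA_real_, 0))
    r <- if (method == "mean_of_ratios") mean(acceptor[m] / donor[m])
         else sum(acceptor[m]) / sum(donor[m])
    c(r, n)
  }
  cr <- ratio_over(cell_mask)
  if (!is.finite(cr[1]) || cr[1] <= 0) stop("cell-wide FRET ratio undefined")
  classes <- list(curved = masks$curved_mask, focal = masks$focal_mask)
  rows <- lapply(names(classes), function(nm) {
    v <- ratio_over(classes[[nm]])
    data.frame(class = nm, n_px = v[2], ratio = v[1], norm_ratio = v[1] / cr[1])
  })
  structure(list(per_class = do.call(rbind, rows), cell_ratio = cr[1],
                 donor_floor = donor_floor, method = method),
            class = "fret_result")
}
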