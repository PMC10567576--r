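# Lattice registration: detect the periodic nanostructure array, tile
# per-structure square windows, average them, and derive end/side or
# pillar/annulus ROI masks in window coordinates.

#' Detect a periodic nanostructure lattice
#'
#' FFT-based 2D autocorrelation peak detection with quadratic sub-pixel
#' refinement. The primary lattice vector is taken from the strongest
#' autocorrelation peak whose length lies in `pitch_band`, then refined
#' against its highest usable harmonic; the lattice phase (origin) is
#' estimated from the complex first-order Fourier coefficient along each
#' lattice axis. Works on bright-field images of bars or on membrane-marker
#' images of pillars.
#'
#' @param image 2D intensity matrix.
#' @param pitch_band `c(min, max)` admissible pitch in micrometres.
#' @param pixel_size micrometres per pixel.
#' @param min_peak minimum normalized autocorrelation peak height for the
#'   periodicity to count as significant.
#' @return object of class `nano_lattice`: `origin` (x, y px), `pitch` (um),
#'   `pitch_px`, `orientation` (degrees in `[0, 90)`), lattice vectors `a1`,
#'   `a2` (px), RMS `residual` (um) of bright-spot centroids against the
#'   ideal grid, and `pixel_size`.
#' @export
detect_lattice <- function(image, pitch_band = c(2, 10), pixel_size = 0.1,
                           min_peak = 0.1) {
  ny <- nrow(image); nx <- ncol(image)
  I0 <- image - mean(image)
  F <- stats::fft(I0)
  A <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / length(I0)
  A0 <- A[1, 1]
  if (A0 <= 0) stop("no lattice: image has no variance")
  dxv <- c(0:(nx - 1)); dxv[dxv > nx / 2] <- dxv[dxv > nx / 2] - nx
  dyv <- c(0:(ny - 1)); dyv[dyv > ny / 2] <- dyv[dyv > ny / 2] - ny
  DX <- matrix(dxv, ny, nx, byrow = TRUE)
  DY <- matrix(dyv, ny, nx)
  R <- sqrt(DX^2 + DY^2)
  rmin <- pitch_band[1] / pixel_size
  rmax <- pitch_band[2] / pixel_size
  cand <- R >= rmin & R <= rmax & (DX > 0 | (DX == 0 & DY > 0))
  if (!any(cand)) stop("no lattice: pitch band empty for this image size")
  Ac <- A / A0
  vmax <- max(Ac[cand])
  if (vmax < min_peak) stop("no lattice: no significant periodicity in band")
  # among strong candidate peaks, take the SHORTEST shift: longer lattice
  # combinations (diagonals, harmonics) are peaks of comparable height.
  # Restrict to local maxima so peak shoulders cannot win.
  locmax <- matrix(TRUE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    locmax <- locmax & (A >= A[(seq_len(ny) - 1 + dy) %% ny + 1,
                               (seq_len(nx) - 1 + dx) %% nx + 1])
  }
  strong <- cand & locmax & Ac >= 0.5 * vmax
  if (!any(strong)) strong <- cand & Ac >= 0.5 * vmax
  peak_idx <- which(strong)[which.min(R[strong])]

  at <- function(iy, ix) A[(iy - 1) %% ny + 1, (ix - 1) %% nx + 1]
  refine <- function(iy, ix) {
    offx <- .quad_refine(at(iy, ix - 1), at(iy, ix), at(iy, ix + 1))
    offy <- .quad_refine(at(iy - 1, ix), at(iy, ix), at(iy + 1, ix))
    c(DX[iy, ix] + offx, DY[iy, ix] + offy)
  }
  pk <- arrayInd(peak_idx, dim(A))
  v1 <- refine(pk[1], pk[2])

  # refine against the highest harmonic that still fits in the image
  r1 <- sqrt(sum(v1^2))
  kmax <- max(1L, floor(0.45 * min(nx, ny) / r1))
  if (kmax > 1L) {
    tx <- kmax * v1[1]; ty <- kmax * v1[2]
    # local search +/- 2 px around the predicted harmonic
    best <- NULL
    for (ddy in -2:2) for (ddx in -2:2) {
      iy <- round(ty) + ddy; ix <- round(tx) + ddx
      val <- at(iy %% ny + 1, ix %% nx + 1)
      if (is.null(best) || val > best$val) best <- list(val = val, iy = iy, ix = ix)
    }
    vk <- refine(best$iy %% ny + 1, best$ix %% nx + 1)
    # unwrap back to the true (un-aliased) harmonic position
    vk[1] <- vk[1] + round((tx - vk[1]) / nx) * nx
    vk[2] <- vk[2] + round((ty - vk[2]) / ny) * ny
    v1 <- vk / kmax
  }
  pitch_px <- sqrt(sum(v1^2))
  if (pitch_px < rmin - 0.5 || pitch_px > rmax + 0.5)
    stop("no lattice: refined pitch left the search band")
  ang <- atan2(v1[2], v1[1]) * 180 / pi
  orientation <- ang %% 90
  th <- orientation * pi / 180
  a1 <- pitch_px * c(cos(th), sin(th))
  a2 <- pitch_px * c(-sin(th), cos(th))

  # phase estimation from first-order Fourier coefficients
  w <- pmax(image - stats::median(image), 0)
  X <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  Y <- matrix(seq_len(ny), ny, nx)
  frac <- function(a) {
    g <- a / sum(a^2)
    z <- sum(w * exp(-2i * pi * (X * g[1] + Y * g[2])))
    (-Arg(z) / (2 * pi)) %% 1
  }
  origin <- frac(a1) * a1 + frac(a2) * a2

  lat <- structure(list(origin = origin, pitch = pitch_px * pixel_size,
                        pitch_px = pitch_px, orientation = orientation,
                        a1 = a1, a2 = a2, residual = NA_real_,
                        pixel_size = pixel_size), class = "nano_lattice")
  # residual: RMS offset of local intensity centroids from predicted nodes
  nodes <- .lattice_node_grid(lat, c(ny, nx), margin = pitch_px / 2)
  if (nrow(nodes)) {
    h <- max(2L, floor(pitch_px / 4))
    offs <- matrix(NA_real_, nrow(nodes), 2)
    for (k in seq_len(nrow(nodes))) {
      cx <- round(nodes$cx[k]); cy <- round(nodes$cy[k])
      xs <- (cx - h):(cx + h); ys <- (cy - h):(cy + h)
      sub <- w[ys, xs]
      tot <- sum(sub)
      if (tot <= 0) next
      offs[k, 1] <- sum(sub * matrix(xs, length(ys), length(xs), byrow = TRUE)) / tot - nodes$cx[k]
      offs[k, 2] <- sum(sub * matrix(ys, length(ys), length(xs))) / tot - nodes$cy[k]
    }
    offs <- offs[stats::complete.cases(offs), , drop = FALSE]
    if (nrow(offs)) {
      shift <- colMeans(offs)  # absorb any global phase error into the origin
      lat$origin <- lat$origin + shift
      offs <- sweep(offs, 2, shift)
      lat$residual <- sqrt(mean(rowSums(offs^2))) * pixel_size
    }
  }
  lat
}

# Node grid of a nano_lattice over an image, keeping nodes at least `margin`
# pixels from the border.
.lattice_node_grid <- function(lat, dims, margin) {
  nmax <- ceiling(max(dims) / lat$pitch_px) + 2L
  grid <- expand.grid(i = -nmax:nmax, j = -nmax:nmax)
  cx <- lat$origin[1] + grid$i * lat$a1[1] + grid$j * lat$a2[1]
  cy <- lat$origin[2] + grid$i * lat$a1[2] + grid$j * lat$a2[2]
  keep <- cx > margin & cx <= dims[2] - margin & cy > margin & cy <= dims[1] - margin
  out <- data.frame(i = grid$i[keep], j = grid$j[keep], cx = cx[keep], cy = cy[keep])
  out[order(out$cy, out$cx), , drop = FALSE]
}

# Accept either a detected nano_lattice or a generator lattice_spec.
.as_nano_lattice <- function(lattice) {
  if (inherits(lattice, "nano_lattice")) return(lattice)
  if (inherits(lattice, "lattice_spec")) {
    p <- lattice$pitch / lattice$pixel_size
    th <- lattice$orientation * pi / 180
    return(structure(list(origin = lattice$origin, pitch = lattice$pitch,
                          pitch_px = p, orientation = lattice$orientation,
                          a1 = p * c(cos(th), sin(th)),
                          a2 = p * c(-sin(th), cos(th)),
                          residual = 0, pixel_size = lattice$pixel_size),
                     class = "nano_lattice"))
  }
  stop("not a lattice")
}

#' Tile congruent square windows centred on lattice nodes
#'
#' One window per lattice node whose square (side = largest odd integer not
#' exceeding the pitch) lies fully inside the image. A window is flagged
#' `in_cell` when at least `in_cell_min` of its pixels lie in `cell_mask`.
#'
#' @param lattice a `nano_lattice` (from [detect_lattice()]) or a
#'   [lattice_spec()].
#' @param image_shape `c(ny, nx)` in pixels.
#' @param cell_mask optional logical matrix; `NULL` marks every window
#'   `in_cell`.
#' @param in_cell_min minimum cell-mask coverage fraction (default 0.8).
#' @return object of class `window_set`: data frame with node indices,
#'   integer window centres `cx`, `cy` and `in_cell`; attributes `side`,
#'   `half`, `lattice`.
#' @export
tile_windows <- function(lattice, image_shape, cell_mask = NULL,
                         in_cell_min = 0.8) {
  lat <- .as_nano_lattice(lattice)
  side <- as.integer(2 * floor((lat$pitch_px - 1e-9) / 2) + 1)
  if (side < 3L) stop("pitch too small to tile windows")
  h <- (side - 1L) / 2L
  nodes <- .lattice_node_grid(lat, image_shape, margin = 0)
  nodes$cx <- round(nodes$cx); nodes$cy <- round(nodes$cy)
  keep <- nodes$cx - h >= 1 & nodes$cx + h <= image_shape[2] &
          nodes$cy - h >= 1 & nodes$cy + h <= image_shape[1]
  nodes <- nodes[keep, , drop = FALSE]
  if (nrow(nodes) == 0L) stop("zero complete windows inside the image")
  nodes$id <- seq_len(nrow(nodes))
  if (is.null(cell_mask)) {
    nodes$in_cell <- TRUE
  } else {
    nodes$in_cell <- vapply(seq_len(nrow(nodes)), function(k) {
      sub <- cell_mask[(nodes$cy[k] - h):(nodes$cy[k] + h),
                       (nodes$cx[k] - h):(nodes$cx[k] + h)]
      mean(sub) >= in_cell_min
    }, logical(1))
  }
  structure(nodes[, c("id", "i", "j", "cx", "cy", "in_cell")],
            side = side, half = h, lattice = lat, class = c("window_set", "data.frame"))
}

#' Pixelwise average of the in-cell windows of an image
#'
#' @param image 2D intensity matrix.
#' @param windows a [tile_windows()] result.
#' @param use logical selector over windows (default: the `in_cell` flags).
#' @return numeric matrix of size `side x side`.
#' @export
average_windows <- function(image, windows, use = windows$in_cell) {
  sel <- which(use)
  if (length(sel) == 0L) stop("no in-cell windows to average")
  h <- attr(windows, "half")
  acc <- 0
  for (k in sel) {
    acc <- acc + image[(windows$cy[k] - h):(windows$cy[k] + h),
                       (windows$cx[k] - h):(windows$cx[k] + h)]
  }
  acc / length(sel)
}

#' Derive bar-end / bar-side ROI masks from an averaged window
#'
#' The bar footprint is the largest Otsu-thresholded component of the
#' averaged window; its principal axis (PCA of pixel coordinates) gives the
#' long axis. The end mask covers the two terminal caps of depth `cap_depth`
#' (default: the measured bar width) of the footprint dilated laterally by
#' `flank_width`; the side mask is the remaining dilated footprint. The
#' default `flank_width = 0` keeps both masks on the exact footprint, which
#' is unbiased when the wrapped-membrane signal is confined to the structure
#' (as in the bundled generator); increase it when a PSF spreads signal
#' beyond the footprint.
#'
#' @param averaged_window matrix from [average_windows()].
#' @param cap_depth cap depth in pixels; `NULL` uses the measured bar width.
#' @param flank_width dilation of the footprint in pixels (default 0).
#' @param min_eccentricity reject footprints rounder than this as
#'   "not a bar".
#' @return object of class `roi_set` with logical `end_mask` and
#'   `side_mask` in window coordinates plus the measured geometry.
#' @export
derive_bar_rois <- function(averaged_window, cap_depth = NULL, flank_width = 0,
                            min_eccentricity = 1.2) {
  thr <- otsu_threshold(averaged_window)
  fp <- averaged_window > thr
  if (!any(fp)) stop("threshold found no footprint")
  lab <- label_components(fp)
  sizes <- tabulate(lab[lab > 0L])
  fp <- lab == which.max(sizes)
  idx <- which(fp, arr.ind = TRUE)
  xy <- cbind(x = idx[, 2], y = idx[, 1])
  ctr <- colMeans(xy)
  cv <- stats::cov(xy)
  eg <- eigen(cv, symmetric = TRUE)
  ecc <- sqrt(eg$values[1] / max(eg$values[2], 1e-9))
  if (ecc < min_eccentricity)
    stop("not a bar (eccentricity ", round(ecc, 2), "); consider pillar ROIs")
  e1 <- eg$vectors[, 1]
  dimw <- dim(averaged_window)
  GX <- matrix(seq_len(dimw[2]), dimw[1], dimw[2], byrow = TRUE) - ctr[1]
  GY <- matrix(seq_len(dimw[1]), dimw[1], dimw[2]) - ctr[2]
  U <- GX * e1[1] + GY * e1[2]
  upx <- (xy[, 1] - ctr[1]) * e1[1] + (xy[, 2] - ctr[2]) * e1[2]
  vpx <- -(xy[, 1] - ctr[1]) * e1[2] + (xy[, 2] - ctr[2]) * e1[1]
  L_half <- max(abs(upx))
  W_half <- max(abs(vpx))
  if (is.null(cap_depth)) cap_depth <- 2 * W_half
  region <- if (flank_width > 0) dilate_box(fp, as.integer(ceiling(flank_width))) else fp
  end_mask <- region & abs(U) > (L_half - cap_depth)
  side_mask <- region & !end_mask
  if (!any(end_mask) || !any(side_mask)) stop("degenerate bar ROIs")
  structure(list(end_mask = end_mask, side_mask = side_mask,
                 footprint = fp, axis = e1, centre = ctr,
                 eccentricity = ecc, L_half = L_half, W_half = W_half,
                 cap_depth = cap_depth, flank_width = flank_width,
                 kind = "bar"), class = "roi_set")
}

#' Derive pillar / annulus ROI masks
#'
#' Disc of radius `r_in` pixels around the window centre ("at nanopillar")
#' and annulus `(r_in, r_out]` ("flat region surrounding nanopillar");
#' defaults 9 and 20 pixels.
#'
#' @param r_in,r_out radii in pixels, `r_in < r_out`.
#' @param side window side in pixels (odd).
#' @return object of class `roi_set` with logical `pillar_mask` and
#'   `annulus_mask`.
#' @export
derive_pillar_rois <- function(r_in = 9, r_out = 20, side = 2L * r_out + 9L) {
  if (r_in >= r_out) stop("r_in must be smaller than r_out")
  side <- as.integer(side)
  if (side %% 2L == 0L) side <- side + 1L
  c0 <- (side + 1L) / 2L
  D <- sqrt(outer((seq_len(side) - c0)^2, (seq_len(side) - c0)^2, `+`))
  structure(list(pillar_mask = D <= r_in,
                 annulus_mask = D > r_in & D <= r_out,
                 r_in = r_in, r_out = r_out, kind = "pillar"),
            class = "roi_set")
}

# Crop/centre a roi mask to a window of side `side` (masks are built around
# their own centre; windows may be smaller or larger).
.fit_mask <- function(mask, side) {
  ms <- nrow(mask)
  if (ms == side) return(mask)
  c_m <- (ms + 1L) / 2L
  h <- (side - 1L) / 2L
  if (ms > side) return(mask[(c_m - h):(c_m + h), (c_m - h):(c_m + h)])
  out <- matrix(FALSE, side, side)
  c_o <- (side + 1L) / 2L
  hm <- (ms - 1L) / 2L
  out[(c_o - hm):(c_o + hm), (c_o - hm):(c_o + hm)] <- mask
  out
}
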