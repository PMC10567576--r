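# Low-level image primitives shared by all modules.
#
# Convention: a 2D image is a numeric matrix indexed [y, x] (row = y, column
# = x), pixel centres at integer coordinates starting at 1. A 3D stack is a
# numeric array [y, x, z] with z ordered bottom -> top.

#' Separable Gaussian blur of a matrix or 3D array
#'
#' Replicate-padded separable convolution with a truncated Gaussian kernel
#' (truncation at 3 sigma). `sigma` may be a scalar or one value per
#' dimension; a zero sigma leaves that dimension untouched.
#'
#' @param x numeric matrix or 3D array.
#' @param sigma kernel standard deviation(s) in pixels.
#' @return blurred object of the same shape.
#' @export
gauss_blur <- function(x, sigma) {
  d <- if (is.matrix(x)) 2L else length(dim(x))
  sigma <- rep_len(sigma, d)
  for (ax in seq_len(d)) {
    if (sigma[ax] > 0) x <- .blur_axis(x, ax, sigma[ax])
  }
  x
}

.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve along one axis with replicate padding, via shifted-slab sums.
.blur_axis <- function(x, axis, sigma) {
  k <- .gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  dm <- dim(x)
  n <- dm[axis]
  # index vector along `axis` for a shift of j, replicate-clamped
  out <- array(0, dm)
  for (j in seq_along(k)) {
    sh <- j - r - 1L
    idx <- pmin(pmax(seq_len(n) + sh, 1L), n)
    slab <- switch(as.character(length(dm)),
      "2" = if (axis == 1L) x[idx, , drop = FALSE] else x[, idx, drop = FALSE],
      "3" = if (axis == 1L) x[idx, , , drop = FALSE]
            else if (axis == 2L) x[, idx, , drop = FALSE]
            else x[, , idx, drop = FALSE])
    out <- out + k[j] * slab
  }
  out
}

#' Otsu threshold of an intensity image
#'
#' Maximizes between-class variance on an `nbins`-bin histogram over the
#' intensity range of `x`. Returns a level in the original intensity units;
#' pixels strictly above the level are foreground.
#'
#' @param x numeric vector, matrix or array.
#' @param nbins number of histogram bins.
#' @return scalar threshold level.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) stop("otsu_threshold: constant image")
  b <- findInterval(v, seq(rng[1], rng[2], length.out = nbins + 1L),
                    rightmost.closed = TRUE, all.inside = TRUE)
  h <- tabulate(b, nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(nbins) - 0.5) * diff(rng) / nbins
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}

# All neighbour offsets for a given connectivity, as an integer matrix with
# one row per offset and one column per dimension.
.conn_offsets <- function(ndim, connectivity) {
  g <- as.matrix(expand.grid(rep(list(-1L:1L), ndim)))
  g <- g[rowSums(g != 0L) > 0L, , drop = FALSE]
  full <- if (ndim == 2L) 8L else 26L
  axis <- if (ndim == 2L) 4L else 6L
  if (connectivity == full) g
  else if (connectivity == axis) g[rowSums(g != 0L) == 1L, , drop = FALSE]
  else stop("unsupported connectivity: ", connectivity)
}

#' Connected-component labelling of a binary mask
#'
#' Breadth-first labelling on a logical matrix (default 8-connectivity) or
#' 3D array (default 26-connectivity). Axis-aligned connectivity (4 / 6) is
#' also supported.
#'
#' @param mask logical matrix or 3D array.
#' @param connectivity 4 or 8 in 2D; 6 or 26 in 3D. Defaults to full.
#' @return integer object of the same shape: 0 = background, 1..k = labels.
#' @export
label_components <- function(mask, connectivity = NULL) {
  dm <- dim(mask)
  ndim <- length(dm)
  if (is.null(connectivity)) connectivity <- if (ndim == 2L) 8L else 26L
  offs <- .conn_offsets(ndim, connectivity)
  # pad with a FALSE border so linear-index offsets never wrap across rows
  pdm <- dm + 2L
  pad <- array(FALSE, pdm)
  core <- lapply(dm, function(n) seq_len(n) + 1L)
  if (ndim == 2L) pad[core[[1]], core[[2]]] <- mask
  else pad[core[[1]], core[[2]], core[[3]]] <- mask
  strides <- c(1L, cumprod(pdm)[-ndim])
  doff <- as.integer(offs %*% strides)
  lab <- array(0L, pdm)
  todo <- which(pad)
  nextlab <- 0L
  for (s in todo) {
    if (lab[s] != 0L) next
    nextlab <- nextlab + 1L
    lab[s] <- nextlab
    frontier <- s
    while (length(frontier)) {
      nb <- rep(frontier, each = length(doff)) + doff
      nb <- unique(nb[pad[nb] & lab[nb] == 0L])
      if (length(nb)) lab[nb] <- nextlab
      frontier <- nb
    }
  }
  if (ndim == 2L) lab <- lab[core[[1]], core[[2]]]
  else lab <- lab[core[[1]], core[[2]], core[[3]]]
  array(lab, dm)
}

#' Binary dilation / erosion with a box structuring element
#'
#' @param mask logical matrix or 3D array.
#' @param r box radius in pixels (structuring element side `2r + 1`).
#' @return logical object of the same shape.
#' @export
dilate_box <- function(mask, r = 1L) .morph_box(mask, r, any_op = TRUE)

#' @rdname dilate_box
#' @export
erode_box <- function(mask, r = 1L) .morph_box(mask, r, any_op = FALSE)

.morph_box <- function(mask, r, any_op) {
  dm <- dim(mask)
  out <- mask
  for (ax in seq_along(dm)) {
    n <- dm[ax]
    acc <- NULL
    for (sh in (-r):r) {
      idx <- pmin(pmax(seq_len(n) + sh, 1L), n)
      slab <- switch(as.character(length(dm)),
        "2" = if (ax == 1L) out[idx, , drop = FALSE] else out[, idx, drop = FALSE],
        "3" = if (ax == 1L) out[idx, , , drop = FALSE]
              else if (ax == 2L) out[, idx, , drop = FALSE]
              else out[, , idx, drop = FALSE])
      acc <- if (is.null(acc)) slab else if (any_op) acc | slab else acc & slab
    }
    out <- array(acc, dm)
  }
  out
}

#' Morphological closing (dilation then erosion), box element
#' @inheritParams dilate_box
#' @export
close_box <- function(mask, r = 1L) erode_box(dilate_box(mask, r), r)

#' Fill enclosed holes of a binary mask
#'
#' Background components not connected to the image border (axis-aligned
#' connectivity) are turned into foreground.
#'
#' @param mask logical matrix or 3D array.
#' @return logical object of the same shape.
#' @export
fill_holes <- function(mask) {
  dm <- dim(mask)
  conn <- if (length(dm) == 2L) 4L else 6L
  bg <- label_components(!mask, connectivity = conn)
  border <- integer(0)
  if (length(dm) == 2L) {
    border <- c(bg[1, ], bg[dm[1], ], bg[, 1], bg[, dm[2]])
  } else {
    border <- c(bg[1, , ], bg[dm[1], , ], bg[, 1, ], bg[, dm[2], ],
                bg[, , 1], bg[, , dm[3]])
  }
  keep <- unique(border[border > 0L])
  mask | (bg > 0L & !(bg %in% keep))
}

# Quadratic sub-pixel refinement of a peak from its two neighbours.
# Returns the fractional offset in (-0.5, 0.5); 0 when degenerate.
.quad_refine <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (ym - yp) / den
  max(min(off, 0.5), -0.5)
}
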