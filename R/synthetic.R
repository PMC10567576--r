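# Synthetic-image generator with recorded ground truth.
#
# The generator emulates the experimental geometries the analysis consumes:
# periodic SiO2 nanobar/nanopillar arrays that deform the plasma membrane
# (fabricated geometry: 200 nm x 2 um bars, 5 um pitch), gradient bar arrays
# with graded end-curvature diameters, time-lapse series at pillars, and 3D
# fibre matrices with a rough top surface and cells at controlled depths.
# Enrichment is phenomenological: a channel's end-enrichment factor E
# multiplies its membrane-bound intensity at high-curvature sub-regions
# (bar-end caps, whole pillar discs). Per-structure wrap factors W_s model
# uneven membrane wrapping and multiply membrane-bound channels jointly.
#
# Noiseless expectation at a structure pixel of a membrane-bound channel:
#   curved sub-region: W_s * E * base_intensity + background
#   flat sub-region:   W_s * base_intensity + background
# Photon noise is Poisson(expectation), read noise additive Gaussian,
# clipped at zero (standard sCMOS approximation).

MEMBRANE_ROLES <- c("membrane", "integrin", "poi", "donor", "acceptor")

#' Specify a periodic nanostructure lattice
#'
#' @param origin lattice origin `(x, y)` in pixels.
#' @param pitch lattice period in micrometres.
#' @param orientation lattice/bar orientation in degrees, in `[0, 180)`.
#' @param structure_kind `"bar"` or `"pillar"`.
#' @param bar_length,bar_width nanobar dimensions in micrometres
#'   (fabricated geometry: 2 and 0.2).
#' @param pillar_diameter nanopillar diameter in micrometres.
#' @param pixel_size micrometres per pixel.
#' @return object of class `lattice_spec`.
#' @export
lattice_spec <- function(origin = c(25, 25), pitch = 5, orientation = 0,
                         structure_kind = c("bar", "pillar"),
                         bar_length = 2, bar_width = 0.2,
                         pillar_diameter = 0.5, pixel_size = 0.1) {
  structure_kind <- match.arg(structure_kind)
  stopifnot(pixel_size > 0, pitch > 0, length(origin) == 2)
  if (orientation < 0 || orientation >= 180) stop("orientation must be in [0, 180)")
  ext <- if (structure_kind == "bar") bar_length else pillar_diameter
  if (pitch <= ext) stop("pitch must exceed the structure extent")
  if (structure_kind == "bar" && bar_length <= 2 * bar_width)
    stop("bar_length must exceed twice bar_width for distinct end caps")
  structure(list(origin = as.numeric(origin), pitch = pitch,
                 orientation = orientation, structure_kind = structure_kind,
                 bar_length = bar_length, bar_width = bar_width,
                 pillar_diameter = pillar_diameter, pixel_size = pixel_size),
            class = "lattice_spec")
}

#' Specify a synthetic imaging channel
#'
#' @param role one of `"registration"`, `"membrane"`, `"integrin"`, `"poi"`,
#'   `"donor"`, `"acceptor"`, `"fibre"`, `"cell"`.
#' @param base_intensity expected signal photons/pixel.
#' @param end_enrichment enrichment factor `E` at high-curvature sub-regions
#'   (scalar, or one value per structure); `E = 1` means no curvature
#'   preference.
#' @param background expected background photons/pixel.
#' @param read_noise_sd Gaussian read noise s.d. in photons.
#' @return object of class `channel_spec`.
#' @export
channel_spec <- function(role, base_intensity = 200, end_enrichment = 1,
                         background = 20, read_noise_sd = 2) {
  role <- match.arg(role, c("registration", "membrane", "integrin", "poi",
                            "donor", "acceptor", "fibre", "cell"))
  if (base_intensity < 0 || background < 0 || any(end_enrichment < 0))
    stop("intensities and enrichment must be non-negative")
  structure(list(role = role, base_intensity = base_intensity,
                 end_enrichment = end_enrichment, background = background,
                 read_noise_sd = read_noise_sd), class = "channel_spec")
}

# Node table for a lattice over an image of size dims = c(ny, nx): all nodes
# whose structure footprint (max extent) fits inside the image.
.lattice_nodes <- function(lattice, dims) {
  ps <- lattice$pixel_size
  p <- lattice$pitch / ps
  th <- lattice$orientation * pi / 180
  a1 <- c(cos(th), sin(th)) * p   # (x, y) in px
  a2 <- c(-sin(th), cos(th)) * p
  ext <- if (lattice$structure_kind == "bar") lattice$bar_length else lattice$pillar_diameter
  half <- ext / ps / 2 + 1
  nmax <- ceiling(max(dims) / p) + 2L
  grid <- expand.grid(i = -nmax:nmax, j = -nmax:nmax)
  cx <- lattice$origin[1] + grid$i * a1[1] + grid$j * a2[1]
  cy <- lattice$origin[2] + grid$i * a1[2] + grid$j * a2[2]
  keep <- cx - half >= 1 & cx + half <= dims[2] & cy - half >= 1 & cy + half <= dims[1]
  nodes <- data.frame(id = seq_len(sum(keep)), i = grid$i[keep], j = grid$j[keep],
                      cx = cx[keep], cy = cy[keep])
  nodes[order(nodes$cy, nodes$cx), , drop = FALSE][, , drop = FALSE]
}

# Paint per-pixel structure id and curved-subregion flag. `widths`/`lengths`
# (px) may vary per structure (gradient arrays).
.paint_structures <- function(nodes, dims, kind, widths, lengths, orientation) {
  sid <- matrix(0L, dims[1], dims[2])
  curved <- matrix(FALSE, dims[1], dims[2])
  th <- orientation * pi / 180
  ct <- cos(th); st <- sin(th)
  for (k in seq_len(nrow(nodes))) {
    cx <- nodes$cx[k]; cy <- nodes$cy[k]
    w2 <- widths[k] / 2; l2 <- lengths[k] / 2
    r <- ceiling(max(w2, l2)) + 1L
    xs <- max(1L, floor(cx - r)):min(dims[2], ceiling(cx + r))
    ys <- max(1L, floor(cy - r)):min(dims[1], ceiling(cy + r))
    gx <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx
    gy <- matrix(ys, length(ys), length(xs)) - cy
    u <- gx * ct + gy * st
    v <- -gx * st + gy * ct
    if (kind == "pillar") {
      inside <- (u^2 + v^2) <= w2^2
      incurv <- inside
    } else {
      seg <- l2 - w2  # half-length of the straight spine
      du <- pmax(abs(u) - seg, 0)
      inside <- (du^2 + v^2) <= w2^2
      # curvature-affected end region: terminal caps of depth = bar width
      incurv <- inside & abs(u) > (l2 - 2 * w2)
    }
    sid[ys, xs][inside] <- nodes$id[k]
    curved[ys, xs][inside] <- incurv[inside]
  }
  list(sid = sid, curved = curved)
}

.apply_noise <- function(expectation, read_noise_sd) {
  v <- rpois(length(expectation), lambda = as.vector(expectation))
  if (read_noise_sd > 0) v <- v + rnorm(length(v), sd = read_noise_sd)
  matrix(pmax(v, 0), nrow(expectation), ncol(expectation))
}

.render_channels <- function(channels, paint, nodes, wrap, cell_mask, noise) {
  n_s <- nrow(nodes)
  sid <- paint$sid
  on_struct <- sid > 0L
  out <- list()
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    E <- rep_len(ch$end_enrichment, n_s)
    expct <- matrix(ch$background, nrow(sid), ncol(sid))
    if (ch$role == "registration") {
      expct[on_struct] <- expct[on_struct] + ch$base_intensity
    } else if (ch$role %in% MEMBRANE_ROLES) {
      expct[cell_mask] <- expct[cell_mask] + ch$base_intensity
      idx <- which(on_struct & cell_mask)
      f <- wrap[sid[idx]]
      f[paint$curved[idx]] <- f[paint$curved[idx]] * E[sid[idx][paint$curved[idx]]]
      expct[idx] <- ch$background + ch$base_intensity * f
    } else stop("role not renderable in a 2D field: ", ch$role)
    out[[nm]] <- if (noise) .apply_noise(expct, ch$read_noise_sd) else expct
  }
  out
}

#' Render a multichannel nanostructure field with known ground truth
#'
#' @param lattice a [lattice_spec()].
#' @param channels named list of [channel_spec()]s.
#' @param wrap per-structure wrap factors `W_s > 0` (recycled), applied
#'   jointly to all membrane-bound channels; default 1.
#' @param cell_footprint logical matrix marking the cell; default the whole
#'   image.
#' @param seed integer RNG seed.
#' @param dims image size `c(ny, nx)` in pixels.
#' @param noise apply Poisson + Gaussian read noise (`TRUE`) or return the
#'   exact expectation (`FALSE`).
#' @return object of class `curv_field`: `channels` (named matrices),
#'   `lattice`, `cell_mask`, `pixel_size`, and `truth` (a `ground_truth`
#'   record of every generator parameter).
#' @export
render_structure_field <- function(lattice, channels, wrap = NULL,
                                   cell_footprint = NULL, seed = 1L,
                                   dims = c(300L, 300L), noise = TRUE) {
  stopifnot(inherits(lattice, "lattice_spec"))
  ps <- lattice$pixel_size
  if (any(dims * ps < 2 * lattice$pitch))
    stop("image extent must cover at least 2x2 lattice periods")
  nodes <- .lattice_nodes(lattice, dims)
  if (nrow(nodes) < 1L) stop("lattice does not fit the image extent")
  n_s <- nrow(nodes)
  wrap <- if (is.null(wrap)) rep(1, n_s) else rep_len(wrap, n_s)
  if (any(wrap <= 0)) stop("wrap factors must be positive")
  if (is.null(cell_footprint)) cell_footprint <- matrix(TRUE, dims[1], dims[2])
  kindpx <- if (lattice$structure_kind == "bar") {
    list(w = rep(lattice$bar_width / ps, n_s), l = rep(lattice$bar_length / ps, n_s))
  } else {
    list(w = rep(lattice$pillar_diameter / ps, n_s),
         l = rep(lattice$pillar_diameter / ps, n_s))
  }
  paint <- .paint_structures(nodes, dims, lattice$structure_kind,
                             kindpx$w, kindpx$l, lattice$orientation)
  set.seed(seed)
  imgs <- .render_channels(channels, paint, nodes, wrap, cell_footprint, noise)
  E_list <- lapply(channels, function(ch) ch$end_enrichment)
  int_E <- if (!is.null(E_list$integrin)) rep_len(E_list$integrin, n_s) else rep(1, n_s)
  truth <- structure(list(
    lattice = lattice, E = E_list, wrap = wrap, nodes = nodes,
    enriched_fraction = mean(int_E > 1), seed = seed), class = "ground_truth")
  structure(list(channels = imgs, lattice = lattice, cell_mask = cell_footprint,
                 pixel_size = ps, truth = truth), class = "curv_field")
}

#' Render a gradient-nanobar field (graded end-curvature diameters)
#'
#' Each diameter is rendered as its own row ("sub-array") of at least
#' `n_per_diameter` bars; bar width equals the end-curvature diameter and bar
#' length scales with it so every structure stays bar-shaped.
#'
#' @param diameters sorted end-curvature diameters in micrometres.
#' @param enrichment_curve function mapping diameter (um) to the integrin
#'   enrichment `E`, or a numeric vector parallel to `diameters`.
#' @param n_per_diameter bars per sub-array (>= 4).
#' @param pitch lattice pitch in micrometres.
#' @param pixel_size micrometres per pixel.
#' @param channels named list of [channel_spec()]s (defaults: integrin +
#'   membrane + registration).
#' @inheritParams render_structure_field
#' @return a `curv_field` whose truth carries per-structure `diameter` and
#'   `E` columns.
#' @export
render_gradient_bar_field <- function(diameters, enrichment_curve,
                                      n_per_diameter = 4L, pitch = 15,
                                      pixel_size = 0.1, channels = NULL,
                                      seed = 1L, noise = TRUE) {
  if (is.unsorted(diameters)) stop("diameters must be sorted")
  if (any(diameters > pitch)) stop("diameter exceeds the pitch")
  if (n_per_diameter < 4L) stop("need >= 4 bars per diameter")
  if (any(pmax(2, 2.5 * diameters) >= pitch))
    stop("bar length would reach the pitch; increase pitch")
  E_of <- if (is.function(enrichment_curve)) {
    vapply(diameters, enrichment_curve, numeric(1))
  } else rep_len(enrichment_curve, length(diameters))
  if (is.null(channels)) channels <- list(
    registration = channel_spec("registration"),
    membrane = channel_spec("membrane"),
    integrin = channel_spec("integrin"))
  p_px <- pitch / pixel_size
  nd <- length(diameters)
  dims <- c(ceiling((nd + 1) * p_px), ceiling((n_per_diameter + 1) * p_px))
  nodes <- expand.grid(col = seq_len(n_per_diameter), row = seq_len(nd))
  nodes <- data.frame(id = seq_len(nrow(nodes)),
                      i = nodes$col, j = nodes$row,
                      cx = (nodes$col - 0.5) * p_px + p_px / 2,
                      cy = (nodes$row - 0.5) * p_px + p_px / 2)
  d_s <- diameters[nodes$j]
  E_s <- E_of[nodes$j]
  w_px <- d_s / pixel_size
  l_px <- pmax(2, 2.5 * d_s) / pixel_size  # keeps caps distinct from sides
  paint <- .paint_structures(nodes, dims, "bar", w_px, l_px, 0)
  chans <- channels
  if (!is.null(chans$integrin)) chans$integrin$end_enrichment <- E_s
  set.seed(seed)
  cell <- matrix(TRUE, dims[1], dims[2])
  imgs <- .render_channels(chans, paint, nodes, rep(1, nrow(nodes)), cell, noise)
  nodes$diameter <- d_s; nodes$E <- E_s
  nodes$length_um <- l_px * pixel_size
  lat <- lattice_spec(origin = c(nodes$cx[1], nodes$cy[1]), pitch = pitch,
                      structure_kind = "bar", pixel_size = pixel_size)
  truth <- structure(list(lattice = lat, E = list(integrin = E_s),
                          wrap = rep(1, nrow(nodes)), nodes = nodes,
                          diameters = diameters, E_curve = E_of, seed = seed),
                     class = "ground_truth")
  structure(list(channels = imgs, lattice = lat, cell_mask = cell,
                 pixel_size = pixel_size, truth = truth), class = "curv_field")
}

#' Render a time-lapse series at nanopillars
#'
#' Static membrane (and optional registration) channels plus one traced
#' channel whose per-structure intensity follows a supplied trace; noise is
#' drawn independently per frame.
#'
#' @inheritParams render_structure_field
#' @param traces matrix `[n_structures x n_frames]` of multiplicative
#'   intensity factors for `trace_channel`.
#' @param n_frames number of frames; must equal `ncol(traces)`.
#' @param frame_interval seconds between frames (protocol default 15 s).
#' @param trace_channel name of the channel driven by `traces`.
#' @return object of class `curv_timelapse`: `frames` (list of named
#'   channel-matrix lists), `frame_interval`, `lattice`, `truth`.
#' @export
render_timelapse <- function(lattice, channels, traces, n_frames = ncol(traces),
                             frame_interval = 15, trace_channel = "poi",
                             wrap = NULL, cell_footprint = NULL, seed = 1L,
                             dims = c(300L, 300L), noise = TRUE) {
  if (n_frames < 2L) stop("need at least 2 frames")
  if (ncol(traces) != n_frames) stop("trace length does not match n_frames")
  nodes <- .lattice_nodes(lattice, dims)
  if (nrow(traces) != nrow(nodes))
    stop("traces must have one row per structure (", nrow(nodes), ")")
  set.seed(seed)
  frame_seeds <- sample.int(.Machine$integer.max, n_frames)
  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    ch_t <- channels
    base_E <- rep_len(ch_t[[trace_channel]]$end_enrichment, nrow(nodes))
    ch_t[[trace_channel]]$end_enrichment <- base_E * traces[, t]
    f <- render_structure_field(lattice, ch_t, wrap = wrap,
                                cell_footprint = cell_footprint,
                                seed = frame_seeds[t], dims = dims, noise = noise)
    frames[[t]] <- f$channels
  }
  truth <- structure(list(lattice = lattice, traces = traces,
                          nodes = .lattice_nodes(lattice, dims),
                          frame_interval = frame_interval, seed = seed),
                     class = "ground_truth")
  structure(list(frames = frames, frame_interval = frame_interval,
                 lattice = lattice, cell_mask = cell_footprint,
                 pixel_size = lattice$pixel_size,
                 truth = truth), class = "curv_timelapse")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a two-channel 3D fibre-matrix stack with embedded cells
#'
#' The fibre channel is a filamentous random field (random line segments
#' with a Gaussian cross-section) truncated above the matrix surface; the
#' cell channel renders hollow spherical shells (membrane marker) at the
#' requested depths below the surface.
#'
#' @param surface_profile matrix `[ny x nx]` of surface heights in
#'   micrometres, or a scalar for a flat surface.
#' @param fibre_density segments per 1000 cubic micrometres.
#' @param cells data frame with columns `x`, `y` (um, lateral), `depth` (um
#'   below the local surface) and `radius` (um).
#' @param voxel_size `c(dx, dy, dz)` micrometres per voxel.
#' @param dims stack size `c(ny, nx, nz)` in voxels (z bottom -> top).
#' @param seed integer RNG seed.
#' @param fibre_base,cell_base,background,read_noise_sd intensity model
#'   (photons).
#' @param noise apply the Poisson + read-noise model.
#' @return object of class `curv_stack`: `channels` (list of 3D arrays
#'   `fibre`, `cell`), `voxel_size`, and `truth` with `cell_depths` equal to
#'   the surface height above each recorded centre.
#' @export
render_matrix_stack <- function(surface_profile, fibre_density = 5, cells,
                                voxel_size = c(1, 1, 1), dims = c(64L, 64L, 100L),
                                seed = 1L, fibre_base = 150, cell_base = 300,
                                background = 10, read_noise_sd = 2, noise = TRUE) {
  dx <- voxel_size[1]; dy <- voxel_size[2]; dz <- voxel_size[3]
  ny <- dims[1]; nx <- dims[2]; nz <- dims[3]
  surf <- if (is.matrix(surface_profile)) surface_profile
          else matrix(surface_profile, ny, nx)
  stopifnot(all(dim(surf) == c(ny, nx)))
  if (any(surf < 0 | surf > nz * dz)) stop("surface outside stack bounds")
  if (any(cells$radius < 2 * max(voxel_size)))
    stop("cell radius below 2 voxels is unsegmentable")
  set.seed(seed)
  zc <- numeric(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    ix <- pmin(pmax(round(cells$x[k] / dx), 1), nx)
    iy <- pmin(pmax(round(cells$y[k] / dy), 1), ny)
    zc[k] <- surf[iy, ix] - cells$depth[k]
    r <- cells$radius[k]
    if (cells$x[k] - r < 0 || cells$x[k] + r > nx * dx ||
        cells$y[k] - r < 0 || cells$y[k] + r > ny * dy ||
        zc[k] - r < 0 || zc[k] + r > nz * dz)
      stop("cell ", k, " does not fit inside the stack")
  }

  # fibre channel: random segments accumulated into the voxel grid
  # sample segment centres in a margin-extended box so fibre density stays
  # uniform up to the surface and the lateral borders (no edge fade)
  mar <- 10
  vol <- (nx * dx + 2 * mar) * (ny * dy + 2 * mar) * (max(surf) + 2 * mar)
  n_seg <- max(1L, round(fibre_density * vol / 1000))
  fib <- array(0, dims)
  step <- 0.5 * min(voxel_size)
  for (s in seq_len(n_seg)) {
    p0 <- c(runif(1, -mar, nx * dx + mar), runif(1, -mar, ny * dy + mar),
            runif(1, -mar, max(surf) + mar))
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    len <- runif(1, 5, 20)
    tseq <- seq(0, len, by = step)
    px <- p0[1] + tseq * dir[1]; py <- p0[2] + tseq * dir[2]
    pz <- p0[3] + tseq * dir[3]
    ix <- round(px / dx); iy <- round(py / dy); iz <- round(pz / dz)
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny & iz >= 1 & iz <= nz
    idx <- cbind(iy[ok], ix[ok], iz[ok])
    if (nrow(idx)) fib[idx] <- fib[idx] + 1
  }
  fib <- gauss_blur(fib, sigma = 1)
  fib <- fib / max(max(fib), 1e-9) * fibre_base
  zmu <- (array(rep(seq_len(nz), each = ny * nx), dims) - 0.5) * dz
  above <- zmu > array(rep(surf, nz), dims)
  fib[above] <- 0

  # cell channel: hollow shells
  cel <- array(0, dims)
  xs <- (seq_len(nx) - 0.5) * dx; ys <- (seq_len(ny) - 0.5) * dy
  zs <- (seq_len(nz) - 0.5) * dz
  shell <- max(voxel_size)
  for (k in seq_len(nrow(cells))) {
    r <- cells$radius[k]
    xr <- which(abs(xs - cells$x[k]) <= r + shell)
    yr <- which(abs(ys - cells$y[k]) <= r + shell)
    zr <- which(abs(zs - zc[k]) <= r + shell)
    dxx <- xs[xr] - cells$x[k]; dyy <- ys[yr] - cells$y[k]; dzz <- zs[zr] - zc[k]
    dist <- sqrt(outer(outer(dyy^2, dxx^2, `+`), dzz^2, `+`))
    cel[yr, xr, zr] <- pmax(cel[yr, xr, zr],
                            cell_base * (abs(dist - r) <= shell))
  }

  mk <- function(a, rns) {
    a <- a + background
    if (!noise) return(a)
    v <- rpois(length(a), as.vector(a))
    if (rns > 0) v <- v + rnorm(length(v), sd = rns)
    array(pmax(v, 0), dims)
  }
  truth <- structure(list(cells = transform(cells, zc = zc),
                          cell_depths = cells$depth, surface = surf,
                          fibre_density = fibre_density, seed = seed),
                     class = "ground_truth")
  structure(list(channels = list(fibre = mk(fib, read_noise_sd),
                                 cell = mk(cel, read_noise_sd)),
                 voxel_size = voxel_size, truth = truth),
            class = "curv_stack")
}

#' Render registered 3D stacks with planted adhesion objects
#'
#' Plants `n_curved` + `n_focal` non-overlapping bright spheres: every
#' object appears in the ITGb5 stack, curved objects also in the FCHo2
#' stack, focal objects also in the vinculin stack — the object-based
#' definition of the two adhesion classes.
#'
#' @param n_curved,n_focal numbers of planted objects.
#' @param dims stack size `c(ny, nx, nz)`.
#' @param radius sphere radius in voxels (scalar or range to sample).
#' @param base,background,read_noise_sd intensity model (photons).
#' @param seed integer RNG seed.
#' @param noise apply Poisson + read noise.
#' @return list with `channels` (`itgb5`, `fcho2`, `vinculin` 3D arrays) and
#'   `truth` (object table with class, centre and exact voxel count).
#' @export
render_adhesion_stacks <- function(n_curved, n_focal, dims = c(48L, 48L, 24L),
                                   radius = c(2, 3.5), base = 200,
                                   background = 5, read_noise_sd = 1,
                                   seed = 1L, noise = TRUE) {
  set.seed(seed)
  n <- n_curved + n_focal
  radius <- rep(range(radius), length.out = 2)
  centres <- matrix(NA_real_, 0, 3)
  rads <- numeric(0)
  guard <- 0L
  while (nrow(centres) < n && guard < 20000L) {
    guard <- guard + 1L
    r <- runif(1, radius[1], radius[2])
    p <- c(runif(1, r + 1, dims[1] - r), runif(1, r + 1, dims[2] - r),
           runif(1, r + 1, dims[3] - r))
    if (nrow(centres) == 0 ||
        all(sqrt(colSums((t(centres) - p)^2)) > (rads + r + 2))) {
      centres <- rbind(centres, p)
      rads <- c(rads, r)
    }
  }
  if (nrow(centres) < n) stop("could not place all objects; reduce n or radius")
  cls <- c(rep("curved", n_curved), rep("focal", n_focal))
  paint <- function(sel) {
    a <- array(FALSE, dims)
    for (k in which(sel)) {
      r <- rads[k]; ct <- centres[k, ]
      ys <- max(1, floor(ct[1] - r)):min(dims[1], ceiling(ct[1] + r))
      xs <- max(1, floor(ct[2] - r)):min(dims[2], ceiling(ct[2] + r))
      zs <- max(1, floor(ct[3] - r)):min(dims[3], ceiling(ct[3] + r))
      d2 <- outer(outer((ys - ct[1])^2, (xs - ct[2])^2, `+`), (zs - ct[3])^2, `+`)
      a[ys, xs, zs] <- a[ys, xs, zs] | (d2 <= r^2)
    }
    a
  }
  all_m <- paint(rep(TRUE, n))
  cur_m <- paint(cls == "curved")
  vin_m <- paint(cls == "focal")
  vox <- vapply(seq_len(n), function(k) sum(paint(seq_len(n) == k)), numeric(1))
  mk <- function(m) {
    a <- background + base * m
    if (!noise) return(a)
    v <- rpois(length(a), as.vector(a)) + rnorm(length(a), sd = read_noise_sd)
    array(pmax(v, 0), dims)
  }
  truth <- data.frame(class = cls, cy = centres[, 1], cx = centres[, 2],
                      cz = centres[, 3], radius = rads, voxels = vox)
  list(channels = list(itgb5 = mk(all_m), fcho2 = mk(cur_m), vinculin = mk(vin_m)),
       truth = truth, seed = seed)
}
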