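# Independent brute-force oracles used to check the package's fast paths.
# These deliberately share no code with the implementation.

# Exhaustive-shift autocorrelation: returns the integer shift vector with
# the largest sum(I * shift(I)) among shifts with 1 <= |d| <= max_shift.
oracle_autocorr_peak <- function(img, max_shift) {
  ny <- nrow(img); nx <- ncol(img)
  best <- NULL
  for (dy in -max_shift:max_shift) for (dx in 0:max_shift) {
    if (dx == 0 && dy <= 0) next
    r <- sqrt(dx^2 + dy^2)
    if (r < 1 || r > max_shift) next
    sh <- img[((seq_len(ny) - 1 + dy) %% ny) + 1, ((seq_len(nx) - 1 + dx) %% nx) + 1]
    v <- sum(img * sh)
    if (is.null(best) || v > best$v) best <- list(v = v, dx = dx, dy = dy)
  }
  best
}

# Spearman rho by the textbook rank-difference formula (valid without ties).
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Moment-preserving threshold by exhaustive search over all 256 cut points:
# for each cut t with below-fraction p, solve the two representative levels
# z0 < z1 that preserve the first two moments, then score the cut by the
# third-moment mismatch; return the cut minimizing the mismatch.
oracle_moments_level <- function(px) {
  rng <- range(px)
  levels <- round((px - rng[1]) / diff(rng) * 255)  # same 0..255 grid
  m1 <- mean(levels); m2 <- mean(levels^2); m3 <- mean(levels^3)
  best_t <- NA_integer_; best_err <- Inf
  for (t in 0:255) {
    p <- mean(levels <= t)
    if (p <= 0 || p >= 1) next
    a <- p + p^2 / (1 - p)
    b <- -2 * m1 * p / (1 - p)
    cc <- m1^2 / (1 - p) - m2
    disc <- b^2 - 4 * a * cc
    if (!is.finite(disc) || disc < 0) next
    z0 <- (-b - sqrt(disc)) / (2 * a)
    z1 <- (m1 - p * z0) / (1 - p)
    err <- abs(p * z0^3 + (1 - p) * z1^3 - m3)
    if (err < best_err) { best_err <- err; best_t <- t }
  }
  best_t
}

# Check that the implementation's level and the exhaustive-search level
# agree up to the discrete p0 bracket: either identical, or the oracle is
# the last cut below the moment-preserving fraction p0 while the
# implementation takes the first cut above it (no cut lies between).
expect_moments_agree <- function(px) {
  thr <- moments_threshold(px)
  t_impl <- attr(thr, "level"); p0 <- attr(thr, "p0")
  t_orc <- oracle_moments_level(px)
  rng <- range(px)
  lev <- round((px - rng[1]) / diff(rng) * 255)
  cum <- cumsum(tabulate(lev + 1L, 256L) / length(lev))
  if (t_impl == t_orc) {
    succeed()
  } else {
    expect_lt(t_orc, t_impl)
    expect_lte(cum[t_orc + 1L], p0 + 1e-9)   # oracle: a cut below p0
    expect_gte(cum[t_impl + 1L], p0 - 1e-9)  # dialect: first cut above p0
  }
  invisible(NULL)
}

# Connected-component count via igraph on the pixel/voxel adjacency graph.
oracle_component_sizes <- function(mask, connectivity) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) return(integer(0))
  key <- apply(idx, 1, paste, collapse = ",")
  lookup <- seq_len(n); names(lookup) <- key
  offs <- as.matrix(expand.grid(rep(list(-1L:1L), ncol(idx))))
  offs <- offs[rowSums(offs != 0L) > 0L, , drop = FALSE]
  if (connectivity %in% c(4L, 6L)) offs <- offs[rowSums(offs != 0L) == 1L, , drop = FALSE]
  edges <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[r, ], `+`)
    nbk <- apply(nb, 1, paste, collapse = ",")
    hit <- !is.na(lookup[nbk])
    edges <- c(edges, rbind(lookup[key[hit]], lookup[nbk[hit]]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  unname(comp$csize)
}

# Small noiseless / noisy bar-field fixture shared by several tests.
make_bar_field <- function(E = 1, seed = 1, dims = c(320L, 320L), noise = TRUE,
                           wrap = NULL, base = 200, background = 20) {
  render_structure_field(
    lattice_spec(),
    channels = list(
      registration = channel_spec("registration", base_intensity = base,
                                  background = background),
      membrane = channel_spec("membrane", base_intensity = base,
                              background = background),
      integrin = channel_spec("integrin", base_intensity = base,
                              end_enrichment = E, background = background)),
    wrap = wrap, seed = seed, dims = dims, noise = noise)
}

run_bar_pipeline <- function(field, flank_width = 0, background = c(20, 20)) {
  reg <- field$channels$registration
  lat <- detect_lattice(reg, c(2, 10), field$pixel_size)
  win <- tile_windows(lat, dim(reg), field$cell_mask)
  avg <- average_windows(reg, win)
  rois <- derive_bar_rois(avg, flank_width = flank_width)
  end_side_ratios(field$channels$integrin, field$channels$membrane,
                  win, rois, background = background)
}

# Hand-built single-window window_set for toy-pixel tests.
toy_windows <- function(side = 21L, cx = 11L, cy = 11L) {
  structure(data.frame(id = 1L, i = 0L, j = 0L, cx = cx, cy = cy,
                       in_cell = TRUE),
            side = side, half = (side - 1L) %/% 2L,
            class = c("window_set", "data.frame"))
}
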