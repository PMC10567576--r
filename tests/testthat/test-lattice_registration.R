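# Lattice detection, window tiling, window averaging and ROI derivation.

test_that("detect_lattice recovers an exact grid and the fabricated pitch", {
  # noiseless 5-um-pitch array at 0.1 um/px
  f <- make_bar_field(seed = 1, dims = c(320L, 320L), noise = FALSE)
  lat <- detect_lattice(f$channels$registration, c(2, 10), 0.1)
  expect_equal(lat$pitch_px, 50, tolerance = 1e-3)
  expect_lt(min(lat$orientation, 90 - lat$orientation), 0.05)
  expect_lt(lat$residual, 0.02)

  # fabricated-geometry render with default noise: pitch 5 um
  fn <- make_bar_field(seed = 2, dims = c(320L, 320L))
  latn <- detect_lattice(fn$channels$registration, c(2, 10), 0.1)
  expect_equal(latn$pitch, 5, tolerance = 0.01)
})

test_that("32x32 toy: detected pitch equals the exhaustive-shift autocorrelation peak", {
  img <- matrix(0, 32, 32)
  img[cbind(rep(c(8, 16, 24), each = 4), rep(c(8, 16, 24), 4)[1:12])] <- 100
  pk <- oracle_autocorr_peak(img - mean(img), max_shift = 12)
  lat <- detect_lattice(img, pitch_band = c(0.4, 1.2), pixel_size = 0.1)
  expect_equal(sqrt(pk$dx^2 + pk$dy^2), 8)
  expect_equal(lat$pitch_px, 8, tolerance = 0.2)
})

test_that("non-periodic image fails with 'no lattice'", {
  set.seed(1)
  expect_error(detect_lattice(matrix(rnorm(64^2), 64), c(2, 10), 0.1),
               "no lattice")
})

test_that("detection is translation-equivariant (origin shifts mod lattice)", {
  f <- make_bar_field(seed = 3, dims = c(320L, 320L), noise = FALSE)
  img <- f$channels$registration
  lat0 <- detect_lattice(img, c(2, 10), 0.1)
  for (sh in list(c(7L, 3L), c(13L, 21L), c(2L, 40L))) {
    shifted <- img[c((sh[2] + 1):320, 1:sh[2]), c((sh[1] + 1):320, 1:sh[1])]
    lat1 <- detect_lattice(shifted, c(2, 10), 0.1)
    expect_equal(lat1$pitch_px, lat0$pitch_px, tolerance = 0.02)
    d <- (lat1$origin + sh) - lat0$origin
    # difference must be a lattice vector
    frac <- c(sum(d * lat0$a1) / sum(lat0$a1^2), sum(d * lat0$a2) / sum(lat0$a2^2))
    expect_equal(frac, round(frac), tolerance = 0.02)
  }
})

test_that("pitch recovery error < 0.5 px on noisy fields across seeds", {
  for (seed in 1:5) {
    f <- make_bar_field(seed = seed, dims = c(300L, 300L), base = 60,
                        background = 30)  # SNR well above 5
    lat <- detect_lattice(f$channels$registration, c(2, 10), 0.1)
    expect_lt(abs(lat$pitch_px - 50), 0.5)
  }
})

test_that("tile_windows counts, geometry and in_cell flagging", {
  lat <- lattice_spec(origin = c(25, 25), pitch = 5, pixel_size = 0.1)
  win <- tile_windows(lat, c(500L, 500L))
  expect_equal(nrow(win), 100)          # 10 x 10 nodes fit completely
  expect_equal(attr(win, "side"), 49)   # side <= pitch: no overlap
  expect_true(all(win$in_cell))

  # cell over the left half: about half the windows in_cell
  cell <- matrix(FALSE, 500, 500); cell[, 1:250] <- TRUE
  win2 <- tile_windows(lat, c(500L, 500L), cell)
  expect_equal(nrow(win2), 100)
  expect_gte(sum(win2$in_cell), 40)
  expect_lte(sum(win2$in_cell), 60)

  # per-cell bar counts in the paper's tens-to-hundreds range are natural
  expect_gte(nrow(win), 26)
  expect_error(tile_windows(lat, c(30L, 30L)), "zero complete windows")
})

test_that("average_windows: identity on identical windows, sd ~ sigma/sqrt(N)", {
  f <- make_bar_field(seed = 1, dims = c(320L, 320L), noise = FALSE)
  win <- tile_windows(f$lattice, c(320L, 320L))
  avg <- average_windows(f$channels$registration, win)
  h <- attr(win, "half")
  one <- f$channels$registration[(win$cy[1] - h):(win$cy[1] + h),
                                 (win$cx[1] - h):(win$cx[1] + h)]
  expect_equal(avg, one)

  # Monte-Carlo: averaging N iid-noise windows shrinks the sd by sqrt(N)
  set.seed(11)
  sigma <- 5
  img <- matrix(100, 320, 320) + matrix(rnorm(320^2, sd = sigma), 320)
  avgn <- average_windows(img, win)
  expect_equal(sd(avgn), sigma / sqrt(nrow(win)), tolerance = 0.2)
  expect_error(average_windows(img, win, use = rep(FALSE, nrow(win))),
               "no in-cell windows")
})

test_that("derive_bar_rois: symmetry, disjointness, per-pixel predicate oracle", {
  # hand-drawn 21x21 axis-aligned toy footprint: 3 px wide, 15 px long
  w <- matrix(10, 21, 21)
  w[10:12, 4:18] <- 100
  rois <- derive_bar_rois(w, flank_width = 0)
  expect_false(any(rois$end_mask & rois$side_mask))
  expect_true(all((rois$end_mask | rois$side_mask) == (w > 50)))
  # exhaustive geometric predicate: measured bar half-width = max pixel
  # centre offset = 1, so cap depth = 2 px from the bar tips
  # (|x - 11| > L_half - cap_depth = 7 - 2 = 5), inside the footprint
  for (y in 1:21) for (x in 1:21) {
    inside <- w[y, x] > 50
    is_end <- inside && abs(x - 11) > 5
    expect_identical(rois$end_mask[y, x], is_end)
    expect_identical(rois$side_mask[y, x], inside && !is_end)
  }
  # mirror symmetry under both bar axes
  expect_identical(rois$end_mask, rois$end_mask[21:1, ])
  expect_identical(rois$end_mask, rois$end_mask[, 21:1])

  # a round footprint is rejected as "not a bar"
  disc <- matrix(10, 21, 21)
  disc[(row(disc) - 11)^2 + (col(disc) - 11)^2 <= 36] <- 100
  expect_error(derive_bar_rois(disc), "not a bar")
})

test_that("bar ROIs translated to every window reproduce per-bar ratios", {
  f <- make_bar_field(E = 2, seed = 1, dims = c(320L, 320L), noise = FALSE)
  win <- tile_windows(f$lattice, c(320L, 320L))
  avg <- average_windows(f$channels$registration, win)
  rois <- derive_bar_rois(avg, flank_width = 0)
  r <- direct_end_side(f$channels$integrin, win, rois, background = 20)
  # every translated window yields the exact closed-form ratio
  expect_equal(r$per_bar$ratio_norm, rep(2, nrow(win)))
})

test_that("derive_pillar_rois: defaults, degenerate cases, enumeration oracle", {
  rois <- derive_pillar_rois()           # 0-9 / 10-20 px defaults
  expect_equal(rois$r_in, 9); expect_equal(rois$r_out, 20)
  expect_false(any(rois$pillar_mask & rois$annulus_mask))
  side <- nrow(rois$pillar_mask); c0 <- (side + 1) / 2
  n_in <- 0L; n_ann <- 0L
  for (y in seq_len(side)) for (x in seq_len(side)) {
    d <- sqrt((x - c0)^2 + (y - c0)^2)
    n_in <- n_in + (d <= 9); n_ann <- n_ann + (d > 9 && d <= 20)
  }
  expect_equal(sum(rois$pillar_mask), n_in)
  expect_equal(sum(rois$annulus_mask), n_ann)

  r0 <- derive_pillar_rois(r_in = 0, r_out = 5)
  expect_equal(sum(r0$pillar_mask), 1)   # single-pixel pillar mask
  expect_error(derive_pillar_rois(r_in = 9, r_out = 9), "smaller")
})
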