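# Generator: closed-form expectations, determinism, noise statistics,
# wrap-confound bookkeeping, gradient / time-lapse / 3D-stack contracts.

test_that("noiseless render matches the closed-form expectation pixelwise", {
  lat <- lattice_spec()
  f <- render_structure_field(
    lat, channels = list(integrin = channel_spec("integrin",
      base_intensity = 100, end_enrichment = 2, background = 10)),
    seed = 1, dims = c(160L, 160L), noise = FALSE)
  img <- f$channels$integrin
  # only three values can occur: flat/side 110 and bar-end 210
  expect_setequal(unique(as.vector(img)), c(110, 210))
  # bar-end pixels exist in every structure and sit at cap positions
  expect_gt(sum(img == 210), 0)

  # E = 1 everywhere: constant over the whole frame (membrane footprint)
  f1 <- render_structure_field(
    lat, channels = list(membrane = channel_spec("membrane",
      base_intensity = 100, end_enrichment = 1, background = 10)),
    seed = 1, dims = c(160L, 160L), noise = FALSE)
  expect_equal(unique(as.vector(f1$channels$membrane)), 110)
})

test_that("fabricated geometry puts structure centres one pitch apart", {
  lat <- lattice_spec(pitch = 5, pixel_size = 0.1)
  f <- render_structure_field(lat,
    channels = list(registration = channel_spec("registration")),
    seed = 1, dims = c(200L, 200L), noise = FALSE)
  nd <- f$truth$nodes
  row1 <- nd[abs(nd$cy - nd$cy[1]) < 1, ]
  expect_equal(diff(sort(row1$cx)), rep(50, nrow(row1) - 1))
})

test_that("fixed seed gives bit-identical renders; noiseless is deterministic", {
  a <- make_bar_field(E = 1.5, seed = 42, dims = c(160L, 160L))
  b <- make_bar_field(E = 1.5, seed = 42, dims = c(160L, 160L))
  expect_identical(a$channels, b$channels)
  c1 <- make_bar_field(E = 1.5, seed = 1, dims = c(160L, 160L), noise = FALSE)
  c2 <- make_bar_field(E = 1.5, seed = 2, dims = c(160L, 160L), noise = FALSE)
  expect_identical(c1$channels, c2$channels)
})

test_that("mean of many noisy renders converges to the expectation (3 SE)", {
  lat <- lattice_spec()
  ch <- list(integrin = channel_spec("integrin", base_intensity = 100,
                                     end_enrichment = 2, background = 10,
                                     read_noise_sd = 2))
  expct <- render_structure_field(lat, ch, seed = 1, dims = c(110L, 110L),
                                  noise = FALSE)$channels$integrin
  n <- 150L
  acc <- 0
  for (k in seq_len(n))
    acc <- acc + render_structure_field(lat, ch, seed = k, dims = c(110L, 110L))$channels$integrin
  avg <- acc / n
  se <- sqrt(expct + 4) / sqrt(n)  # var = Poisson + read noise
  frac_outside <- mean(abs(avg - expct) > 3 * se)
  expect_lt(frac_outside, 0.01)   # ~0.3% expected by chance
})

test_that("wrap factors hit membrane and integrin jointly; truth records them", {
  lat <- lattice_spec()
  set.seed(9); W <- runif(36, 0.5, 1.5)
  f <- render_structure_field(lat, channels = list(
    membrane = channel_spec("membrane", background = 0),
    integrin = channel_spec("integrin", background = 0, end_enrichment = 3)),
    wrap = W, seed = 1, dims = c(320L, 320L), noise = FALSE)
  expect_equal(f$truth$wrap, rep_len(W, nrow(f$truth$nodes)))
  # at any bar-side pixel the two channels have the identical wrap factor
  m <- f$channels$membrane / 200; i <- f$channels$integrin / 200
  side_px <- which(m != 1 & i == m)   # wrapped, not enriched
  expect_gt(length(side_px), 0)
  # normalized end/side is invariant: integrin/membrane at every structure
  # pixel is either 1 (side) or E (end)
  expect_setequal(round(unique(as.vector(i / m)), 10), c(1, 3))
})

test_that("invalid geometry and parameters are rejected", {
  expect_error(lattice_spec(pitch = 1.5, bar_length = 2), "pitch")
  expect_error(lattice_spec(bar_length = 0.3, bar_width = 0.2), "caps")
  expect_error(channel_spec("integrin", base_intensity = -5), "non-negative")
  expect_error(render_structure_field(lattice_spec(),
    list(membrane = channel_spec("membrane")), dims = c(60L, 60L)),
    "2x2 lattice periods")
  expect_error(render_structure_field(lattice_spec(),
    list(membrane = channel_spec("membrane")), wrap = -1,
    dims = c(160L, 160L)), "positive")
})

test_that("gradient field: labelled sub-arrays, constant-curve identity, step recovery", {
  dia <- c(0.2, 0.5, 1, 2)
  g <- render_gradient_bar_field(dia, function(d) ifelse(d < 1.5, 2, 1),
                                 pixel_size = 0.25, seed = 3, noise = FALSE)
  nd <- g$truth$nodes
  expect_equal(sort(unique(nd$diameter)), dia)
  expect_equal(nrow(nd), 4 * length(dia))
  expect_equal(unique(nd$E[nd$diameter < 1.5]), 2)
  expect_equal(unique(nd$E[nd$diameter >= 1.5]), 1)
  expect_error(render_gradient_bar_field(c(1, 20), 1), "diameter exceeds")

  # recovery: per-diameter direct end/side ratio against recorded truth
  img <- g$channels$integrin
  ratios <- vapply(seq_len(nrow(nd)), function(k) {
    w2 <- nd$diameter[k] / 0.25 / 2; l2 <- nd$length_um[k] / 0.25 / 2
    xs <- round(nd$cx[k] + seq(-l2 - 1, l2 + 1)); ys <- round(nd$cy[k] + seq(-w2 - 1, w2 + 1))
    sub <- img[ys, xs] - 20
    u <- abs(matrix(xs, length(ys), length(xs), byrow = TRUE) - nd$cx[k])
    v <- abs(matrix(ys, length(ys), length(xs)) - nd$cy[k])
    du <- pmax(u - (l2 - w2), 0)
    inside <- (du^2 + v^2) <= w2^2  # rounded-rectangle footprint predicate
    endm <- inside & u > (l2 - 2 * w2)
    mean(sub[endm]) / mean(sub[inside & !endm])
  }, numeric(1))
  per_d <- tapply(ratios, nd$diameter, mean)
  expect_equal(as.numeric(per_d[c("0.2", "0.5", "1")]), rep(2, 3), tolerance = 1e-10)
  expect_equal(as.numeric(per_d[["2"]]), 1, tolerance = 1e-10)

  # constant curve of 1: all sub-arrays statistically identical (noiseless:
  # every bar has ratio exactly 1)
  g1 <- render_gradient_bar_field(dia, 1, pixel_size = 0.25, seed = 4, noise = FALSE)
  expect_equal(unique(g1$truth$nodes$E), 1)
})

test_that("time-lapse: frame count arithmetic, trace validation, constant movie", {
  # 15 s per frame for 20 min -> 80 frames
  expect_equal(20 * 60 / 15, 80)
  lat <- lattice_spec(structure_kind = "pillar", pillar_diameter = 1.8)
  np <- nrow(tile_windows(lat, c(200L, 200L)))
  ch <- list(poi = channel_spec("poi", base_intensity = 100))
  expect_error(render_timelapse(lat, ch, traces = matrix(1, np, 5),
                                n_frames = 6, dims = c(200L, 200L)),
               "does not match")
  tl <- render_timelapse(lat, ch, traces = matrix(1, np, 4), seed = 2,
                         dims = c(200L, 200L), noise = FALSE)
  expect_length(tl$frames, 4)
  expect_identical(tl$frames[[1]], tl$frames[[2]])  # constant, noiseless
})

test_that("3D stack: depth bookkeeping, fit checks, tiny-cell rejection", {
  cells <- data.frame(x = 20, y = 20, depth = 50, radius = 5)
  st <- render_matrix_stack(80, cells = cells, dims = c(40L, 40L, 100L),
                            seed = 1, noise = FALSE)
  expect_equal(st$truth$cell_depths, 50)
  expect_equal(st$truth$cells$zc, 30)
  expect_error(render_matrix_stack(80, cells = data.frame(
    x = 20, y = 20, depth = 50, radius = 1.5), dims = c(40L, 40L, 100L)),
    "unsegmentable")
  expect_error(render_matrix_stack(80, cells = data.frame(
    x = 20, y = 20, depth = 78, radius = 5), dims = c(40L, 40L, 100L)),
    "does not fit")
})
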