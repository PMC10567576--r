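# End/side and pillar ratiometrics, enrichment classification, Spearman.

test_that("end_side_ratios: listed toy pixels give ratio_norm = 2.0", {
  win <- toy_windows()
  rois <- derive_pillar_rois(r_in = 3, r_out = 6, side = 21)  # reuse masks
  rois <- structure(list(end_mask = rois$pillar_mask,
                         side_mask = rois$annulus_mask, kind = "bar"),
                    class = "roi_set")
  integrin <- matrix(0, 21, 21); membrane <- matrix(0, 21, 21)
  integrin[rois$end_mask] <- 20; integrin[rois$side_mask] <- 10
  membrane[rois$end_mask] <- 12; membrane[rois$side_mask] <- 12
  r <- end_side_ratios(integrin, membrane, win, rois)
  expect_equal(r$per_bar$ratio_norm, (20 / 10) / (12 / 12))
  expect_equal(r$per_cell$mean_ratio_norm, 2.0)
})

test_that("uniform truth gives per-cell mean ~ 1; E = 1.9 is recovered", {
  r1 <- run_bar_pipeline(make_bar_field(E = 1, seed = 21))
  expect_equal(r1$per_cell$mean_ratio_norm, 1, tolerance = 0.02)
  r19 <- run_bar_pipeline(make_bar_field(E = 1.9, seed = 22))
  expect_equal(r19$per_cell$mean_ratio_norm, 1.9, tolerance = 0.05)
})

test_that("direct ratio is wrap-biased while the normalized ratio is not", {
  set.seed(31)
  W <- runif(36, 0.5, 1.5)
  f <- make_bar_field(E = 2, seed = 31, wrap = W, noise = FALSE)
  win <- tile_windows(f$lattice, dim(f$channels$registration))
  avg <- average_windows(f$channels$registration, win)
  rois <- derive_bar_rois(avg, flank_width = 0)
  norm <- end_side_ratios(f$channels$integrin, f$channels$membrane, win, rois,
                          background = c(20, 20))
  expect_equal(norm$per_bar$ratio_norm, rep(2, nrow(win)))  # exact cancellation

  # direct ratio on a channel whose end sits on wrapped membrane while the
  # side reference is the unwrapped flat area: bias appears
  flat_rois <- structure(list(end_mask = rois$end_mask,
                              side_mask = !dilate_box(rois$footprint, 2) ,
                              kind = "bar"), class = "roi_set")
  direct <- direct_end_side(f$channels$integrin, win, flat_rois, background = 20)
  expect_gt(sd(direct$per_bar$ratio_norm), 0.01)  # wrap variance leaks in
})

test_that("non-positive side means are excluded and logged", {
  win <- toy_windows()
  rois <- list(end_mask = matrix(c(rep(TRUE, 21), rep(FALSE, 420)), 21),
               side_mask = matrix(c(rep(FALSE, 420), rep(TRUE, 21)), 21))
  ch <- matrix(5, 21, 21)
  expect_message(expect_error(
    end_side_ratios(ch, ch, win, rois, background = c(10, 0)),
    "all bars excluded"), "excluded")
})

test_that("gradient_group equals a brute-force groupby mean and drops empties", {
  set.seed(41)
  per_bar <- data.frame(field = rep(1:8, each = 12),
                        diameter = rep(c(0.1, 0.5, 1, 2, 3, 5), 16),
                        ratio = rnorm(96, 1.5, 0.2))
  g <- gradient_group(per_bar)
  expect_equal(nrow(g), 48)  # 6 diameters x 8 fields
  oracle <- aggregate(ratio ~ field + diameter, per_bar, mean)
  m <- merge(g, oracle, by = c("field", "diameter"))
  expect_equal(m$mean_ratio, m$ratio)

  # constant input: all group means equal
  per_bar$ratio <- 2
  expect_true(all(gradient_group(per_bar)$mean_ratio == 2))

  # a diameter with no finite ratios is omitted
  per_bar$ratio[per_bar$diameter == 5] <- NaN
  expect_false(5 %in% gradient_group(per_bar)$diameter)
})

test_that("pillar_ratios: hand-checked normalization and exact unit mean", {
  win <- toy_windows(side = 15, cx = 8, cy = 8)
  win <- rbind(win, data.frame(id = 2L, i = 1L, j = 0L, cx = 8, cy = 8,
                               in_cell = TRUE))
  attr(win, "side") <- 15L; attr(win, "half") <- 7L
  class(win) <- c("window_set", "data.frame")
  rois <- derive_pillar_rois(r_in = 2, r_out = 5, side = 15)
  integrin <- matrix(0, 15, 15); membrane <- matrix(0, 15, 15)
  integrin[rois$pillar_mask] <- 30; integrin[rois$annulus_mask] <- 10
  membrane[rois$pillar_mask] <- 10; membrane[rois$annulus_mask] <- 10
  pr <- pillar_ratios(integrin, membrane, win, rois)
  # raw ratios: pillar 3, annulus 1 (both windows identical)
  # norm constant = mean(3, 3, 1, 1) = 2
  expect_equal(pr$norm_constant, 2)
  expect_equal(sort(unique(pr$per_roi$norm_ratio)), c(0.5, 1.5))
  expect_equal(mean(pr$per_roi$norm_ratio), 1)  # exact, by construction
})

test_that("uniform channels give all norm_ratios exactly 1", {
  win <- toy_windows(side = 43, cx = 22, cy = 22)
  rois <- derive_pillar_rois(9, 20, side = 43)
  u <- matrix(7, 43, 43)
  pr <- pillar_ratios(u, u, win, rois)
  expect_equal(pr$per_roi$norm_ratio, rep(1, 2))
})

test_that("classify_enriched: trivial nulls and ROC against the label oracle", {
  expect_equal(classify_enriched(rep(1, 20))$fraction, 0)
  set.seed(51)
  truth <- runif(200) < 0.4
  scores <- ifelse(truth, rnorm(200, 2, 0.3), rnorm(200, 1, 0.3))
  for (T in c(1.2, 1.5, 1.8)) {
    cl <- classify_enriched(scores, threshold = T)
    # exhaustive label-comparison oracle
    tp <- sum(scores > T & truth); fp <- sum(scores > T & !truth)
    expect_equal(sum(cl$enriched & truth), tp)
    expect_equal(sum(cl$enriched & !truth), fp)
    expect_equal(cl$fraction, (tp + fp) / 200)
  }
})

test_that("spearman_rho equals the rank-formula oracle on all 5-permutations", {
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 5), ]
  x <- c(2.5, 1.1, 7.3, 4.2, 5.9)  # arbitrary distinct values
  for (k in seq_len(nrow(perms))) {
    y <- perms[k, ]
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y))
  }
  # strictly increasing pairs
  expect_equal(spearman_rho(1:7, (1:7)^3), 1.0)
  # 6-point toy
  x6 <- c(3, 1, 4, 1.5, 9, 2.6); y6 <- c(2, 7, 1, 8, 2.8, 1.8)
  expect_equal(spearman_rho(x6, y6), oracle_spearman(x6, y6))
  # constant input undefined
  expect_message(v <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(v))
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(61)
  for (k in 1:25) {
    x <- rnorm(30); y <- rnorm(30)
    r0 <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), r0)
    expect_equal(spearman_rho(x, y^3 + 2 * y), r0)
    expect_equal(spearman_rho(rank(x), y), r0)
  }
})

test_that("spearman_at_pillars recovers a planted rank correlation", {
  lat <- lattice_spec(structure_kind = "pillar", pillar_diameter = 1.8)
  n <- nrow(tile_windows(lat, c(600L, 600L)))
  set.seed(71)
  E <- ifelse(runif(n) < 0.3, 2.5, 1)
  poiE <- pmax(1 + (E - 1) * 0.8 + rnorm(n, 0, 0.3), 0.1)
  f <- render_structure_field(lat, channels = list(
    membrane = channel_spec("membrane"),
    integrin = channel_spec("integrin", end_enrichment = E),
    poi = channel_spec("poi", end_enrichment = poiE)),
    seed = 71, dims = c(600L, 600L))
  win <- tile_windows(lat, c(600L, 600L))
  rois <- derive_pillar_rois()
  sp <- spearman_at_pillars(f$channels$poi, f$channels$integrin,
                            f$channels$membrane, win, rois,
                            background = rep(20, 3))
  # image-free reference on the planted parameters
  ref <- spearman_rho(poiE, E + rnorm(n, 0, 1e-9))
  expect_equal(sp$n, n)
  expect_equal(sp$rho, ref, tolerance = 0.15)
})

test_that("gain invariance: scaling any channel leaves normalized ratios unchanged", {
  f <- make_bar_field(E = 1.7, seed = 81, dims = c(320L, 320L))
  win <- tile_windows(f$lattice, c(320L, 320L))
  avg <- average_windows(f$channels$registration, win)
  rois <- derive_bar_rois(avg, flank_width = 0)
  base <- end_side_ratios(f$channels$integrin, f$channels$membrane, win, rois,
                          background = c(20, 20))
  set.seed(82)
  for (g in exp(runif(10, -2, 2))) {
    r <- end_side_ratios(g * f$channels$integrin, f$channels$membrane, win,
                         rois, background = c(g * 20, 20))
    expect_equal(r$per_bar$ratio_norm, base$per_bar$ratio_norm)
    r2 <- end_side_ratios(f$channels$integrin, g * f$channels$membrane, win,
                          rois, background = c(20, g * 20))
    expect_equal(r2$per_bar$ratio_norm, base$per_bar$ratio_norm)
  }
})

test_that("parameter recovery: |E_hat - E| < 0.1 for E in {1, 1.5, 2, 3}", {
  for (E in c(1, 1.5, 2, 3)) {
    percell <- vapply(1:10, function(cell) {
      f <- make_bar_field(E = E, seed = 1000 * E + cell, dims = c(270L, 270L))
      run_bar_pipeline(f)$per_cell$mean_ratio_norm
    }, numeric(1))
    expect_lt(abs(mean(percell) - E), 0.1)
  }
})
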