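test_that("grid shapes use ceiling division and reject bad input", {
  expect_equal(unname(grid_shape(800, 800, 4)), c(200, 200))
  expect_equal(unname(grid_shape(800, 800, 64)), c(13, 13))
  expect_equal(unname(grid_shape(5, 5, 5)), c(1, 1))
  expect_equal(unname(grid_shape(1, 1, 64)), c(1, 1))
  expect_error(grid_shape(0, 800, 4), "positive")
  expect_error(grid_shape(800, 800, -1), "positive")
})

test_that("the adaptive scan rectangle is a symmetric central window", {
  r <- adaptive_region(adaptive_region_spec(), 1000, 600)
  expect_equal(unname(r), c(330, 96, 670, 504))
  r <- adaptive_region(adaptive_region_spec(), 1, 1)
  expect_equal(unname(r), c(0.33, 0.16, 0.67, 0.84))
  full <- adaptive_region(adaptive_region_spec(half_width_fraction = 0.5,
                                               half_height_fraction = 0.5),
                          640, 480)
  expect_equal(unname(full), c(0, 0, 640, 480))
  off <- adaptive_region(adaptive_region_spec(center_x = 100, center_y = 50),
                         1000, 600)
  expect_equal(off[["x_min"]], 0)  # clipped at the image edge
  expect_error(adaptive_region_spec(half_width_fraction = 0.6), "0, 0.5")
})

test_that("kept columns round half up and form a centred block", {
  expect_equal(kept_columns(200), 66L)
  expect_equal(kept_columns(50), 17L)   # 16.5 rounds up
  expect_equal(kept_columns(13), 4L)
  expect_equal(kept_columns(1), 0L)
  expect_error(kept_columns(-1), "non-negative")
  # monotonicity in the keep fraction
  for (cols in c(1, 7, 13, 50, 200)) {
    ks <- vapply(seq(0, 1, by = 0.05), function(f) kept_columns(cols, f),
                 integer(1))
    expect_true(all(diff(ks) >= 0))
  }
})

test_that("per-level adaptive counts reproduce the published accounting", {
  expected <- data.frame(stride = c(4, 8, 16, 32, 64),
                         std = c(40000, 10000, 2500, 625, 169),
                         ada = c(13200, 3300, 850, 200, 52))
  spec <- adaptive_region_spec()  # table_consistent default
  for (i in seq_len(nrow(expected))) {
    lev <- pyramid_level("P", expected$stride[i], 800, 800)
    expect_equal(nrow(generate_anchor_positions(lev)), expected$std[i])
    expect_equal(nrow(generate_anchor_positions(lev, spec)), expected$ada[i])
  }
})

test_that("eq_region position counts match a brute-force cell-centre scan", {
  spec <- adaptive_region_spec(mode = "eq_region")
  set.seed(17)
  for (rep in 1:25) {
    h <- sample(20:400, 1); w <- sample(20:400, 1)
    stride <- sample(c(4, 8, 16), 1)
    lev <- pyramid_level("Px", stride, h, w)
    if (lev$rows > 50 || lev$cols > 50) next
    rect <- adaptive_region(spec, image_w = w, image_h = h)
    got <- nrow(generate_anchor_positions(lev, spec))
    expect_equal(got, brute_force_positions(lev, rect))
  }
})

test_that("anchors multiply positions by the per-position count", {
  lev <- pyramid_level("P6", 64, 800, 800)
  pos <- generate_anchor_positions(lev)
  a <- generate_anchors(pos, anchor_config())
  expect_equal(nrow(a), nrow(pos) * 3)
  expect_true(all(a[, "x_max"] > a[, "x_min"]))
  # anchors at one position share the cell centre
  one <- generate_anchors(pos[1, , drop = FALSE], anchor_config(), scale = 32)
  expect_equal(nrow(one), 3)
  cx <- (one[, "x_min"] + one[, "x_max"]) / 2
  expect_equal(unname(cx), rep(pos$cx[1], 3))
  none <- generate_anchors(pos[0, , drop = FALSE], anchor_config())
  expect_equal(nrow(none), 0)
})

test_that("the anchor budget reproduces the published totals and reduction", {
  b <- anchor_budget(800, 800)
  expect_equal(b$totals$standard_positions, 53294)
  expect_equal(b$totals$adaptive_positions, 17602)
  expect_equal(b$totals$standard_density, 159882)
  expect_equal(b$totals$adaptive_density, 52806)
  expect_equal(b$totals$density_reduction_pct, 67L)
  expect_equal(b$levels$adaptive_positions, c(13200L, 3300L, 850L, 200L, 52L))
  # density is exactly 3x positions under the default configuration
  expect_equal(b$totals$standard_density, 3 * b$totals$standard_positions)
  expect_equal(b$totals$adaptive_density, 3 * b$totals$adaptive_positions)
  expect_true(all(b$levels$adaptive_positions <= b$levels$standard_positions))
  # no restriction, no reduction
  b0 <- anchor_budget(800, 800, spec = NULL)
  expect_equal(b0$totals$density_reduction_pct, 0L)
  expect_equal(b0$totals$adaptive_positions, b0$totals$standard_positions)
})

test_that("budget serializers emit both formats", {
  b <- anchor_budget(800, 800)
  j <- jsonlite::fromJSON(format_anchor_budget(b, "json"))
  expect_equal(j$totals$adaptive_density, 52806)
  tsv <- format_anchor_budget(b, "tsv")
  expect_match(tsv[2], "^P2\t40000\t13200")
})
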