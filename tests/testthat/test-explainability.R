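test_that("channel weights are the spatial mean of the gradients", {
  a <- array(1, c(2, 2, 1))
  g <- array(c(1, 3, 2, 4), c(2, 2, 1))
  expect_equal(channel_weights(gradcam_context(a, g)), 2.5)
  # constant gradient -> that constant
  g2 <- array(0.7, c(4, 5, 3))
  expect_equal(channel_weights(gradcam_context(array(0, c(4, 5, 3)), g2)),
               rep(0.7, 3))
  # channels are independent
  g3 <- array(c(rep(1, 6), rep(-2, 6)), c(2, 3, 2))
  expect_equal(channel_weights(gradcam_context(array(0, c(2, 3, 2)), g3)),
               c(1, -2))
  expect_error(gradcam_context(array(0, c(2, 2, 1)), array(0, c(3, 2, 1))),
               "shape")
})

test_that("weights match a brute-force double loop on random tensors", {
  set.seed(19)
  for (i in 1:60) {
    h <- sample(1:32, 1); w <- sample(1:32, 1); k <- sample(1:8, 1)
    g <- array(rnorm(h * w * k), c(h, w, k))
    ctx <- gradcam_context(array(rnorm(h * w * k), c(h, w, k)), g)
    manual <- numeric(k)
    for (ch in seq_len(k)) {
      s <- 0
      for (ii in seq_len(h)) for (jj in seq_len(w)) s <- s + g[ii, jj, ch]
      manual[ch] <- s / (h * w)
    }
    expect_equal(channel_weights(ctx), manual)
  }
})

test_that("the heatmap is the rectified weighted channel sum", {
  # weights (1, -2) on all-ones maps: ReLU(-1) = 0 everywhere
  a <- array(1, c(3, 3, 2))
  expect_equal(unclass(gradcam_map(c(1, -2), a)),
               matrix(0, 3, 3), ignore_attr = TRUE)
  # single channel ReLU
  a1 <- array(c(-1, 2), c(1, 2, 1))
  expect_equal(as.numeric(gradcam_map(1, a1)), c(0, 2))
  # positive homogeneity in the weights
  set.seed(4)
  a <- array(rnorm(48), c(4, 4, 3))
  w <- rnorm(3)
  expect_equal(unclass(gradcam_map(3 * w, a)),
               3 * unclass(gradcam_map(w, a)))
  # zero wherever the weighted sum is negative
  m <- 0
  for (k in 1:3) m <- m + w[k] * a[, , k]
  expect_equal(unclass(gradcam_map(w, a))[m < 0],
               rep(0, sum(m < 0)))
  expect_error(gradcam_map(c(1, 2), a), "channels")
})

test_that("heatmaps match a brute-force loop over positions and channels", {
  set.seed(23)
  for (i in 1:40) {
    h <- sample(1:16, 1); w <- sample(1:16, 1); k <- sample(1:6, 1)
    a <- array(rnorm(h * w * k), c(h, w, k))
    wt <- rnorm(k)
    manual <- matrix(0, h, w)
    for (ii in seq_len(h)) for (jj in seq_len(w)) {
      s <- 0
      for (ch in seq_len(k)) s <- s + wt[ch] * a[ii, jj, ch]
      manual[ii, jj] <- max(s, 0)
    }
    expect_equal(unclass(gradcam_map(wt, a)), manual, ignore_attr = TRUE)
  }
})

test_that("overlay respects opacity, size, and degenerate heatmaps", {
  img <- matrix(runif(24 * 20), 24, 20)
  hm <- gradcam_map(1, array(runif(6 * 5), c(6, 5, 1)))
  out <- overlay(hm, img, opacity = 0.4)
  expect_equal(dim(out), c(24, 20, 3))
  # opacity 0: original image unchanged in every channel
  out0 <- overlay(hm, img, opacity = 0)
  for (ch in 1:3) expect_equal(out0[, , ch], img)
  expect_warning(outz <- overlay(matrix(0, 6, 5), img), "all-zero")
  for (ch in 1:3) expect_equal(outz[, , ch], img)
  # resize preserves the argmax location up to cell rounding
  hm2 <- matrix(0, 8, 8); hm2[6, 3] <- 1
  big <- resize_bilinear(hm2, 64, 64)
  peak <- which(big == max(big), arr.ind = TRUE)[1, ]
  expect_lt(abs(peak[["row"]] - 44), 8)
  expect_lt(abs(peak[["col"]] - 20), 8)
})

test_that("detector Grad-CAM concentrates on the fracture box", {
  ds <- tiny_dataset()
  det <- train_toy(ds, detector_config(mode = "adaptive"), epochs = 6,
                   seed = 5)
  a <- ds$annotations[1, ]
  gt <- as.numeric(a[c("x_min", "y_min", "x_max", "y_max")]) *
        (128 / 96)   # dataset is 96px, detector input 128px
  gc <- detector_gradcam(det, ds$images[[1]], box = gt, class = a$label)
  expect_true(all(gc$heatmap >= 0))
  expect_equal(dim(gc$heatmap), c(32, 32))
  expect_equal(gc$context$Z, 32 * 32)
  hc <- heatmap_concentration(gc$heatmap, gt, c(128, 128))
  expect_gt(hc$ratio, 1)
})

test_that("the identity-control randomization arm shows no collapse", {
  ds <- tiny_dataset()
  # 12 images leave rare classes with degenerate split allocations; expected
  rc <- suppressWarnings(
    randomization_check(ds, detector_config(mode = "adaptive"),
                        epochs = 6, seed = 3, permute = FALSE))
  # control arm trains on the same data twice: identical APs by construction
  expect_equal(rc$ap_intact, rc$ap_corrupted)
  expect_error(
    randomization_check(list(images = list(1, 2),
                             index = data.frame(class_label = c("I", "I"))),
                        epochs = 1),
    "2 classes")
})
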