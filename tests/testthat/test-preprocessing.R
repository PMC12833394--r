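test_that("brightness normalization rescales to the unit range times K", {
  expect_equal(as.numeric(brightness_normalize(matrix(c(0, 128, 255), 1))),
               c(0, 128 / 255, 1))
  expect_equal(as.numeric(brightness_normalize(matrix(c(10, 20), 1), 0.5)),
               c(0, 0.5))
  img <- matrix(runif(400, 3, 9), 20, 20)
  out <- brightness_normalize(img)
  expect_equal(range(out), c(0, 1))
  # degenerate constant image maps to zeros, not an error
  expect_equal(brightness_normalize(matrix(7, 3, 3)), matrix(0, 3, 3))
  expect_error(normalization_params(-1), "positive")
})

test_that("normalization is invariant to affine rescaling of the input", {
  set.seed(5)
  for (i in 1:50) {
    img <- matrix(runif(100, -4, 12), 10, 10)
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    expect_equal(brightness_normalize(a * img + b),
                 brightness_normalize(img))
  }
})

test_that("geometric augmentation moves boxes with the pixels", {
  img <- matrix(runif(100 * 100), 100, 100)
  box <- matrix(c(10, 20, 30, 40), 1)
  flip_only <- augmentation_policy(rotation_range = c(0, 0),
                                   crop_fraction = 1, flip_prob = 1,
                                   scale_range = c(1, 1), jitter = 0)
  out <- augment(img, box, flip_only, seed = 3)
  expect_equal(unname(out$boxes[1, ]), c(70, 20, 90, 40))
  expect_equal(out$image, img[, 100:1])
  # identity policy is a no-op
  idp <- augmentation_policy(rotation_range = c(0, 0), crop_fraction = 1,
                             flip_prob = 0, scale_range = c(1, 1), jitter = 0)
  out <- augment(img, box, idp, seed = 3)
  expect_identical(out$image, img)
  expect_equal(unname(out$boxes[1, ]), c(10, 20, 30, 40))
  # fixed seed, identical output
  a <- augment(img, box, seed = 11)
  b <- augment(img, box, seed = 11)
  expect_identical(a$image, b$image)
  expect_identical(a$boxes, b$boxes)
  expect_false(identical(a$image, augment(img, box, seed = 12)$image))
})

test_that("augmentation preserves box validity and drops lost boxes", {
  set.seed(21)
  img <- matrix(runif(80 * 80), 80, 80)
  for (i in 1:40) {
    x <- runif(1, 0, 60); y <- runif(1, 0, 60)
    boxes <- rbind(c(x, y, x + runif(1, 2, 18), y + runif(1, 2, 18)),
                   c(1, 1, 6, 6))   # corner box often lost to the crop
    out <- augment(img, boxes, seed = i)
    if (nrow(out$boxes)) {
      expect_true(all(out$boxes[, 3] > out$boxes[, 1]))
      expect_true(all(out$boxes[, 4] > out$boxes[, 2]))
      expect_true(all(out$boxes[, c(1, 3)] <= ncol(out$image)))
      expect_true(all(out$boxes >= 0))
    }
    expect_true(all(out$kept %in% 1:2))
  }
})

test_that("stratified split uses largest-remainder allocation per class", {
  s <- stratified_split(rep("x", 1004), seed = 2)
  expect_equal(lengths(s), c(train = 602L, validation = 201L, test = 201L))
  s <- stratified_split(rep("x", 10), seed = 2)
  expect_equal(lengths(s), c(train = 6L, validation = 2L, test = 2L))
  # partition property over mixed classes
  labels <- rep(c("a", "b", "c"), c(17, 23, 40))
  s <- stratified_split(labels, seed = 9)
  all_idx <- sort(unname(unlist(s)))
  expect_equal(all_idx, seq_along(labels))
  # determinism
  expect_identical(stratified_split(labels, seed = 4),
                   stratified_split(labels, seed = 4))
  expect_warning(stratified_split(c("a", "a"), seed = 1), "degenerate")
})

test_that("stratified k-fold keeps per-class fold sizes within one", {
  labels <- rep(c("I", "II", "III", "IV"), c(314, 602, 891, 602))
  folds <- stratified_kfold(labels, k = 10, seed = 3)
  expect_equal(sort(unlist(folds)), seq_along(labels))
  for (cl in unique(labels)) {
    sizes <- vapply(folds, function(f) sum(labels[f] == cl), integer(1))
    expect_lte(max(sizes) - min(sizes), 1L)
    expect_true(all(sizes > 0))  # every fold sees every class
  }
  expect_error(stratified_kfold(labels, k = 1), "at least 2")
  # 100 items of one class, k = 10: ten folds of 10
  f <- stratified_kfold(rep("z", 100), k = 10, seed = 1)
  expect_equal(lengths(f), rep(10L, 10))
})

test_that("class weights reproduce the published table and the inverse-mean rule", {
  cw <- class_weights()
  expect_equal(cw$weight, c(1.76, 0.92, 0.62, 0.92))
  expect_equal(cw$support, c(314, 602, 891, 602))
  expect_error(class_weights(c(10, 20, 30, 40)), "inverse_mean")
  im <- class_weights(c(100, 100), "inverse_mean")
  expect_equal(im$weight, c(1, 1))
  im <- class_weights(c(100, 300), "inverse_mean")
  expect_equal(im$weight, c(2, 2 / 3))
  # weight * support is constant under inverse_mean
  set.seed(8)
  for (i in 1:20) {
    sup <- sample(50:900, sample(2:6, 1))
    w <- class_weights(sup, "inverse_mean")$weight
    expect_equal(w * sup, rep(mean(sup), length(sup)))
    expect_equal(sum(w * sup), length(sup) * mean(sup))
  }
  expect_error(class_weights(c(0, 5), "inverse_mean"), "positive")
})
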