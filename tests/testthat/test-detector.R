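test_that("the learning-rate schedule steps down by 0.1 every 10", {
  expect_equal(lr_at(0), 0.001)
  expect_equal(lr_at(9), 0.001)
  expect_equal(lr_at(10), 1e-4)
  expect_equal(lr_at(25), 1e-5)
  ts <- 0:40
  lrs <- lr_at(ts)
  expect_true(all(diff(lrs) <= 0))
  expect_equal(length(unique(lrs[1:10])), 1L)  # piecewise constant
  expect_error(lr_at(-1), "non-negative")
  s <- optimizer_schedule(base_lr = 0.01, decay_period = 5)
  expect_equal(lr_at(5, s), 0.001)
})

test_that("the multi-task loss matches closed forms", {
  # perfect predictions: one-hot correct classes, zero box residuals
  p <- diag(5)[1:3, ]
  t0 <- list(class = 1:3, boxes = matrix(0, 3, 4))
  l <- multitask_loss(p, matrix(0, 3, 4), t0)
  expect_equal(l$total, 0)
  # uniform scores over 5 classes: classification term ln(5) per sample
  pu <- matrix(0.2, 4, 5)
  l <- multitask_loss(pu, matrix(0, 4, 4),
                      list(class = c(1, 2, 3, 5), boxes = matrix(0, 4, 4)))
  expect_equal(l$classification, log(5))
  # doubling the class weights doubles the classification term
  w1 <- c(1, 2, 1, 1, 1)
  l1 <- multitask_loss(pu, matrix(0, 4, 4),
                       list(class = c(1, 2, 3, 5), boxes = matrix(0, 4, 4)),
                       weights = w1)
  l2 <- multitask_loss(pu, matrix(0, 4, 4),
                       list(class = c(1, 2, 3, 5), boxes = matrix(0, 4, 4)),
                       weights = 2 * w1)
  expect_equal(l2$classification, 2 * l1$classification)
  # smooth-L1 box term: residual 0.5 -> 0.125 per coordinate; no positives -> 0
  reg <- matrix(0.5, 2, 4)
  l <- multitask_loss(diag(5)[1:2, ], reg,
                      list(class = 1:2, boxes = matrix(0, 2, 4)))
  expect_equal(l$box_regression, 4 * 0.125)
  l <- multitask_loss(diag(5)[1:2, ], reg,
                      list(class = 1:2, boxes = matrix(0, 2, 4),
                           positive = c(FALSE, FALSE)))
  expect_equal(l$box_regression, 0)
  # permutation invariance over samples
  set.seed(3)
  ps <- matrix(runif(20), 4, 5); ps <- ps / rowSums(ps)
  bx <- matrix(rnorm(16), 4, 4)
  tg <- list(class = c(2, 5, 1, 3), boxes = matrix(rnorm(16), 4, 4))
  perm <- c(3, 1, 4, 2)
  l1 <- multitask_loss(ps, bx, tg)
  l2 <- multitask_loss(ps[perm, ], bx[perm, ],
                       list(class = tg$class[perm], boxes = tg$boxes[perm, ]))
  expect_equal(l1$total, l2$total)
})

test_that("the adaptive RPN position set comes from the anchoring module", {
  cfg_a <- detector_config(mode = "adaptive")
  cfg_s <- detector_config(mode = "standard")
  ma <- fracdet:::new_detector(cfg_a, seed = 1)
  ms <- fracdet:::new_detector(cfg_s, seed = 1)
  expect_equal(ms$n_positions_standard, 32 * 32)
  expect_equal(nrow(ms$positions), 1024)
  # table-consistent rule at 32 columns: round-half-up(0.33*32) = 11 kept
  expect_equal(nrow(ma$positions), 32 * 11)
  frac <- nrow(ma$positions) / nrow(ms$positions)
  expect_gt(frac, 0.30); expect_lt(frac, 0.37)
  # every kept anchor centre lies inside the kept region
  rect_cols <- range(ma$positions$col)
  expect_true(all(ma$positions$col >= rect_cols[1] &
                  ma$positions$col <= rect_cols[2]))
  expect_equal(diff(rect_cols) + 1L, 11L)
})

test_that("a short training run reduces the loss reproducibly", {
  ds <- tiny_dataset()
  det1 <- train_toy(ds, detector_config(mode = "adaptive"), epochs = 4,
                    seed = 5)
  expect_length(det1$loss_trace, 4)
  expect_true(all(is.finite(det1$loss_trace)))
  expect_lt(det1$loss_trace[4], det1$loss_trace[1])
  det2 <- train_toy(ds, detector_config(mode = "adaptive"), epochs = 4,
                    seed = 5)
  expect_identical(det1$loss_trace, det2$loss_trace)
  expect_error(train_toy(list(images = list()), detector_config()), "empty")
})

test_that("prediction thresholds scores and suppresses duplicates", {
  ds <- tiny_dataset()
  det <- train_toy(ds, detector_config(mode = "adaptive"), epochs = 4,
                   seed = 5)
  # untrained zero-ish head on an all-background image: nothing at 0.5
  blank <- matrix(runif(96 * 96, 0, 0.05), 96, 96)
  d0 <- predict(det, blank, score_threshold = 0.999)
  expect_equal(nrow(d0), 0)
  d <- predict(det, ds$images[[1]], score_threshold = 0.01)
  if (nrow(d) > 1) {
    # NMS contract: no two survivors overlap above the threshold
    for (i in 1:(nrow(d) - 1)) for (j in (i + 1):nrow(d)) {
      expect_lte(iou(as.numeric(d[i, 1:4]), as.numeric(d[j, 1:4])), 0.5)
    }
  }
  expect_true(all(d$score >= 0 & d$score <= 1))
  # determinism
  expect_identical(predict(det, ds$images[[1]]), predict(det, ds$images[[1]]))
})

test_that("NMS keeps one of a set of identical boxes", {
  b <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10), c(0, 0, 10, 10),
             c(50, 50, 60, 60))
  keep <- nms(b, c(0.9, 0.8, 0.7, 0.6), 0.5)
  expect_equal(keep, c(1, 4))
})
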