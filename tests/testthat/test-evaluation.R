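test_that("IoU handles overlap, disjointness and degenerate boxes", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
  expect_equal(iou(c(0, 0, 0, 0), c(0, 0, 2, 2)), 0)
  # vectorized over a matrix of boxes
  m <- rbind(c(0, 0, 2, 2), c(1, 0, 3, 2))
  expect_equal(iou(c(0, 0, 2, 2), m), c(1, 1 / 3))
})

test_that("greedy matching enforces one truth per detection and class identity", {
  tr <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                   label = 1, image_id = 1)
  d1 <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                   label = 1, score = 0.9, image_id = 1)
  m <- match_detections(d1, tr)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  # second detection on the same truth is a false positive
  d2 <- rbind(d1, transform(d1, score = 0.8))
  m <- match_detections(d2, tr)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 1, 0))
  # class mismatch at perfect overlap: FP and FN
  d3 <- transform(d1, label = 2)
  m <- match_detections(d3, tr)
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 1, 1))
  # TP + FN always equals the truth count
  expect_equal(m$tp + m$fn, nrow(tr))
})

test_that("precision/recall/F1 handle zero denominators and known values", {
  expect_equal(unlist(precision_recall_f1(list(tp = 1, fp = 0, fn = 0))[1:3]),
               c(precision = 1, recall = 1, f1 = 1))
  expect_equal(unlist(precision_recall_f1(list(tp = 0, fp = 0, fn = 0))[1:3]),
               c(precision = 0, recall = 0, f1 = 0))
  r <- precision_recall_f1(list(tp = 3, fp = 1, fn = 2))
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.6)
  expect_equal(r$f1, 2 * 0.75 * 0.6 / 1.35)
  # published operating point: F1 from precision and recall
  expect_equal(round(f1_score(0.9680, 0.9523), 4), 0.9601)
})

test_that("average precision matches the exhaustive threshold-sweep oracle", {
  # the spec's worked micro-example: scores .9 TP, .8 FP, .7 TP over 2 truths
  tr <- data.frame(x_min = c(0, 20), y_min = 0, x_max = c(10, 30),
                   y_max = 10, label = 1, image_id = 1)
  de <- data.frame(x_min = c(0, 40, 20), y_min = 0,
                   x_max = c(10, 50, 30), y_max = 10,
                   label = 1, score = c(0.9, 0.8, 0.7), image_id = 1)
  got <- average_precision(de, tr)$ap
  expect_equal(got, brute_force_ap(de, tr))
  expect_equal(got, 0.5 * 1 + 0.5 * (2 / 3))
  # randomized instances
  set.seed(77)
  for (i in 1:120) {
    inst <- random_detection_instance(sample(0:10, 1), sample(1:5, 1))
    expect_equal(average_precision(inst$dets, inst$truths)$ap,
                 brute_force_ap(inst$dets, inst$truths),
                 label = sprintf("instance %d", i))
  }
})

test_that("AP edge cases and score-monotonicity invariance", {
  tr <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                   label = 1, image_id = 1)
  perfect <- transform(tr, score = 0.9)
  expect_equal(average_precision(perfect, tr)$ap, 1)
  none <- perfect[0, ]
  expect_equal(average_precision(none, tr)$ap, 0)
  expect_warning(ap0 <- average_precision(perfect, tr[0, ]), "no ground-truth")
  expect_equal(ap0$ap, 0)
  # strictly monotone score transforms leave AP unchanged
  set.seed(41)
  inst <- random_detection_instance(8, 3)
  base <- average_precision(inst$dets, inst$truths)$ap
  d2 <- inst$dets; d2$score <- exp(3 * d2$score) + 1
  expect_equal(average_precision(d2, inst$truths)$ap, base)
  # recall along the curve is non-decreasing
  cur <- average_precision(inst$dets, inst$truths)$curve
  expect_true(all(diff(cur$recall) >= 0))
  expect_true(all(cur$precision >= 0 & cur$precision <= 1))
})

test_that("per-class AP averages into mAP alongside the pooled value", {
  set.seed(13)
  inst <- random_detection_instance(10, 6, n_classes = 3)
  r <- average_precision(inst$dets, inst$truths, per_class = TRUE)
  expect_equal(r$ap, mean(r$per_class))
  expect_true(all(r$per_class >= 0 & r$per_class <= 1))
})

test_that("bootstrap intervals behave at the edges and reproduce", {
  items <- as.list(rep(0.5, 10))
  stat <- function(xs) mean(unlist(xs))
  ci <- bootstrap_ci(items, stat, n_boot = 200, seed = 5)
  expect_equal(unname(ci[c("lower", "upper")]), c(0.5, 0.5))
  set.seed(2)
  items <- as.list(runif(30))
  ci <- bootstrap_ci(items, stat, n_boot = 500, seed = 9)
  expect_lte(ci[["lower"]], stat(items))
  expect_gte(ci[["upper"]], stat(items))
  expect_identical(bootstrap_ci(items, stat, n_boot = 500, seed = 9), ci)
  # doubling n_boot stays within Monte-Carlo tolerance
  ci2 <- bootstrap_ci(items, stat, n_boot = 1000, seed = 9)
  expect_lt(abs(ci2[["lower"]] - ci[["lower"]]), 0.06)
  expect_lt(abs(ci2[["upper"]] - ci[["upper"]]), 0.06)
  expect_warning(bootstrap_ci(items, stat, n_boot = 50, seed = 1),
                 "unstable")
  expect_error(bootstrap_ci(items[1], stat), "at least 2")
})

test_that("site stratification is additive and warns on degenerate labels", {
  tr <- data.frame(x_min = rep(0, 4), y_min = 0, x_max = 10, y_max = 10,
                   label = 1, image_id = 1:4)
  de <- transform(tr, score = 0.9)
  idx <- data.frame(image_id = 1:4, site_label = c("A", "A", "B", "B"))
  out <- stratify_by_site(idx, de, tr)
  expect_named(out, c("A", "B"))
  expect_equal(out$A$tp + out$B$tp, 4)
  expect_equal(out$A$f1, out$B$f1)  # identical data per site
  expect_warning(stratify_by_site(data.frame(image_id = 1:4), de, tr),
                 "no site labels")
})

test_that("demographic shares recompute the published cohort percentages", {
  tab <- demographics_fixture()
  expect_equal(sum(tab$gender), 1410)
  expect_equal(sum(tab$location), 1410)
  expect_equal(sum(tab$mechanism), 1410)
  expect_equal(sum(tab$gender["male", ]), 888)
  expect_equal(sum(tab$location["leg", ]), 510)
  expect_equal(sum(tab$mechanism["rti", ]), 687)
  rep <- demographics_report(tab)
  expect_equal(rep$male_share, 63)
  expect_equal(rep$location_shares[["leg"]], 36.2)
  expect_equal(rep$mechanism_shares[["rti"]], 48.7)
  # borderline rounding: 267/510 = 52.35...; the printed value is 52.3
  expect_lt(abs(rep$location_age_25_44[["leg"]] - 52.3), 0.11)
  # corrupting a margin trips validation with the table named
  bad <- tab; bad$location["leg", 1] <- bad$location["leg", 1] + 5
  expect_error(demographics_report(bad), "location")
})
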