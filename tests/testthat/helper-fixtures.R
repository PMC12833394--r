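# Shared fixtures built in code at test time.

# brute-force oracle for eq_region position counts: scan every cell centre
brute_force_positions <- function(level, rect) {
  n <- 0L
  for (i in seq_len(level$rows)) for (j in seq_len(level$cols)) {
    cx <- (j - 0.5) * level$stride
    cy <- (i - 0.5) * level$stride
    if (cx >= rect[["x_min"]] && cx < rect[["x_max"]] &&
        cy >= rect[["y_min"]] && cy < rect[["y_max"]]) n <- n + 1L
  }
  n
}

# exhaustive threshold-sweep AP oracle: sweep every cut point of the
# deterministically ranked list (descending score, ties by index), compute
# the (recall, precision) point FROM SCRATCH at each cut by re-matching the
# retained detections, and integrate the precision envelope over recall
brute_force_ap <- function(dets, truths, iou_threshold = 0.5) {
  if (nrow(truths) == 0) return(0)
  if (nrow(dets) == 0) return(0)
  ord <- order(-dets$score, seq_len(nrow(dets)))
  dets <- dets[ord, , drop = FALSE]
  pts <- t(vapply(seq_len(nrow(dets)), function(k) {
    m <- match_detections(dets[seq_len(k), , drop = FALSE], truths,
                          iou_threshold)
    c(recall = m$tp / m$n_truth,
      precision = if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else 0)
  }, numeric(2)))
  env <- rev(cummax(rev(pts[, "precision"])))
  r_prev <- c(0, pts[-nrow(pts), "recall"])
  sum((pts[, "recall"] - r_prev) * env)
}

# random detection problem on one image: boxes on a grid so IoUs vary
random_detection_instance <- function(n_det, n_truth, n_classes = 2) {
  mk_box <- function(n) {
    x <- runif(n, 0, 80); y <- runif(n, 0, 80)
    w <- runif(n, 5, 25); h <- runif(n, 5, 25)
    data.frame(x_min = x, y_min = y, x_max = x + w, y_max = y + h)
  }
  truths <- mk_box(n_truth)
  truths$label <- sample.int(n_classes, n_truth, replace = TRUE)
  truths$image_id <- rep(1L, n_truth)
  # half the detections perturb a truth, half are random
  dets <- mk_box(n_det)
  if (n_truth > 0 && n_det > 0) {
    for (i in seq_len(n_det)) {
      if (runif(1) < 0.5) {
        j <- sample.int(n_truth, 1)
        jit <- runif(4, -6, 6)
        dets[i, 1:4] <- truths[j, 1:4] + jit
        if (dets$x_max[i] <= dets$x_min[i]) dets$x_max[i] <- dets$x_min[i] + 1
        if (dets$y_max[i] <= dets$y_min[i]) dets$y_max[i] <- dets$y_min[i] + 1
      }
    }
  }
  dets$label <- sample.int(n_classes, n_det, replace = TRUE)
  dets$score <- round(runif(n_det), 3)   # ties occur; broken by index
  dets$image_id <- rep(1L, n_det)
  list(dets = dets, truths = truths)
}

# small cached synthetic dataset shared across detector-side tests
tiny_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- make_dataset(n = 12, seed = 301,
                                         image_size = c(96, 96))
    ds
  }
})
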