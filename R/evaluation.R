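#' Intersection over union of two boxes
#'
#' @param a,b Numeric `(x_min, y_min, x_max, y_max)`; `b` may be a matrix of
#'   boxes (one per row), in which case a vector is returned.
#' @return IoU value(s) in \[0, 1\]; degenerate zero-area boxes give 0.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 0, 3, 2))  # 1/3
#' @export
iou <- function(a, b) {
  if (is.matrix(b)) return(apply(b, 1, function(bb) iou(a, bb)))
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  area_a <- max(0, a[3] - a[1]) * max(0, a[4] - a[2])
  area_b <- max(0, b[3] - b[1]) * max(0, b[4] - b[2])
  un <- area_a + area_b - inter
  if (un <= 0) 0 else inter / un
}

as_det_df <- function(x) {
  x <- as.data.frame(x)
  need <- c("x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(x)))
    stop("boxes need columns x_min, y_min, x_max, y_max", call. = FALSE)
  if (is.null(x$image_id)) x$image_id <- 1L
  if (is.null(x$label)) x$label <- 1L
  x
}

#' Match detections to ground truth at an IoU threshold
#'
#' Greedy class-aware matching in descending score order (ties broken by
#' detection index): each detection claims its highest-IoU unmatched truth of
#' the same class in the same image, and is a true positive if that IoU
#' reaches the threshold, otherwise a false positive. Truths left unmatched
#' are false negatives, so TP + FN equals the ground-truth count.
#'
#' @param dets Data frame of detections: box columns, `score`, and optional
#'   `label`, `image_id`.
#' @param truths Data frame of ground-truth boxes with optional `label`,
#'   `image_id`.
#' @param iou_threshold Matching threshold, default 0.5.
#' @return A `match_result`: list with `tp`, `fp`, `fn`, `iou_threshold`,
#'   and `detections` (the detections ordered by rank with columns `is_tp`
#'   and `matched_truth`).
#' @export
match_detections <- function(dets, truths, iou_threshold = 0.5) {
  dets <- as_det_df(dets); truths <- as_det_df(truths)
  if (is.null(dets$score)) dets$score <- 1
  ord <- order(-dets$score, seq_len(nrow(dets)))
  dets <- dets[ord, , drop = FALSE]
  truth_used <- rep(FALSE, nrow(truths))
  is_tp <- logical(nrow(dets))
  matched <- rep(NA_integer_, nrow(dets))
  for (i in seq_len(nrow(dets))) {
    cand <- which(!truth_used &
                  truths$image_id == dets$image_id[i] &
                  truths$label == dets$label[i])
    if (!length(cand)) next
    d <- as.numeric(dets[i, c("x_min", "y_min", "x_max", "y_max")])
    ious <- vapply(cand, function(j)
      iou(d, as.numeric(truths[j, c("x_min", "y_min", "x_max", "y_max")])),
      numeric(1))
    j <- cand[which.max(ious)]
    if (max(ious) >= iou_threshold) {
      is_tp[i] <- TRUE
      truth_used[j] <- TRUE
      matched[i] <- j
    }
  }
  dets$is_tp <- is_tp
  dets$matched_truth <- matched
  structure(list(tp = sum(is_tp), fp = sum(!is_tp),
                 fn = nrow(truths) - sum(is_tp),
                 n_truth = nrow(truths),
                 iou_threshold = iou_threshold, detections = dets),
            class = "match_result")
}

#' Precision, recall and F1 from a match result
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, F1 their harmonic mean;
#' any zero denominator yields 0.
#'
#' @param match A `match_result` from [match_detections()], or a list/vector
#'   with elements `tp`, `fp`, `fn`.
#' @return A `metric_report` list: `precision`, `recall`, `f1`, plus the
#'   counts and IoU threshold when available.
#' @examples
#' precision_recall_f1(list(tp = 1, fp = 0, fn = 0))
#' @export
precision_recall_f1 <- function(match) {
  tp <- match$tp %||% match[["tp"]]
  fp <- match$fp; fn <- match$fn
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(precision = p, recall = r, f1 = f1,
                 tp = tp, fp = fp, fn = fn,
                 iou_threshold = match$iou_threshold %||% NA_real_),
            class = "metric_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Harmonic-mean F1 from precision and recall
#'
#' @param precision,recall Values in \[0, 1\].
#' @return F1 score; 0 when both inputs are 0.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Average precision and the precision-recall curve
#'
#' Sweeps the detection-score threshold over the ranked detections
#' (descending score, ties by index), accumulating TP/FP flags from greedy
#' IoU matching, and integrates the precision-recall curve. Interpolation is
#' all-point by default (the precision envelope, area under the stepwise
#' curve); the 11-point alternative averages the envelope at recalls
#' 0, 0.1, ..., 1.
#'
#' @param dets,truths As in [match_detections()].
#' @param iou_threshold Matching threshold.
#' @param interpolation `"all_point"` or `"eleven_point"`.
#' @param per_class If `TRUE`, compute AP separately per ground-truth class
#'   and return the mean (mAP) along with the per-class values.
#' @return An `ap_result` list: `ap`, `curve` (data frame with `recall`,
#'   `precision`, `score`), `iou_threshold`; for `per_class = TRUE` also
#'   `per_class` (named vector).
#' @export
average_precision <- function(dets, truths, iou_threshold = 0.5,
                              interpolation = c("all_point", "eleven_point"),
                              per_class = FALSE) {
  interpolation <- match.arg(interpolation)
  dets <- as_det_df(dets); truths <- as_det_df(truths)
  if (nrow(truths) == 0) {
    warning("no ground-truth boxes; AP undefined, returning 0")
    return(structure(list(ap = 0,
                          curve = data.frame(recall = numeric(0),
                                             precision = numeric(0),
                                             score = numeric(0)),
                          iou_threshold = iou_threshold), class = "ap_result"))
  }
  if (per_class) {
    cls <- sort(unique(truths$label))
    aps <- vapply(cls, function(cl) {
      average_precision(dets[dets$label == cl, , drop = FALSE],
                        truths[truths$label == cl, , drop = FALSE],
                        iou_threshold, interpolation)$ap
    }, numeric(1))
    names(aps) <- as.character(cls)
    pooled <- average_precision(dets, truths, iou_threshold, interpolation)
    pooled$per_class <- aps
    pooled$ap <- mean(aps)
    pooled$pooled_ap <- average_precision(dets, truths, iou_threshold,
                                          interpolation)$ap
    return(pooled)
  }
  m <- match_detections(dets, truths, iou_threshold)
  d <- m$detections
  if (nrow(d) == 0)
    return(structure(list(ap = 0,
                          curve = data.frame(recall = numeric(0),
                                             precision = numeric(0),
                                             score = numeric(0)),
                          iou_threshold = iou_threshold), class = "ap_result"))
  tp_cum <- cumsum(d$is_tp)
  fp_cum <- cumsum(!d$is_tp)
  rec <- tp_cum / m$n_truth
  prec <- tp_cum / (tp_cum + fp_cum)
  curve <- data.frame(recall = rec, precision = prec, score = d$score)
  # precision envelope: for each point, the max precision at >= that recall
  env <- rev(cummax(rev(prec)))
  if (interpolation == "all_point") {
    r_prev <- c(0, head(rec, -1))
    ap <- sum((rec - r_prev) * env)
  } else {
    grid <- seq(0, 1, by = 0.1)
    pk <- vapply(grid, function(g) {
      sel <- rec >= g - 1e-12
      if (any(sel)) max(prec[sel]) else 0
    }, numeric(1))
    ap <- mean(pk)
  }
  structure(list(ap = ap, curve = curve, iou_threshold = iou_threshold),
            class = "ap_result")
}

#' Percentile bootstrap confidence interval over images
#'
#' Resamples whole images with replacement and recomputes the statistic,
#' returning the percentile interval. The resampling unit is the image, so
#' per-image correlation between detections is respected.
#'
#' @param items A list of per-image inputs (any structure the statistic
#'   understands).
#' @param statistic Function taking a list of items and returning a scalar.
#' @param n_boot Number of bootstrap resamples (default 2000; fewer than 100
#'   triggers a warning).
#' @param level Confidence level, default 0.95.
#' @param seed Integer seed.
#' @return Named numeric `(lower, upper, point)`.
#' @export
bootstrap_ci <- function(items, statistic, n_boot = 2000, level = 0.95,
                         seed = 1L) {
  n <- length(items)
  if (n < 2) stop("bootstrap needs at least 2 images", call. = FALSE)
  if (n_boot < 100) warning("n_boot < 100 gives unstable intervals")
  point <- statistic(items)
  stats <- numeric(n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      stats[b] <- statistic(items[sample.int(n, n, replace = TRUE)])
    }
  })
  a <- (1 - level) / 2
  q <- stats::quantile(stats, c(a, 1 - a), names = FALSE, na.rm = TRUE)
  c(lower = q[1], upper = q[2], point = point)
}

#' Site-stratified metric reports
#'
#' Computes a metric pipeline independently for each acquisition-site label,
#' so deployment variation across hospitals can be assessed. Images with a
#' missing site fall into one pooled stratum with a warning; declared sites
#' with zero images are omitted with a warning.
#'
#' @param index Data frame with columns `image_id` and `site_label`.
#' @param dets,truths Detection / truth data frames carrying `image_id`.
#' @param iou_threshold Matching threshold.
#' @return Named list of `metric_report` objects, one per site, each with an
#'   `ap` element appended.
#' @export
stratify_by_site <- function(index, dets, truths, iou_threshold = 0.5) {
  if (is.null(index$site_label) || all(is.na(index$site_label))) {
    warning("no site labels; computing one pooled stratum")
    index$site_label <- "pooled"
  }
  dets <- as_det_df(dets); truths <- as_det_df(truths)
  out <- list()
  for (s in unique(index$site_label)) {
    ids <- index$image_id[index$site_label == s]
    if (!length(ids)) { warning(sprintf("site '%s' has no images", s)); next }
    ds <- dets[dets$image_id %in% ids, , drop = FALSE]
    ts <- truths[truths$image_id %in% ids, , drop = FALSE]
    rep <- precision_recall_f1(match_detections(ds, ts, iou_threshold))
    rep$ap <- if (nrow(ts)) average_precision(ds, ts, iou_threshold)$ap else NA_real_
    out[[as.character(s)]] <- rep
  }
  out
}

#' Derived shares from the demographic tables
#'
#' Recomputes the headline cohort percentages from the count tables: male
#' share of all patients, per-location and per-mechanism shares, and the
#' within-location age concentration for the 25-44 band. All values are
#' `count ratio * 100`.
#'
#' @param table A `demographic_table` from [demographics_fixture()].
#' @param digits Decimal places for the reported shares (round half up),
#'   default 1.
#' @return List with `male_share`, `location_shares`, `mechanism_shares`,
#'   `location_age_25_44` (share of each location's fractures in the
#'   25-34/34-44 bands) and `grand_total`.
#' @export
demographics_report <- function(table, digits = 1) {
  stopifnot(inherits(table, "demographic_table"))
  validate_demographics(table)
  g <- table$grand_total
  pct <- function(x, n) round_half_up(x / n * 100, digits)
  loc <- rowSums(table$location)
  mech <- rowSums(table$mechanism)
  band_25_44 <- c("25-34", "34-44")
  conc <- apply(table$location[, band_25_44, drop = FALSE], 1, sum) / loc * 100
  list(male_share = pct(sum(table$gender["male", ]), g),
       location_shares = pct(loc, g),
       mechanism_shares = pct(mech, g),
       location_age_25_44 = round_half_up(conc, digits),
       grand_total = g)
}

validate_demographics <- function(table) {
  g <- table$grand_total
  for (nm in c("gender", "location", "mechanism")) {
    s <- sum(table[[nm]])
    if (s != g)
      stop(sprintf("margin inconsistency: %s table sums to %d, expected %d",
                   nm, s, g), call. = FALSE)
  }
  ages <- colSums(table$gender)
  for (nm in c("location", "mechanism")) {
    if (any(colSums(table[[nm]]) != ages))
      stop(sprintf("margin inconsistency: %s age-band totals disagree with the gender table",
                   nm), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
plot.ap_result <- function(x, ...) {
  graphics::plot(c(0, x$curve$recall), c(1, x$curve$precision), type = "s",
                 xlim = c(0, 1), ylim = c(0, 1), xlab = "Recall",
                 ylab = "Precision",
                 main = sprintf("PR curve (AP = %.3f @ IoU %.2f)",
                                x$ap, x$iou_threshold), ...)
  invisible(x)
}

#' Write a PR curve to a PNG file
#'
#' @param x An `ap_result` from [average_precision()].
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
export_pr_curve <- function(x, path, width = 600, height = 600) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot(x)
  invisible(path)
}
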