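#' Detector configuration
#'
#' Configuration of the two-stage detector scaffold: a convolutional backbone
#' feeding a region proposal network (RPN) whose anchor-position set is
#' produced by the anchoring module, followed by a classification head over
#' pooled features. The runnable backbone is `"toy-cnn"`, a shallow two-layer
#' convolutional pyramid (total feature stride 4) sized for desk-scale
#' experiments on synthetic phantoms; the ResNet/ResNeXt identifiers used at
#' clinical scale are accepted as configuration values but have no trainable
#' implementation here.
#'
#' @param input_size Image size `c(height, width)`; inputs are resized to
#'   this.
#' @param backbone Backbone identifier; `"toy-cnn"` (runnable), or one of
#'   `"resnet-50"`, `"resnet-101"`, `"resnext-50"`, `"resnext-101"`
#'   (declarative only).
#' @param channels Feature channels of the two toy conv layers.
#' @param mode Anchoring mode, `"adaptive"` (restricted position set from
#'   [generate_anchor_positions()]) or `"standard"` (full grid).
#' @param spec [adaptive_region_spec()] used when `mode = "adaptive"`.
#' @param n_classes Number of fracture classes (background is added
#'   internally).
#' @param weights A [class_weights()] table or `NULL` for uniform weights.
#' @param anchor_scale Anchor side length in pixels at the feature stride.
#' @param aspect_ratios Anchor aspect ratios per position.
#' @param score_threshold Objectness threshold for [predict()] detections.
#' @param nms_iou Non-maximum-suppression IoU threshold.
#' @return A `detector_config` object.
#' @export
detector_config <- function(input_size = c(128, 128),
                            backbone = "toy-cnn",
                            channels = c(8, 16),
                            mode = c("adaptive", "standard"),
                            spec = adaptive_region_spec(),
                            n_classes = 4,
                            weights = NULL,
                            anchor_scale = 24,
                            aspect_ratios = c(0.5, 1, 2),
                            score_threshold = 0.5,
                            nms_iou = 0.5) {
  mode <- match.arg(mode)
  backbone <- match.arg(backbone, c("toy-cnn", "resnet-50", "resnet-101",
                                    "resnext-50", "resnext-101"))
  structure(list(input_size = input_size, backbone = backbone,
                 channels = channels, mode = mode, spec = spec,
                 n_classes = n_classes, weights = weights,
                 anchor_scale = anchor_scale, aspect_ratios = aspect_ratios,
                 score_threshold = score_threshold, nms_iou = nms_iou),
            class = "detector_config")
}

#' Optimizer schedule
#'
#' SGD hyper-parameters with a step learning-rate schedule: the rate starts
#' at `base_lr` and is multiplied by `decay_factor` after every
#' `decay_period` schedule steps. The defaults are the full-scale training
#' settings (base rate 0.001, momentum 0.9, weight decay 0.0001, factor 0.1
#' every 10). Schedule steps are epochs here: a per-minibatch 0.1 decay
#' would extinguish the rate almost immediately.
#'
#' @param base_lr Initial learning rate.
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 weight-decay coefficient.
#' @param decay_factor Multiplicative decay applied each period.
#' @param decay_period Steps between decays.
#' @return An `optimizer_schedule` object.
#' @export
optimizer_schedule <- function(base_lr = 0.001, momentum = 0.9,
                               weight_decay = 0.0001, decay_factor = 0.1,
                               decay_period = 10) {
  stopifnot(base_lr > 0, decay_factor > 0, decay_period >= 1)
  structure(list(base_lr = base_lr, momentum = momentum,
                 weight_decay = weight_decay, decay_factor = decay_factor,
                 decay_period = decay_period), class = "optimizer_schedule")
}

#' Learning rate at a schedule step
#'
#' `lr(t) = base_lr * decay_factor^floor(t / decay_period)`; with the
#' defaults, 0.001 at t = 0, 0.0001 from t = 10, and so on. Non-increasing
#' and piecewise constant.
#'
#' @param t Schedule step (epoch), non-negative.
#' @param schedule An [optimizer_schedule()].
#' @return The learning rate.
#' @examples
#' lr_at(0)   # 0.001
#' lr_at(10)  # 1e-4
#' @export
lr_at <- function(t, schedule = optimizer_schedule()) {
  if (any(t < 0)) stop("schedule step must be non-negative", call. = FALSE)
  schedule$base_lr * schedule$decay_factor^floor(t / schedule$decay_period)
}

#' Multi-task detection loss
#'
#' Combined classification and box-regression loss: class-weighted
#' cross-entropy over predicted class probabilities, averaged over all
#' samples, plus smooth-L1 loss on box-regression residuals averaged over
#' the positive (object-matched) samples; the total is their sum. With no
#' positive samples the box term contributes 0.
#'
#' @param class_scores Matrix (n x C) of predicted class probabilities, rows
#'   summing to 1.
#' @param box_regressions Matrix (n x 4) of predicted box offsets.
#' @param targets List with `class` (integer class index per sample),
#'   `boxes` (n x 4 target offsets), and optional `positive` (logical mask
#'   of samples contributing to the box term; defaults to all).
#' @param weights Per-class weight vector or [class_weights()] table;
#'   `NULL` for uniform.
#' @return List with `total`, `classification`, `box_regression`.
#' @examples
#' p <- matrix(0.2, 2, 5)
#' multitask_loss(p, matrix(0, 2, 4),
#'                list(class = c(1, 2), boxes = matrix(0, 2, 4)))
#' @export
multitask_loss <- function(class_scores, box_regressions, targets,
                           weights = NULL) {
  class_scores <- as.matrix(class_scores)
  box_regressions <- as.matrix(box_regressions)
  n <- nrow(class_scores)
  stopifnot(length(targets$class) == n)
  w <- if (is.null(weights)) rep(1, ncol(class_scores))
       else if (inherits(weights, "class_weight_table")) weights$weight
       else weights
  if (length(w) < ncol(class_scores))
    w <- c(w, rep(1, ncol(class_scores) - length(w)))  # background weight 1
  p_true <- class_scores[cbind(seq_len(n), targets$class)]
  cls <- mean(w[targets$class] * -log(pmax(p_true, 1e-12)))
  pos <- targets$positive %||% rep(TRUE, n)
  box <- 0
  if (any(pos)) {
    res <- box_regressions[pos, , drop = FALSE] -
           targets$boxes[pos, , drop = FALSE]
    box <- mean(rowSums(smooth_l1(res)))
  }
  list(total = cls + box, classification = cls, box_regression = box)
}

# ---- internal model machinery -------------------------------------------

new_detector <- function(config, seed = 1L) {
  h <- config$input_size[1]; w <- config$input_size[2]
  C1 <- config$channels[1]; C2 <- config$channels[2]
  A <- length(config$aspect_ratios)
  nc <- config$n_classes
  ci1 <- conv_index(h, w, 1L, k = 5L, stride = 2L, pad = 2L)
  ci2 <- conv_index(ci1$Ho, ci1$Wo, C1, k = 5L, stride = 2L, pad = 2L)
  stride_total <- 4L
  level <- pyramid_level("P2", stride_total, h, w)
  stopifnot(level$rows == ci2$Ho, level$cols == ci2$Wo)
  pos <- generate_anchor_positions(level,
    spec = if (config$mode == "adaptive") config$spec else NULL)
  pos_idx <- pos$row + (pos$col - 1L) * level$rows
  anchors <- generate_anchors(pos,
    anchor_config(scales = config$anchor_scale,
                  aspect_ratios = config$aspect_ratios))
  params <- with_seed(seed, list(
    W1 = matrix(rnorm(25 * C1, 0, sqrt(2 / 25)), 25, C1),
    b1 = numeric(C1),
    W2 = matrix(rnorm(25 * C1 * C2, 0, sqrt(2 / (25 * C1))), 25 * C1, C2),
    b2 = numeric(C2),
    Wobj = matrix(rnorm(C2 * A, 0, 0.01), C2, A),
    bobj = rep(-2, A),          # low objectness prior
    Wreg = matrix(rnorm(C2 * 4 * A, 0, 0.01), C2, 4 * A),
    breg = numeric(4 * A),
    Whead = matrix(rnorm((C2 + 6) * (nc + 1), 0, 0.01), C2 + 6, nc + 1),
    bhead = numeric(nc + 1)))
  list(config = config, params = params, ci1 = ci1, ci2 = ci2,
       level = level, positions = pos, pos_idx = pos_idx, anchors = anchors,
       n_positions_standard = level$rows * level$cols)
}

backbone_forward <- function(model, X) {
  p <- model$params
  c1 <- conv_forward(array(X, c(dim(X), 1L)), model$ci1, p$W1, p$b1)
  A1 <- relu(c1$Z)
  c2 <- conv_forward(array(A1, c(model$ci1$Ho, model$ci1$Wo,
                                 model$config$channels[1])),
                     model$ci2, p$W2, p$b2)
  A2 <- relu(c2$Z)                       # N2 x C2
  list(cols1 = c1$cols, Z1 = c1$Z, A1 = A1,
       cols2 = c2$cols, Z2 = c2$Z, A2 = A2)
}

decode_boxes <- function(anchors, t) {
  aw <- anchors[, 3] - anchors[, 1]
  ah <- anchors[, 4] - anchors[, 2]
  acx <- (anchors[, 1] + anchors[, 3]) / 2
  acy <- (anchors[, 2] + anchors[, 4]) / 2
  cx <- acx + t[, 1] * aw
  cy <- acy + t[, 2] * ah
  w <- aw * exp(pmin(pmax(t[, 3], -4), 4))
  h <- ah * exp(pmin(pmax(t[, 4], -4), 4))
  cbind(x_min = cx - w / 2, y_min = cy - h / 2,
        x_max = cx + w / 2, y_max = cy + h / 2)
}

encode_box <- function(anchor, gt) {
  aw <- anchor[3] - anchor[1]; ah <- anchor[4] - anchor[2]
  acx <- (anchor[1] + anchor[3]) / 2; acy <- (anchor[2] + anchor[4]) / 2
  gw <- gt[3] - gt[1]; gh <- gt[4] - gt[2]
  gcx <- (gt[1] + gt[3]) / 2; gcy <- (gt[2] + gt[4]) / 2
  c((gcx - acx) / aw, (gcy - acy) / ah, log(gw / aw), log(gh / ah))
}

iou_one_many <- function(box, mat) {
  ix <- pmax(0, pmin(box[3], mat[, 3]) - pmax(box[1], mat[, 1]))
  iy <- pmax(0, pmin(box[4], mat[, 4]) - pmax(box[2], mat[, 2]))
  inter <- ix * iy
  a <- max(0, box[3] - box[1]) * max(0, box[4] - box[2])
  b <- pmax(0, mat[, 3] - mat[, 1]) * pmax(0, mat[, 4] - mat[, 2])
  un <- a + b - inter
  ifelse(un > 0, inter / un, 0)
}

# pooled conv features of a box, augmented with its normalized geometry
# (centre and size); the diaphyseal third that drives the treatment class is
# a function of axial position, which pooled local features cannot encode.
roi_features <- function(model, A2mat, box) {
  cells <- roi_cells(model, box)
  f <- colMeans(A2mat[model$pos_idx[cells], , drop = FALSE])
  h <- model$config$input_size[1]; w <- model$config$input_size[2]
  cxn <- (box[1] + box[3]) / 2 / w; cyn <- (box[2] + box[4]) / 2 / h
  # quadratic centre terms let the linear head separate mid-shaft boxes from
  # the two extremes (proximal/distal), which no linear function of the
  # centre alone can do
  geom <- c(cxn, cyn, (box[3] - box[1]) / w, (box[4] - box[2]) / h,
            4 * (cxn - 0.5)^2, 4 * (cyn - 0.5)^2)
  list(f = c(f, geom), cells = cells)
}

roi_cells <- function(model, box) {
  pos <- model$positions
  inside <- pos$cx >= box[1] & pos$cx < box[3] &
            pos$cy >= box[2] & pos$cy < box[4]
  cells <- which(inside)
  if (!length(cells)) {
    bx <- (box[1] + box[3]) / 2; by <- (box[2] + box[4]) / 2
    cells <- which.min((pos$cx - bx)^2 + (pos$cy - by)^2)
  }
  cells
}

# One image: forward pass, loss, and (optionally) parameter gradients.
detector_step <- function(model, X, gt_box, gt_label, rng,
                          compute_grads = TRUE, n_neg = 32L, n_bg = 2L) {
  p <- model$params
  cfg <- model$config
  A <- length(cfg$aspect_ratios)
  fb <- backbone_forward(model, X)
  Fk <- fb$A2[model$pos_idx, , drop = FALSE]    # kept positions x C2
  O <- Fk %*% p$Wobj + rep(p$bobj, each = nrow(Fk))       # nk x A
  Tm <- Fk %*% p$Wreg + rep(p$breg, each = nrow(Fk))      # nk x 4A
  nk <- nrow(Fk)
  M <- nk * A
  # anchor ai = (pos-1)*A + a ordering matches generate_anchors()
  ious <- iou_one_many(gt_box, model$anchors)
  pos_a <- ious >= 0.7
  pos_a[which.max(ious)] <- TRUE
  neg_a <- ious <= 0.3 & !pos_a
  neg_pool <- which(neg_a)
  Ovec_all <- as.numeric(t(O))
  ns <- min(n_neg, length(neg_pool))
  neg_s <- integer(0)
  if (ns > 0) {
    # half hard negatives (highest current objectness), half random
    nh <- ns %/% 2
    hard <- neg_pool[order(-Ovec_all[neg_pool])][seq_len(nh)]
    rnd <- neg_pool[vapply(seq_len(ns - nh), function(i)
      rng$int(length(neg_pool)), integer(1))]
    neg_s <- unique(c(hard, rnd))
  }
  samp <- c(which(pos_a), neg_s)
  y <- c(rep(1, sum(pos_a)), rep(0, length(neg_s)))
  o_s <- Ovec_all[samp]                          # anchor-major: ai index
  # balance the two arms: few positive anchors must not be drowned out
  np <- sum(y == 1); nn <- sum(y == 0)
  arm_w <- ifelse(y == 1, 0.5 / max(1, np), 0.5 / max(1, nn))
  obj_loss <- sum(arm_w * bce_with_logits(o_s, y))
  # box regression on positive anchors
  pos_idx_a <- which(pos_a)
  tgt <- t(vapply(pos_idx_a, function(ai)
    encode_box(model$anchors[ai, ], gt_box), numeric(4)))
  Tvec <- matrix(as.numeric(t(Tm)), ncol = 4, byrow = TRUE)  # M x 4
  res <- Tvec[pos_idx_a, , drop = FALSE] - tgt
  reg_loss <- mean(rowSums(smooth_l1(res)))
  # classification head: ground-truth ROI + random background ROIs
  rois <- list(list(box = gt_box, label = gt_label))
  h <- cfg$input_size[1]; w <- cfg$input_size[2]
  for (b in seq_len(n_bg)) {
    for (try in 1:10) {
      bw <- 16 + rng$unif(0, 24); bh <- 16 + rng$unif(0, 24)
      bx <- rng$unif(0, w - bw); by <- rng$unif(0, h - bh)
      cand <- c(bx, by, bx + bw, by + bh)
      if (iou(cand, gt_box) < 0.1) { rois <- c(rois, list(list(
        box = cand, label = cfg$n_classes + 1L))); break }
    }
  }
  wts <- if (is.null(cfg$weights)) rep(1, cfg$n_classes + 1L)
         else c(cfg$weights$weight, 1)
  cls_loss <- 0
  head_grads <- list()
  for (r in rois) {
    rf <- roi_features(model, fb$A2, r$box)
    z <- as.numeric(rf$f %*% p$Whead + p$bhead)
    pr <- softmax_row(z)
    cls_loss <- cls_loss + wts[r$label] * -log(max(pr[r$label], 1e-12))
    if (compute_grads) {
      dz <- wts[r$label] * pr
      dz[r$label] <- dz[r$label] - wts[r$label]
      head_grads <- c(head_grads,
                      list(list(cells = rf$cells, f = rf$f, dz = dz)))
    }
  }
  cls_loss <- cls_loss / length(rois)
  total <- obj_loss + reg_loss + cls_loss
  out <- list(loss = total, objectness = obj_loss, box_regression = reg_loss,
              classification = cls_loss)
  if (!compute_grads) return(out)

  grads <- lapply(p, function(x) x * 0)
  dFmat <- matrix(0, nrow(fb$A2), ncol(fb$A2))   # all positions x C2
  # objectness gradients
  dO <- matrix(0, nk, A)
  dvec <- arm_w * (sigmoid(o_s) - y)
  ai <- samp
  pos_of <- ((ai - 1L) %/% A) + 1L
  a_of <- ((ai - 1L) %% A) + 1L
  for (i in seq_along(ai)) dO[pos_of[i], a_of[i]] <-
    dO[pos_of[i], a_of[i]] + dvec[i]
  grads$Wobj <- crossprod(Fk, dO)
  grads$bobj <- colSums(dO)
  dFk <- dO %*% t(p$Wobj)
  # regression gradients
  dT <- matrix(0, nk, 4L * A)
  dres <- smooth_l1_grad(res) / max(1, length(pos_idx_a))
  for (i in seq_along(pos_idx_a)) {
    ai <- pos_idx_a[i]
    pp <- ((ai - 1L) %/% A) + 1L
    aa <- ((ai - 1L) %% A) + 1L
    dT[pp, (aa - 1L) * 4L + 1:4] <- dT[pp, (aa - 1L) * 4L + 1:4] + dres[i, ]
  }
  grads$Wreg <- crossprod(Fk, dT)
  grads$breg <- colSums(dT)
  dFk <- dFk + dT %*% t(p$Wreg)
  dFmat[model$pos_idx, ] <- dFmat[model$pos_idx, ] + dFk
  # head gradients
  C2 <- ncol(fb$A2)
  for (g in head_grads) {
    grads$Whead <- grads$Whead + outer(g$f, g$dz) / length(rois)
    grads$bhead <- grads$bhead + g$dz / length(rois)
    df <- as.numeric(p$Whead[seq_len(C2), ] %*% g$dz) / length(rois)
    idx <- model$pos_idx[g$cells]
    dFmat[idx, ] <- dFmat[idx, ] +
      matrix(df, length(idx), C2, byrow = TRUE) / length(g$cells)
  }
  # through conv2
  dZ2 <- dFmat * (fb$Z2 > 0)
  bb2 <- conv_backward(dZ2, fb$cols2, model$ci2, p$W2, need_dx = TRUE)
  grads$W2 <- bb2$dW; grads$b2 <- bb2$db
  dA1 <- matrix(bb2$dX, nrow(fb$A1), ncol(fb$A1))
  dZ1 <- dA1 * (fb$Z1 > 0)
  bb1 <- conv_backward(dZ1, fb$cols1, model$ci1, p$W1, need_dx = FALSE)
  grads$W1 <- bb1$dW; grads$b1 <- bb1$db
  out$grads <- grads
  out
}

#' Train the toy detector on a synthetic dataset
#'
#' Runs SGD with momentum and weight decay over the dataset for the given
#' number of epochs, one image per step, with the learning rate following
#' [lr_at()] per epoch. Images are brightness-normalized ([brightness_normalize()])
#' and resized to the configured input size; in adaptive mode the RPN scores
#' only the restricted anchor-position set. The whole run is reproducible
#' from `seed`.
#'
#' The default toy schedule uses a larger base rate (0.05) than the
#' full-scale default: with a two-layer backbone, a few dozen images, and a
#' handful of epochs, the full-scale rate of 0.001 barely moves the weights.
#'
#' @param dataset A `synthetic_dataset` from [make_dataset()] (or a list
#'   with `images` and `annotations` of the same shape).
#' @param config A [detector_config()].
#' @param epochs Number of passes over the data.
#' @param seed Integer seed.
#' @param schedule An [optimizer_schedule()].
#' @param head_lr_mult Learning-rate multiplier for the classification head
#'   (the head's geometry features are small relative to pooled activations
#'   and learn slowly at the shared rate).
#' @return A `toy_detector`: the trained model with `loss_trace` (per-epoch
#'   mean loss), per-term traces, and the position accounting
#'   (`n_positions`, `n_positions_standard`).
#' @export
train_toy <- function(dataset, config = detector_config(), epochs = 20,
                      seed = 1L,
                      schedule = optimizer_schedule(base_lr = 0.01),
                      head_lr_mult = 5) {
  if (length(dataset$images) == 0) stop("empty dataset", call. = FALSE)
  model <- new_detector(config, seed = seed)
  imgs <- lapply(dataset$images, function(im) {
    im <- brightness_normalize(im)
    if (!all(dim(im) == config$input_size))
      im <- resize_bilinear(im, config$input_size[1], config$input_size[2])
    im
  })
  ann <- dataset$annotations
  # per-image ground truth (one box per phantom), rescaled if input resized
  gt <- lapply(seq_along(imgs), function(i) {
    a <- ann[ann$image_id == i, , drop = FALSE][1, ]
    src <- dim(dataset$images[[i]])
    sx <- config$input_size[2] / src[2]; sy <- config$input_size[1] / src[1]
    list(box = c(a$x_min * sx, a$y_min * sy, a$x_max * sx, a$y_max * sy),
         label = a$label)
  })
  n <- length(imgs)
  vel <- lapply(model$params, function(x) x * 0)
  rng <- local_rng(seed + 7L)
  trace <- numeric(epochs)
  terms <- matrix(0, epochs, 3,
                  dimnames = list(NULL, c("objectness", "box_regression",
                                          "classification")))
  order_rng <- local_rng(seed + 13L)
  for (ep in seq_len(epochs)) {
    lr <- lr_at(ep - 1L, schedule)
    ord <- order(vapply(seq_len(n), function(i) order_rng$unif(), numeric(1)))
    losses <- numeric(n)
    tsum <- c(0, 0, 0)
    for (i in ord) {
      st <- detector_step(model, imgs[[i]], gt[[i]]$box, gt[[i]]$label, rng)
      losses[i] <- st$loss
      tsum <- tsum + c(st$objectness, st$box_regression, st$classification)
      for (nm in names(model$params)) {
        lm <- if (nm %in% c("Whead", "bhead")) head_lr_mult else 1
        g <- st$grads[[nm]] + schedule$weight_decay * model$params[[nm]]
        vel[[nm]] <- schedule$momentum * vel[[nm]] - lr * lm * g
        model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
      }
    }
    trace[ep] <- mean(losses)
    terms[ep, ] <- tsum / n
  }
  structure(list(model = model, config = config, loss_trace = trace,
                 term_trace = terms,
                 n_positions = nrow(model$positions),
                 n_positions_standard = model$n_positions_standard,
                 epochs = epochs, seed = seed, schedule = schedule),
            class = "toy_detector")
}

#' @export
print.toy_detector <- function(x, ...) {
  cat(sprintf(
    "Toy two-stage detector (%s anchoring: %d/%d RPN positions)\n",
    x$config$mode, x$n_positions, x$n_positions_standard))
  cat(sprintf("  %d epochs, loss %.3f -> %.3f\n", x$epochs,
              x$loss_trace[1], x$loss_trace[x$epochs]))
  invisible(x)
}

#' Non-maximum suppression
#'
#' Greedy suppression: keep the highest-scoring box, drop boxes overlapping
#' it above the IoU threshold, repeat.
#'
#' @param boxes Matrix of corner-format boxes.
#' @param scores Numeric scores.
#' @param iou_threshold Suppression threshold.
#' @return Integer indices of surviving boxes, in descending score order.
#' @export
nms <- function(boxes, scores, iou_threshold = 0.5) {
  ord <- order(-scores, seq_along(scores))
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1) break
    rest <- ord[-1]
    ious <- iou_one_many(boxes[i, ], boxes[rest, , drop = FALSE])
    ord <- rest[ious <= iou_threshold]
  }
  keep
}

#' Detect fractures in an image
#'
#' Forward pass of the trained toy detector: objectness scores at the RPN
#' positions, box decoding from the anchors, score thresholding,
#' non-maximum suppression, and classification of each surviving box by the
#' head. Deterministic for a fixed model and image.
#'
#' @param object A `toy_detector`.
#' @param image Numeric image matrix (resized/normalized internally).
#' @param score_threshold Minimum objectness (sigmoid) score; defaults to
#'   the configured value.
#' @param nms_iou NMS threshold; defaults to the configured value.
#' @param max_detections Cap on returned detections.
#' @param ... Unused.
#' @return A data frame (`detection_set`): columns `x_min`, `y_min`,
#'   `x_max`, `y_max`, `label`, `class`, `score`, sorted by descending
#'   score; zero rows when nothing clears the threshold.
#' @export
predict.toy_detector <- function(object, image,
                                 score_threshold = NULL, nms_iou = NULL,
                                 max_detections = 20L, ...) {
  model <- object$model
  cfg <- object$config
  score_threshold <- score_threshold %||% cfg$score_threshold
  nms_iou <- nms_iou %||% cfg$nms_iou
  im <- brightness_normalize(image)
  if (!all(dim(im) == cfg$input_size))
    im <- resize_bilinear(im, cfg$input_size[1], cfg$input_size[2])
  p <- model$params
  fb <- backbone_forward(model, im)
  Fk <- fb$A2[model$pos_idx, , drop = FALSE]
  O <- Fk %*% p$Wobj + rep(p$bobj, each = nrow(Fk))
  Tm <- Fk %*% p$Wreg + rep(p$breg, each = nrow(Fk))
  A <- length(cfg$aspect_ratios)
  scores <- sigmoid(as.numeric(t(O)))
  Tvec <- matrix(as.numeric(t(Tm)), ncol = 4, byrow = TRUE)
  sel <- which(scores > score_threshold)
  empty <- data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      label = integer(0), class = character(0),
                      score = numeric(0))
  if (!length(sel)) return(structure(empty, class = c("detection_set",
                                                      "data.frame")))
  boxes <- decode_boxes(model$anchors[sel, , drop = FALSE],
                        Tvec[sel, , drop = FALSE])
  boxes <- t(apply(boxes, 1, clip_box,
                   w = cfg$input_size[2], h = cfg$input_size[1]))
  ok <- boxes[, 3] > boxes[, 1] & boxes[, 4] > boxes[, 2]
  sel <- sel[ok]; boxes <- boxes[ok, , drop = FALSE]
  if (!length(sel)) return(structure(empty, class = c("detection_set",
                                                      "data.frame")))
  keep <- nms(boxes, scores[sel], nms_iou)
  keep <- head(keep, max_detections)
  boxes <- boxes[keep, , drop = FALSE]
  sc <- scores[sel][keep]
  labels <- integer(nrow(boxes)); probs <- numeric(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    rf <- roi_features(model, fb$A2, boxes[i, ])
    pr <- softmax_row(as.numeric(rf$f %*% p$Whead + p$bhead))
    labels[i] <- which.max(pr[seq_len(cfg$n_classes)])
    probs[i] <- pr[labels[i]]
  }
  # final confidence combines RPN objectness with the head's class belief
  out <- data.frame(x_min = boxes[, 1], y_min = boxes[, 2],
                    x_max = boxes[, 3], y_max = boxes[, 4],
                    label = labels,
                    class = c("I", "II", "III", "IV")[labels],
                    score = sc * probs, objectness = sc,
                    class_prob = probs)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("detection_set", "data.frame"))
}

#' Evaluate a trained toy detector on a dataset
#'
#' Runs [predict()] over every image (at a permissive score threshold so the
#' precision-recall sweep has a ranked list to work with) and computes the
#' average precision against the dataset's ground truth.
#'
#' @param detector A `toy_detector`.
#' @param dataset A `synthetic_dataset`.
#' @param iou_threshold Matching threshold.
#' @param score_threshold Detection score floor used for the ranked list.
#' @return List with `ap`, `ap_result`, `detections`, `truths`, and the
#'   [precision_recall_f1()] report at the configured operating threshold.
#' @export
evaluate_detector <- function(detector, dataset, iou_threshold = 0.5,
                              score_threshold = 0.1) {
  dets <- list()
  for (i in seq_along(dataset$images)) {
    d <- predict(detector, dataset$images[[i]],
                 score_threshold = score_threshold)
    if (nrow(d)) { d$image_id <- i; dets <- c(dets, list(d)) }
  }
  dets <- if (length(dets)) do.call(rbind, dets) else
    data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
               y_max = numeric(0), label = integer(0), score = numeric(0),
               image_id = integer(0))
  truths <- dataset$annotations
  # ground truth lives in source-image coordinates; predictions are in the
  # configured input frame
  src <- dim(dataset$images[[1]])
  cfg <- detector$config
  sx <- cfg$input_size[2] / src[2]; sy <- cfg$input_size[1] / src[1]
  truths <- transform(truths, x_min = x_min * sx, x_max = x_max * sx,
                      y_min = y_min * sy, y_max = y_max * sy)
  apr <- average_precision(dets, truths, iou_threshold)
  op <- dets[dets$score > cfg$score_threshold, , drop = FALSE]
  rep <- precision_recall_f1(match_detections(op, truths, iou_threshold))
  list(ap = apr$ap, ap_result = apr, detections = dets, truths = truths,
       report = rep)
}
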