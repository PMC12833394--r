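#' Grad-CAM context
#'
#' Bundle of the quantities Grad-CAM needs at the target convolutional
#' layer: the feature-map activations, the gradient of the class score with
#' respect to them, and the score itself. `Z`, the normalization factor, is
#' the number of spatial positions per channel.
#'
#' @param activations Numeric H x W x K array of feature maps.
#' @param gradients Numeric array of the same shape: `d y_c / d A`.
#' @param class_score The scalar class score `y_c` (pre-softmax).
#' @return A `gradcam_context` object with `Z = H * W`.
#' @export
gradcam_context <- function(activations, gradients, class_score = NA_real_) {
  if (length(dim(activations)) == 2L)
    activations <- array(activations, c(dim(activations), 1L))
  if (length(dim(gradients)) == 2L)
    gradients <- array(gradients, c(dim(gradients), 1L))
  if (!all(dim(activations) == dim(gradients)))
    stop("activations and gradients must be shape-identical", call. = FALSE)
  d <- dim(activations)
  structure(list(activations = activations, gradients = gradients,
                 class_score = class_score, Z = d[1] * d[2]),
            class = "gradcam_context")
}

#' Grad-CAM channel weights
#'
#' The weight of each feature channel is the global average of the class
#' score's gradient over that channel's spatial positions:
#' `alpha_k = (1/Z) * sum_ij dy_c/dA_ijk`.
#'
#' @param ctx A [gradcam_context()].
#' @return Numeric vector of per-channel weights.
#' @examples
#' a <- array(1, c(2, 2, 1)); g <- array(c(1, 3, 2, 4), c(2, 2, 1))
#' channel_weights(gradcam_context(a, g))  # 2.5
#' @export
channel_weights <- function(ctx) {
  stopifnot(inherits(ctx, "gradcam_context"))
  if (ctx$Z == 0) stop("empty feature map (Z = 0)", call. = FALSE)
  apply(ctx$gradients, 3, mean)
}

#' Grad-CAM heatmap from weights and activations
#'
#' Pointwise rectified weighted sum of the feature channels:
#' `ReLU(sum_k alpha_k A_k)`. The output is non-negative by construction and
#' has the feature map's spatial size.
#'
#' @param weights Per-channel weights (one per activation channel).
#' @param activations H x W x K activation array (a matrix is treated as a
#'   single channel).
#' @return Numeric H x W matrix with class `heatmap`.
#' @export
gradcam_map <- function(weights, activations) {
  if (length(dim(activations)) == 2L)
    activations <- array(activations, c(dim(activations), 1L))
  K <- dim(activations)[3]
  if (length(weights) != K)
    stop(sprintf("got %d weights for %d channels", length(weights), K),
         call. = FALSE)
  d <- dim(activations)
  m <- matrix(0, d[1], d[2])
  for (k in seq_len(K)) m <- m + weights[k] * activations[, , k]
  structure(pmax(m, 0), class = c("heatmap", "matrix", "array"))
}

#' Overlay a heatmap on a grayscale image
#'
#' Bilinearly resizes the heatmap to the image size, min-max normalizes it,
#' maps it through a colour scale, and alpha-blends it over the image. At
#' opacity 0 the original image is returned unchanged (as RGB); an all-zero
#' heatmap yields the plain image with a warning.
#'
#' @param heatmap Non-negative matrix from [gradcam_map()].
#' @param image Grayscale image matrix.
#' @param opacity Blend factor in \[0, 1\].
#' @param palette Colour palette name passed to [grDevices::hcl.colors()].
#' @return H x W x 3 numeric array (RGB in \[0, 1\]).
#' @export
overlay <- function(heatmap, image, opacity = 0.4, palette = "Inferno") {
  stopifnot(opacity >= 0, opacity <= 1)
  image <- as_pixel_matrix(image)
  h <- nrow(image); w <- ncol(image)
  gray <- array(rep(pmin(pmax(image, 0), 1), 3), c(h, w, 3))
  if (opacity == 0) return(gray)
  if (all(heatmap == 0)) {
    warning("all-zero heatmap; returning the plain image")
    return(gray)
  }
  hm <- resize_bilinear(unclass(heatmap), h, w)
  hm <- (hm - min(hm)) / (max(hm) - min(hm))
  cols <- grDevices::hcl.colors(256, palette)
  rgb <- grDevices::col2rgb(cols) / 255
  idx <- pmin(pmax(floor(hm * 255) + 1L, 1L), 256L)
  heat <- array(0, c(h, w, 3))
  for (ch in 1:3) heat[, , ch] <- matrix(rgb[ch, idx], h, w)
  (1 - opacity) * gray + opacity * heat
}

#' Grad-CAM explanation of a detector decision
#'
#' Computes the Grad-CAM heatmap at the last convolutional layer of the toy
#' backbone for a chosen detection. The class score is the pre-softmax head
#' logit of the selected box's class; its gradient with respect to the
#' feature maps flows through the ROI mean-pooling, so only the pooled
#' cells carry gradient mass, and the channel weights are their global
#' spatial average.
#'
#' @param detector A trained `toy_detector`.
#' @param image Image matrix.
#' @param box Corner-format box to explain; `NULL` takes the top detection
#'   (error if there is none).
#' @param class Integer class index for the score; `NULL` takes the head's
#'   argmax over fracture classes for the box.
#' @return List with `heatmap`, `context` (a [gradcam_context()]), `box`,
#'   `class`, `class_score`.
#' @export
detector_gradcam <- function(detector, image, box = NULL, class = NULL) {
  model <- detector$model
  cfg <- detector$config
  im <- brightness_normalize(image)
  if (!all(dim(im) == cfg$input_size))
    im <- resize_bilinear(im, cfg$input_size[1], cfg$input_size[2])
  if (is.null(box)) {
    d <- predict(detector, image, score_threshold = 0.1)
    if (!nrow(d)) stop("no detection to explain", call. = FALSE)
    box <- as.numeric(d[1, c("x_min", "y_min", "x_max", "y_max")])
    if (is.null(class)) class <- d$label[1]
  }
  fb <- backbone_forward(model, im)
  rows <- model$level$rows; cols <- model$level$cols
  A2 <- array(fb$A2, c(rows, cols, cfg$channels[2]))
  rf <- roi_features(model, fb$A2, box)
  idx <- model$pos_idx[rf$cells]
  z <- as.numeric(rf$f %*% model$params$Whead + model$params$bhead)
  if (is.null(class)) class <- which.max(z[seq_len(cfg$n_classes)])
  # only the pooled convolutional part of the head carries gradient to A
  grad_mat <- matrix(0, rows * cols, cfg$channels[2])
  grad_mat[idx, ] <- matrix(model$params$Whead[seq_len(cfg$channels[2]), class],
                            length(idx), cfg$channels[2],
                            byrow = TRUE) / length(idx)
  G <- array(grad_mat, c(rows, cols, cfg$channels[2]))
  ctx <- gradcam_context(A2, G, class_score = z[class])
  wts <- channel_weights(ctx)
  hm <- gradcam_map(wts, A2)
  list(heatmap = hm, context = ctx, box = box, class = class,
       class_score = z[class])
}

#' Label/image randomization sanity check
#'
#' Trains the toy detector twice from scratch — once on the intact training
#' data, once on a corrupted copy in which ground-truth labels are randomly
#' permuted and the images are replaced by intensity-matched Gaussian noise —
#' and evaluates both on the same intact held-out split. A model whose
#' performance stems from genuine image-label associations collapses to
#' near-chance average precision on the corrupted run; a corrupted-run AP at
#' or below half the intact AP is reported as a pass.
#'
#' @param dataset A `synthetic_dataset` with at least two classes.
#' @param config A [detector_config()].
#' @param epochs Training epochs for each arm.
#' @param seed Integer seed driving the split, the permutation, the noise,
#'   and both training runs.
#' @param train_fraction Fraction of images used for training.
#' @param permute `TRUE` for the corruption arm; `FALSE` runs the identity
#'   control (no permutation, no noise), in which no degradation is
#'   expected.
#' @param train_fn Training function, by default [train_toy()]; must accept
#'   `(dataset, config, epochs, seed)`.
#' @return A `randomization_report` list: `ap_intact`, `ap_corrupted`,
#'   `degradation_ratio` (corrupted / intact), `pass`
#'   (ratio at or below 0.5), and the two evaluation objects.
#' @export
randomization_check <- function(dataset, config = detector_config(),
                                epochs = 12, seed = 1L,
                                train_fraction = 0.7, permute = TRUE,
                                train_fn = train_toy) {
  labs <- dataset$index$class_label
  if (length(unique(labs)) < 2)
    stop("randomization check needs at least 2 classes", call. = FALSE)
  n <- length(dataset$images)
  split <- stratified_split(labs, c(train_fraction, 0, 1 - train_fraction),
                            seed = seed)
  tr_idx <- split$train; te_idx <- split$test
  subset_ds <- function(ds, idx) {
    ann <- ds$annotations[ds$annotations$image_id %in% idx, , drop = FALSE]
    ann$image_id <- match(ann$image_id, idx)
    list(images = ds$images[idx], annotations = ann,
         index = transform(ds$index[idx, ], image_id = seq_along(idx)),
         image_size = ds$image_size)
  }
  train_ds <- subset_ds(dataset, tr_idx)
  test_ds <- subset_ds(dataset, te_idx)

  intact <- train_fn(train_ds, config, epochs = epochs, seed = seed)
  ev_intact <- evaluate_detector(intact, test_ds)

  corr_ds <- train_ds
  if (permute) {
    with_seed(seed + 1L, {
      perm <- sample.int(nrow(corr_ds$annotations))
      corr_ds$annotations$label <- corr_ds$annotations$label[perm]
      corr_ds$annotations$class <- corr_ds$annotations$class[perm]
      corr_ds$images <- lapply(corr_ds$images, function(im) {
        pmin(pmax(matrix(rnorm(length(im), mean(im), stats::sd(im)),
                         nrow(im), ncol(im)), 0), 1)
      })
    })
  }
  corrupted <- train_fn(corr_ds, config, epochs = epochs, seed = seed)
  ev_corr <- evaluate_detector(corrupted, test_ds)

  ratio <- if (ev_intact$ap > 0) ev_corr$ap / ev_intact$ap else NA_real_
  structure(list(ap_intact = ev_intact$ap, ap_corrupted = ev_corr$ap,
                 degradation_ratio = ratio,
                 pass = isTRUE(ratio <= 0.5) ||
                        (ev_intact$ap > 0 && ev_corr$ap == 0),
                 permuted = permute,
                 eval_intact = ev_intact, eval_corrupted = ev_corr),
            class = "randomization_report")
}

#' @export
print.randomization_report <- function(x, ...) {
  cat(sprintf(
    "Randomization check (%s): intact AP %.3f, corrupted AP %.3f (ratio %.2f) -> %s\n",
    if (x$permuted) "labels permuted + noise images" else "identity control",
    x$ap_intact, x$ap_corrupted, x$degradation_ratio,
    if (x$pass) "degraded as expected" else "no collapse"))
  invisible(x)
}

#' Fraction of heatmap mass inside ground-truth boxes
#'
#' Diagnostic for saliency localization: the mean Grad-CAM intensity inside
#' the ground-truth box divided by the mean intensity outside it (values
#' above 1 mean the explanation concentrates on the fracture).
#'
#' @param heatmap Heatmap matrix (feature-map or image scale).
#' @param box Ground-truth box in the same coordinate frame as `ref_size`.
#' @param ref_size `c(height, width)` of the frame the box lives in.
#' @return List with `inside_mean`, `outside_mean`, `ratio`.
#' @export
heatmap_concentration <- function(heatmap, box, ref_size) {
  hm <- resize_bilinear(unclass(heatmap), ref_size[1], ref_size[2])
  xs <- matrix(rep(seq_len(ref_size[2]) - 0.5, each = ref_size[1]),
               ref_size[1], ref_size[2])
  ys <- matrix(rep(seq_len(ref_size[1]) - 0.5, times = ref_size[2]),
               ref_size[1], ref_size[2])
  inside <- xs >= box[1] & xs < box[3] & ys >= box[2] & ys < box[4]
  im <- mean(hm[inside]); om <- mean(hm[!inside])
  list(inside_mean = im, outside_mean = om,
       ratio = if (om > 0) im / om else Inf)
}
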